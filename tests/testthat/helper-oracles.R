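# Naive O(n^2) computation of Rao's U that never sorts: each point's
# neighbour arc is the smallest clockwise distance to any other point.
# Duplicate values are ordered by index so that exactly one member of a
# group of ties carries the arc to the next distinct value (and a fully
# coincident sample gives one arc of 2*pi).
naive_rao_u <- function(x) {
  n <- length(x)
  arcs <- numeric(n)
  for (i in seq_len(n)) {
    gaps <- vapply(seq_len(n)[-i], function(j) {
      d <- (x[j] - x[i]) %% (2 * pi)
      if (x[j] == x[i] && j < i) 2 * pi else d
    }, numeric(1))
    arcs[i] <- min(gaps)
  }
  0.5 * sum(abs(arcs - 2 * pi / n))
}

# Exact null tail probability P(U >= u0) for rounded uniform samples:
# enumerate all n_bins^n equally likely bin assignments.
enumerate_discrete_tail <- function(n, n_bins, u0) {
  width <- 2 * pi / n_bins
  grids <- rep(list(seq_len(n_bins) - 1L), n)
  combos <- as.matrix(expand.grid(grids))
  u <- apply(combos, 1, function(bins) rao_u(angle_sample(bins * width)))
  mean(u >= u0)
}

# Circular summaries used by the sampler tests.
mean_resultant_length <- function(x) {
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}
mean_direction <- function(x) {
  atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)
}
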