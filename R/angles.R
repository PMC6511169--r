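#' Validated circular sample
#'
#' Construct an `angle_sample`: a sorted numeric vector of angles in radians
#' on `[0, 2*pi)`. Input may be given in radians or degrees; degrees are
#' converted on entry and the original unit is kept as provenance. Accepted
#' input ranges are deliberately narrow -- `[-4*pi, 6*pi)` radians or
#' `[-720, 1080)` degrees -- so that unit mistakes (e.g. degrees passed as
#' radians) are caught instead of silently wrapped away.
#'
#' Ties are legal and preserved: rounded or grouped angle data naturally
#' contains ties, and the spacing statistic is defined for them (a tie gives
#' a zero arc).
#'
#' @param x numeric vector of angles.
#' @param unit `"radians"` or `"degrees"`. No automatic detection is
#'   attempted: a value such as 350 is valid in either unit.
#' @return An object of class `angle_sample`: the sorted angles in radians,
#'   with attributes `source_unit` and `n`.
#' @examples
#' angle_sample(c(370, 10, -20), unit = "degrees")
#' angle_sample(c(0, pi / 2, pi, 3 * pi / 2))
#' @export
angle_sample <- function(x, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  if (length(x) == 0L) stop("empty input: at least two angles are required")
  if (!is.numeric(x)) stop("angles must be numeric")
  if (anyNA(x) || any(!is.finite(x))) {
    stop("angles must be finite and non-missing")
  }
  lo <- if (unit == "radians") -4 * pi else -720
  hi <- if (unit == "radians") 6 * pi else 1080
  bad <- which(x < lo | x >= hi)
  if (length(bad) > 0L) {
    stop(sprintf(
      "angle %.6g (position %d) outside the accepted %s range [%g, %g)",
      x[bad[1]], bad[1], unit, lo, hi
    ))
  }
  if (length(x) < 2L) stop("sample size must be at least 2")
  values <- if (unit == "degrees") x * pi / 180 else x
  values <- sort(wrap_radians(values))
  structure(values,
    source_unit = unit, n = length(values),
    class = "angle_sample"
  )
}

#' @rdname angle_sample
#' @export
is_angle_sample <- function(x) inherits(x, "angle_sample")

# Reduce angles modulo 2*pi into [0, 2*pi). %% already maps negatives into
# the positive range; the extra guard handles values that floating-point
# rounding leaves at exactly 2*pi.
wrap_radians <- function(x) {
  x <- x %% (2 * pi)
  x[x >= 2 * pi] <- 0
  x
}

# Coerce raw numerics leniently where a function accepts either form.
as_angle_sample <- function(x, unit = "radians") {
  if (is_angle_sample(x)) x else angle_sample(x, unit = unit)
}

#' @export
print.angle_sample <- function(x, ...) {
  cat(sprintf(
    "Circular sample: n = %d angles (radians, sorted; entered in %s)\n",
    length(x), attr(x, "source_unit")
  ))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Circular spacings (neighbour arc lengths)
#'
#' The n arcs between consecutive ordered angles, including the wrap-around
#' arc from the largest angle back to the smallest across 0. The arcs always
#' sum to `2*pi`; ties produce zero arcs.
#'
#' @param sample an [angle_sample], or a numeric vector of radians.
#' @return Numeric vector of n arc lengths in radians.
#' @examples
#' spacings(angle_sample(c(0, pi / 2, pi, 3 * pi / 2)))
#' @export
spacings <- function(sample) {
  x <- as_angle_sample(sample)
  n <- length(x)
  c(diff(as.numeric(x)), 2 * pi - x[[n]] + x[[1]])
}

#' Rao's spacing statistic
#'
#' Under uniformity the n neighbour arcs all have expectation `2*pi/n`;
#' Rao's statistic is half the summed absolute deviation from that
#' expectation, `U = 0.5 * sum(|T_i - 2*pi/n|)`. It is zero exactly at
#' perfectly equal spacing and attains its maximum `2*pi*(n-1)/n` when all
#' points coincide.
#'
#' @param sample an [angle_sample], or a numeric vector of radians.
#' @param units `"radians"` (default) or `"degrees"` for the returned value.
#' @return The statistic U as a single number.
#' @examples
#' rao_u(angle_sample(c(0, pi / 2))) # pi/2
#' rao_u(angle_sample(c(10, 20, 200, 275, 350), unit = "degrees"),
#'   units = "degrees"
#' )
#' @export
rao_u <- function(sample, units = c("radians", "degrees")) {
  units <- match.arg(units)
  x <- as_angle_sample(sample)
  u <- cpp_rao_u(as.numeric(x))
  if (units == "degrees") u * 180 / pi else u
}

#' Read angles from a text or CSV file
#'
#' Reads one angle per line from plain text, or a column from a CSV file
#' (selected by name or index; a header line is detected automatically).
#' Parse failures are reported with their line number.
#'
#' @param path file path.
#' @param unit `"radians"` or `"degrees"`; passed to [angle_sample()].
#' @param column `NULL` for plain one-angle-per-line input, or a column
#'   name or 1-based index for CSV input.
#' @return An [angle_sample].
#' @export
read_angles <- function(path, unit = c("radians", "degrees"), column = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data in file: ", path)

  if (is.null(column) && !grepl(",", lines[1], fixed = TRUE)) {
    raw <- suppressWarnings(as.numeric(trimws(lines)))
    if (anyNA(raw)) {
      bad <- which(is.na(raw))[1]
      stop(sprintf(
        "cannot parse angle on line %d: '%s'", bad, trimws(lines[bad])
      ))
    }
    return(angle_sample(raw, unit = unit))
  }

  first_fields <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(trimws(first_fields))))
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        header = has_header, strip.white = TRUE)
  if (is.null(column)) column <- 1L
  if (is.character(column)) {
    if (!column %in% names(df)) {
      stop(sprintf(
        "column '%s' not found (columns: %s)",
        column, paste(names(df), collapse = ", ")
      ))
    }
    col <- df[[column]]
  } else {
    if (column < 1 || column > ncol(df)) {
      stop(sprintf("column index %d out of range (1..%d)", column, ncol(df)))
    }
    col <- df[[column]]
  }
  raw <- suppressWarnings(as.numeric(col))
  if (anyNA(raw)) {
    bad <- which(is.na(raw))[1]
    stop(sprintf(
      "cannot parse angle on line %d: '%s'",
      bad + has_header, as.character(col[bad])
    ))
  }
  angle_sample(raw, unit = unit)
}
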