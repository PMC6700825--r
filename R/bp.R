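#' Mean arterial pressure from a single reading
#'
#' MAP is the time-averaged arterial pressure over one cardiac cycle,
#' approximated from an oscillometric reading as
#' \eqn{(2 \cdot \mathrm{DBP} + \mathrm{SBP}) / 3}.
#'
#' @param systolic Systolic blood pressure (mmHg).
#' @param diastolic Diastolic blood pressure (mmHg). Must be strictly below
#'   the systolic value and strictly positive.
#' @return MAP in mmHg (vectorised).
#' @examples
#' map_from_reading(120, 90) # 100
#' @export
map_from_reading <- function(systolic, diastolic) {
  if (any(diastolic <= 0)) stop("diastolic pressure must be positive")
  if (any(systolic <= diastolic)) {
    stop("systolic pressure must exceed diastolic pressure")
  }
  (systolic + 2 * diastolic) / 3
}

#' Stability of two consecutive blood-pressure readings
#'
#' A pair of consecutive readings is stable when the variation is within
#' 10 mmHg systolic and 6 mmHg diastolic.
#'
#' @param prev,next_ Numeric length-2 vectors `c(systolic, diastolic)`.
#' @return `TRUE` when both variations are within bounds.
#' @export
is_stable <- function(prev, next_) {
  abs(next_[1] - prev[1]) <= 10 && abs(next_[2] - prev[2]) <= 6
}

#' Parse an encoded blood-pressure series
#'
#' Cohort files encode one arm's reading series as semicolon-separated
#' `"systolic/diastolic"` pairs, e.g. `"120/80;118/78"`.
#'
#' @param x A single series string.
#' @return A numeric matrix with columns `systolic`, `diastolic`, one row
#'   per reading in measurement order.
#' @export
parse_bp_series <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  vals <- lapply(parts, function(p) {
    sd <- suppressWarnings(as.numeric(strsplit(p, "/", fixed = TRUE)[[1]]))
    if (length(sd) != 2L || anyNA(sd)) {
      stop("malformed blood-pressure reading: '", p, "'")
    }
    sd
  })
  m <- do.call(rbind, vals)
  colnames(m) <- c("systolic", "diastolic")
  m
}

#' @rdname parse_bp_series
#' @param readings Numeric matrix as returned by [parse_bp_series()].
#' @export
format_bp_series <- function(readings) {
  paste(sprintf("%g/%g", readings[, 1], readings[, 2]), collapse = ";")
}

#' MAP of one arm from its reading series
#'
#' The arm MAP is the mean per-reading MAP of the last two readings of the
#' series (measurement continues until consecutive readings stabilise, so a
#' recorded series is expected to end on a stable pair). If the final pair
#' is not stable the MAP is still computed but flagged.
#'
#' @param readings Numeric matrix, one row per reading, columns
#'   systolic/diastolic; at least two rows.
#' @return List with elements `map` (mmHg) and `stable` (logical).
#' @export
arm_map <- function(readings) {
  if (!is.matrix(readings) || nrow(readings) < 2L) {
    stop("an arm MAP requires at least two readings")
  }
  n <- nrow(readings)
  last2 <- readings[c(n - 1L, n), , drop = FALSE]
  maps <- map_from_reading(last2[, 1], last2[, 2])
  stable <- is_stable(last2[1, ], last2[2, ])
  if (!stable) {
    warning("final reading pair is not stable (>10 mmHg systolic or >6 mmHg diastolic)")
  }
  list(map = mean(maps), stable = stable)
}

#' Final MAP from both arms
#'
#' Both arms are measured; the arm with the highest final MAP is used for
#' analysis. The stability flag is `TRUE` only when both arms ended on a
#' stable pair.
#'
#' @param left,right Reading matrices for the left and right arm.
#' @return An object of class `map_result`: list with `map_left`,
#'   `map_right`, `final_map` (all mmHg) and `stable`.
#' @export
final_map <- function(left, right) {
  l <- withCallingHandlers(arm_map(left), warning = function(w) invokeRestart("muffleWarning"))
  r <- withCallingHandlers(arm_map(right), warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(
      map_left = l$map, map_right = r$map,
      final_map = max(l$map, r$map),
      stable = l$stable && r$stable
    ),
    class = "map_result"
  )
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf(
    "MAP left %.2f / right %.2f mmHg -> final %.2f (%s)\n",
    x$map_left, x$map_right, x$final_map,
    if (x$stable) "stable" else "UNSTABLE"
  ))
  invisible(x)
}
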