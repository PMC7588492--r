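#' Base-2 radical-inverse (van der Corput) sequence
#'
#' Deterministic low-discrepancy fractions in `[0, 1)`. The i-th element is
#' the base-2 radical inverse of `i - 1`, so the sequence starts
#' 0, 1/2, 1/4, 3/4, 1/8, 5/8, ... Quasi-random points fill the unit
#' interval far more evenly than uniform random draws, which tend to form
#' clusters and leave gaps.
#'
#' @param n number of points.
#' @param offset optional rotation in `[0, 1)`; each fraction becomes
#'   `(u + offset) mod 1` (a Cranley-Patterson rotation), which preserves
#'   the low-discrepancy structure while randomising the point set.
#' @return numeric vector of length `n` in `[0, 1)`.
#' @export
#' @examples
#' radical_inverse(4) # 0 0.50 0.25 0.75
radical_inverse <- function(n, offset = 0) {
  stopifnot(n >= 0, offset >= 0, offset < 1)
  if (n == 0) return(numeric(0))
  u <- vapply(seq_len(n) - 1L, function(i) {
    x <- 0
    f <- 0.5
    while (i > 0L) {
      x <- x + f * (i %% 2L)
      i <- i %/% 2L
      f <- f / 2
    }
    x
  }, numeric(1))
  (u + offset) %% 1
}

#' Sample one quasi-random prediction point per admission
#'
#' Chooses, for every admission, a single time point inside its observation
#' window at which a prediction is scored -- the design used to compare a
#' continuously predicting model against human raters who each assess a
#' chart once. Low-discrepancy fractions (base-2 radical inverse with a
#' seed-derived rotation) spread the points evenly over the relative
#' observation time, so the sample cannot accidentally concentrate in, say,
#' the first half of every stay.
#'
#' @param windows data frame with columns `admission_id`, `start_h`,
#'   `end_h` (one row per admission). Rows are processed in `admission_id`
#'   order so the mapping from sequence element to admission is
#'   deterministic.
#' @param seed integer; rotates the sequence. `NULL` leaves it unrotated.
#' @param step_h grid spacing in hours (default 0.25 = 15 min).
#' @return tibble with `admission_id`, `frac` (the low-discrepancy
#'   fraction), `point_h` (absolute time of the sampled grid step) and
#'   `step` (0-based grid index).
#' @export
sample_prediction_points <- function(windows, seed = NULL, step_h = 0.25) {
  stopifnot(all(c("admission_id", "start_h", "end_h") %in% names(windows)))
  if (nrow(windows) == 0) abort("`windows` must contain at least one admission.")
  windows <- dplyr::arrange(windows, .data$admission_id)
  offset <- if (is.null(seed)) 0 else with_seed(seed, stats::runif(1))
  u <- radical_inverse(nrow(windows), offset = offset)
  len <- windows$end_h - windows$start_h
  n_steps <- pmax(floor(len / step_h + 1e-9), 0)  # last grid index
  step <- clamp(round(u * len / step_h), 0, n_steps)
  tibble::tibble(
    admission_id = windows$admission_id,
    frac = u,
    step = as.integer(step),
    point_h = windows$start_h + step * step_h
  )
}

# Star discrepancy of a 1-D point set (exact for the L-infinity star
# discrepancy over intervals [0, t)): used in tests to show the
# quasi-random sample is more uniform than random draws.
star_discrepancy <- function(u) {
  n <- length(u)
  s <- sort(u)
  i <- seq_len(n)
  max(pmax(abs(i / n - s), abs((i - 1) / n - s)))
}
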