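# Detection-accuracy statistics against human annotation: count agreement
# for whole videos and event-level wave recovery.

#' Signed count error
#'
#' Net error = N_alg - N_hum: negative when the algorithm under-counts
#' relative to the human annotation.
#'
#' @param n_alg Individuals detected by the algorithm (>= 0).
#' @param n_hum Individuals counted by a human annotator (>= 0).
#' @return Signed integer difference.
#' @export
net_error <- function(n_alg, n_hum) {
  stopifnot(n_alg >= 0, n_hum >= 0)
  n_alg - n_hum
}

#' Relative count error (percent)
#'
#' |N_alg - N_hum| / N_hum x 100. Full precision is returned; for display
#' the convention is 2 significant figures ([format_percent()]). The sign
#' of the disagreement is carried by [net_error()].
#'
#' @inheritParams net_error
#' @return Percent error (>= 0), full precision.
#' @export
relative_error <- function(n_alg, n_hum) {
  stopifnot(n_alg >= 0)
  if (n_hum < 1) stop("n_hum must be >= 1")
  abs(n_alg - n_hum) / n_hum * 100
}

#' Agreement accuracy (percent)
#'
#' 100 - relative error: how closely the algorithm's individual count
#' matches the human annotation.
#'
#' @inheritParams net_error
#' @return Percent agreement, full precision.
#' @export
agreement_accuracy <- function(n_alg, n_hum) {
  100 - relative_error(n_alg, n_hum)
}

#' Display rounding to 2 significant figures
#'
#' @param x Percent value.
#' @return Numeric rounded to 2 significant figures (5.66 -> 5.7,
#'   85.2 -> 85).
#' @export
format_percent <- function(x) signif(x, 2)

#' All count-agreement statistics for one video
#'
#' @inheritParams net_error
#' @return A `DetectionMetrics` list: `n_alg`, `n_hum`, `net_error`,
#'   `relative_error`, `agreement_accuracy` (full precision) and
#'   display-rounded `relative_error_pct`, `agreement_accuracy_pct`.
#' @export
detection_metrics <- function(n_alg, n_hum) {
  structure(list(
    n_alg = n_alg, n_hum = n_hum,
    net_error = net_error(n_alg, n_hum),
    relative_error = relative_error(n_alg, n_hum),
    agreement_accuracy = agreement_accuracy(n_alg, n_hum),
    relative_error_pct = format_percent(relative_error(n_alg, n_hum)),
    agreement_accuracy_pct = format_percent(agreement_accuracy(n_alg, n_hum))
  ), class = "DetectionMetrics")
}

#' @export
print.DetectionMetrics <- function(x, ...) {
  cat(sprintf("N_alg = %d, N_hum = %d: net %+d, relative %g%%, agreement %g%%\n",
              x$n_alg, x$n_hum, x$net_error,
              x$relative_error_pct, x$agreement_accuracy_pct))
  invisible(x)
}

#' Fraction of annotated wave events recovered
#'
#' Matches detected wave-peak times to annotated ones per individual,
#' greedily in time order and one-to-one: each annotated event takes the
#' earliest unused detection within `tolerance` seconds. Returns the
#' percentage of annotated events matched.
#'
#' @param detected Data frame `id`, `peak_time_s` of algorithm detections.
#' @param truth Data frame `id`, `peak_time_s` of annotated events.
#' @param tolerance Maximum |detected - annotated| time difference, s.
#' @return Percent of truth events matched, or `NA` if `truth` is empty.
#' @export
wave_detection_accuracy <- function(detected, truth, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  if (nrow(truth) == 0) return(NA_real_)
  matched <- 0L
  for (id in unique(truth$id)) {
    tt <- sort(truth$peak_time_s[truth$id == id])
    dd <- sort(detected$peak_time_s[detected$id == id])
    used <- logical(length(dd))
    for (t in tt) {
      ok <- which(!used & abs(dd - t) <= tolerance)
      if (length(ok) > 0) {
        used[ok[1]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  100 * matched / nrow(truth)
}
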