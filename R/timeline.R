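#' Protocol event timeline
#'
#' Timestamps (seconds from recording start) of the occlusion protocol:
#' start of the pre-occlusion baseline, cuff inflation, cuff deflation, and
#' optionally a second baseline followed by sublingual nitroglycerin (NTG)
#' administration. Events must be strictly increasing in temporal order
#' (baseline < inflate < deflate < second baseline < NTG); the second
#' baseline precedes NTG because the NTG response is referenced to it.
#'
#' @param t_baseline_start start of the pre-occlusion baseline (s).
#' @param t_cuff_inflate cuff inflation time (s); the cuff is inflated to
#'   50 mmHg above resting systolic pressure, abolishing the test-arm pulse.
#' @param t_cuff_deflate cuff deflation time (s); default occlusion duration
#'   is 300 s (5 min).
#' @param t_second_baseline_start optional start of the second baseline
#'   preceding NTG (s).
#' @param t_ntg optional NTG administration time (s).
#' @return An object of class `ppg_timeline`.
#' @examples
#' event_timeline(5, 90, 390)
#' @export
event_timeline <- function(t_baseline_start, t_cuff_inflate, t_cuff_deflate,
                           t_second_baseline_start = NULL, t_ntg = NULL) {
  tl <- list(
    t_baseline_start = as.numeric(t_baseline_start),
    t_cuff_inflate = as.numeric(t_cuff_inflate),
    t_cuff_deflate = as.numeric(t_cuff_deflate),
    t_second_baseline_start = if (is.null(t_second_baseline_start)) NULL else as.numeric(t_second_baseline_start),
    t_ntg = if (is.null(t_ntg)) NULL else as.numeric(t_ntg)
  )
  ev <- unlist(tl[!vapply(tl, is.null, logical(1))])
  if (any(!is.finite(ev)) || any(ev < 0)) {
    stop("protocol error: timeline events must be finite and non-negative")
  }
  if (any(diff(ev) <= 0)) {
    stop("protocol error: timeline events must be strictly increasing ",
         "(baseline < inflate < deflate < second baseline < NTG)")
  }
  if (is.null(tl$t_second_baseline_start) != is.null(tl$t_ntg)) {
    stop("protocol error: second baseline and NTG times must be given together")
  }
  structure(tl, class = "ppg_timeline")
}

#' Default occlusion protocol timeline
#'
#' Convenience constructor for the standard protocol: baseline from 5 s,
#' 5-min occlusion from 90 s to 390 s, and (if `ntg = TRUE`) a second
#' baseline at 620 s with NTG given at 720 s.
#'
#' @param baseline_start baseline start (s).
#' @param occlusion_start cuff inflation (s).
#' @param occlusion_duration occlusion length (s), 300 by protocol.
#' @param ntg include the nitroglycerin phase?
#' @return A `ppg_timeline`.
#' @export
protocol_timeline <- function(baseline_start = 5, occlusion_start = 90,
                              occlusion_duration = 300, ntg = FALSE) {
  deflate <- occlusion_start + occlusion_duration
  if (ntg) {
    event_timeline(baseline_start, occlusion_start, deflate,
                   t_second_baseline_start = deflate + 230,
                   t_ntg = deflate + 330)
  } else {
    event_timeline(baseline_start, occlusion_start, deflate)
  }
}

# Last instant the protocol needs: the end of the latest measurement window.
timeline_end <- function(timeline) {
  end <- timeline$t_cuff_deflate + 80
  if (!is.null(timeline$t_ntg)) end <- max(end, timeline$t_ntg + 220)
  end
}

timeline_to_list <- function(timeline) {
  tl <- unclass(timeline)
  tl[!vapply(tl, is.null, logical(1))]
}

timeline_from_list <- function(x) {
  event_timeline(x$t_baseline_start, x$t_cuff_inflate, x$t_cuff_deflate,
                 t_second_baseline_start = x$t_second_baseline_start,
                 t_ntg = x$t_ntg)
}

#' @export
print.ppg_timeline <- function(x, ...) {
  cat("PPG protocol timeline (s):\n")
  cat(sprintf("  baseline start %.1f | cuff %.1f-%.1f (%.0f s occlusion)\n",
              x$t_baseline_start, x$t_cuff_inflate, x$t_cuff_deflate,
              x$t_cuff_deflate - x$t_cuff_inflate))
  if (!is.null(x$t_ntg)) {
    cat(sprintf("  second baseline %.1f | NTG %.1f\n",
                x$t_second_baseline_start, x$t_ntg))
  }
  invisible(x)
}
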