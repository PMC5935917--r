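#' Canonical single-cycle pulse shape
#'
#' A dimensionless template of one cardiac cycle of the digital volume
#' pulse: a raised-cosine systolic upstroke over the first
#' `upstroke_frac` of the cycle followed by an exponential diastolic decay
#' rescaled to return exactly to 0 at the next foot. The template is 0 at
#' the foot, reaches its single global maximum of 1 at the end of the
#' upstroke, and is sampled on a uniform phase grid.
#'
#' @param n number of samples over one cycle.
#' @param upstroke_frac fraction of the cycle occupied by the systolic
#'   upstroke (default 0.3).
#' @param decay_tau diastolic decay constant, in units of the decay
#'   segment's duration (default 0.3).
#' @return An object of class `pulse_template` with elements `samples`,
#'   `upstroke_frac`, `decay_tau`.
#' @examples
#' tpl <- pulse_template()
#' range(tpl$samples)  # 0 .. 1
#' @export
pulse_template <- function(n = 100, upstroke_frac = 0.3, decay_tau = 0.3) {
  stopifnot(n >= 8, upstroke_frac > 0, upstroke_frac < 1, decay_tau > 0)
  u <- seq(0, 1, length.out = n + 1)[-(n + 1)]
  structure(
    list(samples = pulse_shape(u, upstroke_frac, decay_tau),
         upstroke_frac = upstroke_frac, decay_tau = decay_tau),
    class = "pulse_template"
  )
}

# Closed-form template value at phase in [0, 1).
pulse_shape <- function(phase, upstroke_frac = 0.3, decay_tau = 0.3) {
  phase <- phase %% 1
  y <- numeric(length(phase))
  up <- phase < upstroke_frac
  y[up] <- 0.5 * (1 - cos(pi * phase[up] / upstroke_frac))
  v <- (phase[!up] - upstroke_frac) / (1 - upstroke_frac)
  y[!up] <- (exp(-v / decay_tau) - exp(-1 / decay_tau)) / (1 - exp(-1 / decay_tau))
  y
}
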