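#' Per-pulse response amplitudes and final decay time
#'
#' Splits the recorded observable into inter-pulse windows (one per stimulus,
#' the last extending to the end of the trace), measures the baseline-
#' subtracted peak in each, and the decay time of the final response.
#'
#' The decay-time definition is configurable: `"efold"` (default; time for
#' the final response to fall from its peak to 1/e of the peak),
#' `"t10_90"`-style `"t90_10"` (fall from 90% to 10% of peak), or `"exp"`
#' (time constant of a log-linear fit to the decay between 90% and 10% of
#' peak).
#'
#' @param res A [simulate_synapse()] result (or any data frame with a `time`
#'   column and the signal column).
#' @param signal Column to summarize; default picks `i_vc` for voltage clamp
#'   or `v_m` for current clamp.
#' @param protocol A [stim_train()]; defaults to the protocol attribute.
#' @param decay One of `"efold"`, `"t90_10"`, `"exp"`.
#' @param baseline Baseline level; default is the pre-stimulus mean of the
#'   signal.
#' @return A list with `peaks` (tibble: pulse, t_peak, peak signed value,
#'   amplitude) and `decay_time` (ms, `NA` for a flat trace).
#' @export
#' @examples
#' sim <- simulate_synapse(synapse_params(), t_end = 300)
#' synapse_metrics(sim)$peaks
synapse_metrics <- function(res, signal = NULL,
                            protocol = attr(res, "protocol"),
                            decay = c("efold", "t90_10", "exp"),
                            baseline = NULL) {
  decay <- match.arg(decay)
  if (is.null(signal)) {
    signal <- if ("i_vc" %in% names(res)) "i_vc" else "v_m"
  }
  stopifnot(signal %in% names(res), inherits(protocol, "stim_train"),
            length(protocol$onsets) >= 1)
  t <- res$time
  y <- res[[signal]]
  if (is.null(baseline)) {
    pre <- t < protocol$onsets[1]
    baseline <- if (any(pre)) mean(y[pre]) else y[1]
  }
  yb <- y - baseline

  on <- protocol$onsets
  win_end <- c(on[-1], max(t))
  peaks <- purrr::map_dfr(seq_along(on), function(k) {
    idx <- which(t >= on[k] & t < win_end[k])
    if (k == length(on)) idx <- which(t >= on[k])
    i <- idx[which.max(abs(yb[idx]))]
    tibble::tibble(pulse = k, t_peak = t[i], peak = yb[i],
                   amplitude = abs(yb[i]))
  })

  last <- peaks[nrow(peaks), ]
  dec_idx <- which(t >= last$t_peak)
  dec_t <- t[dec_idx]; dec_y <- abs(yb[dec_idx])
  pk <- last$amplitude
  decay_time <- NA_real_
  if (pk > 0 && length(dec_idx) > 2) {
    cross <- function(level) {
      below <- which(dec_y <= level * pk)
      if (!length(below)) return(NA_real_)
      i <- below[1]
      if (i == 1) return(dec_t[1])
      # linear interpolation of the crossing time
      t0 <- dec_t[i - 1]; t1 <- dec_t[i]
      y0 <- dec_y[i - 1]; y1 <- dec_y[i]
      t0 + (y0 - level * pk) / (y0 - y1) * (t1 - t0)
    }
    decay_time <- switch(decay,
      efold = cross(exp(-1)) - last$t_peak,
      t90_10 = cross(0.1) - cross(0.9),
      exp = {
        keep <- dec_y <= 0.9 * pk & dec_y >= 0.1 * pk & dec_y > 0
        if (sum(keep) > 3) {
          fit <- stats::lm(log(dec_y[keep]) ~ dec_t[keep])
          -1 / stats::coef(fit)[2]
        } else NA_real_
      })
  }
  list(peaks = peaks, decay_time = unname(decay_time), baseline = baseline,
       signal = signal)
}
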