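#' FRAP trace container
#'
#' Raw fluorescence-recovery time series: the bleached ROI, an unbleached
#' reference region (the surrounding diffuse pool, tracking acquisition
#' photobleaching) and a background region outside cell boundaries.
#' The bleach happens at `t = 0`; the first `n_pre` frames are
#' pre-bleach baseline.
#'
#' @param time_s Strictly increasing time points (s); pre-bleach frames
#'   have `time_s < 0`.
#' @param roi,reference,background Intensity series, equal length.
#' @param n_pre Number of pre-bleach frames (>= 1).
#' @return A `frap_trace` object.
#' @export
frap_trace <- function(time_s, roi, reference, background, n_pre) {
  n <- length(time_s)
  if (any(lengths(list(roi, reference, background)) != n))
    stop("all series must have the same length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (n_pre < 1 || n_pre >= n)
    stop("n_pre must be in [1, length(time_s) - 1]", call. = FALSE)
  structure(list(time_s = time_s, roi = roi, reference = reference,
                 background = background, n_pre = as.integer(n_pre)),
            class = "frap_trace")
}

#' Double-normalize a FRAP trace
#'
#' EasyFRAP-style double normalization: background is subtracted from ROI
#' and reference, the ROI is scaled to its pre-bleach mean, and the
#' reference correction
#' \deqn{I_{dn}(t) = \frac{\overline{ref-bg}_{pre}}{ref(t)-bg(t)} \cdot
#'   \frac{roi(t)-bg(t)}{\overline{roi-bg}_{pre}}}
#' cancels any acquisition photobleaching shared by ROI and reference.
#' The pre-bleach mean of the normalized curve is 1 by construction.
#'
#' @param trace A [frap_trace()].
#' @return `data.frame` with `time_s`, `normalized`, `is_pre_bleach`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  ref_bg <- trace$reference - trace$background
  if (any(ref_bg <= 0))
    stop("reference - background must be strictly positive", call. = FALSE)
  pre <- seq_len(trace$n_pre)
  roi_bg <- trace$roi - trace$background
  i_dn <- (mean(ref_bg[pre]) / ref_bg) * (roi_bg / mean(roi_bg[pre]))
  data.frame(time_s = trace$time_s, normalized = i_dn,
             is_pre_bleach = seq_along(trace$time_s) <= trace$n_pre)
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of `I(t) = I0 + A * (1 - exp(-k * t))` to the
#' post-bleach (`t >= 0`) frames. Starting values: `I0` at the first
#' post-bleach point, `A` from the last point, `k = log(2) / t_mid` with
#' `t_mid` the first crossing of the midpoint. `fit_ok` is `FALSE` when
#' the solver fails or the fitted amplitude is not positive; the fallback
#' plateau is then the mean of the last 5 frames.
#'
#' @param normalized Output of [normalize_trace()].
#' @return List: `I0`, `amplitude`, `rate`, `plateau`, `fit_ok`.
#' @export
fit_recovery <- function(normalized) {
  post <- normalized[normalized$time_s >= 0, ]
  if (nrow(post) < 5) stop("need at least 5 post-bleach frames", call. = FALSE)
  t <- post$time_s; y <- post$normalized
  i0 <- y[1]
  a0 <- y[length(y)] - i0
  fallback <- mean(y[seq.int(max(1, length(y) - 4), length(y))])
  mid <- i0 + a0 / 2
  t_mid <- if (a0 > 0 && any(y >= mid & t > 0)) min(t[y >= mid & t > 0])
           else max(t[-1]) / 4
  k0 <- log(2) / max(t_mid, .Machine$double.eps)
  fit <- NULL
  if (a0 > 1e-8) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ I0 + A * (1 - exp(-k * t)),
                        start = list(I0 = i0, A = a0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        stats::nls(y ~ I0 + A * (1 - exp(-k * t)),
                   start = list(I0 = i0, A = a0, k = k0)),
        error = function(e) NULL)
  }
  if (!is.null(fit)) {
    p <- coef(fit)
    if (is.finite(p[["A"]]) && p[["A"]] > 0 && p[["k"]] > 0) {
      return(list(I0 = unname(p[["I0"]]), amplitude = unname(p[["A"]]),
                  rate = unname(p[["k"]]),
                  plateau = unname(p[["I0"]] + p[["A"]]), fit_ok = TRUE))
    }
  }
  list(I0 = i0, amplitude = max(fallback - i0, 0), rate = NA_real_,
       plateau = fallback, fit_ok = FALSE)
}

#' FRAP mobility metrics
#'
#' Extracts the four reported mobility statistics from a normalized curve
#' and its exponential fit:
#' \itemize{
#'  \item `max_recovery`: the plateau `I0 + A` relative to the pre-bleach
#'    level (= 1).
#'  \item `mobile_fraction_pct`: `100 * (I_max - I0) / (1 - I0)`; `NA`
#'    when the curve never dropped (`I0 >= 1`).
#'  \item `auc`: trapezoidal integral of the normalized curve over
#'    `[0, auc_window_s]` (a curve pinned at 1 gives the window length).
#'  \item `t_half_s`: earliest time the curve reaches halfway between
#'    `I0` and the plateau, linearly interpolated between frames;
#'    equivalently `log(2)/k` from the fit.
#' }
#'
#' @param normalized Output of [normalize_trace()].
#' @param fit Output of [fit_recovery()]; computed when `NULL`.
#' @param auc_window_s Integration window (default 120 s, the recording
#'   window the metrics are reported over).
#' @return List of class `frap_metrics`: `mobile_fraction_pct`, `auc`,
#'   `max_recovery`, `t_half_s`, `t_half_fit_s`, `fit_params`, `fit_ok`.
#' @export
compute_metrics <- function(normalized, fit = NULL, auc_window_s = 120) {
  if (is.null(fit)) fit <- fit_recovery(normalized)
  post <- normalized[normalized$time_s >= 0, ]
  t <- post$time_s; y <- post$normalized
  i0 <- fit$I0
  i_max <- fit$plateau
  mf <- if (i0 >= 1) NA_real_ else 100 * (i_max - i0) / (1 - i0)
  tw <- t[t <= auc_window_s]; yw <- y[t <= auc_window_s]
  auc <- trapz(tw, yw)
  mid <- i0 + (i_max - i0) / 2
  t_half <- interp_first_crossing(t, y, mid)
  t_half_fit <- if (fit$fit_ok) log(2) / fit$rate else NA_real_
  structure(list(
    mobile_fraction_pct = mf, auc = auc, max_recovery = i_max,
    t_half_s = t_half, t_half_fit_s = t_half_fit,
    fit_params = fit[c("I0", "amplitude", "rate")], fit_ok = fit$fit_ok),
    class = "frap_metrics")
}

# Earliest t where y first reaches `level`, linear interpolation between
# bracketing frames; NA when never reached.
interp_first_crossing <- function(t, y, level) {
  hit <- which(y >= level)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(t[1])
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' @export
print.frap_metrics <- function(x, ...) {
  cat(sprintf(
    "FRAP metrics: m.f. %.1f%%, AUC %.1f a.u., max recovery %.3f, t1/2 %.1f s\n",
    x$mobile_fraction_pct, x$auc, x$max_recovery, x$t_half_s))
  invisible(x)
}

#' Analyze one or more FRAP traces end to end
#'
#' Normalizes, fits and extracts metrics for each trace.
#'
#' @param traces A [frap_trace()] or a list of them (optionally named).
#' @param auc_window_s Passed to [compute_metrics()].
#' @return `data.frame`, one row per trace, with the metric columns.
#' @export
analyze_frap <- function(traces, auc_window_s = 120) {
  if (inherits(traces, "frap_trace")) traces <- list(traces)
  out <- lapply(seq_along(traces), function(i) {
    norm <- normalize_trace(traces[[i]])
    m <- compute_metrics(norm, auc_window_s = auc_window_s)
    data.frame(trace = if (!is.null(names(traces))) names(traces)[i] else i,
               mobile_fraction_pct = m$mobile_fraction_pct, auc = m$auc,
               max_recovery = m$max_recovery, t_half_s = m$t_half_s,
               t_half_fit_s = m$t_half_fit_s, fit_ok = m$fit_ok)
  })
  do.call(rbind, out)
}
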