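#' Configuration for the FRAP trace simulator
#'
#' Generates traces from the model the analysis inverts: a
#' single-exponential recovery after an instantaneous bleach at `t = 0`,
#' \deqn{roi(t) = bg + s(t)\,[I_0 + (P - I_0)(1 - 2^{-t/t_{1/2}})]}
#' with pre-bleach frames at `bg + s(t)`, a reference trace
#' `bg + s(t)` and a flat background `bg`, where
#' `s(t) = exp(-reference_decay_rate * t)` is the acquisition
#' photobleaching factor shared by ROI and reference (so double
#' normalization cancels it exactly). The `2^(-t/t_half)` kernel makes
#' `half_time_s` the literal half-time of recovery.
#'
#' @param pre_bleach_frames Number of baseline frames before the bleach
#'   (default 3).
#' @param frame_interval_s Sampling interval (default 1 s).
#' @param total_time_s Post-bleach recording time (default 120 s).
#' @param post_bleach_floor Normalized intensity immediately after the
#'   bleach (`I0`), in `[0, 1)`.
#' @param plateau Asymptotic recovery level `P`, in `(I0, 1]`.
#' @param half_time_s Recovery half-time (s).
#' @param reference_decay_rate Acquisition photobleaching rate (1/s).
#' @param background_level Constant background offset.
#' @param noise_sd Gaussian noise added to all three series.
#' @param seed Integer seed or `NULL`.
#' @return A validated `frap_sim_config` list.
#' @export
frap_sim_config <- function(pre_bleach_frames = 3L, frame_interval_s = 1,
                            total_time_s = 120, post_bleach_floor = 0.3,
                            plateau = 0.8, half_time_s = 10,
                            reference_decay_rate = 0, background_level = 0.05,
                            noise_sd = 0, seed = NULL) {
  stopifnot_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  stopifnot_scalar(total_time_s, "total_time_s", positive = TRUE)
  stopifnot_scalar(half_time_s, "half_time_s", positive = TRUE)
  stopifnot_scalar(reference_decay_rate, "reference_decay_rate", nonneg = TRUE)
  stopifnot_scalar(background_level, "background_level", nonneg = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (pre_bleach_frames < 1) stop("pre_bleach_frames must be >= 1", call. = FALSE)
  if (post_bleach_floor < 0 || post_bleach_floor >= 1)
    stop("post_bleach_floor must be in [0, 1)", call. = FALSE)
  if (plateau <= post_bleach_floor || plateau > 1)
    stop("plateau must be in (post_bleach_floor, 1]", call. = FALSE)
  structure(list(
    pre_bleach_frames = as.integer(pre_bleach_frames),
    frame_interval_s = frame_interval_s, total_time_s = total_time_s,
    post_bleach_floor = post_bleach_floor, plateau = plateau,
    half_time_s = half_time_s, reference_decay_rate = reference_decay_rate,
    background_level = background_level, noise_sd = noise_sd, seed = seed),
    class = "frap_sim_config")
}

#' Simulate a FRAP trace
#'
#' @param cfg A [frap_sim_config()].
#' @return A [frap_trace()].
#' @export
render_frap_trace <- function(cfg) {
  stopifnot(inherits(cfg, "frap_sim_config"))
  with_seed(cfg$seed, {
    dt <- cfg$frame_interval_s
    t_pre <- -rev(seq_len(cfg$pre_bleach_frames)) * dt
    t_post <- seq(0, cfg$total_time_s, by = dt)
    time_s <- c(t_pre, t_post)
    s <- exp(-cfg$reference_decay_rate * time_s)
    rec <- cfg$post_bleach_floor +
      (cfg$plateau - cfg$post_bleach_floor) * (1 - 2^(-t_post / cfg$half_time_s))
    signal <- c(rep(1, length(t_pre)), rec)
    bg <- cfg$background_level
    roi <- bg + s * signal
    reference <- bg + s * 1
    background <- rep(bg, length(time_s))
    if (cfg$noise_sd > 0) {
      roi <- roi + rnorm(length(roi), 0, cfg$noise_sd)
      reference <- reference + rnorm(length(reference), 0, cfg$noise_sd)
      background <- background + rnorm(length(background), 0, cfg$noise_sd)
    }
    frap_trace(time_s, roi, reference, background, cfg$pre_bleach_frames)
  })
}
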