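#' Write a scene to disk
#'
#' Writes a two-page 16-bit TIFF (page 1: endogenous, page 2: exogenous),
#' a JSON sidecar with the calibration (and scene configuration when the
#' scene came from the simulator), and — when ground truth is supplied —
#' CSVs of the true cell and assembly records.
#'
#' @param scene An [image_scene()].
#' @param path Output TIFF path; the sidecar is `<path>.json` and ground
#'   truth CSVs `<path>.cells.csv` / `<path>.assemblies.csv`.
#' @param ground_truth Optional ground-truth list from [render_scene()].
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path, ground_truth = NULL) {
  stopifnot(inherits(scene, "image_scene"))
  pages <- list(scene$endogenous / scene$bit_saturation,
                scene$exogenous / scene$bit_saturation)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(pixel_size_um = scene$pixel_size_um,
                  bit_saturation = scene$bit_saturation,
                  n_channels = 2L, n_z = 1L)
  if (!is.null(ground_truth)) {
    cfg <- ground_truth$config
    sidecar$config <- cfg[setdiff(names(cfg), "assembly_rates")]
    sidecar$config$assembly_rates <- as.list(cfg$assembly_rates)
    write.csv(ground_truth$cells, paste0(path, ".cells.csv"),
              row.names = FALSE)
    write.csv(ground_truth$assemblies, paste0(path, ".assemblies.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scene from a TIFF file
#'
#' Reads 1-2 channel TIFFs, maximum-projecting any Z dimension per
#' channel. Page layout is taken from the JSON sidecar (`n_channels`,
#' `n_z`, channel-major page order); without a sidecar, 1 or 2 pages are
#' treated as 1 or 2 single-plane channels and the calibration must be
#' supplied. RGB pages are rejected unless a `channel_map` picks the two
#' color planes to use.
#'
#' @param path TIFF path.
#' @param pixel_size_um,bit_saturation Calibration overrides; required
#'   when no sidecar exists.
#' @param channel_map For RGB input: integer pair giving the color planes
#'   holding the endogenous and exogenous channels.
#' @return An [image_scene()]. Single-channel input duplicates the
#'   channel into an all-zero exogenous channel.
#' @export
read_scene <- function(path, pixel_size_um = NULL, bit_saturation = NULL,
                       channel_map = NULL) {
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  psz <- pixel_size_um %||% sidecar$pixel_size_um
  if (is.null(psz))
    stop("missing pixel calibration: supply pixel_size_um or a sidecar",
         call. = FALSE)
  sat <- bit_saturation %||% sidecar$bit_saturation %||% 65535
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (is.null(channel_map))
        stop("RGB/multi-sample TIFF needs a channel_map", call. = FALSE)
      return(p)   # split below
    }
    p
  })
  if (length(dim(pages[[1]])) == 3L) {
    p <- pages[[1]]
    endo <- p[, , channel_map[1]]; exo <- p[, , channel_map[2]]
    return(image_scene(endo * sat, exo * sat, psz, sat))
  }
  n_ch <- sidecar$n_channels %||% min(length(pages), 2L)
  if (n_ch > 2) stop("more than 2 channels needs a channel map", call. = FALSE)
  n_z <- sidecar$n_z %||% (length(pages) / n_ch)
  if (n_ch * n_z != length(pages))
    stop("page count does not match n_channels * n_z", call. = FALSE)
  proj <- function(ps) Reduce(pmax, ps)
  endo <- proj(pages[seq_len(n_z)])
  exo <- if (n_ch == 2) proj(pages[n_z + seq_len(n_z)])
         else matrix(0, nrow(endo), ncol(endo))
  image_scene(endo * sat, exo * sat, psz, sat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read FRAP traces as CSV
#'
#' Column layout: `trace_id`, `time_s`, `roi`, `reference`, `background`,
#' `is_pre_bleach`.
#'
#' @param traces A [frap_trace()] or (optionally named) list of them.
#' @param path CSV path.
#' @return `write_frap_csv`: `path` invisibly. `read_frap_csv`: a named
#'   list of [frap_trace()] objects.
#' @export
write_frap_csv <- function(traces, path) {
  if (inherits(traces, "frap_trace")) traces <- list(trace = traces)
  if (is.null(names(traces))) names(traces) <- seq_along(traces)
  rows <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.frame(trace_id = id, time_s = tr$time_s, roi = tr$roi,
               reference = tr$reference, background = tr$background,
               is_pre_bleach = seq_along(tr$time_s) <= tr$n_pre)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "roi", "reference", "background", "is_pre_bleach")
  if (!all(need %in% names(df)))
    stop("FRAP CSV must have columns: trace_id, ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$trace_id)) df$trace_id <- "trace"
  out <- lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$time_s), ]
    frap_trace(d$time_s, d$roi, d$reference, d$background,
               n_pre = sum(d$is_pre_bleach))
  })
  out
}
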