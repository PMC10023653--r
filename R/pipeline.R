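#' Segment and measure one scene
#'
#' Convenience wrapper running nucleus segmentation, cell growing,
#' assembly detection and per-cell measurement on one scene.
#'
#' @param scene An [image_scene()] or a TIFF path readable by
#'   [read_scene()].
#' @param params A [classifier_params()].
#' @return List: `scene`, `nuclei`, `cells`, `assemblies`,
#'   `cell_records`.
#' @export
process_scene <- function(scene, params = classifier_params()) {
  if (is.character(scene)) scene <- read_scene(scene)
  nuclei <- segment_nuclei(scene)
  cells <- segment_cells(scene, nuclei)
  assemblies <- detect_assemblies(scene, cells, nuclei, params)
  cell_records <- measure_cells(scene, nuclei, cells, assemblies)
  list(scene = scene, nuclei = nuclei, cells = cells,
       assemblies = assemblies, cell_records = cell_records)
}

#' Run the full quantification pipeline over a batch of scenes
#'
#' Processes control scenes and one or more variant conditions: segments
#' every scene, builds the control reference (sequestration cutoff and
#' GFP gate) from the control cells, flags sequestering assemblies, gates
#' transfected cells, partitions endogenous pools, summarizes each image
#' and fits the concentration-dependence regressions per condition.
#' Scenes are isolated: a failing scene is reported and skipped, it does
#' not abort the batch. With a seed (used when any input is a
#' [scene_config()] to simulate) reruns are deterministic.
#'
#' @param conditions Named list of scene lists. Each scene may be an
#'   [image_scene()], a TIFF path, or a [scene_config()] (simulated on
#'   the fly). The control condition holds GFP-only cells.
#' @param control Name of the control condition (default `"control"`).
#' @param mock Optional name of an untransfected condition used for the
#'   GFP gate; when absent the gate comes from the control cells.
#' @param params A [classifier_params()].
#' @param output_dir When non-`NULL`, tidy CSVs and a JSON report are
#'   written there.
#' @param seed Base seed for simulated scenes (scene `i` of condition `j`
#'   gets a derived sub-seed).
#' @return List of class `pipeline_result`: `control_reference`, `cells`,
#'   `assemblies`, `quant`, `image_summaries`, `regressions`, `report`.
#' @export
run_pipeline <- function(conditions, control = "control", mock = NULL,
                         params = classifier_params(), output_dir = NULL,
                         seed = NULL) {
  stopifnot(is.list(conditions), !is.null(names(conditions)))
  if (!control %in% names(conditions))
    stop("no condition named '", control, "'", call. = FALSE)
  failed <- character(0)
  all_cells <- list(); all_asms <- list(); summaries <- list()

  for (cond in names(conditions)) {
    for (i in seq_along(conditions[[cond]])) {
      scene_in <- conditions[[cond]][[i]]
      tag <- sprintf("%s_%d", cond, i)
      res <- tryCatch({
        if (inherits(scene_in, "scene_config")) {
          if (!is.null(seed))
            scene_in$seed <- (seed * 1009L + match(cond, names(conditions)) *
                                101L + i) %% .Machine$integer.max
          scene_in <- render_scene(scene_in)$scene
        }
        process_scene(scene_in, params)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, sprintf("%s: %s", tag, conditionMessage(res)))
        next
      }
      cr <- res$cell_records
      if (nrow(cr)) { cr$scene <- tag; cr$condition <- cond }
      asm <- res$assemblies
      if (nrow(asm)) { asm$scene <- tag; asm$condition <- cond }
      all_cells[[tag]] <- cr
      all_asms[[tag]] <- list(df = asm)
    }
  }

  cells_df <- do.call(rbind, all_cells[lengths(all_cells) > 0])
  asms_df <- do.call(rbind, lapply(all_asms, function(x) x$df))
  if (is.null(cells_df) || !nrow(cells_df))
    stop("no scene produced any cells", call. = FALSE)

  ctrl_cells <- cells_df[cells_df$condition == control, , drop = FALSE]
  mock_cells <- if (!is.null(mock))
    cells_df[cells_df$condition == mock, , drop = FALSE] else NULL
  ref <- build_control_reference(ctrl_cells, untransfected_cells = mock_cells)

  cells_df <- apply_gfp_gate(cells_df, ref)
  if (!is.null(asms_df) && nrow(asms_df))
    asms_df <- flag_sequestering(asms_df, ref)
  else asms_df <- data.frame()

  quant <- do.call(rbind, lapply(split(cells_df, cells_df$scene), function(cc) {
    q <- partition_endogenous(cc, ref = ref)
    q$scene <- cc$scene[1]; q$condition <- cc$condition[1]
    q
  }))
  rownames(quant) <- NULL

  for (tag in unique(cells_df$scene)) {
    cc <- cells_df[cells_df$scene == tag, , drop = FALSE]
    aa <- if (nrow(asms_df))
      asms_df[asms_df$scene == tag, , drop = FALSE] else asms_df
    s <- summarize_image(cc, aa)
    if (nrow(s)) { s$scene <- tag; s$condition <- cc$condition[1] }
    summaries[[tag]] <- s
  }
  summaries_df <- do.call(rbind, summaries[lengths(summaries) > 0])

  regressions <- list()
  for (cond in setdiff(names(conditions), c(control, mock))) {
    q <- quant[quant$condition == cond & quant$transfected %in% TRUE, ,
               drop = FALSE]
    if (nrow(q) >= 3 && stats::var(q$exogenous_level) > 0) {
      regressions[[cond]] <- list(
        diffuse = regress_concentration(q, "diffuse"),
        sequestered = regress_concentration(q, "sequestered"))
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("tdpquant")),
    n_scenes = length(unique(cells_df$scene)),
    n_cells = nrow(cells_df),
    n_assemblies = nrow(asms_df),
    failed_scenes = failed,
    seed = seed,
    params = unclass(params))

  out <- structure(list(
    control_reference = ref, cells = cells_df, assemblies = asms_df,
    quant = quant, image_summaries = summaries_df,
    regressions = regressions, report = report),
    class = "pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cells_df, file.path(output_dir, "cells.csv"), row.names = FALSE)
    write.csv(asms_df, file.path(output_dir, "assemblies.csv"),
              row.names = FALSE)
    write.csv(quant, file.path(output_dir, "cell_quant.csv"),
              row.names = FALSE)
    write.csv(summaries_df, file.path(output_dir, "image_summaries.csv"),
              row.names = FALSE)
    reg_df <- do.call(rbind, lapply(names(regressions), function(cond) {
      do.call(rbind, lapply(c("diffuse", "sequestered"), function(resp) {
        r <- regressions[[cond]][[resp]]
        data.frame(condition = cond, response = resp, slope = r$slope,
                   intercept = r$intercept, r_squared = r$r_squared, n = r$n)
      }))
    }))
    if (!is.null(reg_df))
      write.csv(reg_df, file.path(output_dir, "regressions.csv"),
                row.names = FALSE)
    jsonlite::write_json(c(report, list(control_reference = unclass(ref))),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
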