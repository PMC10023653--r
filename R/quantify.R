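#' Measure per-cell records from a segmented scene
#'
#' For every segmented cell, measures the nuclear endogenous pools split
#' by the detected-assembly mask: the total nuclear signal, the diffuse
#' pool (nucleus excluding assembly pixels) and the sequestered pool
#' (assembly pixels, nuclear and cytoplasmic reported separately). The
#' nuclear identity diffuse + nuclear-sequestered = nuclear total holds
#' exactly because the masks are disjoint by construction.
#'
#' @param scene An [image_scene()].
#' @param nuclei,cells Label matrices from [segment_nuclei()] /
#'   [segment_cells()].
#' @param assemblies Result of [detect_assemblies()] (its `"labels"`
#'   attribute supplies the object mask).
#' @return `data.frame`, one row per cell: mean intensities
#'   (`nuclear_endogenous_total`, `nuclear_endogenous_diffuse`,
#'   `exogenous_level`), integrated sums (`nuclear_total_sum`,
#'   `diffuse_sum`, `nuclear_sequestered_sum`,
#'   `cytoplasmic_sequestered_sum`), areas and assembly counts.
#'   `transfected` is `NA` until a GFP gate is applied
#'   (see [apply_gfp_gate()]).
#' @export
measure_cells <- function(scene, nuclei, cells, assemblies) {
  stopifnot(inherits(scene, "image_scene"))
  n_cells <- max(cells, nuclei, 0L)
  endo <- scene$endogenous; exo <- scene$exogenous
  asm_lab <- attr(assemblies, "labels")
  if (is.null(asm_lab)) asm_lab <- matrix(0L, nrow(endo), ncol(endo))
  kept <- asm_lab %in% assemblies$assembly_id
  dim(kept) <- dim(asm_lab)
  # pixels of each assembly belong to the assembly's parent cell
  asm_cell <- matrix(0L, nrow(endo), ncol(endo))
  if (nrow(assemblies)) {
    map <- integer(max(asm_lab))
    # assemblies with no parent cell (detached from every cell mask) stay 0
    map[assemblies$assembly_id] <-
      ifelse(is.na(assemblies$cell_id), 0L, assemblies$cell_id)
    sel <- which(kept)
    asm_cell[sel] <- map[asm_lab[sel]]
  }
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    nuc <- nuclei == i
    cel <- cells == i | asm_cell == i
    if (!any(nuc) && !any(cel)) next
    in_asm <- nuc & kept
    diff_mask <- nuc & !kept
    cyto_asm <- asm_cell == i & !nuc
    out[[i]] <- data.frame(
      cell_id = i,
      nucleus_area_um2 = sum(nuc) * scene$pixel_size_um^2,
      cell_area_um2 = sum(cel) * scene$pixel_size_um^2,
      nuclear_endogenous_total = if (any(nuc)) mean(endo[nuc]) else NA_real_,
      nuclear_endogenous_diffuse =
        if (any(diff_mask)) mean(endo[diff_mask]) else NA_real_,
      nuclear_total_sum = sum(endo[nuc]),
      diffuse_sum = sum(endo[diff_mask]),
      nuclear_sequestered_sum = sum(endo[in_asm]),
      cytoplasmic_sequestered_sum = sum(endo[cyto_asm]),
      exogenous_level = if (any(cel)) mean(exo[cel]) else NA_real_,
      transfected = NA,
      n_assemblies = sum(assemblies$cell_id == i, na.rm = TRUE))
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  out
}

#' Build the control reference from GFP-only control cells
#'
#' Computes the quantities variant cells are compared against: the lower
#' quartile (Q1, linear-interpolation quantile) of the per-cell diffuse
#' nuclear endogenous means — the sequestration cutoff —, control mean
#' endogenous and exogenous intensities, and the GFP gate for calling
#' cells transfected.
#'
#' @param control_cells `data.frame` from [measure_cells()] on control
#'   scenes; at least 4 cells.
#' @param untransfected_cells Optional [measure_cells()] rows from
#'   mock/untransfected cells; when given, the GFP gate is their
#'   `gate_quantile` exogenous quantile (the natural gate: anything above
#'   untransfected background is transfected). When `NULL` the gate falls
#'   back to the `gate_quantile` quantile of the control cells themselves.
#' @param gate_quantile Quantile for the GFP gate (default 0.99).
#' @return A `control_reference` list: `control_diffuse_Q1`,
#'   `control_mean_endogenous`, `control_mean_exogenous`,
#'   `transfected_gfp_threshold`, `n_cells`.
#' @export
build_control_reference <- function(control_cells, untransfected_cells = NULL,
                                    gate_quantile = 0.99) {
  if (nrow(control_cells) < 4)
    stop("need at least 4 control cells", call. = FALSE)
  diffuse <- control_cells$nuclear_endogenous_diffuse
  gate_pop <- if (!is.null(untransfected_cells))
    untransfected_cells$exogenous_level else control_cells$exogenous_level
  structure(list(
    control_diffuse_Q1 = unname(quantile(diffuse, 0.25, type = 7, na.rm = TRUE)),
    control_mean_endogenous = mean(control_cells$nuclear_endogenous_total,
                                   na.rm = TRUE),
    control_mean_exogenous = mean(control_cells$exogenous_level, na.rm = TRUE),
    transfected_gfp_threshold =
      unname(quantile(gate_pop, gate_quantile, type = 7, na.rm = TRUE)),
    n_cells = nrow(control_cells)),
    class = "control_reference")
}

#' Flag assemblies that sequester endogenous protein
#'
#' An assembly sequesters endogenous TDP-43 when its mean endogenous
#' intensity exceeds (strictly) the lower-quartile diffuse nuclear
#' endogenous intensity of control cells.
#'
#' @param assemblies [detect_assemblies()] output.
#' @param ref A [build_control_reference()] result.
#' @return `assemblies` with the `sequestering` column filled.
#' @export
flag_sequestering <- function(assemblies, ref) {
  stopifnot(inherits(ref, "control_reference"))
  assemblies$sequestering <- assemblies$mean_endogenous > ref$control_diffuse_Q1
  assemblies
}

#' Apply the GFP gate to cell records
#'
#' @param cells [measure_cells()] output.
#' @param ref A [build_control_reference()] result (or a numeric threshold).
#' @return `cells` with `transfected` set to
#'   `exogenous_level > threshold`.
#' @export
apply_gfp_gate <- function(cells, ref) {
  thr <- if (inherits(ref, "control_reference"))
    ref$transfected_gfp_threshold else ref
  cells$transfected <- cells$exogenous_level > thr
  cells
}

#' Partition each cell's endogenous signal into diffuse and sequestered pools
#'
#' Computes, per cell, the fold-changes of total and diffuse nuclear
#' endogenous intensity relative to the control mean, the integrated
#' diffuse and sequestered signals, and the proportion of the cell's
#' endogenous signal held in assemblies. The sequestered pool pools
#' nuclear and cytoplasmic assemblies (cells are compared on everything
#' their aggregates captured); the exact nuclear conservation identity
#' `diffuse_sum + nuclear_sequestered_sum = nuclear_total_sum` is
#' inherited from [measure_cells()].
#'
#' @param cells [measure_cells()] output.
#' @param assemblies Flagged assemblies (unused columns tolerated);
#'   reserved for per-assembly breakdowns.
#' @param ref Optional [build_control_reference()]; without it the fold
#'   columns are `NA`.
#' @return `data.frame`, one row per cell: `fold_total_nuclear`,
#'   `fold_diffuse_nuclear`, `diffuse_signal`, `sequestered_signal`,
#'   `proportion_sequestered`, `exogenous_level`, `transfected`.
#' @export
partition_endogenous <- function(cells, assemblies = NULL, ref = NULL) {
  if (!nrow(cells)) return(data.frame())
  if (any(is.na(cells$nuclear_total_sum)))
    stop("cell without a nucleus mask", call. = FALSE)
  seq_sig <- cells$nuclear_sequestered_sum + cells$cytoplasmic_sequestered_sum
  total <- cells$nuclear_total_sum + cells$cytoplasmic_sequestered_sum
  ctrl <- if (!is.null(ref)) ref$control_mean_endogenous else NA_real_
  data.frame(
    cell_id = cells$cell_id,
    fold_total_nuclear = cells$nuclear_endogenous_total / ctrl,
    fold_diffuse_nuclear = cells$nuclear_endogenous_diffuse / ctrl,
    diffuse_signal = cells$diffuse_sum,
    sequestered_signal = seq_sig,
    proportion_sequestered = ifelse(total > 0, seq_sig / total, 0),
    exogenous_level = cells$exogenous_level,
    transfected = cells$transfected)
}

#' Per-image summary statistics
#'
#' Summaries are computed over cells first, within the image, following
#' the convention that each data point in cross-image comparisons is the
#' mean of all cells within an image. Transfected-cell denominators use
#' the GFP gate; when no cell is transfected the inclusion metrics are
#' `NA`, not zero.
#'
#' @param cells Gated [measure_cells()] output.
#' @param assemblies Flagged [detect_assemblies()] output.
#' @return One-row `data.frame`: `n_cells`, `n_transfected`,
#'   `pct_cells_with_puncta`, `puncta_per_cell`,
#'   `pct_transfected_with_inclusions`, `inclusions_per_transfected_cell`,
#'   `mean_area_inclusion_um2`, `mean_area_anisosome_um2`,
#'   `mean_area_punctum_um2`, `pct_inclusions_sequestering`,
#'   `pct_puncta_sequestering` (puncta and anisosomes pooled).
#' @export
summarize_image <- function(cells, assemblies) {
  if (!nrow(cells)) return(data.frame())
  n <- nrow(cells)
  puncta_classes <- c("punctum", "anisosome")
  cnt <- function(classes, ids) {
    a <- assemblies[assemblies$class %in% classes &
                      assemblies$cell_id %in% ids, , drop = FALSE]
    tab <- table(factor(a$cell_id, levels = ids))
    as.numeric(tab)
  }
  puncta_counts <- cnt(puncta_classes, cells$cell_id)
  transf <- cells$cell_id[which(cells$transfected)]
  incl_counts <- cnt("inclusion", transf)
  mean_area <- function(cls) {
    a <- assemblies[assemblies$class == cls & !assemblies$on_border, ,
                    drop = FALSE]
    if (nrow(a)) mean(a$area_um2) else NA_real_
  }
  pct_seq <- function(classes) {
    a <- assemblies[assemblies$class %in% classes, , drop = FALSE]
    if (nrow(a)) 100 * mean(a$sequestering) else NA_real_
  }
  data.frame(
    n_cells = n,
    n_transfected = length(transf),
    pct_cells_with_puncta = 100 * mean(puncta_counts > 0),
    puncta_per_cell = mean(puncta_counts),
    pct_transfected_with_inclusions =
      if (length(transf)) 100 * mean(incl_counts > 0) else NA_real_,
    inclusions_per_transfected_cell =
      if (length(transf)) mean(incl_counts) else NA_real_,
    mean_area_inclusion_um2 = mean_area("inclusion"),
    mean_area_anisosome_um2 = mean_area("anisosome"),
    mean_area_punctum_um2 = mean_area("punctum"),
    pct_inclusions_sequestering = pct_seq("inclusion"),
    pct_puncta_sequestering = pct_seq(puncta_classes))
}

#' Concentration-dependence regression
#'
#' Ordinary least-squares fit of a per-cell endogenous response (the
#' diffuse nuclear fold-change, or the sequestered signal) against the
#' per-cell exogenous expression level, quantifying how over-expression
#' depletes the diffuse nuclear pool and grows the sequestered one.
#'
#' @param quant [partition_endogenous()] output (needs
#'   `exogenous_level` plus the response column).
#' @param response `"diffuse"` (uses `fold_diffuse_nuclear`, falling back
#'   to `diffuse_signal` when folds are `NA`) or `"sequestered"`
#'   (`sequestered_signal`).
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`, `slope_negative`.
#' @export
regress_concentration <- function(quant, response = c("diffuse", "sequestered")) {
  response <- match.arg(response)
  y <- if (response == "diffuse") {
    if (all(is.na(quant$fold_diffuse_nuclear))) quant$diffuse_signal
    else quant$fold_diffuse_nuclear
  } else quant$sequestered_signal
  x <- quant$exogenous_level
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 cells for a regression", call. = FALSE)
  if (stats::var(x) == 0) stop("zero-variance predictor", call. = FALSE)
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n = length(x),
    slope_negative = unname(coef(fit)[2]) < 0),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, r^2 %.3f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
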