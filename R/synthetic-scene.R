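#' Configuration for the synthetic scene generator
#'
#' Describes one simulated field of view of TDP-43 reporter cells
#' (endogenous channel: TDP-43-mCherry; exogenous channel: a transfected
#' TDP-43-GFP variant). Defaults emulate confocal acquisition at
#' 0.19 um/pixel on a 16-bit detector.
#'
#' The `variant` controls where the exogenous protein and its assemblies
#' live and which assembly classes form by default:
#' \describe{
#'   \item{GFP_only}{free GFP, whole-cell diffuse, no assemblies (control).}
#'   \item{WT}{nuclear diffuse; occasional nuclear puncta and inclusions.}
#'   \item{4FL, 2KQ}{nuclear; shell-like anisosomes (~20 per cell).}
#'   \item{dNLS}{cytoplasmic diffuse; cytoplasmic puncta and inclusions.}
#'   \item{dNLS_4FL, dNLS_2KQ}{cytoplasmic anisosomes and inclusions.}
#' }
#'
#' @param image_shape_px Integer pair, image rows and columns.
#' @param pixel_size_um Pixel size in micrometres.
#' @param bit_saturation Detector saturation value.
#' @param n_cells Number of cells to place.
#' @param transfection_fraction Probability a cell is transfected, in [0,1].
#' @param exo_expression_log_mean,exo_expression_log_sd Parameters of the
#'   per-cell lognormal exogenous expression level (intensity units).
#' @param variant One of `"GFP_only"`, `"WT"`, `"4FL"`, `"2KQ"`, `"dNLS"`,
#'   `"dNLS_4FL"`, `"dNLS_2KQ"`.
#' @param assembly_rates Named nonnegative numeric vector: expected
#'   (Poisson) assembly counts per transfected cell, names among
#'   `punctum`, `anisosome`, `inclusion`. `NULL` picks a variant default.
#' @param sequestration_coefficient Nonnegative partition coefficient: the
#'   endogenous concentration inside assemblies relative to the diffuse
#'   nuclear pool, for a cell at the population-mean expression level. The
#'   effective per-cell coefficient scales with the cell's exogenous
#'   expression, so higher expressers sequester more avidly. 0 means
#'   assemblies exclude endogenous protein.
#' @param endo_level Baseline diffuse nuclear endogenous intensity of an
#'   unperturbed cell (intensity units).
#' @param noise_sd Gaussian read-noise standard deviation (intensity units),
#'   added after ground truth is recorded.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A `scene_config` list, validated.
#' @export
scene_config <- function(image_shape_px = c(832L, 832L),
                         pixel_size_um = 0.19,
                         bit_saturation = 65535,
                         n_cells = 30L,
                         transfection_fraction = 0.8,
                         exo_expression_log_mean = log(5500),
                         exo_expression_log_sd = 0.4,
                         variant = c("WT", "GFP_only", "4FL", "2KQ",
                                     "dNLS", "dNLS_4FL", "dNLS_2KQ"),
                         assembly_rates = NULL,
                         sequestration_coefficient = 3,
                         endo_level = 9800,
                         noise_sd = 150,
                         seed = NULL) {
  variant <- match.arg(variant)
  if (is.null(assembly_rates)) assembly_rates <- default_assembly_rates(variant)
  bad <- setdiff(names(assembly_rates), c("punctum", "anisosome", "inclusion"))
  if (length(bad)) stop("unknown assembly class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(assembly_rates < 0)) stop("assembly rates must be >= 0", call. = FALSE)
  if (transfection_fraction < 0 || transfection_fraction > 1)
    stop("transfection_fraction must be in [0,1]", call. = FALSE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(bit_saturation, "bit_saturation", positive = TRUE)
  stopifnot_scalar(sequestration_coefficient, "sequestration_coefficient",
                   nonneg = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(image_shape_px) != 2L || any(image_shape_px < 16))
    stop("image_shape_px must be two integers >= 16", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  structure(list(
    image_shape_px = as.integer(image_shape_px),
    pixel_size_um = pixel_size_um, bit_saturation = bit_saturation,
    n_cells = as.integer(n_cells),
    transfection_fraction = transfection_fraction,
    exo_expression_log_mean = exo_expression_log_mean,
    exo_expression_log_sd = exo_expression_log_sd,
    variant = variant, assembly_rates = assembly_rates,
    sequestration_coefficient = sequestration_coefficient,
    endo_level = endo_level, noise_sd = noise_sd, seed = seed),
    class = "scene_config")
}

default_assembly_rates <- function(variant) {
  switch(variant,
    GFP_only = c(punctum = 0, anisosome = 0, inclusion = 0),
    WT       = c(punctum = 2, anisosome = 0, inclusion = 0.5),
    `4FL`    = c(punctum = 0, anisosome = 20, inclusion = 0),
    `2KQ`    = c(punctum = 0, anisosome = 20, inclusion = 0),
    dNLS     = c(punctum = 3, anisosome = 0, inclusion = 1),
    dNLS_4FL = c(punctum = 0, anisosome = 5, inclusion = 0.5),
    dNLS_2KQ = c(punctum = 0, anisosome = 5, inclusion = 0.5))
}

cytoplasmic_variant <- function(variant) {
  variant %in% c("dNLS", "dNLS_4FL", "dNLS_2KQ")
}

# Linear indices of pixels inside a rotated ellipse, clipped to the image.
ellipse_idx <- function(shape, center, a_px, b_px, theta = 0) {
  rmax <- ceiling(max(a_px, b_px))
  r0 <- center[1]; c0 <- center[2]
  rows <- max(1L, floor(r0 - rmax)):min(shape[1], ceiling(r0 + rmax))
  cols <- max(1L, floor(c0 - rmax)):min(shape[2], ceiling(c0 + rmax))
  if (!length(rows) || !length(cols)) return(integer(0))
  dr <- rows - r0
  dc <- cols - c0
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr, dc, function(y, x) (x * ct + y * st) / a_px)
  v <- outer(dr, dc, function(y, x) (-x * st + y * ct) / b_px)
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  if (!nrow(inside)) return(integer(0))
  rows[inside[, 1]] + (cols[inside[, 2]] - 1L) * shape[1]
}

disk_idx <- function(shape, center, r_px) ellipse_idx(shape, center, r_px, r_px)

#' Render a ground-truthed synthetic two-channel scene
#'
#' Draws cells as elliptical nuclei (with 1-3 dark nucleolar voids) wrapped
#' in an elliptical cytoplasm, assigns per-cell lognormal exogenous
#' expression, populates transfected cells with assemblies (puncta:
#' homogeneous disks 0.5-2.5 um; anisosomes: shells ~1-4 um with a core
#' void; inclusions: amorphous saturated blobs > 4 um), and partitions
#' each cell's endogenous signal between the diffuse nuclear pool and
#' assembly pixels with exact conservation: given partition coefficient
#' K and a fixed per-cell endowment, the diffuse concentration is
#' `c = T / (A_diffuse + K * A_assembly)` and assembly pixels carry `K*c`.
#' Gaussian read noise is added last; ground truth is recorded before noise.
#'
#' @param cfg A [scene_config()].
#' @return A list with elements `scene` (an [image_scene()]) and
#'   `ground_truth`: a list with `cells` and `assemblies` data frames plus
#'   label matrices `nucleus_labels`, `cell_labels`, `assembly_labels`
#'   (the per-object oracle masks).
#' @export
render_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, render_scene_impl(cfg))
}

render_scene_impl <- function(cfg) {
  shape <- cfg$image_shape_px
  psz <- cfg$pixel_size_um
  sat <- cfg$bit_saturation
  endo <- matrix(0, shape[1], shape[2])
  exo <- matrix(0, shape[1], shape[2])
  nucleus_labels <- matrix(0L, shape[1], shape[2])
  cell_labels <- matrix(0L, shape[1], shape[2])
  assembly_labels <- matrix(0L, shape[1], shape[2])

  cyto_width_um <- 3.5
  um2px <- function(x) x / psz

  # -- place cells: cytoplasm ellipses must not overlap ----------------------
  cells <- list()
  if (cfg$n_cells > 0) {
    attempts <- 0L
    max_attempts <- 400L * cfg$n_cells
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)   # max cytoplasm semi-axis, px
    while (length(cells) < cfg$n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "could not place %d non-overlapping cells in a %dx%d px image",
          cfg$n_cells, shape[1], shape[2]), call. = FALSE)
      a_um <- runif(1, 5.5, 7.5); b_um <- runif(1, 5.5, 7.5)
      theta <- runif(1, 0, pi)
      cyto_r_px <- um2px(max(a_um, b_um) + cyto_width_um)
      margin <- cyto_r_px + 2
      if (2 * margin >= min(shape)) stop("image too small for a cell", call. = FALSE)
      ctr <- c(runif(1, margin, shape[1] - margin),
               runif(1, margin, shape[2] - margin))
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
        if (any(d < radii + cyto_r_px + um2px(0.5))) next
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, cyto_r_px)
      cells[[length(cells) + 1L]] <- list(
        center = ctr, a_um = a_um, b_um = b_um, theta = theta)
    }
  }

  cells_df <- data.frame()
  assemblies_df <- data.frame()
  asm_id <- 0L

  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    a_px <- um2px(cell$a_um); b_px <- um2px(cell$b_um)
    nuc_idx <- ellipse_idx(shape, cell$center, a_px, b_px, cell$theta)
    cyto_idx <- ellipse_idx(shape, cell$center,
                            a_px + um2px(cyto_width_um),
                            b_px + um2px(cyto_width_um), cell$theta)
    nucleus_labels[nuc_idx] <- i
    cell_labels[cyto_idx] <- i

    # nucleolar voids (endogenous-dark), fully inside the nucleus
    n_voids <- sample(1:3, 1)
    void_idx <- integer(0)
    for (v in seq_len(n_voids)) {
      rv_um <- runif(1, 0.5, 0.9)
      pos <- void_center(cell, rv_um, psz)
      void_idx <- c(void_idx, disk_idx(shape, pos, um2px(rv_um)))
    }
    void_idx <- intersect(unique(void_idx), nuc_idx)

    transfected <- runif(1) < cfg$transfection_fraction
    exo_level <- if (transfected)
      rlnorm(1, cfg$exo_expression_log_mean, cfg$exo_expression_log_sd) else 0

    # -- assemblies ----------------------------------------------------------
    cell_asms <- list()
    expr_scale <- exo_level /
      exp(cfg$exo_expression_log_mean + cfg$exo_expression_log_sd^2 / 2)
    if (transfected && cfg$variant != "GFP_only") {
      for (cls in names(cfg$assembly_rates)) {
        rate <- cfg$assembly_rates[[cls]]
        if (rate <= 0) next
        n_k <- rpois(1, rate)
        for (k in seq_len(n_k)) {
          asm <- place_assembly(cls, cell, cell_asms, cfg, shape)
          if (!is.null(asm)) cell_asms[[length(cell_asms) + 1L]] <- asm
        }
      }
    }

    # -- endogenous partition with conservation ------------------------------
    asm_endo_idx <- lapply(cell_asms, `[[`, "endo_idx")
    all_asm_idx <- unlist(lapply(cell_asms, `[[`, "idx"))
    diff_idx <- setdiff(setdiff(nuc_idx, void_idx), all_asm_idx)
    A_diff <- length(diff_idx)
    A_seq <- sum(lengths(asm_endo_idx))
    total_endo <- cfg$endo_level * length(setdiff(nuc_idx, void_idx))
    # assemblies built from more exogenous protein capture endogenous
    # protein more avidly: the effective partition coefficient scales with
    # the cell's expression relative to the population mean
    K <- cfg$sequestration_coefficient * expr_scale
    denom <- A_diff + K * A_seq
    conc <- if (denom > 0) total_endo / denom else 0
    endo[diff_idx] <- conc
    true_seq <- numeric(length(cell_asms))
    for (j in seq_along(cell_asms)) {
      endo[asm_endo_idx[[j]]] <- K * conc
      true_seq[j] <- K * conc * length(asm_endo_idx[[j]])
    }

    # -- exogenous channel ---------------------------------------------------
    if (transfected) {
      # diffuse pool saturates below the detection threshold: very high
      # expressers partition excess protein into assemblies, not the pool
      paint_level <- min(exo_level, 0.95 * 0.25 * sat)
      if (cfg$variant == "GFP_only") {
        exo[cyto_idx] <- paint_level
      } else if (cytoplasmic_variant(cfg$variant)) {
        exo[setdiff(cyto_idx, nuc_idx)] <- paint_level
        exo[setdiff(nuc_idx, void_idx)] <- 0.1 * paint_level
      } else {
        exo[setdiff(cyto_idx, nuc_idx)] <- 0.1 * paint_level
        exo[setdiff(nuc_idx, void_idx)] <- paint_level
      }
    }
    for (j in seq_along(cell_asms)) {
      asm <- cell_asms[[j]]
      exo[asm$idx] <- asm$exo_core
      exo[asm$exo_rim_idx] <- asm$exo_rim
      asm_id <- asm_id + 1L
      assembly_labels[asm$idx] <- asm_id
      cell_labels[asm$idx] <- i   # cytoplasmic blobs can poke past the ellipse
      n_px <- length(asm$idx)
      core_idx <- setdiff(asm$idx, asm$exo_rim_idx)
      core_rim <- if (length(core_idx) && length(asm$exo_rim_idx) < n_px)
        asm$exo_core / asm$exo_rim else NA_real_
      assemblies_df <- rbind(assemblies_df, data.frame(
        assembly_id = asm_id, cell_id = i, class = asm$class,
        compartment = asm$compartment,
        center_row = asm$center[1], center_col = asm$center[2],
        diameter_um = equiv_diameter_um(n_px, psz),
        n_px = n_px, true_sequestered = true_seq[j],
        true_core_rim_ratio = core_rim))
    }

    cells_df <- rbind(cells_df, data.frame(
      cell_id = i, center_row = cell$center[1], center_col = cell$center[2],
      nucleus_a_um = cell$a_um, nucleus_b_um = cell$b_um, theta = cell$theta,
      n_voids = n_voids, transfected = transfected, exo_level = exo_level,
      true_total_endogenous = total_endo,
      true_diffuse = conc * A_diff,
      true_sequestered = sum(true_seq),
      n_assemblies = length(cell_asms)))
  }

  ground_truth <- list(
    cells = cells_df, assemblies = assemblies_df,
    nucleus_labels = nucleus_labels, cell_labels = cell_labels,
    assembly_labels = assembly_labels, config = cfg)

  if (cfg$noise_sd > 0) {
    endo <- endo + rnorm(length(endo), 0, cfg$noise_sd)
    exo <- exo + rnorm(length(exo), 0, cfg$noise_sd)
  }
  endo <- pmin(pmax(endo, 0), sat)
  exo <- pmin(pmax(exo, 0), sat)
  dim(endo) <- shape; dim(exo) <- shape

  list(scene = image_scene(endo, exo, psz, sat), ground_truth = ground_truth)
}

# A nucleolar void center such that the void stays inside the nucleus.
void_center <- function(cell, rv_um, psz) {
  a <- cell$a_um - rv_um - 0.2
  b <- cell$b_um - rv_um - 0.2
  phi <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
  x <- rho * a * cos(phi); y <- rho * b * sin(phi)
  ct <- cos(cell$theta); st <- sin(cell$theta)
  cell$center + c(x * st + y * ct, x * ct - y * st) / psz
}

# Draw geometry + intensities for one assembly; NULL if it cannot be placed
# without overlapping earlier assemblies of the same cell.
place_assembly <- function(cls, cell, existing, cfg, shape) {
  psz <- cfg$pixel_size_um; sat <- cfg$bit_saturation
  cyto <- cytoplasmic_variant(cfg$variant)
  diam_um <- switch(cls,
    punctum = runif(1, 0.5, 2.5),
    # right-skewed over ~1-4 um: most shells are small
    anisosome = 1 + 3 * stats::rbeta(1, 1.1, 6),
    inclusion = runif(1, 4.3, 5.8))
  r_px <- diam_um / 2 / psz
  for (try in 1:300) {
    ctr <- assembly_center(cell, r_px * psz, inclusion = cls == "inclusion",
                           cytoplasmic = cyto, psz = psz)
    if (ctr[1] - r_px < 2 || ctr[2] - r_px < 2 ||
        ctr[1] + r_px > shape[1] - 1 || ctr[2] + r_px > shape[2] - 1) next
    ok <- TRUE
    for (e in existing) {
      if (sqrt(sum((e$center - ctr)^2)) < e$r_px + r_px + 1) { ok <- FALSE; break }
    }
    if (!ok) next
    return(build_assembly(cls, ctr, r_px, diam_um, cell, cfg, shape))
  }
  NULL
}

assembly_center <- function(cell, r_um, inclusion, cytoplasmic, psz) {
  ct <- cos(cell$theta); st <- sin(cell$theta)
  if (cytoplasmic) {
    # hugging the nuclear envelope from outside: most of the object sits in
    # the cytoplasm, but it stays well inside its own cell's territory so
    # segmentation attributes it to the right parent
    phi <- runif(1, 0, 2 * pi)
    off <- 0.3 + 0.55 * r_um
    a <- cell$a_um + off; b <- cell$b_um + off
    x <- a * cos(phi); y <- b * sin(phi)
  } else if (inclusion) {
    # inclusions are as wide as the nucleus; keep them centred so that the
    # majority of their pixels stay nuclear even when lobes cross the envelope
    a <- 0.35 * cell$a_um; b <- 0.35 * cell$b_um
    phi <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
    x <- rho * a * cos(phi); y <- rho * b * sin(phi)
  } else {
    a <- max(0.1, cell$a_um - r_um - 0.2)
    b <- max(0.1, cell$b_um - r_um - 0.2)
    phi <- runif(1, 0, 2 * pi); rho <- sqrt(runif(1))
    x <- rho * a * cos(phi); y <- rho * b * sin(phi)
  }
  cell$center + c(x * st + y * ct, x * ct - y * st) / psz
}

build_assembly <- function(cls, ctr, r_px, diam_um, cell, cfg, shape) {
  sat <- cfg$bit_saturation
  if (cls == "punctum") {
    idx <- disk_idx(shape, ctr, r_px)
    list(class = cls, center = ctr, r_px = r_px, idx = idx,
         endo_idx = idx, exo_rim_idx = idx,
         exo_rim = 0.35 * sat, exo_core = 0.35 * sat,
         compartment = assembly_compartment(cfg))
  } else if (cls == "anisosome") {
    idx <- disk_idx(shape, ctr, r_px)
    core <- disk_idx(shape, ctr, 0.55 * r_px)
    rim <- setdiff(idx, core)
    # shell carries the protein; the core is a void of both channels
    list(class = cls, center = ctr, r_px = r_px, idx = idx,
         endo_idx = rim, exo_rim_idx = rim,
         exo_rim = 0.42 * sat, exo_core = 0.06 * sat,
         compartment = assembly_compartment(cfg))
  } else {
    # amorphous blob: main disk plus 2-4 overlapping satellite lobes
    idx <- disk_idx(shape, ctr, r_px)
    for (s in seq_len(sample(2:4, 1))) {
      phi <- runif(1, 0, 2 * pi)
      off <- runif(1, 0.6, 0.9) * r_px
      rs <- runif(1, 0.3, 0.5) * r_px
      idx <- union(idx, disk_idx(shape, ctr + off * c(sin(phi), cos(phi)), rs))
    }
    lvl <- runif(1, 0.7, 0.85) * sat
    list(class = cls, center = ctr, r_px = r_px, idx = idx,
         endo_idx = idx, exo_rim_idx = idx, exo_rim = lvl, exo_core = lvl,
         compartment = assembly_compartment(cfg))
  }
}

assembly_compartment <- function(cfg) {
  if (cytoplasmic_variant(cfg$variant)) "cytoplasmic" else "nuclear"
}
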