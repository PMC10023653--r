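#' Classifier parameters for assembly detection
#'
#' Encodes the published decision rules: inclusions are large bright
#' objects (intensity above 60% of the saturation point, minimum diameter
#' 4 um); anisosomes/puncta are objects above 25% of saturation with
#' diameter 0.5-4 um, separated from each other by shell morphology
#' (core-to-rim intensity ratio).
#'
#' @param inclusion_intensity_frac Object maximum intensity threshold for
#'   inclusions, as a fraction of saturation (default 0.60).
#' @param puncta_intensity_frac Pixel detection threshold, fraction of
#'   saturation (default 0.25).
#' @param inclusion_min_diameter_um Minimum inclusion equivalent diameter
#'   (default 4).
#' @param puncta_min_diameter_um,puncta_max_diameter_um Diameter window for
#'   puncta/anisosomes (defaults 0.5 and 4).
#' @param shell_core_rim_ratio_max Objects whose core/rim mean-intensity
#'   ratio is at or below this are anisosomes (default 0.5). The core is
#'   the pixel set within 40% of the object-equivalent radius of the
#'   intensity-weighted centroid.
#' @param transfected_gfp_threshold Exogenous mean intensity above which a
#'   cell is called transfected; usually derived from control scenes
#'   (see [build_control_reference()]). `NA` leaves cells unflagged.
#' @return A validated `classifier_params` list.
#' @export
classifier_params <- function(inclusion_intensity_frac = 0.60,
                              puncta_intensity_frac = 0.25,
                              inclusion_min_diameter_um = 4,
                              puncta_min_diameter_um = 0.5,
                              puncta_max_diameter_um = 4,
                              shell_core_rim_ratio_max = 0.5,
                              transfected_gfp_threshold = NA_real_) {
  if (!(puncta_intensity_frac > 0 && puncta_intensity_frac <
        inclusion_intensity_frac && inclusion_intensity_frac <= 1))
    stop("need 0 < puncta_intensity_frac < inclusion_intensity_frac <= 1",
         call. = FALSE)
  if (!(puncta_min_diameter_um > 0 &&
        puncta_min_diameter_um < puncta_max_diameter_um))
    stop("need 0 < puncta_min_diameter_um < puncta_max_diameter_um",
         call. = FALSE)
  structure(list(
    inclusion_intensity_frac = inclusion_intensity_frac,
    puncta_intensity_frac = puncta_intensity_frac,
    inclusion_min_diameter_um = inclusion_min_diameter_um,
    puncta_min_diameter_um = puncta_min_diameter_um,
    puncta_max_diameter_um = puncta_max_diameter_um,
    shell_core_rim_ratio_max = shell_core_rim_ratio_max,
    transfected_gfp_threshold = transfected_gfp_threshold),
    class = "classifier_params")
}

#' Segment nuclei from the endogenous channel
#'
#' Global automatic (Otsu) threshold on the endogenous channel, hole
#' filling (so nucleolar voids belong to their nucleus), morphological
#' opening, distance-map watershed to split touching nuclei, and a
#' minimum-diameter filter.
#'
#' Bright endogenous objects that are also bright in the exogenous
#' channel are aggregates sequestering endogenous protein, not nuclei;
#' candidate labels whose median exogenous intensity reaches
#' `exclude_exo_frac` of saturation are therefore dropped.
#'
#' @param scene An [image_scene()].
#' @param min_diameter_um Smallest acceptable nucleus equivalent diameter
#'   (default 5 um).
#' @param exclude_exo_frac Exogenous mean-intensity fraction above which
#'   a candidate (by median, robust to contained inclusions) is rejected as an aggregate (default 0.25, the assembly
#'   detection threshold).
#' @param threshold_correction Multiplier on the automatic threshold
#'   (default 0.6), the usual correction factor applied when the nuclear
#'   marker itself is depleted by the phenotype under study.
#' @return Integer label matrix; 0 is background. Blank images give an
#'   all-zero matrix.
#' @export
segment_nuclei <- function(scene, min_diameter_um = 5,
                           exclude_exo_frac = 0.25,
                           threshold_correction = 0.6) {
  stopifnot(inherits(scene, "image_scene"))
  x <- scene$endogenous / scene$bit_saturation
  if (max(x) - min(x) < 1e-6) return(matrix(0L, nrow(x), ncol(x)))
  # Two-level guard: with bright aggregates present, Otsu can split
  # aggregates from everything else; when the resulting foreground is
  # implausibly small for a field of cells, rethreshold below the first
  # cut. The correction factor < 1 then keeps nuclei whose diffuse pool
  # is depleted several-fold by sequestration.
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  if (mean(x > thr) < 0.05) {
    sub <- x[x <= thr]
    thr <- EBImage::otsu(EBImage::Image(matrix(sub, nrow = 1L)),
                         range = c(0, 1))
  }
  thr <- threshold_correction * thr
  mask <- x > thr
  # aggregate pixels are bright in the exogenous channel; cutting them out
  # before hole filling keeps envelope-hugging cytoplasmic assemblies (which
  # also sequester endogenous signal) out of the nucleus mask, while
  # assemblies wholly inside a nucleus are refilled as interior holes
  if (!is.na(exclude_exo_frac))
    mask <- mask & (scene$exogenous < exclude_exo_frac * scene$bit_saturation)
  mask <- EBImage::fillHull(EBImage::Image(mask))
  mask <- EBImage::opening(mask, EBImage::makeBrush(5, "disc"))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = 1.5)
  labels <- prune_small(labels, min_diameter_um, scene$pixel_size_um)
  lab <- EBImage::imageData(labels)
  n <- max(lab)
  if (n > 0 && !is.na(exclude_exo_frac)) {
    exo_cut <- exclude_exo_frac * scene$bit_saturation
    drop <- which(vapply(seq_len(n), function(i)
      stats::median(scene$exogenous[lab == i]) >= exo_cut, logical(1)))
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      lab[] <- match(lab, keep, nomatch = 0L)
    }
  }
  matrix(as.integer(lab), nrow(x), ncol(x))
}

prune_small <- function(labels, min_diameter_um, pixel_size_um) {
  dat <- EBImage::imageData(labels)
  min_area <- pi * (min_diameter_um / 2 / pixel_size_um)^2
  tab <- tabulate(dat)
  drop <- which(tab > 0 & tab < min_area)
  if (length(drop)) dat[dat %in% drop] <- 0L
  keep <- sort(unique(dat[dat > 0]))
  if (length(keep)) dat[] <- match(dat, keep, nomatch = 0L)
  EBImage::Image(dat)
}

#' Grow cell regions from nucleus seeds
#'
#' Each nucleus is propagated into a cell body by seeded Voronoi-style
#' region growing (EBImage \code{propagate}) over the summed-channel
#' intensity, restricted to a mask of above-background signal plus a
#' bounded dilation of the nuclei. Every nucleus pixel belongs to its
#' own cell.
#'
#' @param scene An [image_scene()].
#' @param nuclei Label matrix from [segment_nuclei()].
#' @param max_radius_um How far beyond its nucleus a cell may extend
#'   (default 6 um).
#' @return Integer label matrix of cells, label-matched to `nuclei`.
#' @export
segment_cells <- function(scene, nuclei, max_radius_um = 6) {
  stopifnot(inherits(scene, "image_scene"))
  if (!any(nuclei > 0)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  s <- (scene$endogenous + scene$exogenous) / (2 * scene$bit_saturation)
  r_px <- max(1L, round(max_radius_um / scene$pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, "disc")
  grown <- EBImage::dilate(EBImage::Image(nuclei > 0), brush)
  bg <- stats::median(s)
  mask <- (s > bg + 0.02) | (EBImage::imageData(grown) > 0)
  cells <- EBImage::propagate(EBImage::Image(s), EBImage::Image(nuclei),
                              mask = EBImage::Image(mask), lambda = 1e-2)
  matrix(as.integer(EBImage::imageData(cells)), nrow(nuclei), ncol(nuclei))
}

#' Classify one candidate object by the published decision rules
#'
#' Pure decision function, exported so the rules can be exercised exactly:
#' an object is an inclusion if its equivalent diameter is at least
#' `inclusion_min_diameter_um` AND its maximum intensity is at least
#' `inclusion_intensity_frac` of saturation; otherwise, if its diameter
#' falls in `[puncta_min, puncta_max)` it is an anisosome when the
#' core/rim ratio is at or below `shell_core_rim_ratio_max` (or a punctum
#' when above, or when no core can be measured); anything else is
#' discarded (`"none"`). Large-but-dim objects (diameter >= 4 um that
#' pass only the 25% detection threshold) are discarded as
#' unclassifiable.
#'
#' @param equivalent_diameter_um Object area-equivalent diameter, um.
#' @param max_intensity_frac Object maximum intensity as a fraction of
#'   saturation.
#' @param core_rim_ratio Core/rim mean intensity ratio, or `NA`.
#' @param params A [classifier_params()].
#' @return One of `"inclusion"`, `"anisosome"`, `"punctum"`, `"none"`.
#' @export
classify_assembly <- function(equivalent_diameter_um, max_intensity_frac,
                              core_rim_ratio = NA_real_,
                              params = classifier_params()) {
  if (max_intensity_frac < params$puncta_intensity_frac) return("none")
  if (equivalent_diameter_um >= params$inclusion_min_diameter_um &&
      max_intensity_frac >= params$inclusion_intensity_frac) return("inclusion")
  if (equivalent_diameter_um >= params$puncta_min_diameter_um &&
      equivalent_diameter_um < params$puncta_max_diameter_um) {
    if (!is.na(core_rim_ratio) &&
        core_rim_ratio <= params$shell_core_rim_ratio_max) return("anisosome")
    return("punctum")
  }
  "none"
}

#' Detect and classify assemblies in the exogenous channel
#'
#' Candidate objects are hole-filled connected components of pixels at or
#' above `puncta_intensity_frac * bit_saturation` in the exogenous
#' channel (hole filling makes ring-shaped anisosomes single objects with
#' measurable cores). Each object is measured (area-equivalent diameter,
#' per-channel means, maximum exogenous intensity, core/rim ratio) and
#' classified with [classify_assembly()]. The parent cell is the cell
#' label covering the majority of object pixels; the compartment is
#' nuclear when more than half of the pixels (ties included) lie in the
#' parent nucleus. Objects touching the image border are flagged so they
#' can be excluded from size statistics.
#'
#' @param scene An [image_scene()].
#' @param cells Cell label matrix ([segment_cells()]); may be the nucleus
#'   labels when no cytoplasm is segmented.
#' @param nuclei Nucleus label matrix ([segment_nuclei()]).
#' @param params A [classifier_params()].
#' @return `data.frame` with one row per detected (non-discarded) object:
#'   `assembly_id`, `cell_id`, `class`, `compartment`, `area_um2`,
#'   `equivalent_diameter_um`, `max_exogenous`, `mean_exogenous`,
#'   `mean_endogenous`, `core_rim_ratio`, `on_border`, `sequestering`
#'   (`NA` until [flag_sequestering()]), plus an attribute
#'   `"qc_discarded"` counting unclassifiable objects.
#' @export
detect_assemblies <- function(scene, cells, nuclei,
                              params = classifier_params()) {
  stopifnot(inherits(scene, "image_scene"))
  sat <- scene$bit_saturation
  psz <- scene$pixel_size_um
  exo <- scene$exogenous
  mask <- exo >= params$puncta_intensity_frac * sat
  empty <- data.frame(
    assembly_id = integer(0), cell_id = integer(0), class = character(0),
    compartment = character(0), area_um2 = numeric(0),
    equivalent_diameter_um = numeric(0), max_exogenous = numeric(0),
    mean_exogenous = numeric(0), mean_endogenous = numeric(0),
    core_rim_ratio = numeric(0), on_border = logical(0),
    sequestering = logical(0))
  attr(empty, "qc_discarded") <- 0L
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask)))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(exo), ncol(exo))
  n_obj <- max(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  px <- split(seq_along(lab), factor(lab, levels = 0:n_obj))[-1]

  rows <- vector("list", n_obj)
  discarded <- 0L
  for (o in seq_len(n_obj)) {
    idx <- px[[o]]
    n_px <- length(idx)
    d_um <- equiv_diameter_um(n_px, psz)
    vals <- exo[idx]
    ri <- (idx - 1L) %% nr + 1L
    ci <- (idx - 1L) %/% nr + 1L
    w <- vals / sum(vals)
    cen <- c(sum(ri * w), sum(ci * w))
    r_core <- 0.4 * d_um / 2 / psz
    core <- sqrt((ri - cen[1])^2 + (ci - cen[2])^2) <= r_core
    core_rim <- if (any(core) && any(!core))
      mean(vals[core]) / mean(vals[!core]) else NA_real_
    cls <- classify_assembly(d_um, max(vals) / sat, core_rim, params)
    if (cls == "none") { discarded <- discarded + 1L; next }
    cell_tab <- tabulate(cells[idx], nbins = max(cells, 1L))
    cell_id <- if (any(cell_tab > 0)) which.max(cell_tab) else NA_integer_
    in_nuc <- if (!is.na(cell_id)) sum(nuclei[idx] == cell_id) else 0L
    compartment <- if (in_nuc >= n_px / 2) "nuclear" else "cytoplasmic"
    on_border <- any(ri == 1L | ri == nr | ci == 1L | ci == nc)
    rows[[o]] <- data.frame(
      assembly_id = o, cell_id = cell_id, class = cls,
      compartment = compartment, area_um2 = n_px * psz^2,
      equivalent_diameter_um = d_um, max_exogenous = max(vals),
      mean_exogenous = mean(vals), mean_endogenous = mean(scene$endogenous[idx]),
      core_rim_ratio = core_rim, on_border = on_border, sequestering = NA)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  attr(out, "qc_discarded") <- discarded
  attr(out, "labels") <- lab
  out
}

#' Intensity profile along a line segment
#'
#' Samples both channels along the segment from `start_point` to
#' `end_point` (row, col in pixels) at approximately one-pixel spacing
#' using bilinear interpolation. When per-channel control means are
#' supplied, intensities are reported relative to those means (the
#' convention used to compare cells against GFP-only controls).
#'
#' @param scene An [image_scene()].
#' @param start_point,end_point Numeric `(row, col)` pairs inside the image.
#' @param control_means Optional named vector
#'   `c(endogenous = ..., exogenous = ...)`.
#' @return `data.frame` with `distance_um`, `endogenous`, `exogenous`.
#' @export
line_profile <- function(scene, start_point, end_point, control_means = NULL) {
  stopifnot(inherits(scene, "image_scene"))
  d_px <- sqrt(sum((end_point - start_point)^2))
  if (d_px == 0) stop("degenerate zero-length profile segment", call. = FALSE)
  shp <- dim(scene$endogenous)
  pts <- rbind(start_point, end_point)
  if (any(pts < 1) || any(pts[, 1] > shp[1]) || any(pts[, 2] > shp[2]))
    stop("profile endpoints must lie inside the image", call. = FALSE)
  n <- max(2L, ceiling(d_px) + 1L)
  t <- seq(0, 1, length.out = n)
  r <- start_point[1] + t * (end_point[1] - start_point[1])
  c_ <- start_point[2] + t * (end_point[2] - start_point[2])
  prof <- data.frame(
    distance_um = t * d_px * scene$pixel_size_um,
    endogenous = bilinear(scene$endogenous, r, c_),
    exogenous = bilinear(scene$exogenous, r, c_))
  if (!is.null(control_means)) {
    prof$endogenous <- prof$endogenous / control_means[["endogenous"]]
    prof$exogenous <- prof$exogenous / control_means[["exogenous"]]
  }
  prof
}

bilinear <- function(m, r, c_) {
  r0 <- pmin(pmax(floor(r), 1L), nrow(m) - 1L)
  c0 <- pmin(pmax(floor(c_), 1L), ncol(m) - 1L)
  fr <- pmin(pmax(r - r0, 0), 1); fc <- pmin(pmax(c_ - c0, 0), 1)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
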