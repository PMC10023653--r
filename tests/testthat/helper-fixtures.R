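# Shared fixture builders. Everything is generated in code; no files.

# Small, fast scene: 6 cells in a 448 px field.
small_cfg <- function(variant = "WT", seed = 1, ...) {
  scene_config(image_shape_px = c(448L, 448L), n_cells = 6L,
               variant = variant, seed = seed, ...)
}

# Paint a disk into a matrix; returns the modified matrix.
paint_disk <- function(m, center, r_px, value) {
  idx <- tdpquant:::disk_idx(dim(m), center, r_px)
  m[idx] <- value
  m
}

# Paint a ring (outer radius r, core radius cr): rim at rim_value,
# core at core_value.
paint_ring <- function(m, center, r_px, core_frac, rim_value, core_value) {
  outer <- tdpquant:::disk_idx(dim(m), center, r_px)
  core <- tdpquant:::disk_idx(dim(m), center, core_frac * r_px)
  m[setdiff(outer, core)] <- rim_value
  m[core] <- core_value
  m
}

# A one-object scene: blank endogenous channel, one exogenous object.
object_scene <- function(paint, pixel_size_um = 0.19, size = 128L) {
  exo <- paint(matrix(0, size, size))
  image_scene(matrix(0, size, size), exo, pixel_size_um, 65535)
}

# IoU of the best-overlapping segmented label against one truth mask.
best_iou <- function(labels, truth_mask) {
  inside <- labels[truth_mask]
  if (!any(inside > 0)) return(0)
  l <- as.integer(names(which.max(table(inside[inside > 0]))))
  det <- labels == l
  sum(det & truth_mask) / sum(det | truth_mask)
}

# Map detected assemblies to ground-truth objects by best pixel overlap;
# returns a data.frame of matched pairs (gt row, detected row index or NA).
match_assemblies <- function(gt, detected) {
  det_lab <- attr(detected, "labels")
  out <- lapply(seq_len(nrow(gt$assemblies)), function(k) {
    idx <- which(gt$assembly_labels == gt$assemblies$assembly_id[k])
    hits <- det_lab[idx]
    det_id <- if (any(hits > 0))
      as.integer(names(which.max(table(hits[hits > 0])))) else NA_integer_
    row <- if (!is.na(det_id) && det_id %in% detected$assembly_id)
      which(detected$assembly_id == det_id) else NA_integer_
    data.frame(gt_row = k, det_row = row)
  })
  do.call(rbind, out)
}

# Independent sorted-interpolation quantile (brute-force oracle for the
# linear-interpolation convention).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo == h) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
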