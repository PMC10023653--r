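test_that("nuclei are recovered with high overlap on synthetic scenes", {
  r <- render_scene(scene_config(n_cells = 30L, variant = "WT", seed = 8))
  nuc <- segment_nuclei(r$scene)
  expect_equal(max(nuc), 30)
  ious <- sapply(r$ground_truth$cells$cell_id, function(i)
    best_iou(nuc, r$ground_truth$nucleus_labels == i))
  expect_true(all(ious >= 0.7))
})

test_that("blank images segment to nothing", {
  blank <- image_scene(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(max(segment_nuclei(blank)), 0)
  expect_equal(max(segment_cells(blank, matrix(0L, 64, 64))), 0)
  asm <- detect_assemblies(blank, matrix(0L, 64, 64), matrix(0L, 64, 64))
  expect_equal(nrow(asm), 0)
})

test_that("touching nuclei are split by the watershed", {
  endo <- matrix(0, 128, 128)
  # two 5.7-um disks touching at a tangent point
  endo <- paint_disk(endo, c(64, 49), 15, 10000)
  endo <- paint_disk(endo, c(64, 79), 15, 10000)
  sc <- image_scene(endo, matrix(0, 128, 128), 0.19, 65535)
  nuc <- segment_nuclei(sc)
  expect_equal(max(nuc), 2)
})

test_that("cells contain their nuclei and tile without overlap", {
  r <- render_scene(small_cfg(variant = "GFP_only", seed = 12))
  nuc <- segment_nuclei(r$scene)
  cel <- segment_cells(r$scene, nuc)
  for (i in seq_len(max(nuc)))
    expect_true(all(cel[nuc == i] == i))
})

test_that("decision rules classify the printed examples", {
  p <- classifier_params()
  # bright 5-um disk -> inclusion; dim 2-um disk -> punctum
  expect_equal(classify_assembly(5, 0.7, NA, p), "inclusion")
  expect_equal(classify_assembly(2, 0.3, NA, p), "punctum")
  # 2-um ring with hollow core -> anisosome
  expect_equal(classify_assembly(2, 0.3, 0.2, p), "anisosome")
  # sub-resolution speck -> discarded
  expect_equal(classify_assembly(0.4, 0.3, NA, p), "none")
  # >= 4 um but below the 60% brightness rule -> unclassifiable
  expect_equal(classify_assembly(5, 0.4, NA, p), "none")
})

test_that("detection thresholds are applied with >= at the boundary", {
  sat <- 65535
  at <- object_scene(function(m) paint_disk(m, c(64, 64), 6, 0.25 * sat))
  below <- object_scene(function(m) paint_disk(m, c(64, 64), 6,
                                               0.25 * sat - 1))
  zeros <- matrix(0L, 128, 128)
  expect_equal(nrow(detect_assemblies(at, zeros, zeros)), 1)
  expect_equal(nrow(detect_assemblies(below, zeros, zeros)), 0)
})

test_that("the 4-um inclusion size boundary is exact on pixel masks", {
  sat <- 65535
  zeros <- matrix(0L, 128, 128)
  # a blob of exactly n pixels has equivalent diameter 2*sqrt(n/pi)*psz;
  # n = 348 px at 0.19 um/px sits just under 4 um, n = 349 just over
  n_under <- floor(pi * (2 / 0.19)^2)     # 348 -> 3.9994 um
  blob <- function(n) {
    m <- matrix(0, 128, 128)
    rows <- 40 + (seq_len(n) - 1) %% 30
    cols <- 40 + (seq_len(n) - 1) %/% 30
    m[cbind(rows, cols)] <- 0.61 * sat
    m
  }
  under <- detect_assemblies(image_scene(zeros * 0, blob(n_under)),
                             zeros, zeros)
  over <- detect_assemblies(image_scene(zeros * 0, blob(n_under + 1)),
                            zeros, zeros)
  expect_lt(under$equivalent_diameter_um, 4)
  expect_gte(over$equivalent_diameter_um, 4)
  expect_equal(under$class, "punctum")
  expect_equal(over$class, "inclusion")
})

test_that("classification in um is invariant to pixel size", {
  for (psz in c(0.19, 0.38)) {
    sc <- object_scene(function(m)
      paint_disk(m, c(64, 64), 1 / psz, 0.3 * 65535), pixel_size_um = psz)
    asm <- detect_assemblies(sc, matrix(0L, 128, 128), matrix(0L, 128, 128))
    expect_equal(asm$class, "punctum")
    expect_equal(asm$equivalent_diameter_um, 2, tolerance = 0.1)
  }
})

test_that("rings are detected whole and called anisosomes", {
  sat <- 65535
  sc <- object_scene(function(m)
    paint_ring(m, c(64, 64), 8, 0.55, 0.42 * sat, 0.06 * sat))
  asm <- detect_assemblies(sc, matrix(0L, 128, 128), matrix(0L, 128, 128))
  expect_equal(nrow(asm), 1)
  expect_equal(asm$class, "anisosome")
  # hole filling recovers the full disk footprint
  expect_equal(asm$equivalent_diameter_um, 2 * 8 * 0.19, tolerance = 0.1)
  expect_lt(asm$core_rim_ratio, 0.3)
})

test_that("border-straddling objects are flagged", {
  sat <- 65535
  sc <- object_scene(function(m) paint_disk(m, c(2, 64), 6, 0.3 * sat))
  asm <- detect_assemblies(sc, matrix(0L, 128, 128), matrix(0L, 128, 128))
  expect_true(asm$on_border)
})

test_that("compartment assignment follows the majority rule", {
  sat <- 65535
  nuclei <- matrix(0L, 128, 128)
  nuclei[tdpquant:::disk_idx(c(128, 128), c(64, 64), 30)] <- 1L
  cells <- matrix(1L, 128, 128)
  inside <- object_scene(function(m) paint_disk(m, c(64, 64), 5, 0.3 * sat))
  outside <- object_scene(function(m) paint_disk(m, c(64, 110), 5, 0.3 * sat))
  expect_equal(detect_assemblies(inside, cells, nuclei)$compartment, "nuclear")
  expect_equal(detect_assemblies(outside, cells, nuclei)$compartment,
               "cytoplasmic")
})

test_that("line profiles reflect object geometry", {
  sat <- 65535
  ring <- object_scene(function(m)
    paint_ring(m, c(64, 64), 10, 0.55, 0.4 * sat, 0.02 * sat))
  # make the endogenous channel mirror the shell
  ring$endogenous <- ring$exogenous
  prof <- line_profile(ring, c(64, 40), c(64, 88))
  y <- prof$endogenous
  half <- ceiling(length(y) / 2)
  mid <- y[which.min(abs(prof$distance_um - max(prof$distance_um) / 2))]
  expect_lt(mid, 0.5 * max(y))          # central dip
  # a shell maximum on each side of the core
  expect_equal(max(y[1:half]), max(y))
  expect_equal(max(y[half:length(y)]), max(y))
  disk <- object_scene(function(m) paint_disk(m, c(64, 64), 8, 0.4 * sat))
  disk$endogenous <- disk$exogenous
  pd <- line_profile(disk, c(64, 40), c(64, 88))
  expect_equal(max(pd$endogenous), 0.4 * sat, tolerance = 1e-6)
  flat <- line_profile(disk, c(5, 5), c(5, 120))
  expect_true(all(flat$exogenous == 0)) # uniform background
  expect_error(line_profile(disk, c(10, 10), c(10, 10)), "degenerate")
  # normalization to control means
  pn <- line_profile(disk, c(64, 40), c(64, 88),
                     control_means = c(endogenous = 0.4 * sat,
                                       exogenous = 0.2 * sat))
  expect_equal(max(pn$endogenous), 1, tolerance = 1e-6)
})
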