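make_cells <- function(diffuse, exo = seq_along(diffuse)) {
  data.frame(cell_id = seq_along(diffuse),
             nuclear_endogenous_total = diffuse,
             nuclear_endogenous_diffuse = diffuse,
             exogenous_level = exo)
}

test_that("control reference uses the interpolated lower quartile", {
  ref <- build_control_reference(make_cells(c(1, 2, 3, 4)))
  expect_equal(ref$control_diffuse_Q1, 1.75)
  # constant input and permutation invariance
  expect_equal(build_control_reference(make_cells(rep(7, 6)))$control_diffuse_Q1, 7)
  shuffled <- make_cells(c(3, 1, 4, 2))
  expect_equal(build_control_reference(shuffled)$control_diffuse_Q1, 1.75)
  expect_error(build_control_reference(make_cells(c(1, 2, 3))), "at least 4")
})

test_that("control reference matches a brute-force quantile oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    x <- rnorm(n, 100, 30)
    ref <- build_control_reference(make_cells(x))
    expect_equal(ref$control_diffuse_Q1, oracle_quantile(x, 0.25))
    expect_equal(ref$transfected_gfp_threshold,
                 oracle_quantile(seq_along(x), 0.99))
  }
})

test_that("sequestration flag uses a strict cutoff at control Q1", {
  ref <- build_control_reference(make_cells(c(1, 2, 3, 4)))  # Q1 = 1.75
  asm <- data.frame(assembly_id = 1:3, mean_endogenous = c(1.75, 3.5, 1.0),
                    sequestering = NA)
  flagged <- flag_sequestering(asm, ref)
  expect_identical(flagged$sequestering, c(FALSE, TRUE, FALSE))
})

test_that("endogenous partition reproduces a closed-form constructed cell", {
  # nucleus of 400 px, one nuclear assembly covering 10% of it at 5x the
  # diffuse intensity: sequestered proportion = 0.5/1.4
  endo <- matrix(0, 40, 40)
  nuclei <- matrix(0L, 40, 40)
  nuclei[11:30, 11:30] <- 1L
  endo[11:30, 11:30] <- 100
  asm_lab <- matrix(0L, 40, 40)
  asm_lab[11:14, 11:20] <- 1L           # 40 px = 10% of the nucleus
  endo[11:14, 11:20] <- 500
  sc <- image_scene(endo, matrix(0, 40, 40), 0.19, 65535)
  asm <- data.frame(assembly_id = 1L, cell_id = 1L, class = "punctum",
                    compartment = "nuclear", mean_endogenous = 500,
                    on_border = FALSE, sequestering = NA)
  attr(asm, "labels") <- asm_lab
  cr <- measure_cells(sc, nuclei, nuclei, asm)
  q <- partition_endogenous(cr, asm)
  expect_equal(q$proportion_sequestered, 0.5 / 1.4, tolerance = 1e-12)
  expect_equal(cr$diffuse_sum + cr$nuclear_sequestered_sum,
               cr$nuclear_total_sum)
  # no assemblies: everything is diffuse
  cr0 <- measure_cells(sc, nuclei, nuclei, asm[0, ])
  q0 <- partition_endogenous(cr0)
  expect_equal(q0$proportion_sequestered, 0)
  expect_equal(q0$diffuse_signal, cr0$nuclear_total_sum)
})

test_that("sequestration recovery and conservation hold on noiseless scenes", {
  r <- render_scene(scene_config(n_cells = 12L, variant = "2KQ",
                                 noise_sd = 0, seed = 31))
  p <- process_scene(r$scene)
  expect_equal(p$cell_records$diffuse_sum + p$cell_records$nuclear_sequestered_sum,
               p$cell_records$nuclear_total_sum, tolerance = 1e-12)
  q <- partition_endogenous(p$cell_records)
  gt <- r$ground_truth$cells
  matched <- sapply(q$cell_id, function(l) {
    idx <- which(p$nuclei == l)
    tt <- table(r$ground_truth$nucleus_labels[idx])
    as.integer(names(which.max(tt)))
  })
  truth <- (gt$true_sequestered /
              (gt$true_diffuse + gt$true_sequestered))[matched]
  expect_lt(max(abs(q$proportion_sequestered - truth)), 0.02)
})

test_that("image summaries follow the per-image denominators", {
  cells <- data.frame(cell_id = 1:10, transfected = rep(c(TRUE, FALSE), 5))
  asm <- data.frame(assembly_id = 1:5,
                    cell_id = c(1, 1, 2, 4, 7),
                    class = c("punctum", "punctum", "punctum", "punctum",
                              "inclusion"),
                    compartment = "nuclear", area_um2 = c(1, 1, 2, 2, 20),
                    on_border = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                    sequestering = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  s <- summarize_image(cells, asm)
  expect_equal(s$pct_cells_with_puncta, 30)     # cells 1, 2, 4 of 10
  expect_equal(s$puncta_per_cell, 0.4)
  expect_equal(s$pct_transfected_with_inclusions, 20)  # cell 7 of 1,3,5,7,9
  expect_equal(s$inclusions_per_transfected_cell, 0.2)
  expect_true(is.na(s$mean_area_inclusion_um2))  # only a border inclusion
  expect_equal(s$mean_area_punctum_um2, 1.5)
  expect_equal(s$pct_puncta_sequestering, 75)
  # no transfected cells: inclusion metrics are NA, not zero
  none <- summarize_image(transform(cells, transfected = FALSE), asm)
  expect_true(is.na(none$pct_transfected_with_inclusions))
  expect_true(is.na(none$inclusions_per_transfected_cell))
})

test_that("puncta burden recovers the generating rate across images", {
  counts <- unlist(lapply(1:4, function(s) {
    r <- render_scene(scene_config(n_cells = 15L, variant = "WT", seed = s,
                                   assembly_rates = c(punctum = 1.5)))
    g <- r$ground_truth$cells
    g$n_assemblies[g$transfected]
  }))
  ci <- poisson.test(sum(counts), length(counts))$conf.int
  expect_true(ci[1] <= 1.5 && 1.5 <= ci[2])
})

test_that("regressions recover exact lines and reject degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  q <- data.frame(exogenous_level = x, fold_diffuse_nuclear = -0.5 * x + 2,
                  sequestered_signal = NA)
  r <- regress_concentration(q, "diffuse")
  expect_equal(r$slope, -0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_true(r$slope_negative)
  expect_error(regress_concentration(q[1:2, ], "diffuse"), "at least 3")
  qz <- transform(q, exogenous_level = 1)
  expect_error(regress_concentration(qz, "diffuse"), "zero-variance")
})

test_that("GFP-only controls are neutral: mean diffuse fold is 1", {
  r <- render_scene(scene_config(n_cells = 20L, variant = "GFP_only",
                                 seed = 55))
  p <- process_scene(r$scene)
  ref <- build_control_reference(p$cell_records)
  q <- partition_endogenous(p$cell_records, ref = ref)
  expect_equal(mean(q$fold_diffuse_nuclear), 1, tolerance = 0.02)
  expect_equal(mean(q$proportion_sequestered), 0, tolerance = 0.01)
})
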