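# Synthetic-data generators: planted effects, determinism, ground truth.

test_that("noise-free simulation plants exact fold changes", {
  cfg <- sim_config(n_genes = 400L, within_treatment_cv = 0,
                    planted_log2fc = 1, seed = 7L)
  sim <- simulate_expression(cfg)
  m <- sim$expr$rpkm
  up <- sim$truth$gene_id[sim$truth$direction == "UP"]
  down <- sim$truth$gene_id[sim$truth$direction == "DOWN"]
  for (e in c("E1", "E2")) {
    expect_equal(m[up, paste0(e, "_ENZA")], 2 * m[up, paste0(e, "_VEH")],
                 ignore_attr = TRUE)
    expect_equal(m[down, paste0(e, "_NODHT")],
                 m[down, paste0(e, "_DHT")] / 2, ignore_attr = TRUE)
  }
  # realized contrasts equal the planted effect exactly at zero pseudocount
  ctr <- compute_contrasts(sim$expr, pseudocount = 0)
  expect_equal(unname(ctr[up, ]), matrix(1, length(up), 4L))
  expect_equal(unname(ctr[down, ]), matrix(-1, length(down), 4L))
  null_g <- sim$truth$gene_id[sim$truth$class == "NULL"]
  expect_equal(unname(ctr[null_g, ]), matrix(0, length(null_g), 4L))
})

test_that("default configuration plants the reference class counts exactly", {
  cfg <- sim_config()
  expect_identical(unname(planted_counts(cfg)), c(312, 206, 171, 98))
  sim <- simulate_expression(sim_config(seed = 2L))
  tab <- table(sim$truth$class)
  expect_equal(unname(tab[c("DOWN_HIGH", "DOWN_LOW", "UP_HIGH", "UP_LOW")]),
               c(312, 206, 171, 98), ignore_attr = TRUE)
  expect_equal(sum(tab), cfg$n_genes)  # labels partition the universe
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_expression(sim_config(n_genes = 300L, seed = 9L))
  b <- simulate_expression(sim_config(n_genes = 300L, seed = 9L))
  expect_identical(a$expr$rpkm, b$expr$rpkm)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_expression(sim_config(n_genes = 300L, seed = 10L))
  expect_false(identical(a$expr$rpkm, c_$expr$rpkm))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(frac_planted_up = 0.6, frac_planted_down = 0.5),
               "sum to less than 1")
  expect_error(sim_config(planted_log2fc = 0), "positive")
  expect_error(sim_config(within_treatment_cv = -0.1), ">= 0")
  expect_error(sim_config(high_low_split = 1.2), "proportions")
})

test_that("discordant controls break concordance in one modality only", {
  cfg <- sim_config(n_genes = 300L, within_treatment_cv = 0,
                    n_discordant = 10L, seed = 3L)
  sim <- simulate_expression(cfg)
  disc <- sim$truth$gene_id[sim$truth$discordant]
  expect_length(disc, 10L)
  expect_true(all(sim$truth$class[sim$truth$discordant] == "NULL"))
  ctr <- compute_contrasts(sim$expr, pseudocount = 0)
  expect_true(all(ctr[disc, "E1_NODHT_vs_DHT"] > 0))
  expect_true(all(ctr[disc, "E1_ENZA_vs_VEH"] < 0))
})

test_that("simulated gene sets hit the planted in-set differential rate", {
  truth <- data.frame(gene_id = sprintf("G%04d", 1:2000),
                      class = rep(c("UP_HIGH", "NULL"), c(80L, 1920L)),
                      stringsAsFactors = FALSE)
  f_bg <- 0.04
  # null case: expected in-set fraction equals the background fraction
  for (ef in c(1, 5)) {
    sets <- simulate_gene_sets(truth, n_sets = 1000L, enrichment_factor = ef,
                               size_range = c(100L, 100L), seed = 21L)
    target <- min(ef * f_bg, 1)
    expect_equal(attr(sets, "target_fraction"), target)
    frac <- mean(vapply(sets, function(s)
      mean(s %in% truth$gene_id[truth$class != "NULL"]), numeric(1L)))
    se <- sqrt(target * (1 - target) / (1000 * 100))
    expect_lt(abs(frac - target), 3 * se)
  }
})

test_that("gene-set generation validates inputs", {
  truth <- data.frame(gene_id = letters, class = rep("NULL", 26L))
  expect_error(simulate_gene_sets(truth, enrichment_factor = 0.5), ">= 1")
  expect_error(simulate_gene_sets(truth, size_range = c(10L, 100L)),
               "exceeds the gene universe")
})

test_that("fucci simulation ramps G0 under enzalutamide and reverts on washout", {
  sched <- c("ENZA", "ENZA", "ENZA", "ENZA", "VEH")
  tr <- simulate_fucci(n_cells = 400L, schedule = sched, plateau = 0.9,
                       seed = 5L)
  g0 <- vapply(1:5, function(w)
    mean(tr$true_state[tr$week == w] == "G1_G0"), numeric(1L))
  expect_gt(g0[4L], g0[1L])          # monotone construction
  expect_lt(g0[5L], g0[4L])          # washout reverses the shift
  # all-vehicle schedule is stationary within sampling error
  tv <- simulate_fucci(n_cells = 400L, schedule = rep("VEH", 4L), seed = 6L)
  gv <- vapply(1:4, function(w)
    mean(tv$true_state[tv$week == w] == "G1_G0"), numeric(1L))
  se <- sqrt(0.25 * 0.75 / 400)
  expect_true(all(abs(gv - 0.25) < 4 * se))
  expect_error(simulate_fucci(schedule = c("ENZA", "DMSO")), "unknown")
  expect_identical(simulate_fucci(n_cells = 50L, seed = 1L),
                   simulate_fucci(n_cells = 50L, seed = 1L))
})

test_that("mask simulation renders analytic geometry and is reproducible", {
  one_disc <- simulate_masks(n_cysts = 0L, n_spheroids = 1L,
                             spheroid_radius_um = c(25, 25), seed = 4L)
  expect_equal(one_disc$truth$true_area_um2, pi * 625)
  one_cyst <- simulate_masks(n_cysts = 1L, n_spheroids = 0L,
                             cyst_lumen_radius_um = c(30, 30), seed = 4L)
  expect_equal(one_cyst$truth$true_lumen_diameter_um, 60)
  a <- simulate_masks(n_cysts = 3L, n_spheroids = 2L, seed = 12L)
  b <- simulate_masks(n_cysts = 3L, n_spheroids = 2L, seed = 12L)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)
  # impossible packing fails after the retry limit
  expect_error(
    simulate_masks(n_cysts = 0L, n_spheroids = 40L,
                   spheroid_radius_um = c(60, 60),
                   image_size_px = c(300L, 300L), max_retries = 20L,
                   seed = 1L),
    "retries")
})

test_that("mask PNG round-trips label identity", {
  m <- simulate_masks(n_cysts = 1L, n_spheroids = 2L,
                      image_size_px = c(256L, 256L), seed = 8L)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m$mask, path)
  expect_identical(read_mask_png(path), m$mask)
})
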