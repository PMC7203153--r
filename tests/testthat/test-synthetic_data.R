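small_library <- function(n = 40, seed = 60) {
  recs <- lapply(seq_len(n), function(i)
    peptide_record(sprintf("p%03d", i), random_aa(15, seed + i), "external"))
  do.call(rbind, recs)
}

test_that("microarray generator is degenerate at zero noise and seed-stable", {
  lib <- small_library(10)
  spec <- screen_sim_spec(lib, noise_cv = 0, assay_scale_sd = 0, seed = 5)
  sim <- gen_microarray(spec)
  per_pep <- split(sim$spots$intensity[sim$spots$condition_id == "uncompeted"],
                   sim$spots$peptide_id[sim$spots$condition_id == "uncompeted"])
  for (v in per_pep) expect_equal(length(unique(v)), 1)
  # bit-reproducible under the seed
  sim2 <- gen_microarray(spec)
  expect_identical(sim, sim2)
  noisy <- gen_microarray(screen_sim_spec(lib, noise_cv = 0.1, seed = 5))
  expect_identical(noisy, gen_microarray(screen_sim_spec(lib, noise_cv = 0.1,
                                                         seed = 5)))
})

test_that("charge drives intensity in the generated library", {
  lib <- small_library(150, seed = 70)
  sim <- gen_microarray(screen_sim_spec(lib, noise_cv = 0.05,
                                        assay_scale_sd = 0.05, seed = 6))
  aggs <- aggregate_replicates(sim$spots)
  un <- aggs[aggs$condition_id == "uncompeted", ]
  charges <- vapply(lib$sequence, net_charge, numeric(1))
  names(charges) <- lib$id
  r <- cor(charges[un$peptide_id], un$grand_mean)
  expect_gt(r, 0.4)
})

test_that("selective-set retention passes through to percent selectivity", {
  lib <- small_library(20, seed = 80)
  retained <- setNames(c(0.9, 0.7), lib$id[1:2])
  sim <- gen_microarray(screen_sim_spec(lib, selective_set = retained,
                                        default_retention = 0.3,
                                        noise_cv = 0, assay_scale_sd = 0,
                                        seed = 7))
  aggs <- aggregate_replicates(sim$spots)
  un <- aggs[aggs$condition_id == "uncompeted", ]
  co <- aggs[aggs$condition_id == "competed_0.1", ]
  sel <- selectivity_table(un, co)
  expect_equal(sel$percent_selectivity[sel$peptide_id == lib$id[1]], 90,
               tolerance = 5e-2)
  expect_equal(sel$percent_selectivity[sel$peptide_id == lib$id[2]], 70,
               tolerance = 5e-2)
  others <- sel$percent_selectivity[!sel$peptide_id %in% lib$id[1:2]]
  expect_true(all(abs(others - 30) < 1e-6))
})

test_that("planted top binders are recovered from a noisy screen", {
  lib <- small_library(100, seed = 90)
  planted <- sort(lib$id[seq(5, 50, by = 5)])
  sim <- gen_microarray(screen_sim_spec(
    lib, peptide_effects = setNames(rep(4, length(planted)), planted),
    noise_cv = 0.1, assay_scale_sd = 0.05, seed = 8))
  aggs <- aggregate_replicates(sim$spots)
  top <- select_top_fraction(aggs[aggs$condition_id == "uncompeted", ], 0.10)
  expect_gte(length(intersect(top, planted)) / length(planted), 0.9)
})

test_that("titration generator inverts exactly at zero noise", {
  truth <- data.frame(peptide_id = c("a", "b"), y0 = c(0.01, 0.03),
                      bmax = c(0.05, 0.04), kd_uM = c(521, 388), hill = 1)
  for (artifact in c(FALSE, TRUE)) {
    sim <- gen_titration(titration_sim_spec(truth, noise_sd = 0,
                                            viscosity_artifact = artifact))
    curves <- process_titration(sim$titrations, transform = FALSE)
    for (id in truth$peptide_id) {
      tr <- truth[truth$peptide_id == id, ]
      conc <- curves[[id]]$conc
      # triplicate measurements per concentration by default
      expect_equal(length(conc), 3 * 13)
      expected <- tr$y0 + tr$bmax / (1 + (tr$kd_uM / pmax(conc, 1e-300)))
      expected[conc == 0] <- tr$y0
      expect_equal(curves[[id]]$r, expected, tolerance = 1e-12)
    }
  }
  # total intensity is conserved after blank correction
  sim <- gen_titration(titration_sim_spec(truth, noise_sd = 0,
                                          viscosity_artifact = TRUE))
  cc <- blank_correct(sim$titrations)
  expect_equal(cc$I_par + 2 * cc$I_perp, rep(3, nrow(cc)), tolerance = 1e-9)
})

test_that("titration truths outside the anisotropy range are rejected", {
  bad <- data.frame(peptide_id = "x", y0 = 0.8, bmax = 0.5, kd_uM = 100,
                    hill = 1)
  expect_error(titration_sim_spec(bad), "outside")
})

test_that("frame generator respects the script and rejects infeasible ones", {
  script <- data.frame(frame = c(1, 2), res_a = c(2, 3), res_b = c(1, 1))
  fs <- gen_frames(2, 4, 3, script, jitter_sd = 0.05, seed = 11)
  cm <- contact_map(fs, cutoff = 3.0)
  expect_equal(cm$raw_counts[2, 1], 1)
  expect_equal(cm$raw_counts[3, 1], 1)
  expect_equal(sum(cm$raw_counts), 2)
  # unscripted pairs stay >= 6 A apart
  expect_true(all(contact_map(fs, cutoff = 5.9)$raw_counts ==
                  cm$raw_counts))
  clash <- data.frame(frame = c(1, 1), res_a = c(1, 2), res_b = c(1, 1))
  expect_error(gen_frames(2, 3, 3, clash), "infeasible")
  expect_identical(gen_frames(2, 3, 3, script[1, ], seed = 12),
                   gen_frames(2, 3, 3, script[1, ], seed = 12))
})

test_that("cell screen elevates region peptides and is seed-stable", {
  tiles <- tile_sequence(random_aa(131, 95), tiling_spec(15, 2), "par", "I")
  regions <- list(c(40, 60))
  cells <- gen_cell_screen(tiles, regions, effect_size = 60, background = 20,
                           noise_sd = 1, seed = 13)
  expect_identical(cells,
                   gen_cell_screen(tiles, regions, effect_size = 60,
                                   background = 20, noise_sd = 1, seed = 13))
  rk1 <- rank_binding(cells$cells_1, cells$control)
  rk2 <- rank_binding(cells$cells_2, cells$control)
  # region peptides occupy the best (lowest) ranks in both conditions
  n_region <- sum(cells$truth)
  expect_gt(n_region, 3)
  best1 <- rk1$peptide_id[order(rk1$rank)][seq_len(n_region)]
  best2 <- rk2$peptide_id[order(rk2$rank)][seq_len(n_region)]
  expect_setequal(best1, names(cells$truth)[cells$truth])
  expect_setequal(best2, names(cells$truth)[cells$truth])
  # zero effect -> rank association collapses
  null <- gen_cell_screen(tiles, regions, effect_size = 0, background = 20,
                          noise_sd = 5, seed = 14)
  rho0 <- cor(rank_binding(null$cells_1, null$control)$rank,
              rank_binding(null$cells_2, null$control)$rank,
              method = "spearman")
  expect_lt(abs(rho0), 0.5)
})
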