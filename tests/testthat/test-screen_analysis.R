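test_that("replicate aggregation computes grand mean, CV and retention", {
  aggs <- aggregate_replicates(spots_from_assays(list(70, 100, 130)))
  expect_equal(aggs$grand_mean, 100)
  expect_equal(aggs$inter_assay_sd, 30)
  expect_equal(aggs$inter_assay_cv, 0.30)
  expect_false(aggs$retained)
  expect_identical(aggs$reason, "high_cv")

  flat <- aggregate_replicates(spots_from_assays(list(100, 100, 100)))
  expect_equal(flat$inter_assay_cv, 0)
  expect_true(flat$retained)

  zero <- aggregate_replicates(spots_from_assays(list(0, 0, 0)))
  expect_true(is.na(zero$inter_assay_cv))
  expect_false(zero$retained)
  expect_identical(zero$reason, "zero_mean")
})

test_that("grand mean averages assay means, not raw spots, and is label-invariant", {
  # unbalanced replicates: assay means (10, 40) -> grand mean 25
  spots <- rbind(
    data.frame(peptide_id = "p", condition_id = "c", assay_id = 1,
               replicate = 1:3, intensity = c(5, 10, 15)),
    data.frame(peptide_id = "p", condition_id = "c", assay_id = 2,
               replicate = 1, intensity = 40))
  expect_equal(aggregate_replicates(spots)$grand_mean, 25)
  # permuting assay labels changes nothing
  relabel <- spots
  relabel$assay_id <- c(2, 2, 2, 1)
  expect_equal(aggregate_replicates(relabel)$grand_mean, 25)
})

test_that("top-fraction selection sizes by floor and breaks ties by id", {
  aggs <- data.frame(peptide_id = sprintf("p%02d", 1:10),
                     condition_id = "c", n_assays = 3,
                     grand_mean = c(5, 9, 9, 1, 2, 3, 4, 6, 7, 8),
                     intra_assay_sd = 0, inter_assay_sd = 0,
                     inter_assay_cv = 0, retained = TRUE, reason = "ok")
  expect_identical(select_top_fraction(aggs, 0.20), c("p02", "p03"))
  expect_setequal(select_top_fraction(aggs, 1.0), aggs$peptide_id)
  # invariance to row order
  shuffled <- aggs[sample(nrow(aggs)), ]
  expect_identical(select_top_fraction(shuffled, 0.20),
                   select_top_fraction(aggs, 0.20))
  # 762 peptides at 5% -> 38
  big <- data.frame(peptide_id = sprintf("q%04d", 1:762),
                    condition_id = "c", n_assays = 3,
                    grand_mean = 762:1, intra_assay_sd = 0,
                    inter_assay_sd = 0, inter_assay_cv = 0,
                    retained = TRUE, reason = "ok")
  expect_length(select_top_fraction(big, 0.05), 38)
  # non-retained peptides never enter the selection
  big$retained[big$peptide_id == "q0001"] <- FALSE
  expect_false("q0001" %in% select_top_fraction(big, 0.05))
  expect_warning(select_top_fraction(aggs, 0.05), "empty selection")
})

test_that("percent selectivity is the retained-binding ratio", {
  agg <- function(id, m) data.frame(peptide_id = id, condition_id = "c",
                                    grand_mean = m)
  expect_equal(percent_selectivity(agg("p", 1000),
                                   agg("p", 1000))$percent_selectivity, 100)
  expect_equal(percent_selectivity(agg("p", 1000),
                                   agg("p", 0))$percent_selectivity, 0)
  ps <- percent_selectivity(agg("p", 1000), agg("p", 850))
  expect_equal(ps$percent_selectivity, 85)
  expect_gt(ps$percent_selectivity, 80)  # classified selective at the >80 cut
  # not evaluable at background
  ps0 <- percent_selectivity(agg("p", 50), agg("p", 10), background = 100)
  expect_true(is.na(ps0$percent_selectivity))
  expect_false(ps0$evaluable)
  # scale invariance: multiplying all intensities leaves the percent unchanged
  expect_equal(percent_selectivity(agg("p", 3000),
                                   agg("p", 2550))$percent_selectivity, 85)
})

test_that("condition correlation handles both methods and degenerate input", {
  expect_equal(condition_correlation(1:5, 1:5)$estimate, 1)
  expect_equal(condition_correlation(c(1, 2, 3), c(3, 2, 1))$estimate, -1)
  expect_equal(condition_correlation(c(1, 2, 3), c(3, 2, 1),
                                     "spearman")$estimate, -1)
  sp <- condition_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4), "spearman")
  expect_equal(sp$estimate, 0.8)
  expect_equal(sp$n, 4)
  flat <- condition_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_false(flat$ok)
  expect_true(is.na(flat$estimate))
  expect_error(condition_correlation(1:3, 1:4), "paired")
})

test_that("decile profile partitions equally and tracks planted charge signal", {
  aggs <- data.frame(peptide_id = sprintf("p%03d", 1:100),
                     condition_id = "c", grand_mean = 1:100)
  charges <- setNames(round((1:100) / 12), aggs$peptide_id)  # charge ~ intensity
  prof <- intensity_decile_profile(aggs, charges)
  expect_equal(prof$n, rep(10, 10))
  expect_true(all(diff(prof$mean_charge) >= 0))
  expect_true(all(diff(prof$mean_intensity) > 0))
  # N = 762: bin sizes differ by at most 1
  big <- data.frame(peptide_id = sprintf("q%04d", 1:762),
                    condition_id = "c", grand_mean = runif(762))
  bigc <- setNames(rnorm(762), big$peptide_id)
  prof762 <- intensity_decile_profile(big, bigc)
  expect_lte(diff(range(prof762$n)), 1)
  expect_equal(sum(prof762$n), 762)
})

test_that("mass-equivalent conversion reproduces the polymer/monomer arithmetic", {
  expect_equal(round(mass_equivalent_conc(10, 100, 300, 309.3)), 970)
  expect_equal(mass_equivalent_conc(5, 100, 300, 300), 500)  # identity scaling
  expect_equal(mass_equivalent_conc(1, 1, 309.3, 309.3), 1)
})

test_that("binding ranks subtract control, floor at zero and average ties", {
  rk <- rank_binding(c(a = 5, b = 3, c = 9))
  expect_equal(rk$rank, c(2, 3, 1))
  rk2 <- rank_binding(c(a = 4), control = c(6))
  expect_equal(rk2$adjusted, 0)
  rk3 <- rank_binding(c(a = 10, b = 10, c = 1))
  expect_equal(rk3$rank, c(1.5, 1.5, 3))
})

test_that("spearman via rank-then-pearson equals the closed form on tie-free data", {
  set.seed(7)
  for (i in 1:20) {
    x <- sample(100, 15)
    y <- sample(100, 15)
    expect_equal(cor(rank(x), rank(y)), spearman_closed_form(x, y),
                 tolerance = 1e-12)
    expect_equal(condition_correlation(x, y, "spearman")$estimate,
                 spearman_closed_form(x, y), tolerance = 1e-12)
  }
})
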