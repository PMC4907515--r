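test_that("three-way ANOVA matches the sequential least-squares oracle exactly", {
  ds <- integer_fixture()
  got <- anova_three_way(ds, "yield")
  want <- oracle_anova_lm(ds, "yield")
  got_df <- as.data.frame(got)[match(want$term, got$term), ]
  expect_equal(got_df$df, want$df)
  expect_equal(got_df$sumsq, want$sumsq, tolerance = 1e-12)
  expect_equal(got_df$meansq, want$meansq, tolerance = 1e-12)
  # exact partition
  expect_equal(sum(got$sumsq), sum((ds$yield - mean(ds$yield))^2),
               tolerance = 1e-12)

  # and on a larger random layout
  ds2 <- simulate_met(varcomp_spec(), design_dims(g = 12, t = 2, y = 3, r = 2),
                      seed = 5)
  got2 <- anova_three_way(ds2, "yield")
  want2 <- oracle_anova_lm(ds2, "yield")
  expect_equal(as.data.frame(got2)[match(want2$term, got2$term), ]$sumsq,
               want2$sumsq, tolerance = 1e-9)
})

test_that("constant data gives an all-zero sums-of-squares partition", {
  ds <- make_balanced_ds(values = rep(3, 24))
  a <- anova_three_way(ds, "yield")
  expect_true(all(abs(a$sumsq) < 1e-12))
})

test_that("unbalanced layouts are rejected with the missing cells named", {
  ds <- make_balanced_ds()
  drop_one <- as.data.frame(ds)[-1, ]
  ds2 <- trial_dataset(drop_one)
  expect_error(anova_three_way(ds2, "yield"), "unbalanced.*e1/RI/1/1")
  withna <- as.data.frame(ds)
  withna$yield[3] <- NA
  expect_error(anova_three_way(trial_dataset(withna), "yield"),
               "missing value")
})

test_that("variance components solve the expected-mean-squares equations", {
  ds <- integer_fixture()
  ms <- anova_three_way(ds, "yield")
  vc <- estimate_varcomps(ms)
  want <- oracle_varcomps(oracle_anova_lm(ds, "yield"), g = 3, t = 2, y = 2,
                          r = 2)
  for (nm in names(want))
    expect_equal(vc[[nm]], unname(want[[nm]]), tolerance = 1e-12)

  # all mean squares equal => all interaction/genotypic components zero
  flat <- ms
  flat$meansq <- rep(2, nrow(flat))
  vc0 <- estimate_varcomps(flat)
  expect_equal(vc0$sigma2_G, 0)
  expect_equal(vc0$sigma2_GT, 0)
  expect_equal(vc0$sigma2_GY, 0)
  expect_equal(vc0$sigma2_GTY, 0)
  expect_equal(vc0$sigma2_e, 2)

  expect_error(estimate_varcomps(ms, dims = design_dims(4, 2, 2, 2)),
               "mismatch")
  expect_error(estimate_varcomps(as.data.frame(ms)), "anova_three_way")
})

test_that("pure-noise simulations give F near 1 and negative components flagged", {
  spec <- varcomp_spec(mu = 50, sigma2_G = 0, sigma2_GT = 0, sigma2_GY = 0,
                       sigma2_GTY = 0, sigma2_e = 8)
  dims <- design_dims(g = 20, t = 2, y = 2, r = 2)
  ratios <- t(vapply(1:60, function(i) {
    a <- anova_three_way(simulate_met(spec, dims, seed = 100 + i), "yield")
    m <- setNames(a$meansq, a$term)
    m[c("G", "GT", "GY", "GTY")] / m[["residual"]]
  }, numeric(4)))
  expect_true(all(abs(colMeans(ratios) - 1) < 0.15))

  any_negative <- any(vapply(1:10, function(i) {
    vc <- estimate_varcomps(
      anova_three_way(simulate_met(spec, dims, seed = 300 + i), "yield"))
    length(vc$negative) > 0
  }, logical(1)))
  expect_true(any_negative)  # under a null, moment estimates go negative
})

test_that("heritability follows the variance-ratio formula and its limits", {
  mk <- function(G, GT, GY, GTY, e, dims = design_dims(10, 2, 2, 2)) {
    structure(list(sigma2_G = G, sigma2_GT = GT, sigma2_GY = GY,
                   sigma2_GTY = GTY, sigma2_e = e, dims = dims,
                   negative = character(0)), class = "varcomps")
  }
  # hand evaluation: 4 / (4 + 1 + 1 + 0.5 + 1) * 100
  expect_equal(broad_sense_heritability(mk(4, 2, 2, 2, 8)), 400 / 7.5)
  expect_equal(broad_sense_heritability(mk(0, 5, 1, 2, 8)), 0)
  expect_equal(broad_sense_heritability(mk(3, 0, 0, 0, 0)), 100)
  h0 <- broad_sense_heritability(mk(0, 0, 0, 0, 0))
  expect_equal(as.numeric(h0), 0)
  expect_true(isTRUE(attr(h0, "degenerate")))
  # negative components are truncated inside the formula
  expect_equal(broad_sense_heritability(mk(4, -3, 2, 2, 8)),
               4 / (4 + 0 + 1 + 0.5 + 1) * 100)
  # monotone: up in sigma2_G, down in every masking component
  base <- broad_sense_heritability(mk(4, 2, 2, 2, 8))
  expect_gt(broad_sense_heritability(mk(5, 2, 2, 2, 8)), base)
  expect_lt(broad_sense_heritability(mk(4, 3, 2, 2, 8)), base)
  expect_lt(broad_sense_heritability(mk(4, 2, 3, 2, 8)), base)
  expect_lt(broad_sense_heritability(mk(4, 2, 2, 3, 8)), base)
  expect_lt(broad_sense_heritability(mk(4, 2, 2, 2, 9)), base)
})

test_that("heritability is scale-invariant while GA scales linearly", {
  ds <- simulate_met(varcomp_spec(), design_dims(g = 15, t = 2, y = 2, r = 2),
                     seed = 9)
  scaled <- as.data.frame(ds)
  scaled$yield <- scaled$yield * 3.7
  scaled <- trial_dataset(scaled)
  g1 <- gain_summary(ds, "yield")
  g2 <- gain_summary(scaled, "yield")
  expect_equal(g2$H_BS, g1$H_BS, tolerance = 1e-9)
  expect_equal(g2$GA, 3.7 * g1$GA, tolerance = 1e-9)
  expect_equal(g2$gain_pct, g1$gain_pct, tolerance = 1e-9)
})

test_that("gain arithmetic reproduces the published yield summary rows", {
  # base row: sigmaP back-solved from GA = K sigmaP H; forward closes the loop
  sigmaP_base <- 74.84 / (2.06 * 0.2981)
  expect_equal(sigmaP_base, 121.86, tolerance = 1e-4)
  expect_equal(genetic_advance(121.86, 29.81), 74.84, tolerance = 1e-4)
  expect_equal(round(genetic_gain_percent(74.84, 513.4), 2), 14.58)
  expect_equal(round(genetic_gain_percent(57.4, 601.2), 2), 9.55)
  expect_equal(round(gain_over_reference(601.2, 513.4), 1), 17.1)
  expect_equal(gain_over_reference(110, 100), 10)
  expect_equal(gain_over_reference(100, 100), 0)
  expect_equal(genetic_advance(10, 0), 0)
  expect_equal(genetic_advance(10, 50, K = 0), 0)
  expect_equal(genetic_gain_percent(0, 500), 0)
  expect_error(genetic_advance(-1, 50), "sigmaP")
  expect_error(genetic_advance(1, 120), "H_pct")
  expect_error(genetic_gain_percent(10, 0), "mean")
  expect_error(gain_over_reference(10, 0), "ref_mean")
})

test_that("variance components and heritability are recovered from simulations", {
  spec <- varcomp_spec(mu = 100, sigma2_G = 4, sigma2_GT = 2, sigma2_GY = 2,
                       sigma2_GTY = 2, sigma2_e = 8)
  dims <- design_dims(g = 60, t = 2, y = 2, r = 2)
  res <- t(vapply(1:60, function(i) {
    vc <- estimate_varcomps(
      anova_three_way(simulate_met(spec, dims, seed = 5000 + i), "yield"))
    c(vc$sigma2_G, vc$sigma2_GT, vc$sigma2_GY, vc$sigma2_GTY, vc$sigma2_e,
      broad_sense_heritability(vc))
  }, numeric(6)))
  truth <- c(4, 2, 2, 2, 8)
  expect_true(all(abs(colMeans(res)[1:5] - truth) / truth < 0.15))
  expect_lt(abs(mean(res[, 6]) - 400 / 7.5), 5)
})

test_that("gain_table analyses populations and families separately", {
  spec <- varcomp_spec(mu = 600)
  base <- simulate_met(spec, design_dims(g = 20, t = 2, y = 2, r = 2),
                       seed = 31, entry_prefix = "b", pop_class = "base")
  hs <- simulate_met(varcomp_spec(mu = 660),
                     design_dims(g = 12, t = 2, y = 2, r = 2),
                     seed = 32, entry_prefix = "hs", pop_class = "halfsib")
  hs$family <- ifelse(as.integer(sub("hs", "", hs$entry)) <= 6, "hs1", "hs2")
  chk <- simulate_met(varcomp_spec(mu = 630),
                      design_dims(g = 2, t = 2, y = 2, r = 2),
                      seed = 33, entry_prefix = "chk", pop_class = "check")
  ds <- trial_dataset(rbind(as.data.frame(base), as.data.frame(hs),
                            as.data.frame(chk)))
  gt <- gain_table(ds, "yield", f5_entries = c("b01", "b02"),
                   check_entry = "chk1")
  expect_setequal(gt$group, c("base", "hsib", "hs1", "hs2"))
  expect_true(all(is.na(gt$error)))
  expect_true(all(gt$H_BS >= 0 & gt$H_BS <= 100))
  hsib_row <- gt[gt$group == "hsib", ]
  expect_equal(hsib_row$gain_pct,
               hsib_row$GA / hsib_row$mean * 100, tolerance = 1e-12)
  expect_false(is.na(hsib_row$gain_over_F5_pct))
  # families with a single replicate cannot be analysed but do not abort
  one_rep <- trial_dataset(as.data.frame(ds)[ds$rep == 1L, ])
  gt2 <- gain_table(one_rep, "yield")
  expect_true(all(!is.na(gt2$error)))
})
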