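test_that("t-test on entry means: degenerate and error cases", {
  x <- c(10, 12, 14, 16)
  tt <- mean_shift_ttest(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_equal(tt$estimate, 0)
  expect_error(mean_shift_ttest(1, x), ">= 2")
  expect_equal(mean_shift_ttest(x, x + 1, var_equal = TRUE)$method, "pooled t")
})

test_that("null Welch p-values are uniform and the test has power at 2 SD shift", {
  set.seed(101)
  p_null <- replicate(1000, {
    mean_shift_ttest(rnorm(10), rnorm(10))$p_value
  })
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)

  set.seed(202)
  rej <- replicate(1000, {
    mean_shift_ttest(rnorm(10, mean = 2), rnorm(10))$p_value < 0.05
  })
  # noncentral-t oracle: ncp = 2/sqrt(2/10) gives power ~0.985 at alpha 0.05
  expect_gt(mean(rej), 0.95)
})

test_that("a single Dunnett comparison reduces to the unadjusted t-test", {
  set.seed(7)
  a <- rnorm(8, 5); ctrl <- rnorm(10, 4)
  d <- dunnett_many_to_one(list(fam = a), ctrl, seed = 3)
  expect_equal(d$p_adjusted, d$p_unadjusted, tolerance = 5e-3)
  # pooled two-sample t with the same df
  tt <- t.test(a, ctrl, var.equal = TRUE)
  expect_equal(d$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(d$p_unadjusted, tt$p.value, tolerance = 1e-12)
})

test_that("Dunnett adjustment is dominated by Bonferroni and monotone in |t|", {
  set.seed(11)
  for (battery in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(4:9, 1), i / 4))
    names(groups) <- paste0("g", seq_len(k))
    ctrl <- rnorm(8)
    d <- dunnett_many_to_one(groups, ctrl, seed = battery)
    bonf <- pmin(1, d$p_unadjusted * k)
    expect_true(all(d$p_adjusted <= bonf + 2e-3))
    expect_true(all(d$p_adjusted >= d$p_unadjusted - 1e-12))
    ord <- order(abs(d$t), decreasing = TRUE)
    expect_true(all(diff(d$p_adjusted[ord]) >= -1e-12))
  }
  expect_error(dunnett_many_to_one(list(a = rep(1, 3)), rep(2, 4)),
               "zero-variance")
})

test_that("Dunnett familywise error is calibrated for three null groups", {
  k <- 3L; n <- 8L
  df <- k * n + n - k - 1L
  lam <- sqrt(n / (n + n))
  corr <- tcrossprod(rep(lam, k)); diag(corr) <- 1
  crit <- rsmet:::dunnett_quantile(0.05, df, corr, seed = 99)
  set.seed(303)
  hits <- replicate(2000, {
    g <- matrix(rnorm(k * n), n)
    ctrl <- rnorm(n)
    s2 <- (sum(apply(g, 2, var)) * (n - 1) + var(ctrl) * (n - 1)) / df
    tmax <- max(abs(colMeans(g) - mean(ctrl)) / sqrt(s2 * 2 / n))
    tmax > crit
  })
  # binomial MC error: sd = sqrt(.05*.95/2000) ~ 0.0049
  expect_lt(abs(mean(hits) - 0.05), 3.5 * sqrt(0.05 * 0.95 / 2000))
})

test_that("adjusted means equal arithmetic means on balanced data", {
  ds <- simulate_met(varcomp_spec(), design_dims(g = 8, t = 2, y = 2, r = 2),
                     seed = 13)
  am <- adjusted_means(ds, "yield")
  em <- entry_means(ds, "yield", "entry")
  expect_equal(am$adjusted_mean[match(em$entry, am$entry)], em$mean,
               tolerance = 1e-9)

  cds <- make_balanced_ds(values = rep(4.2, 24))
  # lm warns about a perfect fit on constant data; the means are still exact
  am0 <- suppressWarnings(adjusted_means(cds, "yield"))
  expect_true(all(am0$adjusted_mean == 4.2))
})

test_that("adjusted means match a normal-equations oracle when a cell is missing", {
  # 3 entries x 2 environments, one missing cell
  df <- data.frame(entry = c("a", "a", "b", "b", "c"),
                   treatment = c("RI", "RF", "RI", "RF", "RI"),
                   year = 1L, rep = 1L,
                   yield = c(10, 6, 12, 9, 15))
  ds <- trial_dataset(df)
  am <- adjusted_means(ds, "yield")

  # independent solve: dummy design built by hand, predictions averaged
  entries <- c("a", "b", "c"); envs <- c("RI", "RF")
  X <- cbind(1, as.numeric(df$entry == "b"), as.numeric(df$entry == "c"),
             as.numeric(df$treatment == "RF"))
  beta <- drop(solve(crossprod(X), crossprod(X, df$yield)))
  oracle <- vapply(entries, function(e) {
    mean(vapply(envs, function(v) {
      sum(c(1, e == "b", e == "c", v == "RF") * beta)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(am$adjusted_mean[match(entries, am$entry)], unname(oracle),
               tolerance = 1e-9)

  # entry with no observations is dropped with a warning
  df2 <- rbind(df, data.frame(entry = "d", treatment = "RI", year = 1L,
                              rep = 2L, yield = NA))
  expect_warning(am2 <- adjusted_means(trial_dataset(df2), "yield"),
                 "excluded: d")
  expect_setequal(am2$entry, entries)
})

test_that("trait correlations: diagonal, symmetry, flags, constant traits", {
  set.seed(31)
  m <- data.frame(entry = paste0("e", 1:30),
                  yield = rnorm(30, 600, 60))
  m$hi <- 0.4 + 0.002 * (m$yield - 600) + rnorm(30, 0, 0.02)
  m$flat <- 5
  expect_warning(tc <- trait_correlations(m), "constant")
  expect_equal(diag(tc$r), c(yield = 1, hi = 1, flat = 1))
  expect_true(tc$sig["yield", "yield"])
  expect_equal(tc$r, t(tc$r))
  expect_true(is.na(tc$r["flat", "yield"]))
  expect_gt(tc$r["yield", "hi"], 0)
  expect_error(trait_correlations(m[1:3, ]), ">= 4")
  expect_error(trait_correlations(m[, 1:2]), ">= 2")
})

test_that("correlation estimates land in the Fisher-z band around the truth", {
  rho <- 0.5; n <- 150
  set.seed(404)
  inside <- replicate(500, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    m <- data.frame(a = x, b = y)
    r <- trait_correlations(m)$r["a", "b"]
    abs(atanh(r) - atanh(rho)) <= 1.96 / sqrt(n - 3)
  })
  expect_gte(mean(inside), 0.93)
})

test_that("an induced negative biomass-HI dependence is recovered and flagged", {
  set.seed(55)
  n <- 40
  biomass <- rnorm(n, 1700, 150)
  hi <- pmin(1, pmax(0, 0.9 - 0.0003 * biomass + rnorm(n, 0, 0.02)))
  tc <- trait_correlations(data.frame(biomass = biomass, hi = hi))
  expect_lt(tc$r["biomass", "hi"], 0)
  expect_true(tc$sig["biomass", "hi"])
})

test_that("BLUPs shrink towards zero and never exceed raw deviations", {
  spec <- varcomp_spec(mu = 500, sigma2_G = 0, sigma2_GT = 0, sigma2_GY = 0,
                       sigma2_GTY = 0, sigma2_e = 400)
  ds <- simulate_met(spec, design_dims(g = 25, t = 2, y = 2, r = 2), seed = 17)
  fit <- suppressMessages(fit_blups(ds, "yield"))
  em <- entry_means(ds, "yield", "entry")
  dev <- em$mean - mean(em$mean)
  b <- fit$blups$blup[match(em$entry, fit$blups$progeny)]
  expect_true(all(abs(b) <= abs(dev) + 1e-8))
  expect_lt(mean(abs(b)), 0.5 * mean(abs(dev)))
})

test_that("on balanced data the BLUP ranking equals the raw-mean ranking", {
  ds <- simulate_met(varcomp_spec(), design_dims(g = 20, t = 2, y = 2, r = 2),
                     seed = 23)
  fit <- fit_blups(ds, "yield")
  em <- entry_means(ds, "yield", "entry")
  raw_rank <- rank(-em$mean)
  blup_rank <- fit$blups$rank[match(em$entry, fit$blups$progeny)]
  expect_equal(blup_rank, as.integer(raw_rank))
  expect_true(all(fit$varcomp$variance >= 0))
  expect_error(fit_blups(ds, "biomass"), "not present")
})

test_that("shrinkage ranking recovers true effects at least as well as raw means", {
  # heteroscedastic plot counts: half the progenies have 1 plot, half have 9
  one_sim <- function(seed) {
    set.seed(seed)
    n_prog <- 30
    g_true <- rnorm(n_prog, 0, 8)
    n_i <- rep(c(1L, 9L), length.out = n_prog)
    df <- do.call(rbind, lapply(seq_len(n_prog), function(i) {
      data.frame(entry = sprintf("p%02d", i), treatment = "RI", year = 1L,
                 rep = seq_len(n_i[i]),
                 yield = 100 + g_true[i] + rnorm(n_i[i], 0, 12))
    }))
    ds <- trial_dataset(df)
    fit <- suppressMessages(fit_blups(ds, "yield"))
    em <- entry_means(ds, "yield", "entry")
    ord <- sprintf("p%02d", seq_len(n_prog))
    b <- fit$blups$blup[match(ord, fit$blups$progeny)]
    # a singular fit shrinks every progeny to the same value; its ranking
    # carries no information, scored as correlation 0
    c(blup = if (stats::sd(b) == 0) 0
             else cor(b, g_true, method = "spearman"),
      raw = cor(em$mean[match(ord, em$entry)], g_true, method = "spearman"))
  }
  res <- vapply(1:60, one_sim, numeric(2))
  expect_gte(mean(res["blup", ]), mean(res["raw", ]))
})
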