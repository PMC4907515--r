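#' Two-sample t-test on entry means
#'
#' Tests whether two populations of entry (line) means differ, with the
#' entry mean — not the plot — as the experimental unit. Welch's
#' unequal-variance form is the default; set `var_equal = TRUE` for the
#' pooled test.
#'
#' @param group_a,group_b numeric vectors of entry means (length >= 2 each).
#' @param var_equal pool the variances?
#' @return List with `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference a - b), `method`.
#' @export
mean_shift_ttest <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 entry means")
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value,
       estimate = unname(diff(rev(ht$estimate))),
       method = if (var_equal) "pooled t" else "Welch t")
}

# Two-sided Dunnett quantile for k comparisons with correlation matrix R.
dunnett_quantile <- function(alpha, df, corr, seed = 1L, abseps = 1e-4) {
  with_seed(seed, {
    mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = corr,
                  algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                 maxpts = 100000L))$quantile
  })
}

#' Dunnett many-to-one comparisons
#'
#' Compares each of `k` groups of entry means against one control group with
#' familywise error control. Statistics use the variance pooled over all
#' groups (error df `N - k - 1`); adjusted two-sided p-values come from the
#' multivariate-t distribution of the maximum statistic under the Dunnett
#' correlation structure `rho_ij = lambda_i * lambda_j`,
#' `lambda_i = sqrt(n_i / (n_i + n_0))`, integrated by Genz-Bretz
#' quasi-Monte-Carlo with a fixed seed (absolute tolerance `abseps`,
#' default 1e-4; results reproducible bit-for-bit for a given seed).
#' Adjusted p-values are made monotone in `|t|` (an isotonic pass removes
#' any integration jitter) and never fall below the unadjusted p.
#'
#' @param groups named list of numeric vectors of entry means (each >= 2
#'   values).
#' @param control numeric vector of control entry means (>= 2 values,
#'   non-degenerate).
#' @param alpha familywise level in (0, 1), used for the `reject` column.
#' @param seed integer seed for the quasi-Monte-Carlo integration.
#' @param abseps absolute tolerance of the integration.
#' @return data.frame with one row per group: `group`, `n`, `estimate`
#'   (group - control), `t`, `df`, `p_unadjusted`, `p_adjusted`, `reject`.
#' @export
dunnett_many_to_one <- function(groups, control, alpha = 0.05, seed = 1L,
                                abseps = 1e-4) {
  if (!is.list(groups) || !length(groups))
    stop("`groups` must be a non-empty list")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(x) x[!is.na(x)])
  control <- control[!is.na(control)]
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L) || length(control) < 2L)
    stop("every group and the control need >= 2 entry means")
  if (stats::sd(control) == 0 && all(vapply(groups, stats::sd, 0) == 0))
    stop("degenerate (zero-variance) data: pooled variance is 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  k <- length(groups)
  n0 <- length(control)
  N <- sum(sizes) + n0
  df <- N - k - 1L
  ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0)) +
    sum((control - mean(control))^2)
  s2 <- ss / df
  if (s2 == 0) stop("degenerate (zero-variance) data: pooled variance is 0")
  est <- vapply(groups, mean, 0) - mean(control)
  se <- sqrt(s2 * (1 / sizes + 1 / n0))
  tval <- est / se
  lam <- sqrt(sizes / (sizes + n0))
  corr <- tcrossprod(lam)
  diag(corr) <- 1
  p_unadj <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p_adj <- vapply(seq_len(k), function(i) {
    with_seed(seed, {
      1 - mvtnorm::pmvt(lower = rep(-abs(tval[i]), k),
                        upper = rep(abs(tval[i]), k),
                        df = df, corr = corr, type = "shifted",
                        algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                       maxpts = 100000L))[1]
    })
  }, 0)
  # isotonic in |t|: larger statistics never get larger adjusted p
  ord <- order(abs(tval), decreasing = TRUE)
  p_adj[ord] <- cummax(p_adj[ord])
  p_adj <- pmin(1, pmax(p_adj, p_unadj))
  data.frame(group = names(groups), n = sizes, estimate = est, t = tval,
             df = df, p_unadjusted = p_unadj, p_adjusted = p_adj,
             reject = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Least-squares (adjusted) entry means
#'
#' Entry means adjusted for treatment, year and replicate effects: a fixed
#' linear model `trait ~ entry + env` is fitted, where `env` indexes each
#' replicate within a treatment-by-year combination (so treatment, year,
#' their interaction and replicates-within are all absorbed), and entry
#' least-squares means are averaged over all environment levels via
#' \pkg{emmeans}. On balanced data these equal the arithmetic entry means.
#'
#' @param ds a [trial_dataset()].
#' @param trait trait name.
#' @return data.frame with `entry`, `adjusted_mean`, `se`, `n`. Entries with
#'   no non-missing plots are dropped with a warning.
#' @export
adjusted_means <- function(ds, trait) {
  if (!trait %in% names(ds)) stop("trait not present: ", trait)
  d <- data.frame(y = ds[[trait]],
                  entry = factor(ds$entry),
                  env = interaction(ds$treatment, ds$year, ds$rep,
                                    drop = TRUE))
  keep <- !is.na(d$y)
  lost <- setdiff(levels(d$entry), unique(as.character(d$entry[keep])))
  if (length(lost))
    warning("entry(ies) without observations excluded: ",
            paste(lost, collapse = ", "))
  d <- droplevels(d[keep, ])
  fit <- if (nlevels(d$env) > 1L) stats::lm(y ~ entry + env, data = d)
         else stats::lm(y ~ entry, data = d)
  em <- as.data.frame(emmeans::emmeans(fit, "entry"))
  out <- data.frame(entry = as.character(em$entry),
                    adjusted_mean = em$emmean,
                    se = em$SE,
                    n = as.integer(table(d$entry)[as.character(em$entry)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Trait correlation matrix with significance flags
#'
#' Pearson correlations between trait columns of an entry x trait table of
#' adjusted means, with two-sided t-based p-values and a 5%-level (or
#' `alpha`) significance flag.
#'
#' @param means data.frame of adjusted means: one row per entry, one numeric
#'   column per trait (a character `entry` column is ignored); >= 4 entries
#'   and >= 2 traits.
#' @param alpha flag level.
#' @return List of class `trait_correlations`: matrices `r`, `p`,
#'   logical `sig`, and `n`. Constant traits give `NA` entries with a
#'   warning.
#' @export
trait_correlations <- function(means, alpha = 0.05) {
  means <- as.data.frame(means)
  num <- vapply(means, is.numeric, logical(1))
  x <- as.matrix(means[num])
  if (nrow(x) < 4L) stop("need >= 4 entries, got ", nrow(x))
  if (ncol(x) < 2L) stop("need >= 2 traits, got ", ncol(x))
  traits <- colnames(x)
  m <- length(traits)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  const <- apply(x, 2L, stats::sd, na.rm = TRUE) == 0
  if (any(const))
    warning("constant trait(s), correlations undefined: ",
            paste(traits[const], collapse = ", "))
  for (a in 2:m) for (b in seq_len(a - 1L)) {
    if (const[a] || const[b]) next
    ct <- stats::cor.test(x[, a], x[, b], method = "pearson")
    r[a, b] <- r[b, a] <- unname(ct$estimate)
    p[a, b] <- p[b, a] <- ct$p.value
  }
  structure(list(r = r, p = p, sig = p < alpha, n = nrow(x),
                 alpha = alpha),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 3, ...) {
  cat("trait correlations on adjusted means (n =", x$n, "entries); * p <",
      x$alpha, "\n")
  m <- matrix("", nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  low <- lower.tri(m, diag = TRUE)
  m[low] <- paste0(format(round(x$r[low], digits)),
                   ifelse(!is.na(x$sig[low]) & x$sig[low], "*", ""))
  print(m, quote = FALSE)
  invisible(x)
}

#' Progeny BLUPs from the six-term random model
#'
#' Fits, by REML via \pkg{lme4}, the all-random intercept model
#' `trait ~ (1|progeny) + (1|treatment) + (1|year) +
#' (1|rep in treatment:year) + (1|progeny:treatment) + (1|progeny:year)`
#' and returns the shrinkage predictions (BLUPs) of the progeny effects,
#' ranked descending. Random terms whose grouping factor has fewer than two
#' levels in the data (e.g. a single-year trial) are dropped with a message.
#' A fit that fails lme4's convergence checks is an error carrying the
#' optimizer diagnostics.
#'
#' @param ds a [trial_dataset()].
#' @param trait response trait name.
#' @param progeny_col column holding the progeny identifier (default
#'   `"entry"`).
#' @return List of class `blup_fit`: `blups` (data.frame `progeny`, `blup`,
#'   `rank`), `varcomp` (data.frame of REML variance components), `formula`,
#'   and `model` (the `lmerMod`).
#' @export
fit_blups <- function(ds, trait = "yield", progeny_col = "entry") {
  if (!trait %in% names(ds)) stop("trait not present: ", trait)
  if (!progeny_col %in% names(ds)) stop("column not present: ", progeny_col)
  d <- data.frame(y = ds[[trait]],
                  progeny = factor(ds[[progeny_col]]),
                  treatment = factor(ds$treatment),
                  year = factor(ds$year),
                  rep_ty = interaction(ds$rep, ds$treatment, ds$year,
                                       drop = TRUE))
  d <- d[!is.na(d$y), ]
  if (nlevels(droplevels(d$progeny)) < 2L)
    stop("need >= 2 progenies")
  terms <- c("(1 | progeny)",
             if (nlevels(droplevels(d$treatment)) > 1L) "(1 | treatment)",
             if (nlevels(droplevels(d$year)) > 1L) "(1 | year)",
             if (nlevels(droplevels(d$rep_ty)) > 1L) "(1 | rep_ty)",
             if (nlevels(droplevels(d$treatment)) > 1L)
               "(1 | progeny:treatment)",
             if (nlevels(droplevels(d$year)) > 1L) "(1 | progeny:year)")
  dropped <- 6L - length(terms)
  if (dropped > 0L)
    message(dropped,
            " random term(s) dropped (grouping factor with < 2 levels)")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  if (isTRUE(fit@optinfo$conv$opt != 0))
    stop("REML fit did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  re <- lme4::ranef(fit)$progeny
  blups <- data.frame(progeny = rownames(re), blup = re[["(Intercept)"]],
                      stringsAsFactors = FALSE)
  blups <- blups[order(-blups$blup), ]
  blups$rank <- seq_len(nrow(blups))
  rownames(blups) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(blups = blups,
                 varcomp = data.frame(term = vc$grp, variance = vc$vcov,
                                      sd = vc$sdcor,
                                      stringsAsFactors = FALSE),
                 formula = form,
                 model = fit),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("blup_fit:", deparse(x$formula), "\n")
  cat("variance components:\n")
  print(x$varcomp, row.names = FALSE)
  cat("top progenies:\n")
  print(utils::head(x$blups, 5L), row.names = FALSE)
  invisible(x)
}
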