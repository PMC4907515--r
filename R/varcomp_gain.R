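#' Three-way ANOVA of a balanced trial
#'
#' Exact sums-of-squares decomposition of one trait for the balanced
#' genotype (G) x treatment (T) x year (Y) layout with replicates nested in
#' treatment-by-year: terms G, T, Y, GT, GY, TY, GTY, R(TY) and residual.
#' Computed by closed-form marginal-total algebra, so the partition is exact
#' (component sums of squares add to the total). Unbalanced layouts are
#' rejected — the expected-mean-squares algebra used downstream by
#' [estimate_varcomps()] assumes balance.
#'
#' @param ds a [trial_dataset()].
#' @param trait trait name; must be observed in every cell.
#' @return data.frame with columns `term`, `df`, `sumsq`, `meansq`, class
#'   `rsmet_anova`, with the design dimensions attached as attribute
#'   `"dims"`.
#' @export
anova_three_way <- function(ds, trait) {
  if (!trait %in% names(ds)) stop("trait not present: ", trait)
  v <- ds[[trait]]
  G <- factor(ds$entry); Tr <- factor(ds$treatment)
  Yr <- factor(ds$year); Rp <- factor(ds$rep)
  g <- nlevels(G); t <- nlevels(Tr); y <- nlevels(Yr); r <- nlevels(Rp)
  tab <- table(G, Tr, Yr, Rp)
  if (any(tab != 1L) || anyNA(v)) {
    idx <- which(tab == 0L, arr.ind = TRUE)
    cells <- if (nrow(idx)) {
      apply(utils::head(idx, 5L), 1L, function(i)
        paste(levels(G)[i[1]], levels(Tr)[i[2]], levels(Yr)[i[3]],
              levels(Rp)[i[4]], sep = "/"))
    } else character(0)
    na_note <- if (anyNA(v)) sprintf("; %d missing value(s) in '%s'",
                                     sum(is.na(v)), trait) else ""
    dup_note <- if (any(tab > 1L)) "; duplicated cells present" else ""
    stop("unbalanced layout for trait '", trait, "'",
         if (length(cells)) paste0(": missing cell(s) ",
                                   paste(cells, collapse = ", ")) else "",
         dup_note, na_note)
  }
  N <- length(v)
  cf <- sum(v)^2 / N
  ss_of <- function(..., divisor) {
    sum(tapply(v, list(...), sum)^2) / divisor - cf
  }
  ss_G <- ss_of(G, divisor = t * y * r)
  ss_T <- ss_of(Tr, divisor = g * y * r)
  ss_Y <- ss_of(Yr, divisor = g * t * r)
  ss_GT <- ss_of(G, Tr, divisor = y * r) - ss_G - ss_T
  ss_GY <- ss_of(G, Yr, divisor = t * r) - ss_G - ss_Y
  ss_TY <- ss_of(Tr, Yr, divisor = g * r) - ss_T - ss_Y
  ss_GTY <- ss_of(G, Tr, Yr, divisor = r) -
    ss_G - ss_T - ss_Y - ss_GT - ss_GY - ss_TY
  ss_R <- ss_of(Tr, Yr, Rp, divisor = g) - ss_T - ss_Y - ss_TY
  ss_tot <- sum(v^2) - cf
  ss_E <- ss_tot - (ss_G + ss_T + ss_Y + ss_GT + ss_GY + ss_TY +
                      ss_GTY + ss_R)
  out <- data.frame(
    term = c("G", "T", "Y", "GT", "GY", "TY", "GTY", "R(TY)", "residual"),
    df = c(g - 1L, t - 1L, y - 1L,
           (g - 1L) * (t - 1L), (g - 1L) * (y - 1L), (t - 1L) * (y - 1L),
           (g - 1L) * (t - 1L) * (y - 1L),
           t * y * (r - 1L),
           (g - 1L) * t * y * (r - 1L)),
    sumsq = c(ss_G, ss_T, ss_Y, ss_GT, ss_GY, ss_TY, ss_GTY, ss_R, ss_E),
    stringsAsFactors = FALSE)
  out$meansq <- ifelse(out$df > 0L, out$sumsq / out$df, NA_real_)
  structure(out, dims = design_dims(g, t, y, r),
            class = c("rsmet_anova", "data.frame"))
}

#' Method-of-moments variance components from the three-way ANOVA
#'
#' Solves the expected-mean-squares equations of the all-random balanced
#' G x T x Y model:
#' `sigma2_e = MS_error`;
#' `sigma2_GTY = (MS_GTY - MS_error) / r`;
#' `sigma2_GY = (MS_GY - MS_GTY) / (r t)`;
#' `sigma2_GT = (MS_GT - MS_GTY) / (r y)`;
#' `sigma2_G = (MS_G - MS_GT - MS_GY + MS_GTY) / (r t y)`.
#' Negative method-of-moments estimates are retained as estimated and
#' flagged; [broad_sense_heritability()] truncates them to zero.
#'
#' @param ms an `rsmet_anova` table from [anova_three_way()].
#' @param dims optional [design_dims()]; must match the table's own.
#' @return A `varcomps` list: `sigma2_G`, `sigma2_GT`, `sigma2_GY`,
#'   `sigma2_GTY`, `sigma2_e`, `dims`, `negative` (names of negative
#'   estimates).
#' @export
estimate_varcomps <- function(ms, dims = NULL) {
  if (!inherits(ms, "rsmet_anova"))
    stop("`ms` must come from anova_three_way()")
  md <- attr(ms, "dims")
  if (!is.null(dims)) {
    if (!identical(unlist(dims), unlist(md)))
      stop("dims mismatch: table has g=", md$g, ", t=", md$t,
           ", y=", md$y, ", r=", md$r)
  }
  dims <- md
  if (dims$g < 2L || dims$t < 2L || dims$y < 2L || dims$r < 2L)
    stop("variance-component estimation needs >= 2 levels of entry, ",
         "treatment, year and replicate")
  m <- stats::setNames(ms$meansq, ms$term)
  r <- dims$r; t <- dims$t; y <- dims$y
  vc <- list(
    sigma2_G = (m[["G"]] - m[["GT"]] - m[["GY"]] + m[["GTY"]]) / (r * t * y),
    sigma2_GT = (m[["GT"]] - m[["GTY"]]) / (r * y),
    sigma2_GY = (m[["GY"]] - m[["GTY"]]) / (r * t),
    sigma2_GTY = (m[["GTY"]] - m[["residual"]]) / r,
    sigma2_e = m[["residual"]])
  neg <- names(vc)[unlist(vc) < 0]
  structure(c(vc, list(dims = dims, negative = neg)), class = "varcomps")
}

#' @export
print.varcomps <- function(x, ...) {
  cat(sprintf("varcomps (g=%d, t=%d, y=%d, r=%d):\n",
              x$dims$g, x$dims$t, x$dims$y, x$dims$r))
  cat(sprintf("  sigma2_G=%.4g  sigma2_GT=%.4g  sigma2_GY=%.4g  sigma2_GTY=%.4g  sigma2_e=%.4g\n",
              x$sigma2_G, x$sigma2_GT, x$sigma2_GY, x$sigma2_GTY, x$sigma2_e))
  if (length(x$negative))
    cat("  negative estimate(s):", paste(x$negative, collapse = ", "),
        "(truncated to 0 in heritability)\n")
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' Entry-mean-basis heritability of the three-way random model, in percent:
#' `H = sigma2_G / (sigma2_G + sigma2_GT/t + sigma2_GY/y +
#' sigma2_GTY/(t*y) + sigma2_e/(r*y*t)) * 100`.
#' Negative component estimates are truncated to zero for this computation
#' (they remain visible in the `varcomps` object). A zero genotypic variance
#' gives 0; an all-zero denominator gives 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param vc a `varcomps` from [estimate_varcomps()], or a bare list with
#'   the five components and `dims`.
#' @return Heritability percent in `[0, 100]`.
#' @export
broad_sense_heritability <- function(vc) {
  d <- vc$dims
  if (is.null(d)) stop("vc must carry design dims")
  comp <- vapply(c("sigma2_G", "sigma2_GT", "sigma2_GY", "sigma2_GTY",
                   "sigma2_e"),
                 function(nm) max(0, vc[[nm]]), numeric(1))
  den <- comp["sigma2_G"] + comp["sigma2_GT"] / d$t + comp["sigma2_GY"] / d$y +
    comp["sigma2_GTY"] / (d$t * d$y) + comp["sigma2_e"] / (d$r * d$y * d$t)
  if (den == 0) {
    h <- 0
    attr(h, "degenerate") <- TRUE
    return(h)
  }
  unname(comp["sigma2_G"] / den * 100)
}

#' Phenotypic standard deviation
#'
#' Standard deviation of entry means over all plots (the default, matching
#' selection among entries) or of raw plot values.
#'
#' @param ds a [trial_dataset()].
#' @param trait trait name.
#' @param basis `"entry_mean"` or `"plot"`.
#' @return Standard deviation in trait units.
#' @export
phenotypic_sd <- function(ds, trait, basis = c("entry_mean", "plot")) {
  basis <- match.arg(basis)
  if (basis == "plot") return(stats::sd(ds[[trait]], na.rm = TRUE))
  stats::sd(entry_means(ds, trait, group_by = "entry")$mean)
}

#' Genetic advance under truncation selection
#'
#' Expected gain from one round of truncation selection,
#' `GA = K * sigmaP * H/100` (the breeder's equation with heritability in
#' percent), where `K` is the standardized selection intensity (2.06 at 5%
#' selection) and `sigmaP` the phenotypic standard deviation on the basis
#' selection acts on.
#'
#' @param sigmaP phenotypic standard deviation (>= 0), trait units.
#' @param H_pct broad-sense heritability, percent in `[0, 100]`.
#' @param K standardized selection intensity (default 2.06).
#' @return Genetic advance in trait units (>= 0 when `K >= 0`).
#' @export
genetic_advance <- function(sigmaP, H_pct, K = 2.06) {
  if (any(sigmaP < 0)) stop("sigmaP must be >= 0")
  if (any(H_pct < 0 | H_pct > 100)) stop("H_pct must lie in [0, 100]")
  K * sigmaP * (H_pct / 100)
}

#' Genetic gain as a percentage of the mean
#'
#' @param GA genetic advance, trait units.
#' @param mean population mean (> 0), trait units.
#' @return `GA / mean * 100`.
#' @export
genetic_gain_percent <- function(GA, mean) {
  if (any(mean <= 0)) stop("mean must be > 0")
  GA / mean * 100
}

#' Percent gain over a reference mean
#'
#' `(mean - ref_mean) / ref_mean * 100`; negative values mean the population
#' lies below the reference.
#'
#' @param mean population mean, trait units.
#' @param ref_mean reference mean (> 0), trait units.
#' @return Percent difference.
#' @export
gain_over_reference <- function(mean, ref_mean) {
  if (any(ref_mean <= 0)) stop("ref_mean must be > 0")
  (mean - ref_mean) / ref_mean * 100
}

#' Gain summary for one population subset
#'
#' Runs the full chain for one trait on one (balanced) subset of records:
#' three-way ANOVA, variance components, broad-sense heritability,
#' phenotypic SD on the entry-mean basis, genetic advance and genetic gain
#' percent, plus optional percent gains over a parent (F5) mean and a check
#' mean.
#'
#' @param ds a [trial_dataset()] (already subset to the population of
#'   interest).
#' @param trait trait name.
#' @param K selection intensity.
#' @param f5_ref_mean,check_ref_mean optional reference means for the gain
#'   columns.
#' @param sigmaP_basis basis for the phenotypic SD, see [phenotypic_sd()].
#' @return One-row data.frame: `trait`, `n_entries`, `mean`, `sigmaP`,
#'   `H_BS`, `K`, `GA`, `gain_pct`, `gain_over_F5_pct`,
#'   `gain_over_check_pct`, `negative_components`.
#' @export
gain_summary <- function(ds, trait, K = 2.06, f5_ref_mean = NULL,
                         check_ref_mean = NULL,
                         sigmaP_basis = "entry_mean") {
  ms <- anova_three_way(ds, trait)
  vc <- estimate_varcomps(ms)
  H <- broad_sense_heritability(vc)
  em <- entry_means(ds, trait, group_by = "entry")
  mu <- mean(em$mean)
  sp <- phenotypic_sd(ds, trait, basis = sigmaP_basis)
  GA <- genetic_advance(sp, H, K)
  data.frame(
    trait = trait,
    n_entries = nrow(em),
    mean = mu,
    sigmaP = sp,
    H_BS = H,
    K = K,
    GA = GA,
    gain_pct = genetic_gain_percent(GA, mu),
    gain_over_F5_pct = if (is.null(f5_ref_mean)) NA_real_
                       else gain_over_reference(mu, f5_ref_mean),
    gain_over_check_pct = if (is.null(check_ref_mean)) NA_real_
                          else gain_over_reference(mu, check_ref_mean),
    negative_components = paste(vc$negative, collapse = ","),
    stringsAsFactors = FALSE)
}

#' Per-population gain table
#'
#' Builds the gain table for one trait with one row per analysis group: the
#' base population, the pooled half-sib population, and each half-sib family
#' separately (each family analysed on its own records, as in per-cross
#' analyses of variance). Groups whose records are unbalanced for the trait
#' are reported with an `error` note instead of aborting the table.
#'
#' @param ds a [trial_dataset()] containing `pop_class` labels.
#' @param trait trait name.
#' @param K selection intensity.
#' @param f5_entries optional entry ids of the original parents; their
#'   pooled trait mean feeds `gain_over_F5_pct`.
#' @param check_entry optional check entry id for `gain_over_check_pct`.
#' @return data.frame with a leading `group` column, one row per group.
#' @export
gain_table <- function(ds, trait, K = 2.06, f5_entries = NULL,
                       check_entry = NULL) {
  ref_mean <- function(ids) {
    if (is.null(ids)) return(NULL)
    sub <- ds[ds$entry %in% ids, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    mean(entry_means(structure(sub, traits = trial_traits(ds),
                               class = class(ds)),
                     trait, group_by = "entry")$mean)
  }
  f5_mean <- ref_mean(f5_entries)
  check_mean <- ref_mean(check_entry)
  groups <- list()
  if (any(ds$pop_class == "base", na.rm = TRUE))
    groups[["base"]] <- ds$pop_class == "base"
  if (any(ds$pop_class == "halfsib", na.rm = TRUE))
    groups[["hsib"]] <- ds$pop_class == "halfsib"
  fams <- sort(unique(ds$family[ds$pop_class == "halfsib" &
                                  !is.na(ds$family)]))
  for (f in fams) groups[[f]] <- !is.na(ds$family) & ds$family == f
  if (!length(groups)) groups[["all"]] <- rep(TRUE, nrow(ds))
  rows <- lapply(names(groups), function(gname) {
    sub <- structure(ds[groups[[gname]], , drop = FALSE],
                     traits = trial_traits(ds), class = class(ds))
    res <- tryCatch(
      gain_summary(sub, trait, K = K, f5_ref_mean = f5_mean,
                   check_ref_mean = check_mean),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(group = gname, trait = trait, n_entries = NA_integer_,
                 mean = NA_real_, sigmaP = NA_real_, H_BS = NA_real_,
                 K = K, GA = NA_real_, gain_pct = NA_real_,
                 gain_over_F5_pct = NA_real_, gain_over_check_pct = NA_real_,
                 negative_components = NA_character_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      res$error <- NA_character_
      cbind(data.frame(group = gname, stringsAsFactors = FALSE), res)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
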