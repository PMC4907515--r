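#' Variance-component specification for a synthetic trial
#'
#' Describes the generating model of a balanced multi-environment trial:
#' independent Gaussian random effects for genotype (G), genotype x treatment
#' (GT), genotype x year (GY), genotype x treatment x year (GTY), replicates
#' nested in treatment-by-year, and plot residual, around a grand mean `mu`
#' plus optional fixed treatment and year shifts.
#'
#' Defaults emulate a wheat grain-yield trial in grams per plot: grand mean
#' 600 g, plot-level coefficient of variation near 20%, and a broad-sense
#' heritability on an entry-mean basis (two treatments, two years, two
#' replicates) of about 31% — the magnitude typical of yield under water
#' stress.
#'
#' @param mu grand mean (trait units).
#' @param sigma2_G,sigma2_GT,sigma2_GY,sigma2_GTY,sigma2_e variances (>= 0)
#'   of the corresponding random effects.
#' @param treatment_effects named additive shifts for `RI` and `RF`.
#' @param year_effects numeric vector of additive year shifts (recycled to
#'   the number of years; default all zero).
#' @param rep_effect_sd standard deviation (>= 0) of the replicate-within-
#'   treatment-by-year effect.
#' @return A `varcomp_spec` list.
#' @seealso [simulate_met()], [selection_scenario()]
#' @export
varcomp_spec <- function(mu = 600,
                         sigma2_G = 1200,
                         sigma2_GT = 1200,
                         sigma2_GY = 1200,
                         sigma2_GTY = 800,
                         sigma2_e = 10000,
                         treatment_effects = c(RI = 0, RF = 0),
                         year_effects = NULL,
                         rep_effect_sd = 0) {
  v <- c(sigma2_G = sigma2_G, sigma2_GT = sigma2_GT, sigma2_GY = sigma2_GY,
         sigma2_GTY = sigma2_GTY, sigma2_e = sigma2_e)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all variances must be finite and >= 0")
  if (rep_effect_sd < 0) stop("rep_effect_sd must be >= 0")
  if (!all(c("RI", "RF") %in% names(treatment_effects)))
    stop("treatment_effects must name both RI and RF")
  structure(list(mu = mu,
                 sigma2_G = sigma2_G, sigma2_GT = sigma2_GT,
                 sigma2_GY = sigma2_GY, sigma2_GTY = sigma2_GTY,
                 sigma2_e = sigma2_e,
                 treatment_effects = treatment_effects[c("RI", "RF")],
                 year_effects = year_effects,
                 rep_effect_sd = rep_effect_sd),
            class = "varcomp_spec")
}

#' @export
print.varcomp_spec <- function(x, ...) {
  cat("varcomp_spec: mu =", x$mu, "\n")
  cat(sprintf("  sigma2: G=%g GT=%g GY=%g GTY=%g e=%g; rep sd=%g\n",
              x$sigma2_G, x$sigma2_GT, x$sigma2_GY, x$sigma2_GTY,
              x$sigma2_e, x$rep_effect_sd))
  invisible(x)
}

# Heritability on an entry-mean basis implied by a generating spec.
implied_h2 <- function(spec, dims) {
  den <- spec$sigma2_G + spec$sigma2_GT / dims$t + spec$sigma2_GY / dims$y +
    spec$sigma2_GTY / (dims$t * dims$y) +
    spec$sigma2_e / (dims$r * dims$y * dims$t)
  if (den == 0) return(0)
  spec$sigma2_G / den
}

#' Simulate a balanced multi-environment trial
#'
#' Draws a fully balanced genotype x treatment x year x replicate dataset
#' from the additive model
#' `y = mu + G_i + T_j + Y_k + GT_ij + GY_ik + GTY_ijk + R_l(jk) + e_ijkl`,
#' every random effect independent Gaussian with the variance stated in
#' `spec`. The same seed always reproduces the identical dataset.
#'
#' @param spec a [varcomp_spec()].
#' @param dims a [design_dims()]; `t` must be 2 (the RI/RF design).
#' @param seed integer seed.
#' @param trait trait column name for the simulated values.
#' @param entry_prefix prefix for generated entry identifiers.
#' @param pop_class population class label for all records.
#' @param genetic_values optional numeric vector of length `g` to use as the
#'   genotypic effects `G_i` instead of drawing them (used by the selection
#'   simulator); still centred around `mu`.
#' @return A [trial_dataset()] with `g*t*y*r` records; the true genotypic
#'   effects are attached as attribute `"genetic_values"`.
#' @export
simulate_met <- function(spec, dims, seed, trait = "yield",
                         entry_prefix = "g", pop_class = "base",
                         genetic_values = NULL) {
  stopifnot(inherits(spec, "varcomp_spec"), inherits(dims, "design_dims"))
  if (dims$t != 2L)
    stop("simulate_met generates the paired RI/RF design; dims$t must be 2")
  with_seed(seed, {
    g <- dims$g; t <- dims$t; y <- dims$y; r <- dims$r
    G <- if (is.null(genetic_values))
      stats::rnorm(g, 0, sqrt(spec$sigma2_G))
    else {
      if (length(genetic_values) != g)
        stop("genetic_values must have length dims$g")
      genetic_values
    }
    trt_lev <- c("RI", "RF")
    Tshift <- spec$treatment_effects[trt_lev]
    Yshift <- if (is.null(spec$year_effects)) rep(0, y)
              else rep_len(spec$year_effects, y)
    GT <- matrix(stats::rnorm(g * t, 0, sqrt(spec$sigma2_GT)), g, t)
    GY <- matrix(stats::rnorm(g * y, 0, sqrt(spec$sigma2_GY)), g, y)
    GTY <- array(stats::rnorm(g * t * y, 0, sqrt(spec$sigma2_GTY)),
                 dim = c(g, t, y))
    R <- array(stats::rnorm(t * y * r, 0, spec$rep_effect_sd),
               dim = c(t, y, r))
    grid <- expand.grid(entry = seq_len(g), trt = seq_len(t),
                        year = seq_len(y), rep = seq_len(r),
                        KEEP.OUT.ATTRS = FALSE)
    eps <- stats::rnorm(nrow(grid), 0, sqrt(spec$sigma2_e))
    val <- spec$mu + G[grid$entry] + Tshift[grid$trt] + Yshift[grid$year] +
      GT[cbind(grid$entry, grid$trt)] + GY[cbind(grid$entry, grid$year)] +
      GTY[cbind(grid$entry, grid$trt, grid$year)] +
      R[cbind(grid$trt, grid$year, grid$rep)] + eps
    ids <- sprintf("%s%0*d", entry_prefix, nchar(g), seq_len(g))
    df <- data.frame(entry = ids[grid$entry],
                     family = NA_character_,
                     pop_class = pop_class,
                     treatment = trt_lev[grid$trt],
                     year = as.integer(grid$year),
                     rep = as.integer(grid$rep),
                     stringsAsFactors = FALSE)
    df[[trait]] <- as.numeric(val)
    ds <- trial_dataset(df, traits = trait)
    attr(ds, "genetic_values") <- stats::setNames(G, ids)
    ds
  })
}

#' Recurrent-selection scenario
#'
#' Parameters of a truncation-selection experiment on a simulated base
#' population: per cycle the top `selection_fraction` of entries on
#' phenotype means (across all plots) are selected, and the offspring
#' genotypic mean is shifted by the realized phenotypic selection
#' differential times the heritability (the breeder's equation applied with
#' the realized rather than the expected differential). The final base and
#' selected populations additionally receive a multiplicative rainfed-yield
#' adjustment so their RF/RI mean-yield ratios match `stress_yield_ratio_*`
#' — emulating a base population whose yield collapses under rainfed stress
#' while the selected half-sib population maintains it.
#'
#' Default sizes mirror a realistic programme: a base population of 157
#' lines, 75 selected-progeny lines, 5% truncation (standardized intensity
#' near `K = 2.06`), base RF:RI ratio 0.53 and selected RF:RI ratio 1.09.
#'
#' @param n_base base-population entry count.
#' @param n_progeny entry count of the final selected population.
#' @param n_cycles number of selection cycles (>= 0).
#' @param selection_fraction fraction of entries kept, in (0, 1].
#' @param K standardized selection intensity used for *expected*-gain
#'   calculations (2.06 at 5% selection).
#' @param h2 generating-truth heritability in `[0, 1]`; default `NULL`
#'   derives it from the variance components and design dimensions.
#' @param stress_yield_ratio_base,stress_yield_ratio_selected target RF/RI
#'   mean-yield ratios (> 0) for the base and selected populations.
#' @param seed integer seed.
#' @return A `selection_scenario` list.
#' @export
selection_scenario <- function(n_base = 157L, n_progeny = 75L,
                               n_cycles = 1L, selection_fraction = 0.05,
                               K = 2.06, h2 = NULL,
                               stress_yield_ratio_base = 0.53,
                               stress_yield_ratio_selected = 1.09,
                               seed = 1L) {
  if (selection_fraction <= 0 || selection_fraction > 1)
    stop("selection_fraction must lie in (0, 1]")
  if (stress_yield_ratio_base <= 0 || stress_yield_ratio_selected <= 0)
    stop("stress yield ratios must be > 0")
  if (!is.null(h2) && (h2 < 0 || h2 > 1))
    stop("h2 must lie in [0, 1]")
  if (n_cycles < 0) stop("n_cycles must be >= 0")
  structure(list(n_base = as.integer(n_base),
                 n_progeny = as.integer(n_progeny),
                 n_cycles = as.integer(n_cycles),
                 selection_fraction = selection_fraction,
                 K = K, h2 = h2,
                 stress_yield_ratio_base = stress_yield_ratio_base,
                 stress_yield_ratio_selected = stress_yield_ratio_selected,
                 seed = as.integer(seed)),
            class = "selection_scenario")
}

# Multiply RF plot values so the population RF/RI mean ratio hits `ratio`.
apply_stress_ratio <- function(ds, ratio, trait = "yield") {
  rf <- ds$treatment == "RF"
  m_rf <- mean(ds[[trait]][rf])
  m_ri <- mean(ds[[trait]][!rf])
  ds[[trait]][rf] <- ds[[trait]][rf] * ratio * m_ri / m_rf
  ds
}

#' Simulate a recurrent-selection response
#'
#' Runs `n_cycles` of truncation selection on simulated phenotype entry
#' means and returns the paired base and selected populations as
#' [trial_dataset()]s, labelled `pop_class = "base"` and `"halfsib"`.
#' Selection acts on the raw simulated phenotypes; the RF stress-ratio
#' adjustment is applied to the returned datasets afterwards, so the
#' realized genetic response is untouched by the stress differential.
#'
#' @param scn a [selection_scenario()].
#' @param spec a [varcomp_spec()].
#' @param dims a [design_dims()] giving the per-cycle trial layout (`g` is
#'   taken from the scenario, not from `dims`).
#' @param trait simulated trait name.
#' @return List with elements `base` and `selected` (both `trial_dataset`),
#'   and attributes `realized_response` (total genotypic-mean shift, trait
#'   units), `differentials` (per-cycle realized phenotypic selection
#'   differentials) and `h2` (the heritability used).
#' @export
simulate_selection_response <- function(scn, spec, dims, trait = "yield") {
  stopifnot(inherits(scn, "selection_scenario"),
            inherits(spec, "varcomp_spec"),
            inherits(dims, "design_dims"))
  n_sel <- max(1L, ceiling(scn$selection_fraction * scn$n_base))
  if (n_sel < 2L)
    stop("selection_fraction keeps fewer than 2 parents (",
         n_sel, " of ", scn$n_base, ")")
  h2 <- if (is.null(scn$h2)) implied_h2(spec, dims) else scn$h2
  base_dims <- design_dims(g = scn$n_base, t = dims$t, y = dims$y, r = dims$r)
  shift <- 0
  diffs <- numeric(0)
  base_ds <- NULL
  with_seed(scn$seed, {
    cycle_seeds <- sample.int(.Machine$integer.max, scn$n_cycles + 2L)
    for (cy in seq_len(scn$n_cycles)) {
      cur <- simulate_met(spec, base_dims, seed = cycle_seeds[cy],
                          trait = trait, entry_prefix = "b",
                          pop_class = "base")
      # shift applies to the genotypic mean of the current cycle's parents
      cur[[trait]] <- cur[[trait]] + shift
      if (cy == 1L) base_ds <- cur
      pm <- entry_means(cur, trait, group_by = "entry")
      sel <- utils::head(pm[order(-pm$mean), ], n_sel)
      S <- mean(sel$mean) - mean(pm$mean)
      diffs <- c(diffs, S)
      shift <- shift + h2 * S
    }
    if (is.null(base_ds))
      base_ds <- simulate_met(spec, base_dims,
                               seed = cycle_seeds[scn$n_cycles + 1L],
                               trait = trait, entry_prefix = "b",
                               pop_class = "base")
    sel_dims <- design_dims(g = scn$n_progeny, t = dims$t, y = dims$y,
                            r = dims$r)
    sel_spec <- spec
    sel_spec$mu <- spec$mu + shift
    sel_ds <- simulate_met(sel_spec, sel_dims,
                           seed = cycle_seeds[scn$n_cycles + 2L],
                           trait = trait, entry_prefix = "hs",
                           pop_class = "halfsib")
    out <- list(base = apply_stress_ratio(base_ds,
                                          scn$stress_yield_ratio_base,
                                          trait),
                selected = apply_stress_ratio(sel_ds,
                                              scn$stress_yield_ratio_selected,
                                              trait))
    attr(out, "realized_response") <- shift
    attr(out, "differentials") <- diffs
    attr(out, "h2") <- h2
    class(out) <- "selection_response"
    out
  })
}

#' @export
print.selection_response <- function(x, ...) {
  cat(sprintf("selection_response: base g=%d, selected g=%d | realized genotypic shift %.2f (h2 = %.3f)\n",
              trial_design(x$base)$g, trial_design(x$selected)$g,
              attr(x, "realized_response"), attr(x, "h2")))
  invisible(x)
}
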