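# Printed drought-index table frozen from the published comparison of 16
# entries (10 half-sib families, the pooled half-sib population, two checks,
# the two original parents, and the base population). Reference means are the
# pooled half-sib row (y_rf = 650.9, y_ri = 597). Known errata in the printed
# table, from recomputing every cell by hand: the base row's MRP/REI/STI do
# not follow the stated formulas, and the GMP column is systematically ~0.5-1%
# below sqrt(y_rf * y_ri) (consistent with per-replicate geometric means).
table6_printed <- function() {
  tab <- read.csv(text = '
entry,y_rf,y_ri,tol,gmp,mpi,mrp,rei,sti,tol_rank,gmp_rank,mpi_rank,mrp_rank,rei_rank,sti_rank
hs116,595.7,564.9,-30.8,575.1,580.3,1.86,0.87,0.94,9,11,12,11,11,11
hs26,621,551.5,-69.5,570.1,586.3,1.88,0.88,0.96,5,12,10,10,10,10
hs35,593.9,584.3,-9.6,582.0,589.1,1.89,0.89,0.97,11,9,9,9,9,9
hs39,626,602.3,-23.8,611.6,614.1,1.97,0.97,1.06,10,8,8,8,8,8
hs48,616.5,648.8,32.3,629.7,632.6,2.03,1.03,1.12,13,3,4,4,4,4
hs65,710.8,638.8,-72.0,669.0,674.8,2.16,1.17,1.27,4,1,1,1,1,1
hs68,623,628.3,5.3,618.2,625.7,2.01,1.01,1.10,12,7,5,5,5,5
hs79,652.8,596.7,-56.1,620.3,624.8,2,1,1.09,6,6,6,6,6,6
hs86,709.3,566.4,-142.9,628.9,637.9,2.04,1.03,1.13,2,4,3,3,3,3
hs91,678.1,622,-56.1,643.0,650.1,2.08,1.09,1.18,7,2,2,2,2,2
hsib,650.9,597,-53.9,623.4,624.0,2,1,1.09,8,5,7,7,7,7
HD2987,637.5,525,-112.5,578.4,581.3,1.86,0.86,0.94,3,10,11,12,12,12
HD3043,695,462.5,-232.5,566.4,578.8,1.84,0.83,0.90,1,13,13,13,14,13
HI1500,335.7,726.1,390.4,493.7,530.9,1.73,0.63,0.68,15,14,14,15,15,14
HUW510,182,651.6,469.7,344.4,416.8,1.37,0.31,0.33,16,16,16,16,16,16
base,353.6,673.2,319.6,487.9,513.4,1.83,0.84,0.44,14,15,15,14,13,15
', stringsAsFactors = FALSE)
  tab
}

table6_means <- function() {
  read.csv(system.file("extdata", "table6_yield_means.csv", package = "rsmet"),
           stringsAsFactors = FALSE)
}

# Plot-level re-encoding of the entry x treatment means (one plot per cell).
table6_plot_ds <- function() {
  w <- table6_means()
  long <- rbind(
    data.frame(entry = w$entry, pop_class = w$pop_class, treatment = "RF",
               year = 1L, rep = 1L, yield = w$y_rf,
               stringsAsFactors = FALSE),
    data.frame(entry = w$entry, pop_class = w$pop_class, treatment = "RI",
               year = 1L, rep = 1L, yield = w$y_ri,
               stringsAsFactors = FALSE))
  trial_dataset(long)
}

# Small balanced dataset with deterministic values.
make_balanced_ds <- function(g = 3L, t = 2L, y = 2L, r = 2L,
                             values = NULL, trait = "yield") {
  grid <- expand.grid(entry = paste0("e", seq_len(g)),
                      treatment = c("RI", "RF")[seq_len(t)],
                      year = seq_len(y), rep = seq_len(r),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(values)) values <- seq_len(nrow(grid))
  grid[[trait]] <- values
  trial_dataset(grid, traits = trait)
}

# Integer fixture for the exact variance-component checks: 3 x 2 x 2 x 2,
# hand-chosen small integers (exact in double arithmetic).
integer_fixture <- function() {
  vals <- c(12, 7, 9, 14, 6, 11, 8, 13, 10, 5, 15, 9,
            7, 12, 11, 6, 13, 8, 9, 14, 10, 7, 12, 11)
  make_balanced_ds(g = 3L, t = 2L, y = 2L, r = 2L, values = vals)
}

# Independent ANOVA oracle: sequential sums of squares from stats::lm on the
# orthogonal balanced layout (a different code path from the closed-form
# marginal-total algebra inside the package).
oracle_anova_lm <- function(ds, trait) {
  d <- data.frame(v = ds[[trait]],
                  G = factor(ds$entry), T = factor(ds$treatment),
                  Y = factor(ds$year), R = factor(ds$rep))
  a <- stats::anova(stats::lm(v ~ G * T * Y + T:Y:R, data = d))
  key <- c(G = "G", T = "T", Y = "Y", `G:T` = "GT", `G:Y` = "GY",
           `T:Y` = "TY", `G:T:Y` = "GTY", `T:Y:R` = "R(TY)",
           Residuals = "residual")
  data.frame(term = unname(key[rownames(a)]), df = a$Df, sumsq = a$`Sum Sq`,
             meansq = a$`Mean Sq`, stringsAsFactors = FALSE)
}

# Expected-mean-squares solve written out longhand for the oracle path.
oracle_varcomps <- function(ms, g, t, y, r) {
  m <- setNames(ms$meansq, ms$term)
  list(sigma2_e = m[["residual"]],
       sigma2_GTY = (m[["GTY"]] - m[["residual"]]) / r,
       sigma2_GY = (m[["GY"]] - m[["GTY"]]) / (r * t),
       sigma2_GT = (m[["GT"]] - m[["GTY"]]) / (r * y),
       sigma2_G = (m[["G"]] - m[["GT"]] - m[["GY"]] + m[["GTY"]]) / (r * t * y))
}
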