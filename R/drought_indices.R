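check_yields <- function(yi_ns, yi_s) {
  if (any(yi_ns < 0, na.rm = TRUE) || any(yi_s < 0, na.rm = TRUE))
    stop("yields must be non-negative")
}
check_refs <- function(...) {
  refs <- c(...)
  if (any(!is.finite(refs)) || any(refs <= 0))
    stop("reference means must be finite and > 0")
}

#' Drought-tolerance indices
#'
#' Six yield-based indices contrasting an entry's mean yield under stress
#' (rainfed, `yi_s`) and non-stress (restricted irrigation, `yi_ns`), some
#' normalized by population reference means `y_s`, `y_ns`:
#'
#' * `tol`: stress tolerance, `yi_ns - yi_s` (negative = higher yield under
#'   stress; smaller is better).
#' * `mpi`: mean productivity, `(yi_ns + yi_s) / 2`.
#' * `gmp`: geometric mean productivity, `sqrt(yi_s * yi_ns)`.
#' * `mrp`: mean relative performance, `yi_s/y_s + yi_ns/y_ns`.
#' * `rei`: relative efficiency, `(yi_s/y_s) * (yi_ns/y_ns)`.
#' * `sti`: stress tolerance index, `yi_ns * yi_s / y_ns^2`.
#'
#' All functions are vectorized over entries. By the AM-GM inequality
#' `gmp <= mpi` always, with equality iff `yi_s = yi_ns`, and
#' `rei <= (mrp/2)^2`.
#'
#' @param yi_ns entry mean yield under non-stress (RI), g/plot.
#' @param yi_s entry mean yield under stress (RF), g/plot.
#' @param y_s,y_ns reference population mean yields under stress and
#'   non-stress (> 0).
#' @return Numeric vector of index values; `tol`, `mpi`, `gmp` in g/plot,
#'   `mrp`, `rei`, `sti` dimensionless.
#' @name drought_indices
NULL

#' @rdname drought_indices
#' @export
tol <- function(yi_ns, yi_s) yi_ns - yi_s

#' @rdname drought_indices
#' @export
mpi <- function(yi_ns, yi_s) (yi_ns + yi_s) / 2

#' @rdname drought_indices
#' @export
gmp <- function(yi_ns, yi_s) {
  check_yields(yi_ns, yi_s)
  sqrt(yi_ns * yi_s)
}

#' @rdname drought_indices
#' @export
mrp <- function(yi_ns, yi_s, y_ns, y_s) {
  check_refs(y_ns, y_s)
  yi_s / y_s + yi_ns / y_ns
}

#' @rdname drought_indices
#' @export
rei <- function(yi_ns, yi_s, y_ns, y_s) {
  check_refs(y_ns, y_s)
  (yi_s / y_s) * (yi_ns / y_ns)
}

#' @rdname drought_indices
#' @export
sti <- function(yi_ns, yi_s, y_ns) {
  check_refs(y_ns)
  yi_ns * yi_s / y_ns^2
}

#' Index table with per-index entry rankings
#'
#' Computes all six drought-tolerance indices for every entry and ranks
#' entries within each index: ascending for TOL (most negative = rank 1,
#' i.e. highest relative yield under stress) and descending for all others
#' (largest = rank 1). Ties receive the average rank by default;
#' `ties = "competition"` gives min-rank ("1224") ranking instead.
#'
#' @param means data.frame with columns `entry`, `y_rf` (stress mean yield)
#'   and `y_ri` (non-stress mean yield), e.g. from [ri_rf_means()].
#' @param reference either an entry id present in `means` whose own RF/RI
#'   means define the reference `(y_s, y_ns)`, or a named numeric
#'   `c(y_rf = ..., y_ri = ...)`.
#' @param ties tie policy for ranks: `"average"` or `"competition"`.
#' @return data.frame with one row per entry: yields, the six index values
#'   and the six rank columns (`tol_rank`, ..., `sti_rank`). The reference
#'   means used are attached as attribute `"reference"`.
#' @export
compute_index_table <- function(means, reference,
                                ties = c("average", "competition")) {
  ties <- match.arg(ties)
  means <- as.data.frame(means)
  need <- c("entry", "y_rf", "y_ri")
  miss <- setdiff(need, names(means))
  if (length(miss))
    stop("`means` must have columns entry, y_rf, y_ri; missing: ",
         paste(miss, collapse = ", "))
  if (!nrow(means)) stop("no entries supplied")
  if (is.character(reference)) {
    i <- match(reference, means$entry)
    if (is.na(i)) stop("reference entry not found: ", reference)
    ref <- c(y_rf = means$y_rf[i], y_ri = means$y_ri[i])
  } else {
    if (!all(c("y_rf", "y_ri") %in% names(reference)))
      stop("numeric reference must name y_rf and y_ri")
    ref <- reference[c("y_rf", "y_ri")]
  }
  check_refs(ref)
  yi_s <- means$y_rf; yi_ns <- means$y_ri
  out <- data.frame(entry = means$entry,
                    y_rf = yi_s, y_ri = yi_ns,
                    tol = tol(yi_ns, yi_s),
                    gmp = gmp(yi_ns, yi_s),
                    mpi = mpi(yi_ns, yi_s),
                    mrp = mrp(yi_ns, yi_s, ref[["y_ri"]], ref[["y_rf"]]),
                    rei = rei(yi_ns, yi_s, ref[["y_ri"]], ref[["y_rf"]]),
                    sti = sti(yi_ns, yi_s, ref[["y_ri"]]),
                    stringsAsFactors = FALSE)
  tie_method <- if (ties == "average") "average" else "min"
  rk <- function(x, ascending) {
    rank(if (ascending) x else -x, ties.method = tie_method)
  }
  out$tol_rank <- rk(out$tol, ascending = TRUE)
  for (idx in c("gmp", "mpi", "mrp", "rei", "sti"))
    out[[paste0(idx, "_rank")]] <- rk(out[[idx]], ascending = FALSE)
  attr(out, "reference") <- ref
  out
}

#' Correlations among drought-tolerance indices
#'
#' Pearson correlations between the six index columns of a
#' [compute_index_table()] result, with two-sided p-values. Used to pick a
#' yardstick index: an index positively correlated with all others summarizes
#' the suite.
#'
#' @param table data.frame with columns `tol`, `gmp`, `mpi`, `mrp`, `rei`,
#'   `sti` and at least 3 rows.
#' @return List of class `index_correlations` with matrices `r` and `p`
#'   (entries `NA` where a column is constant) and `n`.
#' @export
index_correlations <- function(table) {
  idx <- c("tol", "gmp", "mpi", "mrp", "rei", "sti")
  miss <- setdiff(idx, names(table))
  if (length(miss))
    stop("index column(s) missing: ", paste(miss, collapse = ", "))
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 entries to correlate indices, got ", n)
  r <- p <- matrix(NA_real_, 6L, 6L, dimnames = list(idx, idx))
  for (a in seq_along(idx)) {
    for (b in seq_len(a)) {
      xa <- table[[idx[a]]]; xb <- table[[idx[b]]]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
        if (a == b && stats::sd(xa) > 0) { r[a, a] <- 1; p[a, a] <- 0 }
        next
      }
      if (a == b) { r[a, a] <- 1; p[a, a] <- 0; next }
      ct <- stats::cor.test(xa, xb, method = "pearson")
      r[a, b] <- r[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  if (any(is.na(diag(r))))
    warning("constant index column(s): ",
            paste(idx[is.na(diag(r))], collapse = ", "))
  structure(list(r = r, p = p, n = n), class = "index_correlations")
}

#' @export
print.index_correlations <- function(x, digits = 3, ...) {
  cat("index correlations (n =", x$n, "entries):\n")
  print(round(x$r, digits))
  invisible(x)
}
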