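.design_cols <- c("entry", "family", "pop_class", "treatment", "year", "rep", "block")
.pop_classes <- c("base", "halfsib", "parent", "check")
.treatments <- c("RI", "RF")

#' Plot-level field-trial dataset
#'
#' Constructs a validated `trial_dataset`: a data.frame of plot-level
#' phenotype records from a trial run under two moisture regimes, restricted
#' irrigation (`RI`, the non-stress treatment) and rainfed (`RF`, the stress
#' treatment), across one or more years with replicates (optionally blocked)
#' nested within each treatment-by-year combination.
#'
#' Required design columns are `entry` (line identifier), `treatment`
#' (`"RI"`/`"RF"`), `year` and `rep`; `family`, `pop_class` (one of
#' `"base"`, `"halfsib"`, `"parent"`, `"check"`) and `block` are optional.
#' All remaining numeric columns are treated as traits unless `traits` is
#' given. Trait values may be missing (`NA`); design keys
#' (entry, treatment, year, rep) must be unique.
#'
#' Units are carried as supplied and never converted; yields are grams per
#' plot in the bundled fixtures, canopy temperatures in degrees Celsius,
#' chlorophyll in SPAD units, NDVI in `[-1, 1]` and harvest index in
#' `[0, 1]`.
#'
#' @param df data.frame of plot records.
#' @param traits character vector naming the trait columns; default: all
#'   numeric non-design columns.
#' @return A `trial_dataset` (a data.frame with attributes `traits` and
#'   `design`).
#' @seealso [read_trial_csv()], [entry_means()], [trial_design()]
#' @examples
#' df <- expand.grid(entry = c("a", "b"), treatment = c("RI", "RF"),
#'                   year = 1L, rep = 1:2)
#' df$yield <- 500 + seq_len(nrow(df))
#' ds <- trial_dataset(df)
#' trial_design(ds)
#' @export
trial_dataset <- function(df, traits = NULL) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("entry", "treatment", "year", "rep")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$family)) df$family <- NA_character_
  if (is.null(df$pop_class)) df$pop_class <- NA_character_
  for (col in c("entry", "family", "pop_class", "treatment"))
    df[[col]] <- as.character(df[[col]])
  df$year <- as.integer(df$year)
  df$rep <- as.integer(df$rep)
  if (!is.null(df$block)) df$block <- as.integer(df$block)
  if (is.null(traits)) {
    traits <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                      .design_cols)
  }
  if (!length(traits)) stop("no trait columns found")
  absent <- setdiff(traits, names(df))
  if (length(absent))
    stop("trait column(s) not in data: ", paste(absent, collapse = ", "))
  df <- df[c(intersect(.design_cols, names(df)), traits)]
  structure(df,
            traits = traits,
            class = c("trial_dataset", "data.frame")) |>
    validate_trial_dataset()
}

validate_trial_dataset <- function(ds) {
  bad_trt <- setdiff(unique(ds$treatment), .treatments)
  if (length(bad_trt))
    stop("treatment values outside {RI, RF}: ",
         paste(bad_trt, collapse = ", "),
         " (supply a `treatment_map` to normalize labels)")
  pc <- ds$pop_class[!is.na(ds$pop_class)]
  bad_pc <- setdiff(unique(pc), .pop_classes)
  if (length(bad_pc))
    stop("pop_class values outside {", paste(.pop_classes, collapse = ", "),
         "}: ", paste(bad_pc, collapse = ", "))
  if (any(ds$rep < 1L, na.rm = TRUE) || anyNA(ds$rep))
    stop("rep must be an integer >= 1")
  if (!is.null(ds$block) && any(ds$block < 1L, na.rm = TRUE))
    stop("block must be an integer >= 1")
  tr <- trial_traits(ds)
  if ("hi" %in% tr && any(ds$hi < 0 | ds$hi > 1, na.rm = TRUE))
    stop("harvest index (hi) must lie in [0, 1]")
  if ("ndvi" %in% tr && any(ds$ndvi < -1 | ds$ndvi > 1, na.rm = TRUE))
    stop("ndvi must lie in [-1, 1]")
  if ("yield" %in% tr && any(ds$yield < 0, na.rm = TRUE))
    stop("yield must be non-negative")
  key <- paste(ds$entry, ds$treatment, ds$year, ds$rep, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicate design key(s) (entry, treatment, year, rep): ",
         paste(gsub("\r", "/", utils::head(dup, 5L)), collapse = "; "))
  ds
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- trial_design(x)
  cat(sprintf("trial_dataset: %d plot records | %d entries x %d treatments x %d years x %d reps\n",
              nrow(x), d$g, d$t, d$y, d$r))
  cat("traits:", paste(trial_traits(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more records\n")
  invisible(x)
}

#' Trait names of a trial dataset
#' @param ds a `trial_dataset`.
#' @return Character vector of trait column names.
#' @export
trial_traits <- function(ds) attr(ds, "traits")

#' Design dimensions
#'
#' `design_dims()` constructs a design-dimension record (entry, treatment,
#' year and replicate counts); `trial_design()` reads the dimensions off a
#' dataset's factor levels.
#'
#' @param g,t,y,r entry, treatment, year and replicate counts (all >= 1).
#' @return A `design_dims` list with elements `g`, `t`, `y`, `r`.
#' @export
design_dims <- function(g, t = 2L, y = 1L, r = 2L) {
  v <- c(g = g, t = t, y = y, r = r)
  if (any(v < 1) || any(v != as.integer(v)))
    stop("design dimensions must be integers >= 1")
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "design_dims")
}

#' @rdname design_dims
#' @param ds a `trial_dataset`.
#' @export
trial_design <- function(ds) {
  design_dims(g = length(unique(ds$entry)),
              t = length(unique(ds$treatment)),
              y = length(unique(ds$year)),
              r = length(unique(ds$rep)))
}

#' @export
print.design_dims <- function(x, ...) {
  cat(sprintf("design: g = %d entries, t = %d treatments, y = %d years, r = %d reps\n",
              x$g, x$t, x$y, x$r))
  invisible(x)
}

#' Read plot-level trial records from CSV
#'
#' Reads an RFC 4180 CSV of plot records into a [trial_dataset()]. Column
#' names can be remapped via `schema`, raw treatment labels normalized via
#' `treatment_map` (the stress level must map to `"RF"`, the non-stress
#' level to `"RI"`). Non-numeric trait cells become `NA` and are counted in
#' a message.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical column names to
#'   file column names, e.g. `c(entry = "line", yield = "gy")`.
#' @param treatment_map named character vector mapping raw treatment labels
#'   to `"RI"`/`"RF"`, e.g. `c(irrigated = "RI", drought = "RF")`.
#' @param traits optional explicit trait column selection (canonical names).
#' @return A `trial_dataset`.
#' @export
read_trial_csv <- function(path, schema = NULL, treatment_map = NULL,
                           traits = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent))
      stop("schema names missing column(s) in file: ",
           paste(absent, collapse = ", "))
    idx <- match(unname(schema), names(raw))
    names(raw)[idx] <- names(schema)
  }
  req <- c("entry", "treatment", "year", "rep")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.null(treatment_map)) {
    mapped <- unname(treatment_map[raw$treatment])
    mapped[is.na(mapped) & raw$treatment %in% .treatments] <-
      raw$treatment[is.na(mapped) & raw$treatment %in% .treatments]
    unk <- unique(raw$treatment[is.na(mapped)])
    if (length(unk))
      stop("treatment label(s) not covered by treatment_map: ",
           paste(unk, collapse = ", "))
    raw$treatment <- mapped
  }
  trait_cols <- if (is.null(traits))
    setdiff(names(raw), .design_cols) else traits
  if (!length(trait_cols)) stop("no trait columns present")
  n_bad <- 0L
  for (col in trait_cols) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    n_bad <- n_bad + sum(is.na(num) & !is.na(raw[[col]]) &
                           nzchar(trimws(raw[[col]])))
    raw[[col]] <- num
  }
  if (n_bad > 0L)
    message(n_bad, " non-numeric trait cell(s) set to NA")
  trial_dataset(raw, traits = trait_cols)
}

#' Write a result table
#'
#' Writes any tabular result as CSV, TSV or a pipe-delimited markdown table.
#' CSV/TSV round-trip numeric values at full precision.
#'
#' @param rows non-empty data.frame.
#' @param path output file path.
#' @param format one of `"csv"`, `"tsv"`, `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv", "markdown")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  if (!nrow(rows)) stop("refusing to write an empty table")
  switch(format,
    csv = utils::write.csv(rows, path, row.names = FALSE),
    tsv = utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                             quote = FALSE),
    markdown = writeLines(format_markdown_table(rows), path))
  invisible(path)
}

format_markdown_table <- function(df) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, digits = 7) else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(rw) paste0("| ", paste(rw, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Group means of a trait
#'
#' Arithmetic means of one trait over non-missing plots, per combination of
#' design factors. Group sizes (`n`, non-missing plot counts) are reported
#' alongside. This is the basis for all index and gain computations: entry
#' means under each treatment feed the drought-tolerance indices, and entry
#' means over all plots feed the phenotypic standard deviation.
#'
#' @param ds a `trial_dataset`.
#' @param trait trait name.
#' @param group_by subset of `c("entry","family","pop_class","treatment","year")`.
#' @return data.frame of grouping columns plus `mean` and `n`, ordered by
#'   the grouping columns.
#' @export
entry_means <- function(ds, trait, group_by = c("entry", "treatment")) {
  if (!trait %in% names(ds)) stop("trait not present: ", trait)
  allowed <- c("entry", "family", "pop_class", "treatment", "year")
  bad <- setdiff(group_by, allowed)
  if (length(bad))
    stop("invalid grouping factor(s): ", paste(bad, collapse = ", "))
  v <- ds[[trait]]
  keys <- lapply(ds[group_by], as.character)
  id <- do.call(paste, c(keys, sep = "\r"))
  ok <- !is.na(v)
  means <- tapply(v[ok], id[ok], mean)
  ns <- tapply(rep(1L, sum(ok)), id[ok], sum)
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- group_by
  if ("year" %in% group_by) out$year <- as.integer(out$year)
  out$mean <- as.numeric(means)
  out$n <- as.integer(ns)
  out <- out[do.call(order, out[group_by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Entry yield means in RI/RF wide form
#'
#' Pivots per-entry treatment means to one row per entry with columns `y_ri`
#' (non-stress mean) and `y_rf` (stress mean) — the inputs the
#' drought-tolerance indices expect.
#'
#' @param ds a `trial_dataset`.
#' @param trait trait name, default `"yield"`.
#' @return data.frame with columns `entry`, `y_rf`, `y_ri` (and `pop_class`
#'   when present in `ds`).
#' @export
ri_rf_means <- function(ds, trait = "yield") {
  m <- entry_means(ds, trait, group_by = c("entry", "treatment"))
  wide <- data.frame(entry = sort(unique(m$entry)), stringsAsFactors = FALSE)
  for (trt in c("RF", "RI")) {
    sub <- m[m$treatment == trt, ]
    wide[[if (trt == "RF") "y_rf" else "y_ri"]] <-
      sub$mean[match(wide$entry, sub$entry)]
  }
  if (any(!is.na(ds$pop_class))) {
    wide$pop_class <- ds$pop_class[match(wide$entry, ds$entry)]
  }
  wide
}
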