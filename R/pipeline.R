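#' Pipeline run configuration
#'
#' Validates and normalizes a pipeline configuration. Exactly one of
#' `input` (a plot-level CSV) or `scenario` (a synthetic selection-response
#' scenario, see [selection_scenario()]) must be given. All defaults —
#' `K = 2.06`, `alpha = 0.05`, Welch t-tests, average-rank ties — are
#' recorded in the run's provenance block so no default stays silent.
#'
#' @param input path to a plot-level trial CSV, or `NULL`.
#' @param scenario list of synthetic-scenario settings (fields of
#'   [selection_scenario()], plus optional sub-lists `spec` for
#'   [varcomp_spec()] and `dims` with `t`, `y`, `r`), or `NULL`.
#' @param traits trait names to analyse; the first is the yield-like trait
#'   used for indices and BLUPs.
#' @param reference_entries list with optional members `f5_parent`
#'   (character vector of parent entry ids), `check` (check entry id) and
#'   `index_reference` (entry id whose RF/RI means anchor the indices; if
#'   omitted, the pooled half-sib population means are used).
#' @param K selection intensity.
#' @param alpha test level in (0, 1).
#' @param seed integer seed for every stochastic step.
#' @param output_dir directory for report files, or `NULL` to skip writing.
#' @param ties rank tie policy, `"average"` or `"competition"`.
#' @param var_equal use pooled- instead of Welch-variance t-tests.
#' @param schema,treatment_map passed to [read_trial_csv()].
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, scenario = NULL, traits = "yield",
                       reference_entries = list(), K = 2.06, alpha = 0.05,
                       seed = 1L, output_dir = NULL,
                       ties = "average", var_equal = FALSE,
                       schema = NULL, treatment_map = NULL,
                       log_level = "info") {
  if (is.null(input) == is.null(scenario))
    stop("exactly one of `input` and `scenario` must be set")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(K) || K < 0) stop("K must be a non-negative number")
  if (!length(traits)) stop("at least one trait is required")
  if (!ties %in% c("average", "competition"))
    stop("ties must be 'average' or 'competition'")
  if (!log_level %in% c("info", "quiet"))
    stop("log_level must be 'info' or 'quiet'")
  structure(list(input = input, scenario = scenario,
                 traits = as.character(traits),
                 reference_entries = reference_entries,
                 K = K, alpha = alpha, seed = as.integer(seed),
                 output_dir = output_dir, ties = ties,
                 var_equal = var_equal, schema = schema,
                 treatment_map = treatment_map, log_level = log_level),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping")
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$schema)) raw$schema <- unlist(raw$schema)
  if (!is.null(raw$treatment_map)) raw$treatment_map <- unlist(raw$treatment_map)
  do.call(run_config, raw)
}

scenario_from_config <- function(scn_cfg, seed) {
  spec_args <- scn_cfg$spec %||% list()
  if (!is.null(spec_args$treatment_effects))
    spec_args$treatment_effects <- unlist(spec_args$treatment_effects)
  spec <- do.call(varcomp_spec, spec_args)
  dims_args <- scn_cfg$dims %||% list()
  dims <- design_dims(g = 1L, t = dims_args$t %||% 2L,
                      y = dims_args$y %||% 2L, r = dims_args$r %||% 2L)
  scn_args <- scn_cfg[setdiff(names(scn_cfg), c("spec", "dims"))]
  scn_args$seed <- seed
  scn <- do.call(selection_scenario, scn_args)
  list(scn = scn, spec = spec, dims = dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bind_trial_datasets <- function(a, b) {
  traits <- union(trial_traits(a), trial_traits(b))
  trial_dataset(rbind(as.data.frame(a)[names(a)],
                      as.data.frame(b)[names(a)]),
                traits = traits)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load or simulate the trial data, entry
#' means, per-population gain tables for every trait, drought-tolerance
#' index table with rankings, population comparisons (t-tests of each
#' half-sib family against base and pooled checks, Dunnett many-to-one tests
#' against the base population), trait correlations on adjusted means, and
#' progeny BLUPs. A failure in one stage or trait is recorded in
#' `$errors` and the remaining stages continue. Re-running with the same
#' configuration and seed reproduces every output byte-identically.
#'
#' @param cfg a [run_config()] (or a path accepted by [load_run_config()]).
#' @return A `report_bundle` list: `data`, `gain_tables` (one per trait),
#'   `index_table`, `ttest_table`, `dunnett_table`, `correlations`,
#'   `blups`, `errors`, and `provenance` (config hash, seed, package
#'   version, defaults). Written to `cfg$output_dir` via [write_report()]
#'   when set.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  say <- function(...) if (cfg$log_level == "info") message(...)
  errors <- list()
  note <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    say("stage '", stage, "' failed: ", conditionMessage(e))
    NULL
  }

  ds <- if (!is.null(cfg$input)) {
    say("reading ", cfg$input)
    read_trial_csv(cfg$input, schema = cfg$schema,
                   treatment_map = cfg$treatment_map)
  } else {
    say("simulating selection-response scenario (seed ", cfg$seed, ")")
    parts <- scenario_from_config(cfg$scenario, cfg$seed)
    sim <- simulate_selection_response(parts$scn, parts$spec, parts$dims,
                                       trait = cfg$traits[1L])
    bind_trial_datasets(sim$base, sim$selected)
  }
  yield_trait <- cfg$traits[1L]
  refs <- cfg$reference_entries

  gain_tables <- stats::setNames(lapply(cfg$traits, function(tr) {
    tryCatch(gain_table(ds, tr, K = cfg$K, f5_entries = refs$f5_parent,
                        check_entry = refs$check),
             error = function(e) note(paste0("gain:", tr), e))
  }), cfg$traits)

  index_table <- tryCatch({
    wide <- ri_rf_means(ds, yield_trait)
    reference <- if (!is.null(refs$index_reference)) {
      refs$index_reference
    } else {
      hs <- ds[!is.na(ds$pop_class) & ds$pop_class == "halfsib", ,
               drop = FALSE]
      if (!nrow(hs)) stop("no index_reference given and no half-sib records")
      hs <- structure(hs, traits = trial_traits(ds), class = class(ds))
      hm <- entry_means(hs, yield_trait, c("entry", "treatment"))
      c(y_rf = mean(tapply(hm$mean[hm$treatment == "RF"],
                           hm$entry[hm$treatment == "RF"], mean)),
        y_ri = mean(tapply(hm$mean[hm$treatment == "RI"],
                           hm$entry[hm$treatment == "RI"], mean)))
    }
    compute_index_table(wide, reference, ties = cfg$ties)
  }, error = function(e) note("indices", e))

  fam_means <- function() {
    hs <- ds[!is.na(ds$family) & ds$pop_class %in% "halfsib", , drop = FALSE]
    if (!nrow(hs)) return(NULL)
    hs <- structure(hs, traits = trial_traits(ds), class = class(ds))
    em <- entry_means(hs, yield_trait, c("family", "entry"))
    split(em$mean, em$family)
  }
  pop_means <- function(class) {
    sub <- ds[!is.na(ds$pop_class) & ds$pop_class == class, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub <- structure(sub, traits = trial_traits(ds), class = class(ds))
    entry_means(sub, yield_trait, "entry")$mean
  }

  ttest_table <- tryCatch({
    fams <- fam_means()
    base <- pop_means("base")
    chk <- pop_means("check")
    if (is.null(fams) || length(fams) < 1L)
      stop("no half-sib families with family labels")
    rows <- list()
    for (f in names(fams)) {
      for (ref in c("base", "check")) {
        refv <- if (ref == "base") base else chk
        if (is.null(refv) || length(refv) < 2L) next
        tt <- mean_shift_ttest(fams[[f]], refv, var_equal = cfg$var_equal)
        rows[[length(rows) + 1L]] <-
          data.frame(family = f, reference = ref, n_family = length(fams[[f]]),
                     estimate = tt$estimate, t = tt$statistic, df = tt$df,
                     p_value = tt$p_value, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) stop("no reference population with >= 2 entries")
    do.call(rbind, rows)
  }, error = function(e) note("ttests", e))

  dunnett_table <- tryCatch({
    fams <- fam_means()
    base <- pop_means("base")
    if (is.null(fams) || is.null(base))
      stop("Dunnett tests need half-sib families and a base population")
    dunnett_many_to_one(fams, base, alpha = cfg$alpha, seed = cfg$seed)
  }, error = function(e) note("dunnett", e))

  correlations <- tryCatch({
    if (length(cfg$traits) < 2L)
      stop("trait correlations need >= 2 traits")
    tabs <- lapply(cfg$traits, function(tr) adjusted_means(ds, tr))
    entries <- Reduce(intersect, lapply(tabs, `[[`, "entry"))
    m <- data.frame(entry = entries, stringsAsFactors = FALSE)
    for (i in seq_along(cfg$traits))
      m[[cfg$traits[i]]] <-
        tabs[[i]]$adjusted_mean[match(entries, tabs[[i]]$entry)]
    trait_correlations(m, alpha = cfg$alpha)
  }, error = function(e) note("correlations", e))

  blups <- tryCatch({
    sub <- if (any(ds$pop_class %in% "halfsib"))
      structure(ds[ds$pop_class %in% "halfsib", , drop = FALSE],
                traits = trial_traits(ds), class = class(ds))
    else ds
    fit_blups(sub, trait = yield_trait)
  }, error = function(e) note("blups", e))

  cfg_for_hash <- unclass(cfg)
  cfg_for_hash$output_dir <- NULL
  bundle <- structure(list(
    data = ds,
    gain_tables = gain_tables,
    index_table = index_table,
    ttest_table = ttest_table,
    dunnett_table = dunnett_table,
    correlations = correlations,
    blups = blups,
    errors = errors,
    provenance = list(
      config_hash = config_hash(cfg_for_hash),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("rsmet")),
      defaults = list(K = cfg$K, alpha = cfg$alpha,
                      t_test = if (cfg$var_equal) "pooled" else "Welch",
                      ties = cfg$ties),
      notes = c(errors,
                if (!is.null(index_table))
                  list(gmp = paste("GMP is computed as sqrt(Yi_s * Yi_ns)",
                                   "from entry means"))))),
    class = "report_bundle")
  if (!is.null(cfg$output_dir)) write_report(bundle, cfg$output_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' One CSV per table (`gain_<trait>.csv`, `index_table.csv`, `ttests.csv`,
#' `dunnett.csv`, `correlations.csv`, `blups.csv`) plus `provenance.json`.
#' Deterministic: identical bundles produce byte-identical files.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in names(bundle$gain_tables)) {
    gt <- bundle$gain_tables[[tr]]
    if (!is.null(gt))
      write_table(gt, file.path(dir, paste0("gain_", tr, ".csv")))
  }
  if (!is.null(bundle$index_table))
    write_table(bundle$index_table, file.path(dir, "index_table.csv"))
  if (!is.null(bundle$ttest_table))
    write_table(bundle$ttest_table, file.path(dir, "ttests.csv"))
  if (!is.null(bundle$dunnett_table))
    write_table(bundle$dunnett_table, file.path(dir, "dunnett.csv"))
  if (!is.null(bundle$correlations)) {
    cm <- as.data.frame(bundle$correlations$r)
    cm <- cbind(trait = rownames(cm), cm)
    write_table(cm, file.path(dir, "correlations.csv"))
  }
  if (!is.null(bundle$blups))
    write_table(bundle$blups$blups, file.path(dir, "blups.csv"))
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (config", substr(x$provenance$config_hash, 1, 8),
      "seed", x$provenance$seed, ")\n")
  have <- c(gain_tables = sum(!vapply(x$gain_tables, is.null, TRUE)),
            index_table = !is.null(x$index_table),
            ttests = !is.null(x$ttest_table),
            dunnett = !is.null(x$dunnett_table),
            correlations = !is.null(x$correlations),
            blups = !is.null(x$blups))
  cat("tables:", paste(names(have)[have > 0], collapse = ", "), "\n")
  if (length(x$errors))
    cat("stages with errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
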