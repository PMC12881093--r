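parse_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                  "%Y-%m-%dT%H:%M",
                                                  "%Y-%m-%d %H:%M:%S",
                                                  "%Y-%m-%d %H:%M"),
                    optional = TRUE)
  out
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

report_bad_rows <- function(bad, what, path) {
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    stop("file ", path, ": ", what, " on line(s) ",
         paste(utils::head(lines, 10), collapse = ", "),
         if (sum(bad) > 10) sprintf(" (and %d more)", sum(bad) - 10) else "",
         call. = FALSE)
  }
}

#' Read CGM readings from CSV
#'
#' Expects the header `participant_id,timestamp,glucose,unit` with
#' ISO-8601 timestamps and unit `mg/dL` or `mmol/L` (case-insensitive).
#' Values are normalized to mmol/l; rows failing validation abort the read
#' with their line numbers.
#'
#' @param path CSV path.
#' @param nominal_interval Minutes between scheduled readings.
#' @param cc A [conversion_constants()] object.
#' @return A named list of [cgm_trace()] objects, one per participant.
#' @export
read_cgm_csv <- function(path, nominal_interval = 5, cc = conversion_constants()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, c("participant_id", "timestamp", "glucose", "unit"), path)
  ts <- parse_timestamp(df$timestamp)
  report_bad_rows(is.na(ts), "unparseable timestamp", path)
  val <- suppressWarnings(as.numeric(df$glucose))
  report_bad_rows(!is.finite(val) | val <= 0, "invalid glucose value", path)
  key <- gsub("[^a-z]", "", tolower(df$unit))
  known <- key %in% c("mgdl", "mmoll", "mmol")
  report_bad_rows(!known, "unknown unit", path)
  mmol <- glucose_to_mmol(val, df$unit, cc)
  out <- lapply(split(seq_len(nrow(df)), df$participant_id), function(idx) {
    cgm_trace(df$participant_id[idx[1]], ts[idx], mmol[idx], nominal_interval,
              quiet = TRUE)
  })
  out[unique(df$participant_id)]
}

#' Read visit records from CSV
#'
#' Expects the header `participant_id,visit_date,hba1c_mmol_mol`.
#'
#' @param path CSV path.
#' @return A data.frame `participant_id`, `date` (`Date`), `hba1c` (IFCC).
#' @export
read_visits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, c("participant_id", "visit_date", "hba1c_mmol_mol"), path)
  d <- as.Date(df$visit_date, optional = TRUE)
  report_bad_rows(is.na(d), "unparseable visit date", path)
  h <- suppressWarnings(as.numeric(df$hba1c_mmol_mol))
  report_bad_rows(!is.finite(h) | h <= 0 | h >= 250, "invalid HbA1c", path)
  data.frame(participant_id = df$participant_id, date = d, hba1c = h,
             stringsAsFactors = FALSE)
}

#' Read a cohort manifest (JSON)
#'
#' Schema: `{"participants": [{"id": ..., "group": "case"|"control",
#' "diagnosis_date": ...}, ...]}`; `diagnosis_date` is required for cases.
#'
#' @param path JSON path.
#' @return A data.frame `id`, `group`, `diagnosis_date` (`Date`).
#' @export
read_manifest <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (is.null(j$participants)) {
    stop("manifest ", path, " lacks a 'participants' array", call. = FALSE)
  }
  p <- j$participants
  require_columns(p, c("id", "group"), path)
  if (!all(p$group %in% c("case", "control"))) {
    stop("manifest ", path, ": group must be 'case' or 'control'", call. = FALSE)
  }
  dd <- if ("diagnosis_date" %in% names(p)) as.Date(p$diagnosis_date) else
    as.Date(rep(NA, nrow(p)))
  if (any(p$group == "case" & is.na(dd))) {
    stop("manifest ", path, ": cases must carry a diagnosis_date", call. = FALSE)
  }
  data.frame(id = p$id, group = p$group, diagnosis_date = dd,
             stringsAsFactors = FALSE)
}

#' Assemble participant records from the three input tables
#'
#' @param traces Named list of [cgm_trace()] (from [read_cgm_csv()]).
#' @param visits Visit data.frame (from [read_visits_csv()]).
#' @param manifest Manifest data.frame (from [read_manifest()]).
#' @return A list of [participant_record()] objects, one per manifest row
#'   that has both a trace and at least one visit.
#' @export
assemble_records <- function(traces, visits, manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    if (is.null(traces[[id]])) {
      stop("no CGM trace for participant ", id, call. = FALSE)
    }
    v <- visits[visits$participant_id == id, c("date", "hba1c"), drop = FALSE]
    if (nrow(v) == 0L) stop("no visits for participant ", id, call. = FALSE)
    participant_record(id, manifest$group[i], v, traces[[id]],
                       manifest$diagnosis_date[i])
  })
}

#' Write a simulated cohort in the canonical input formats
#'
#' Emits `cgm.csv`, `visits.csv`, `manifest.json` (the formats the readers
#' accept) plus `truth.json` holding the hidden simulation parameters.
#'
#' @param cohort A `cohort_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cgm <- do.call(rbind, lapply(cohort$records, function(r) {
    data.frame(participant_id = r$id,
               timestamp = format(r$trace$time, "%Y-%m-%dT%H:%M", tz = "UTC"),
               glucose = r$trace$glucose, unit = "mmol/L",
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(cgm, file.path(dir, "cgm.csv"), row.names = FALSE, quote = FALSE)
  visits <- do.call(rbind, lapply(cohort$records, function(r) {
    data.frame(participant_id = r$id, visit_date = format(r$visits$date),
               hba1c_mmol_mol = r$visits$hba1c, stringsAsFactors = FALSE)
  }))
  utils::write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- list(participants = lapply(cohort$records, function(r) {
    out <- list(id = r$id, group = r$group)
    if (r$group == "case") out$diagnosis_date <- format(r$diagnosis_date)
    out
  }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(list(seed = cohort$seed, truth = cohort$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste(path, k, sep = "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Resolved configuration for an end-to-end run
#'
#' Builds the full nested parameter block (simulation, aggregation,
#' analysis) with defaults, overridden by the entries of `...` or a list.
#' Unknown keys are rejected so typos cannot silently fall back to a
#' default.
#'
#' @param ... Named overrides, or a single named list of them.  Nested
#'   blocks (`simulate`, `cv`) are merged key-wise.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  defaults <- list(
    seed = 1,
    simulate = unclass(simulation_config()),
    input = list(cgm_csv = NULL, visits_csv = NULL, manifest_json = NULL),
    nominal_interval = 5,
    window_days = 90, min_wear_pct = 70, min_days = 14,
    aggregate_mode = "pooled",
    k_bins = 5, threshold_ifcc = 53,
    quintile_test = "fisher",
    run_rfe = TRUE, run_models = TRUE,
    cv = list(k_folds = 5, repeats = 4, n_perm = 10000,
              rf_ntree = 300, rf_nodesize_grid = c(1, 5, 10)),
    schema_version = 1
  )
  cfg <- merge_config(defaults, user)
  cfg$simulate <- do.call(simulation_config, cfg$simulate)
  structure(cfg, class = "run_config")
}

config_fingerprint <- function(config) {
  plain <- rapply(strip_classes(config), function(x)
    if (inherits(x, "Date")) format(x) else x, how = "replace")
  as.character(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Run the full pipeline: simulate (or ingest), aggregate, analyze
#'
#' With no input paths configured, simulates a cohort from
#' `config$simulate` under `config$seed`; otherwise ingests the three
#' canonical files.  Applies the sufficiency filter and pre-diagnosis
#' censoring via [build_feature_table()], then runs the association
#' pipeline: MIS ranking, mRMR, per-feature AUC, cumulative-rate curves
#' and quintile risk tables for uGMI and HbA1c, the three fixed-threshold
#' trees, and (optionally) RFE and the model comparison.  A fixed seed
#' reproduces the whole bundle.
#'
#' @param config A [run_config()].
#' @param dir Optional output directory; when given, the bundle is written
#'   as CSV/JSON files (`features.csv`, `mis.csv`, `mrmr.csv`, `auc.csv`,
#'   `cumrate.csv`, `quintiles.csv`, `trees.json`, `rfe.csv`,
#'   `models.json`, `config.json`), each JSON embedding the resolved
#'   config and seed.
#' @return A list bundle with elements `features`, `mis`, `mrmr`, `auc`,
#'   `cumrate`, `quintiles`, `trees`, `rfe`, `models`, `config`,
#'   `excluded`.
#' @export
run_end_to_end <- function(config = run_config(), dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input$cgm_csv)) {
    traces <- read_cgm_csv(config$input$cgm_csv,
                           nominal_interval = config$nominal_interval)
    visits <- read_visits_csv(config$input$visits_csv)
    manifest <- read_manifest(config$input$manifest_json)
    records <- assemble_records(traces, visits, manifest)
  } else {
    cohort <- simulate_cohort(config$simulate, config$seed)
    records <- cohort$records
  }
  ft <- build_feature_table(records, window_days = config$window_days,
                            min_wear_pct = config$min_wear_pct,
                            min_days = config$min_days,
                            mode = config$aggregate_mode)
  bundle <- list(features = ft,
                 mis = mis_ranking(ft, k_bins = config$k_bins),
                 mrmr = mrmr_rank(ft, k_bins = config$k_bins),
                 auc = auc_ranking(ft),
                 excluded = attr(ft, "excluded"))
  bundle$cumrate <- do.call(rbind, lapply(c("ugmi", "hba1c"), function(f) {
    cbind(feature = f, cumulative_rate_curves(ft[[f]], ft$outcome))
  }))
  bundle$quintiles <- lapply(
    stats::setNames(nm = c("ugmi", "hba1c")),
    function(f) quintile_risk_table(ft[[f]], ft$outcome, k = config$k_bins,
                                    test = config$quintile_test))
  thr <- config$threshold_ifcc
  bundle$trees <- list(
    ugmi = threshold_tree(ft, "ugmi", thr),
    hba1c = threshold_tree(ft, "hba1c", thr),
    two_layer = threshold_tree(ft, c("ugmi", "hba1c"), c(thr, thr)))
  if (isTRUE(config$run_rfe)) {
    bundle$rfe <- rfe_rank(ft, k_folds = config$cv$k_folds,
                           ntree = config$cv$rf_ntree, seed = config$seed)
  }
  if (isTRUE(config$run_models)) {
    bundle$models <- model_comparison(
      ft, k_folds = config$cv$k_folds, repeats = config$cv$repeats,
      n_perm = config$cv$n_perm, seed = config$seed,
      rf_ntree = config$cv$rf_ntree,
      rf_nodesize_grid = config$cv$rf_nodesize_grid)
  }
  bundle$config <- config
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE, quote = FALSE)
  w(bundle$features, "features.csv")
  w(bundle$mis, "mis.csv")
  w(bundle$mrmr, "mrmr.csv")
  w(bundle$auc, "auc.csv")
  w(bundle$cumrate, "cumrate.csv")
  qt <- do.call(rbind, lapply(names(bundle$quintiles), function(f) {
    cbind(feature = f, bundle$quintiles[[f]]$table)
  }))
  w(qt, "quintiles.csv")
  if (!is.null(bundle$rfe)) w(bundle$rfe$curve, "rfe.csv")
  fingerprint <- config_fingerprint(bundle$config)
  jsonlite::write_json(
    list(seed = bundle$config$seed, config = jsonlite::fromJSON(fingerprint),
         trees = strip_classes(bundle$trees)),
    file.path(dir, "trees.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$models)) {
    jsonlite::write_json(
      list(seed = bundle$config$seed, settings = bundle$models$settings,
           summary = bundle$models$summary, pairwise = bundle$models$pairwise),
      file.path(dir, "models.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  writeLines(fingerprint, file.path(dir, "config.json"))
  invisible(dir)
}
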