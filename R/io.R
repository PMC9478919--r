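# Cohort table I/O with schema validation, YAML run configuration, and the
# umbrella pipeline runner (simulate -> screen -> build score -> evaluate).

.REQUIRED_COLS <- c("patient_id", "arm", "os_time", "os_event")

#' Write a cohort to a tab-delimited file
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a cohort table
#'
#' Reads a delimited (tab or comma) table with a header, validates it against
#' the cohort schema, and returns the valid rows together with a
#' machine-readable record of every rejected row and the reason. Rejection
#' reasons: negative or missing survival times, non-binary event flags,
#' unknown arm labels, non-positive cell counts. PFS columns may be absent
#' when `require_pfs = FALSE`; they are then filled with NA and flagged.
#'
#' @param path Input file.
#' @param require_pfs Require pfs_time/pfs_event columns (default TRUE).
#' @param sep Field separator (default tab; `","` for CSV).
#' @return A `"bct_cohort"` data frame; attributes `rejected` (data frame of
#'   row/reason) and `pfs_present`.
#' @export
read_cohort <- function(path, require_pfs = TRUE, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA")
  miss <- setdiff(.REQUIRED_COLS, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  pfs_present <- all(c("pfs_time", "pfs_event") %in% names(df))
  if (!pfs_present) {
    if (require_pfs) stop("missing required columns: pfs_time, pfs_event")
    df$pfs_time <- NA_real_
    df$pfs_event <- NA_integer_
  }
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond & reasons == ""] <<- why
  }
  bad(!is.finite(df$os_time) | df$os_time < 0, "invalid os_time")
  bad(!df$os_event %in% c(0, 1), "non-binary os_event")
  if (pfs_present) {
    bad(is.na(df$pfs_time) | df$pfs_time < 0, "invalid pfs_time")
    bad(!df$pfs_event %in% c(0, 1), "non-binary pfs_event")
  }
  bad(!df$arm %in% c("treated", "control"), "unknown arm label")
  for (col in grep("^count_", names(df), value = TRUE))
    bad(!is.na(df[[col]]) & df[[col]] <= 0, paste("non-positive", col))
  rejected <- data.frame(row = which(reasons != ""),
                         patient_id = df$patient_id[reasons != ""],
                         reason = reasons[reasons != ""],
                         stringsAsFactors = FALSE)
  out <- df[reasons == "", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bct_cohort", "data.frame")
  attr(out, "rejected") <- rejected
  attr(out, "pfs_present") <- pfs_present
  out
}

#' Read a YAML run configuration
#'
#' Keys mirror [sim_config()] and the screening/scoring parameters
#' (`significance`, `fractions`, `share`, `horizon`, `combination_rule`,
#' `landmark`, `min_events`, and a `simulate:` block passed to `sim_config`).
#'
#' @param path YAML file.
#' @return Named list with validated defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(significance = 0.05,
                   fractions = sort(unique(c(seq(0.1, 0.9, 0.1), 0.25, 0.75))),
                   share = 0.8, horizon = 12, combination_rule = "any_high",
                   landmark = TRUE, min_events = 10L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stopifnot(cfg$significance > 0, cfg$significance < 1)
  if (any(cfg$fractions <= 0 | cfg$fractions >= 1))
    stop("fractions must lie in (0,1)")
  cfg
}

#' Run the full discovery pipeline
#'
#' Orchestrates simulate (optional) -> screen -> score building/selection ->
#' evaluation. Every artifact is returned; when `out_dir` is given they are
#' also written (scan table as TSV, model and report as JSON, audit trail as
#' JSON). Identical configs and seeds produce identical artifacts.
#'
#' @param config List as from [read_run_config()]; may carry a `simulate`
#'   block (arguments to [sim_config()]) when no input cohort is given.
#' @param train Training cohort data frame (simulated when NULL).
#' @param validation Optional named list of validation cohorts.
#' @param out_dir Optional output directory.
#' @return List: `model` (the `"bctscore"` fit), `report`, `scans`, `audit`.
#' @export
run_pipeline <- function(config = list(), train = NULL, validation = NULL,
                         out_dir = NULL) {
  cfg <- config
  defaults <- list(significance = 0.05,
                   fractions = sort(unique(c(seq(0.1, 0.9, 0.1), 0.25, 0.75))),
                   share = 0.8, horizon = 12, combination_rule = "any_high",
                   landmark = TRUE, min_events = 10L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (any(cfg$fractions <= 0 | cfg$fractions >= 1))
    stop("fractions must lie in (0,1)")
  if (is.null(train)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args)) stop("no training cohort and no simulate block")
    train <- simulate_cohort(do.call(sim_config, sim_args))
  }
  if (is.null(cfg$biomarkers)) cfg$biomarkers <- screen_biomarkers()
  model <- bctscore(train, validation = validation,
                    biomarkers = cfg$biomarkers,
                    fractions = cfg$fractions, share = cfg$share,
                    alpha = cfg$significance, horizon = cfg$horizon,
                    combination_rule = cfg$combination_rule,
                    landmark = cfg$landmark, min_events = cfg$min_events)
  report <- if (!is.null(model$selected)) {
    cohorts <- c(list(training = train), validation)
    assemble_report(model, cohorts, horizon = cfg$horizon,
                    landmark = cfg$landmark)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(model$scans, file.path(out_dir, "scans.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_report_json(model$screen$audit, file.path(out_dir, "audit.json"))
    if (!is.null(model$selected))
      write_report_json(list(candidate_id = model$selected$candidate_id,
                             rules = model$selected$rules,
                             combination_rule = model$selected$combination_rule),
                        file.path(out_dir, "model.json"))
    if (!is.null(report))
      write_report_json(report, file.path(out_dir, "report.json"))
  }
  list(model = model, report = report, scans = model$scans,
       audit = model$screen$audit)
}
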