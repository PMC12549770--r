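# File formats: trial CSV, parameter CSV/JSON, configuration, manifests.
# CSV dialect: UTF-8, comma delimiter, '.' decimal, mandatory header,
# empty field = missing. Actions and trial indices are 0-based.

trial_columns <- function() {
  c("subject_id", "block", "trial_in_block", "set_size", "stimulus_id",
    "correct_action", "action", "reward", "rt", "iteration", "delay",
    "reward_history")
}

#' Write a trial table to CSV
#'
#' @param trials Trial data frame (task factors are computed if absent).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_trials <- function(trials, path) {
  if (!all(c("iteration", "delay", "reward_history") %in% names(trials)))
    trials <- compute_task_factors(trials)
  trials <- trials[, trial_columns()]
  write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial CSV
#'
#' Checks the schema, value ranges and the deterministic-feedback
#' invariant (`reward == 1` exactly when `action == correct_action`);
#' violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return Validated trial data frame (empty file with header: zero
#'   rows, no error).
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character",
                                stimulus_id = "character"))
  missing_cols <- setdiff(trial_columns(), names(tr))
  if (length(missing_cols))
    stop("read_trials: missing columns: ",
         paste(missing_cols, collapse = ", "))
  tr <- tr[, trial_columns()]
  if (nrow(tr) == 0) return(tr)
  chk <- function(bad, what) {
    if (any(bad, na.rm = TRUE))
      stop("read_trials: ", what, " at row(s) ",
           paste(head(which(bad)), collapse = ", "))
  }
  chk(!tr$set_size %in% 2:5, "set_size outside 2..5")
  chk(!is.na(tr$action) & !tr$action %in% 0:2, "action outside 0..2")
  chk(!tr$correct_action %in% 0:2, "correct_action outside 0..2")
  responded <- !is.na(tr$action)
  chk(responded & is.na(tr$reward), "responded trial without reward")
  chk(responded &
        (tr$reward != as.integer(tr$action == tr$correct_action)),
      "reward inconsistent with deterministic feedback")
  chk(responded & (is.na(tr$rt) | tr$rt <= 0), "responded trial without RT")
  tr
}

#' Write subject parameters to a flat CSV
#'
#' @param params Data frame with `subject_id` and the 8 parameter
#'   columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_params <- function(params, path) {
  write.csv(params[, c("subject_id", rlwm_param_names())], path,
            row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read subject parameters from CSV
#' @param path CSV path.
#' @return Data frame with `subject_id` and parameter columns.
#' @export
read_params <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(subject_id = "character"))
  miss <- setdiff(c("subject_id", rlwm_param_names()), names(p))
  if (length(miss))
    stop("read_params: missing columns: ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(p)))
    validate_params(unlist(p[i, rlwm_param_names()]))
  p
}

#' Default configuration tree
#'
#' All tunable settings with their defaults, plus the fixed model
#' constants (`beta`, `tau`, `s`), which are read-only: overriding them
#' requires the explicit `allow_fixed_override` flag in the config.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    fixed = list(beta = 50, tau = 0.15, s = 1),
    task = list(chisq_level = 0.01, max_iter = 10000L),
    model = list(h_floor = 0.01, rt_max = 7),
    fit = list(restarts = 4L, maxit = 2000L, reltol = 1e-8, jitter = 0.25),
    cohort = covariate_config(),
    sampler = list(chains = 4L, iter = 5000L, warmup = 1000L),
    prediction = list(n_repeats = 100L, test_frac = 0.2, k_folds = 10L,
                      n_bins = 5L),
    allow_fixed_override = FALSE
  )
}

#' Load and validate a JSON configuration file
#'
#' Unknown keys are rejected (with their paths); missing keys are filled
#' from [default_config()]. The fixed constants `beta`, `tau` and `s`
#' may only be changed when `allow_fixed_override` is set to `TRUE` in
#' the same file.
#'
#' @param path JSON file path (`NULL` returns the defaults).
#' @return Validated configuration tree.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys <- function(u, d, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("load_config: unknown key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (k in names(u))
      if (is.list(d[[k]]) && is.list(u[[k]]))
        check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
  }
  check_keys(user, defaults)
  if (!is.null(user$fixed) && !isTRUE(user$allow_fixed_override)) {
    for (k in names(user$fixed))
      if (!identical(as.numeric(user$fixed[[k]]),
                     as.numeric(defaults$fixed[[k]])))
        stop("load_config: '", "fixed.", k, "' is a fixed model constant; ",
             "set allow_fixed_override = true to change it")
  }
  modifyList(defaults, user)
}

#' Write a run manifest
#'
#' Records the command, configuration echo, seeds, package version,
#' timestamp and md5 checksums of input/output files, so a run can be
#' audited and reproduced.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param seed Seed(s) used.
#' @param config Configuration echo.
#' @param files Character vector of input/output paths to checksum.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, command, seed, config = list(),
                           files = character(0)) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    seed = seed,
    config = config,
    package_version = as.character(packageVersion("rlwmlba")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(setNames(unname(tools::md5sum(files)), files))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
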