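TRIAL_COLUMNS <- c("participant_id", "condition", "block_order", "trial",
                   "choice", "reward", "rt_ms", "good_lake", "cue_target",
                   "cue_after_trial", "paranoia")

#' Write a trials table to CSV
#'
#' Numbers are serialized with 9 significant digits so that round-tripped
#' likelihoods agree to within text precision; missing values are written as
#' empty fields.
#'
#' @param trials Trials data frame.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 9)
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trials table from CSV
#'
#' @param path CSV path with the flat trial schema (see [generate_cohort()]).
#' @return A data frame.
#' @export
read_trials <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  d$participant_id <- as.character(d$participant_id)
  d
}

#' Validate a trials table against the task schema
#'
#' Checks the column set, value domains (`choice` in \{0, 1\}, `trial`
#' within the block length, known condition labels), the design constraint
#' that social information always indicates the good lake
#' (`cue_target == good_lake` in social blocks; control blocks carry none),
#' and duplicate (participant, condition, trial) keys.
#'
#' @param trials A trials data frame or a CSV path.
#' @param config A [task_config()].
#' @return An object of class `"trials_validation"`: list with `ok` and a
#'   character vector `problems`.
#' @export
validate_trials <- function(trials, config = task_config()) {
  if (is.character(trials)) trials <- read_trials(trials)
  problems <- character(0)
  need <- setdiff(c("participant_id", "condition", "trial", "choice",
                    "reward", "good_lake"), names(trials))
  if (length(need)) {
    problems <- c(problems, paste("missing column(s):",
                                  paste(need, collapse = ", ")))
    return(structure(list(ok = FALSE, problems = problems),
                     class = "trials_validation"))
  }
  if (!all(trials$condition %in% CONDITIONS)) {
    problems <- c(problems, "unknown condition label(s)")
  }
  if (!all(trials$choice %in% c(0, 1))) {
    problems <- c(problems, "choice outside {0, 1}")
  }
  if (!all(trials$trial >= 1 & trials$trial <= config$n_trials)) {
    problems <- c(problems,
                  sprintf("trial index outside [1, %d]", config$n_trials))
  }
  if (!all(trials$good_lake %in% c(0, 1))) {
    problems <- c(problems, "good_lake outside {0, 1}")
  }
  social <- trials$condition != "control"
  if ("cue_target" %in% names(trials)) {
    bad <- social & (is.na(trials$cue_target) |
                       trials$cue_target != trials$good_lake)
    if (any(bad)) {
      problems <- c(problems, paste(
        "social block where cue_target != good_lake: social information",
        "must always recommend the good (higher expected reward) lake"))
    }
    if (any(!social & !is.na(trials$cue_target))) {
      problems <- c(problems, "control block carrying a cue_target")
    }
  }
  key <- paste(trials$participant_id, trials$condition, trials$trial)
  if (anyDuplicated(key)) {
    problems <- c(problems, "duplicate (participant, condition, trial) key")
  }
  structure(list(ok = length(problems) == 0L, problems = problems,
                 n_rows = nrow(trials),
                 n_participants = length(unique(trials$participant_id))),
            class = "trials_validation")
}

#' @export
print.trials_validation <- function(x, ...) {
  if (x$ok) {
    cat("trials table OK:", x$n_rows, "rows,", x$n_participants,
        "participants\n")
  } else {
    cat("trials table INVALID:\n")
    for (p in x$problems) cat(" -", p, "\n")
  }
  invisible(x)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generate, validate, filter, measure, fit, and summarise in one seeded
#' call, writing every artifact (trials, ground truth, per-block measures,
#' bootstrap summaries, per-participant fits, recovery shares) plus a run
#' manifest recording the seed, sizes and output hashes to `out_dir`.
#' Rerunning with the same arguments reproduces the primary outputs
#' byte-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param settings A [fit_control()].
#' @param n_boot Bootstrap replicates for the cohort summary.
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory artifacts (`trials`,
#'   `truth`, `measures`, `summary`, `fit`, `shares`, `manifest`).
#' @export
run_pipeline <- function(out_dir, spec = cohort_spec(n_participants = 30),
                         config = task_config(),
                         settings = fit_control(), n_boot = 500,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)

  say("generate: ", spec$n_participants, " participants")
  gen <- generate_cohort(spec, config)

  say("validate")
  val <- validate_trials(gen$trials, config)
  if (!val$ok) {
    stop("pipeline failed at stage 'validate': ",
         paste(val$problems, collapse = "; "))
  }

  say("measures")
  meas <- cohort_measures(gen$trials, config)
  say("summary (", n_boot, " bootstrap replicates)")
  summ <- summarize_cohort(meas, n_boot = n_boot, seed = spec$seed)

  say("fit: ", spec$n_participants, " participants x ",
      settings$n_starts + 1, " starts")
  fit <- social_qlearn(gen$trials, config, settings)
  shares <- high_shares(fit)

  paths <- list(trials = "trials.csv", truth = "truth.csv",
                measures = "measures.csv", summary = "summary.csv",
                fits = "fits.csv")
  paths <- lapply(paths, function(p) file.path(out_dir, p))
  write_trials(gen$trials, paths$trials)
  write_trials(gen$truth, paths$truth)
  write_trials(meas, paths$measures)
  write_trials(summ$means, paths$summary)
  write_trials(fit$fits, paths$fits)

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(list(spec = unclass(spec), config = unclass(config)),
                       cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("socialbandit")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = spec$seed, n_participants = spec$n_participants,
    n_starts = settings$n_starts, n_boot = n_boot,
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    shares = as.list(shares$shares))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", out_dir)
  invisible(list(trials = gen$trials, truth = gen$truth, measures = meas,
                 summary = summ, fit = fit, shares = shares,
                 manifest = manifest))
}

#' Read and write task/agent configurations as YAML or JSON
#'
#' Configurations serialize with their field names unchanged, so files can
#' be edited by hand and shared across tools. The format follows the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param x A [task_config()] or [agent_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_config()` returns `path` invisibly; the readers return
#'   the reconstructed, revalidated object.
#' @export
write_config <- function(x, path) {
  lst <- if (inherits(x, "agent_params")) as.list(unclass(x))
         else unclass(x)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else stop("write_config: unknown extension for ", path)
  invisible(path)
}

read_config_list <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else stop("read_config: unknown extension for ", path)
}

#' @rdname write_config
#' @export
read_task_config <- function(path) {
  do.call(task_config, read_config_list(path))
}

#' @rdname write_config
#' @export
read_agent_params <- function(path) {
  do.call(agent_params, read_config_list(path))
}
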