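#' Write spike data to the delimited spike-table format
#'
#' One row per spike, comma-delimited with a mandatory header:
#' `unit_id` (string), `trial_id` (integer), `condition` (string, may be
#' empty for the onset paradigm), `t_event` (alignment event time within the
#' session, seconds), `spike_time` (seconds, relative to the session clock,
#' i.e. `t_event` plus the aligned time). All times are seconds.
#'
#' @param recs A list of [unit_recording()] objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(recs, path) {
  if (inherits(recs, "unit_recording")) recs <- list(recs)
  rows <- lapply(recs, function(rec) {
    ev <- rec$t_events
    if (is.null(ev)) ev <- rep(0, rec$n_trials)
    do.call(rbind, lapply(seq_len(rec$n_trials), function(j) {
      x <- rec$trials[[j]]
      if (length(x) == 0) return(NULL)
      data.frame(unit_id = rec$unit_id, trial_id = j,
                 condition = ifelse(is.na(rec$condition), "", rec$condition),
                 t_event = ev[j], spike_time = ev[j] + x,
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike table into unit recordings
#'
#' Parses the delimited format of [write_spike_table()], re-expresses spike
#' times relative to each trial's alignment event, sorts them, and groups
#' rows into one [unit_recording()] per (unit, condition).
#'
#' @param path Input file path.
#' @return A named list of [unit_recording()] objects (names
#'   `unit_id` or `unit_id/condition`).
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) stop("spike table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(unit_id = "character"))
  needed <- c("unit_id", "trial_id", "condition", "t_event", "spike_time")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("spike table lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("trial_id", "t_event", "spike_time")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v) & !is.na(tab[[col]])))
      stop(sprintf("non-numeric %s at line %d", col,
                   which(is.na(v) & !is.na(tab[[col]]))[1] + 1L))
    if (any(is.na(v)))
      stop(sprintf("missing %s at line %d", col, which(is.na(v))[1] + 1L))
    tab[[col]] <- v
  }
  tab$condition[is.na(tab$condition)] <- ""
  key <- ifelse(tab$condition == "", tab$unit_id,
                paste(tab$unit_id, tab$condition, sep = "/"))
  out <- lapply(split(tab, key), function(d) {
    ev <- tapply(d$t_event, d$trial_id, function(x) {
      if (length(unique(x)) > 1) stop("inconsistent t_event within a trial")
      x[1]
    })
    trials <- lapply(split(d$spike_time - d$t_event, d$trial_id), sort)
    rec <- unit_recording(d$unit_id[1], unname(trials),
                          condition = if (d$condition[1] == "") NA_character_
                          else d$condition[1])
    rec$t_events <- unname(as.numeric(ev))
    rec
  })
  out
}

#' Read a run configuration file
#'
#' Loads a YAML configuration holding any of the component configurations
#' (`fit`, `analysis`, `population`, `change_paradigm`, `circuit`, `tuning`,
#' `attention`), a `seed`, and an `outdir`, validating each against its
#' constructor so errors name the offending key.
#'
#' @param path YAML file path.
#' @return A list with validated component objects (absent sections are
#'   NULL).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  build <- function(section, ctor) {
    if (is.null(raw[[section]])) return(NULL)
    tryCatch(do.call(ctor, raw[[section]]),
             error = function(e) stop(sprintf("config section '%s': %s",
                                              section, conditionMessage(e))))
  }
  list(fit = build("fit", fit_config),
       analysis = build("analysis", analysis_config),
       population = build("population", population_spec),
       circuit = build("circuit", circuit_params),
       tuning = build("tuning", speed_tuning),
       attention = build("attention", attention_gains),
       change_paradigm = if (!is.null(raw$change_paradigm)) {
         cp <- raw$change_paradigm
         if (is.null(cp$tuning)) stop("config section 'change_paradigm': tuning missing")
         cp$tuning <- do.call(speed_tuning, cp$tuning)
         tryCatch(do.call(change_paradigm_spec, cp),
                  error = function(e) stop(sprintf("config section 'change_paradigm': %s",
                                                   conditionMessage(e))))
       },
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       outdir = if (is.null(raw$outdir)) "." else raw$outdir,
       verbose = isTRUE(raw$verbose))
}

#' Export attention-modulation surfaces as delimited matrices
#'
#' Writes each surface of [attention_surfaces()] as a CSV matrix whose header
#' row and first column give the activation grid.
#'
#' @param surf An [attention_surfaces()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_surfaces <- function(surf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("dF_rise", "dF_sus", "dF_peak")) {
    m <- surf[[nm]]
    if (is.null(m)) next
    d <- as.data.frame(m)
    names(d) <- sprintf("a_post_%g", surf$a)
    d <- cbind(a_pre = surf$a, d)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
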