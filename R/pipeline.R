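#' Batch-process a directory of recordings
#'
#' Discovers every subject in `input_dir` (one `<subject>_states.txt`
#' each), runs [read_recording()] and [analyze_recording()] on each, and
#' writes five tidy tables to `output_dir`: `per_breath.csv`,
#' `indices.csv` (per-state NRD/NME/TTI/drive-rate medians),
#' `spectra.csv`, `entropy.csv` and `occlusion.csv`, plus a long-format
#' `summary_long.csv` of the per-state indices and a `manifest.json`
#' recording the configuration, package version, processed subjects and
#' any failures. Processing continues past per-recording failures, which
#' are logged and tabulated in the manifest.
#'
#' All outputs are deterministically ordered, so identical inputs and
#' configuration yield byte-identical tables.
#'
#' @param input_dir Directory with recordings in the [write_recording()]
#'   layout.
#' @param output_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @param subjects Optional subject ids; default all discovered.
#' @param verbose Log one line per recording per stage.
#' @return Invisibly, a list with `tables`, `subjects`, `failures` and
#'   `n_warnings`.
#' @export
run_batch <- function(input_dir, output_dir, config = analysis_config(),
                      subjects = NULL, verbose = TRUE) {
  if (!dir.exists(input_dir)) stop("no such input directory: ", input_dir)
  if (is.null(subjects)) {
    subjects <- sort(sub("_states\\.txt$", "",
                         list.files(input_dir, pattern = "_states\\.txt$")))
  }
  if (length(subjects) == 0) stop("no recordings found in ", input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  tabs <- list(per_breath = list(), indices = list(), spectra = list(),
               entropy = list(), occlusion = list())
  failures <- list(); n_warn <- 0L
  for (s in subjects) {
    res <- tryCatch(
      withCallingHandlers({
        rec <- read_recording(input_dir, subject = s)
        analyze_recording(rec, config)
      }, warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s]] <- conditionMessage(res)
      if (verbose) message("FAIL ", s, ": ", conditionMessage(res))
      next
    }
    for (nm in names(tabs)) tabs[[nm]][[s]] <- res[[nm]]
    if (verbose)
      message(sprintf("ok   %s: %d breaths, %d spectra, failure effort %d",
                      s, nrow(res$per_breath), nrow(res$spectra),
                      res$effort_series$failure_index))
  }
  if (length(failures) == length(subjects))
    stop("all recordings failed: ",
         paste(names(failures), unlist(failures), collapse = "; "))

  tables <- lapply(tabs, function(x) {
    df <- do.call(rbind, unname(x))
    rownames(df) <- NULL
    df
  })
  ord <- function(df, cols) df[do.call(order, df[intersect(cols, names(df))]), ,
                               drop = FALSE]
  tables$per_breath <- ord(tables$per_breath,
                           c("subject", "muscle", "state", "breath"))
  tables$indices <- ord(tables$indices, c("subject", "muscle", "state"))
  tables$spectra <- ord(tables$spectra, c("subject", "muscle", "state"))
  tables$entropy <- ord(tables$entropy, c("subject", "muscle", "state"))
  tables$occlusion <- ord(tables$occlusion, c("subject", "effort"))

  for (nm in names(tables)) {
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) { v[is.nan(v)] <- NA; v })
    data.table::fwrite(df, file.path(output_dir, paste0(nm, ".csv")),
                       na = "NA", showProgress = FALSE)
  }

  long <- to_long_indices(tables$indices)
  write_summary_table(long, file.path(output_dir, "summary_long.csv"))

  manifest <- list(
    package = "respmech",
    version = as.character(utils::packageVersion("respmech")),
    config = unclass_deep(config),
    subjects = as.list(setdiff(subjects, names(failures))),
    failures = failures,
    n_warnings = n_warn)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tables = tables, subjects = setdiff(subjects, names(failures)),
                 failures = failures, n_warnings = n_warn))
}

# melt the per-state index table to (subject, ..., metric, value) rows
to_long_indices <- function(ind) {
  metrics <- c("nrd", "nme", "tti", "idr", "emg_rise", "ti", "ttot",
               "duty_cycle", "n_breaths")
  rows <- lapply(metrics, function(mname)
    data.frame(subject = ind$subject, genotype = ind$genotype,
               age_months = ind$age_months, muscle = ind$muscle,
               state = ind$state, metric = mname,
               value = as.numeric(ind[[mname]]), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
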