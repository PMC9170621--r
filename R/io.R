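#' Write or read a session trial log as CSV
#'
#' The CSV carries one row per trial with the presented per-axis
#' saturations (empty when the axis was inactive) and the tapped item, plus
#' versioned comment headers recording the seed and completion state so
#' that future changes to the staircase semantics remain detectable.
#'
#' @param session a `"cvd_session"`.
#' @param path file path.
#' @return `write_session_csv` invisibly returns `path`;
#'   `read_session_csv` returns a `"cvd_session"` carrying the replayed
#'   trial log (sufficient for [pool_observations()] and fitting; the live
#'   staircase state is not restored).
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "cvd_session"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# cvdstair session format v1",
    sprintf("# seed=%s complete=%s",
            if (is.null(session$seed)) "NA" else format(session$seed),
            session$complete)
  ), con)
  tr <- session_trials(session)
  # full-precision saturations so a written log replays bit-identically
  for (col in c("sat_protan", "sat_deutan", "sat_tritan")) {
    tr[[col]] <- ifelse(is.na(tr[[col]]), "", sprintf("%.17g", tr[[col]]))
  }
  utils::write.csv(tr, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  header <- readLines(path, n = 2L)
  if (!startsWith(header[1], "# cvdstair session format v1")) {
    stop("format-error: ", path, " is not a v1 session CSV (bad header line 1)")
  }
  meta <- regmatches(header[2],
                     regexec("^# seed=(\\S+) complete=(\\S+)$", header[2]))[[1]]
  if (length(meta) != 3L) {
    stop("format-error: ", path, " has a malformed metadata header (line 2)")
  }
  tr <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("trial_index", "set_index", "sat_protan", "sat_deutan",
            "sat_tritan", "tapped")
  if (!all(need %in% names(tr))) {
    stop("format-error: session CSV missing column(s): ",
         paste(setdiff(need, names(tr)), collapse = ", "))
  }
  for (col in c("sat_protan", "sat_deutan", "sat_tritan")) {
    tr[[col]] <- suppressWarnings(as.numeric(tr[[col]]))
  }
  bad <- which(!tr$tapped %in% c(cvd_axes(), "distractor"))
  if (length(bad)) {
    stop("format-error: invalid tapped value '", tr$tapped[bad[1]],
         "' at data row ", bad[1])
  }
  log <- lapply(seq_len(nrow(tr)), function(i) {
    list(trial_index = tr$trial_index[i],
         set_index = tr$set_index[i],
         saturation = c(protan = tr$sat_protan[i], deutan = tr$sat_deutan[i],
                        tritan = tr$sat_tritan[i]),
         tapped = tr$tapped[i])
  })
  structure(list(
    saturation = NULL, update_count = NULL, active = NULL,
    set_index = max(tr$set_index, 1L), complete = identical(meta[3], "TRUE"),
    log = log,
    seed = if (meta[2] == "NA") NULL else as.numeric(meta[2]),
    cfg = NULL
  ), class = "cvd_session")
}

#' Write cohort results as CSV
#'
#' @param evaluation an [evaluate_cohort()] result.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(evaluation, path) {
  utils::write.csv(evaluation$results, path, row.names = FALSE)
  invisible(path)
}
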