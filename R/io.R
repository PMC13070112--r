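# Delimited-text interfaces: TACs as TSV (frame_start_s, frame_dur_s, one
# column per region), tables as CSV, run metadata as JSON sidecars.

#' Write a TAC bundle to TSV
#'
#' @param tacs named list of [tac()]s sharing one schedule.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path) {
  stopifnot(is.list(tacs), length(tacs) >= 1, all(vapply(tacs, inherits, TRUE, "tac")))
  sched <- tacs[[1]]$schedule
  for (x in tacs) {
    if (!identical(x$schedule$duration_s, sched$duration_s)) {
      stop("all TACs in a bundle must share one schedule")
    }
  }
  df <- data.frame(
    frame_start_s = sched$start_s,
    frame_dur_s = sched$duration_s
  )
  for (nm in names(tacs)) df[[nm]] <- tacs[[nm]]$activity
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TAC bundle from TSV
#'
#' Expects a header `frame_start_s`, `frame_dur_s`, then one activity column
#' per region. The schedule is validated (contiguous, non-overlapping,
#' positive durations).
#'
#' @param path TSV file path.
#' @return Named list of [tac()]s, one per region column.
#' @export
read_tac_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  for (col in c("frame_start_s", "frame_dur_s")) {
    if (!col %in% colnames(df)) {
      stop(sprintf("TAC table %s is missing required column '%s'", path, col))
    }
  }
  sched <- frame_schedule(df$frame_dur_s, df$frame_start_s)
  regions <- setdiff(colnames(df), c("frame_start_s", "frame_dur_s"))
  if (length(regions) == 0) stop("TAC table has no region columns")
  out <- lapply(regions, function(rg) tac(sched, df[[rg]], rg))
  stats::setNames(out, regions)
}

write_sidecar <- function(path, stage, seed, extra = list()) {
  payload <- c(
    list(
      stage = stage, seed = seed,
      package = "petcohort",
      version = as.character(utils::packageVersion("petcohort")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    extra
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

spec_as_list <- function(spec) {
  out <- unclass(spec)
  out$correlations <- as.data.frame(out$correlations)
  out
}
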