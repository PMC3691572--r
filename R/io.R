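#' Read a starch time course from CSV
#'
#' Two dialects are supported. *Replicate* form has one row per rosette:
#' columns `time_hr`, `replicate_id`, `starch_mg_per_g_fw`. *Summary* form
#' has one row per time point: columns `time_hr`, `mean`, `sem`, `n`.
#' Replicate files are also auto-summarized (mean, SEM = sd/sqrt(n)) into
#' the `"summary"` attribute.
#'
#' @param path CSV file path (comma-separated, UTF-8, '.' decimal).
#' @param dialect `"replicate"` or `"summary"`.
#' @return A tibble in the requested dialect; replicate tibbles carry the
#'   auto-summary in `attr(, "summary")`.
#' @export
read_timecourse <- function(path, dialect = c("replicate", "summary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (dialect == "replicate") {
    c("time_hr", "replicate_id", "starch_mg_per_g_fw")
  } else {
    c("time_hr", "mean", "sem", "n")
  }
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(need, "replicate_id")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", cn, "' at data line ",
           bad[1] + 1, " of ", path, call. = FALSE)
    }
    raw[[cn]] <- v
  }
  tb <- tibble::as_tibble(raw[, need])
  if (dialect == "replicate") {
    dup <- duplicated(tb[, c("time_hr", "replicate_id")])
    if (any(dup)) {
      stop("duplicate (time_hr, replicate_id) at data line ",
           which(dup)[1] + 1, " of ", path, call. = FALSE)
    }
    attr(tb, "summary") <- summarize_timecourse(tb)
  } else {
    if (anyDuplicated(tb$time_hr)) {
      stop("duplicate time_hr values in summary file ", path, call. = FALSE)
    }
    tb <- dplyr::arrange(tb, .data$time_hr)
    if (any(tb$sem < 0)) stop("negative SEM in ", path, call. = FALSE)
  }
  tb
}

#' Write a time course or trajectory to CSV
#'
#' Trajectories are written with columns `time_hr`,
#' `starch_mg_per_g_fw` (plus any species columns present); time-course
#' tibbles are written as-is. An optional JSON sidecar records model,
#' parameters and seed for provenance.
#'
#' @param x A `starch_trajectory` or time-course tibble.
#' @param path Output CSV path.
#' @param meta Optional named list written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(x, path, meta = NULL) {
  out <- as.data.frame(x)
  if (inherits(x, "starch_trajectory")) {
    names(out)[names(out) == "starch"] <- "starch_mg_per_g_fw"
  }
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
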