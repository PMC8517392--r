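# Tabular text I/O. All files are plain CSV with a header row; lines starting
# with '#' before the header carry reproducibility metadata (seed, config
# hash) and are ignored on read.

#' Write a CSV table with comment-prefixed metadata lines
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named character vector written as `# key: value` lines above
#'   the header.
#' @return `path`, invisibly.
#' @export
write_psl_csv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV table written by the package (metadata lines skipped)
#'
#' @param path input path.
#' @return a data.frame.
#' @export
read_psl_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read long-format strain traces
#'
#' Expects columns `subject_id`, `segment_id` (1-17), `time_s`, `strain_pct`.
#'
#' @param path CSV path.
#' @return named list (by subject id) of lists of [strain_trace()] objects.
#' @export
read_strain_csv <- function(path) {
  df <- read_psl_csv(path)
  need <- c("subject_id", "segment_id", "time_s", "strain_pct")
  if (!all(need %in% names(df))) {
    stop("strain file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, ]
    traces <- lapply(sort(unique(sub$segment_id)), function(sg) {
      blk <- sub[sub$segment_id == sg, ]
      o <- order(blk$time_s)
      strain_trace(sg, blk$time_s[o], blk$strain_pct[o])
    })
    out[[as.character(sid)]] <- traces
  }
  out
}

#' Write strain traces in long format
#'
#' @param bundles named list (by subject id) of lists of [strain_trace()]s,
#'   or the `bundles` element of [generate_cohort()].
#' @param path output CSV path.
#' @param meta metadata lines, see [write_psl_csv()].
#' @param digits strain values are rounded to this many decimals (file-size
#'   control; 4 decimals is far below speckle-tracking resolution).
#' @return `path`, invisibly.
#' @export
write_strain_csv <- function(bundles, path, meta = NULL, digits = 4) {
  rows <- lapply(names(bundles), function(sid) {
    traces <- bundles[[sid]]
    if (!is.null(traces$traces)) traces <- traces$traces
    do.call(rbind, lapply(traces, function(tr) {
      data.frame(subject_id = sid, segment_id = tr$segment_id,
                 time_s = round(tr$times, 6),
                 strain_pct = round(tr$strain, digits))
    }))
  })
  write_psl_csv(do.call(rbind, rows), path, meta = meta)
}

#' Read valve-event timings
#'
#' Expects columns `subject_id`, `t_mvc_s`, `t_avo_s`, `t_avc_s`, `t_mvo_s`.
#'
#' @param path CSV path.
#' @return named list of [valve_events()] objects.
#' @export
read_events_csv <- function(path) {
  df <- read_psl_csv(path)
  need <- c("subject_id", "t_mvc_s", "t_avo_s", "t_avc_s", "t_mvo_s")
  if (!all(need %in% names(df))) {
    stop("events file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    valve_events(df$t_mvc_s[i], df$t_avo_s[i], df$t_avc_s[i], df$t_mvo_s[i])
  })
  names(out) <- as.character(df$subject_id)
  out
}

#' Write valve-event timings
#'
#' @param bundles named list with per-subject `events` ([valve_events()]).
#' @param path output CSV path.
#' @param meta metadata lines.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(bundles, path, meta = NULL) {
  df <- do.call(rbind, lapply(names(bundles), function(sid) {
    ev <- bundles[[sid]]
    if (!is.null(ev$events)) ev <- ev$events
    data.frame(subject_id = sid, t_mvc_s = ev$t_mvc, t_avo_s = ev$t_avo,
               t_avc_s = ev$t_avc, t_mvo_s = ev$t_mvo)
  }))
  df[-1] <- lapply(df[-1], round, 6)
  write_psl_csv(df, path, meta = meta)
}
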