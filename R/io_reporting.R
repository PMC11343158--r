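# Readers/writers for cell maps, sweeps, event logs and summaries, plus the
# connectivity-matrix report. All on-disk formats are plain text: CSV with
# header rows, and JSON-lines event logs carrying a schema-version field.

LOG_SCHEMA_VERSION <- 1L

#' Write / read a cell map CSV
#'
#' Columns: `id`, `x_um`, `y_um`, `z_um`.
#'
#' @param cells Cell-map data frame.
#' @param path File path.
#' @return `read_cell_map()` returns the cell-map data frame;
#'   `write_cell_map()` returns `path` invisibly.
#' @export
write_cell_map <- function(cells, path) {
  stopifnot(all(c("id", "x_um", "y_um", "z_um") %in% names(cells)))
  utils::write.csv(cells[c("id", "x_um", "y_um", "z_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_map
#' @export
read_cell_map <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df))) {
    stop_domain("cell map must have columns ", paste(need, collapse = ", "))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_domain("malformed value in column '", col, "' at line ",
                  bad[1] + 1L, " (counting the header)")
    }
    df[[col]] <- v
  }
  df$id <- as.integer(df$id)
  df[need]
}

#' Write / read screening sweeps as CSV
#'
#' Long format with columns `time_ms`, `current_pa`, `sweep_id`.
#'
#' @param sweeps A list of `screen_sweep` objects.
#' @param path File path.
#' @return `read_sweeps()` returns a list of `screen_sweep` objects;
#'   `write_sweeps()` returns `path` invisibly.
#' @export
write_sweeps <- function(sweeps, path) {
  rows <- lapply(seq_along(sweeps), function(i) {
    data.frame(time_ms = sweeps[[i]]$time_ms,
               current_pa = sweeps[[i]]$current_pa, sweep_id = i)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweeps
#' @param stim_onset_ms Stimulus onset to attach to the sweeps read back.
#' @export
read_sweeps <- function(path, stim_onset_ms = 50) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "current_pa", "sweep_id")
  if (!all(need %in% names(df))) {
    stop_domain("sweep file must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$sweep_id), function(d) {
    structure(
      data.frame(time_ms = d$time_ms, current_pa = d$current_pa),
      class = c("screen_sweep", "data.frame"),
      stim_onset_ms = stim_onset_ms
    )
  })
}

#' Write / read an experiment event log as JSON lines
#'
#' One JSON object per line with fields `schema_version`, `t`, `pipette`,
#' `cell`, `kind`, `cell2`, `connected`.
#'
#' @param log A `patchwalk_log` or raw event data frame.
#' @param path File path.
#' @return `read_event_log()` returns the event data frame;
#'   `write_event_log()` returns `path` invisibly.
#' @export
write_event_log <- function(log, path) {
  events <- if (inherits(log, "patchwalk_log")) log$events else log
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    rec <- c(list(schema_version = LOG_SCHEMA_VERSION),
             as.list(events[i, c("t", "pipette", "cell", "kind", "cell2",
                                 "connected")]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                na = "null", digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) {
                      stop_domain("parse error on line ", i, ": ",
                                  conditionMessage(e))
                    })
    if (is.null(rec$kind) || is.null(rec$t)) {
      stop_domain("parse error on line ", i, ": missing required field")
    }
    data.frame(
      t = as.numeric(rec$t),
      pipette = if (is.null(rec$pipette)) NA_character_ else rec$pipette,
      cell = if (is.null(rec$cell)) NA_integer_ else as.integer(rec$cell),
      kind = rec$kind,
      cell2 = if (is.null(rec$cell2)) NA_integer_ else as.integer(rec$cell2),
      connected = if (is.null(rec$connected)) NA else as.logical(rec$connected)
    )
  })
  do.call(rbind, rows)
}

#' Write a summary tally CSV
#'
#' @param summary A tally data frame from [summarize_log()] (or the
#'   `replicates` table from [compare_strategies()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Build a connectivity-matrix report from a log
#'
#' Cells are labelled `n.p` — the cell number in order of first whole-cell
#' recording, and the letter of the pipette (manipulator) that held it. The
#' matrix entry (i, j) reports the i -> j directed probe: `"untested"`,
#' `"probed_not_connected"`, or `"connected"`; the diagonal is `"self"`.
#' Entry (i, j) is independent of (j, i). The number of non-untested
#' off-diagonal entries is exactly twice the number of screened pairs.
#'
#' @param log A `patchwalk_log` or raw event data frame containing
#'   `whole_cell` and `probe` events.
#' @param screens Optional data frame (`pre`, `post`, `connected`)
#'   overriding the probe outcomes in the log; every row must reference
#'   cells present in the log.
#' @return A character matrix with `n.p` dimnames and a `labels` attribute
#'   mapping cell id to label.
#' @export
build_connectivity_matrix <- function(log, screens = NULL) {
  events <- if (inherits(log, "patchwalk_log")) log$events else log
  wc <- events[events$kind == "whole_cell", ]
  wc <- wc[order(wc$t), ]
  wc <- wc[!duplicated(wc$cell), ]
  if (nrow(wc) == 0) stop_domain("log contains no whole-cell recordings")
  labels <- setNames(sprintf("%d.%s", seq_len(nrow(wc)), wc$pipette), wc$cell)
  n <- nrow(wc)
  m <- matrix("untested", n, n, dimnames = list(labels, labels))
  diag(m) <- "self"
  probes <- if (is.null(screens)) {
    pr <- events[events$kind == "probe", ]
    data.frame(pre = pr$cell, post = pr$cell2, connected = pr$connected)
  } else {
    screens
  }
  for (i in seq_len(nrow(probes))) {
    pre <- as.character(probes$pre[i])
    post <- as.character(probes$post[i])
    if (!pre %in% names(labels) || !post %in% names(labels)) {
      stop_domain("orphan screen result: cells ", pre, " -> ", post,
                  " not in the log")
    }
    if (is.na(probes$connected[i])) next
    m[labels[pre], labels[post]] <-
      if (isTRUE(probes$connected[i])) "connected" else "probed_not_connected"
  }
  attr(m, "labels") <- labels
  m
}

#' Write a connectivity-matrix report CSV
#'
#' @param matrix_report Matrix from [build_connectivity_matrix()] (or a 0/1
#'   logical matrix from [yield_matrix()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(matrix_report, path) {
  m <- matrix_report
  if (is.logical(m)) m[] <- as.integer(m)
  df <- data.frame(cell = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
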