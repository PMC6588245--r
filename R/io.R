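#' Read a multi-marker trajectory series from a wide CSV/TSV file
#'
#' Layout: one row per frame; columns `<marker>_X`, `<marker>_Y`,
#' `<marker>_Z` for every marker, plus an optional `time` column. The
#' sampling rate is taken from a `# rate: <Hz>` comment header if present,
#' otherwise from the `rate` argument, otherwise inferred from `time`.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"tsv"`. C3D input is not supported by this
#'   reader; convert to wide CSV first.
#' @param rate sampling frequency in Hz; required when the file carries no
#'   rate metadata and no `time` column.
#' @param vertical_axis vertical coordinate index (default 3, Z-up).
#' @param gap_policy `"reject"` (default): any missing sample aborts the
#'   load. `"linear_fill"`: interior gaps are linearly interpolated per
#'   marker-coordinate and the number of filled samples is reported via
#'   `message()`; leading/trailing gaps are never filled. The conservative
#'   default reflects that analyses downstream expect raw, unfiltered data,
#'   so any repair must be an explicit, visible choice.
#' @param scale multiply positions on load (e.g. `1e-3` for mm-unit files).
#' @return a validated [trajectory_series()].
#' @export
load_series <- function(path, dialect = c("csv", "tsv"), rate = NULL,
                        vertical_axis = 3L,
                        gap_policy = c("reject", "linear_fill"),
                        scale = 1.0) {
  dialect <- match.arg(dialect)
  gap_policy <- match.arg(gap_policy)
  if (!file.exists(path) || dir.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"

  header <- readLines(path, n = 5L)
  meta_rate <- grep("^#\\s*rate\\s*:", header, value = TRUE)
  if (length(meta_rate))
    rate <- as.numeric(sub("^#\\s*rate\\s*:\\s*", "", meta_rate[1]))
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(df)
  time_col <- cols[tolower(cols) == "time"]
  marker_cols <- setdiff(cols, time_col)

  suffix <- sub("^.*_(X|Y|Z)$", "\\1", marker_cols)
  base <- sub("_(X|Y|Z)$", "", marker_cols)
  bad <- marker_cols[!grepl("_(X|Y|Z)$", marker_cols)]
  if (length(bad))
    stop(sprintf("malformed marker columns (expect <name>_X/_Y/_Z): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  markers <- unique(base)
  for (m in markers) {
    have <- sort(suffix[base == m])
    if (!identical(have, c("X", "Y", "Z")))
      stop(sprintf("marker '%s' has incomplete coordinate triplet (%s)",
                   m, paste(have, collapse = ",")), call. = FALSE)
  }
  if (is.null(rate)) {
    if (length(time_col) && nrow(df) >= 2L) {
      dt <- diff(df[[time_col]])
      rate <- 1 / stats::median(dt)
    } else {
      stop("sampling rate unknown: no '# rate:' header, no time column, no `rate` argument",
           call. = FALSE)
    }
  }

  nf <- nrow(df)
  pos <- array(NA_real_, dim = c(nf, length(markers), 3L))
  for (k in seq_along(markers)) {
    for (a in 1:3) {
      pos[, k, a] <- as.numeric(df[[paste0(markers[k], "_", c("X", "Y", "Z")[a])]])
    }
  }
  pos <- pos * scale

  if (anyNA(pos)) {
    if (gap_policy == "reject")
      stop("missing samples present and gap_policy = 'reject'", call. = FALSE)
    filled <- 0L
    for (k in seq_along(markers)) {
      for (a in 1:3) {
        v <- pos[, k, a]
        if (anyNA(v)) {
          if (is.na(v[1]) || is.na(v[length(v)]))
            stop(sprintf("leading/trailing gap in %s axis %d cannot be filled",
                         markers[k], a), call. = FALSE)
          filled <- filled + sum(is.na(v))
          pos[, k, a] <- stats::approx(seq_along(v), v, xout = seq_along(v))$y
        }
      }
    }
    message(sprintf("linear_fill: interpolated %d missing samples", filled))
  }
  trajectory_series(pos, rate = rate, marker_names = markers,
                    vertical_axis = vertical_axis, source = path)
}

#' Write a trajectory series to wide CSV/TSV
#'
#' Emits a `# rate:` metadata header followed by a `time` column and one
#' `<marker>_X/_Y/_Z` triplet per marker, full double precision, so that
#' [load_series()] round-trips the data exactly (to well below 1e-9 m).
#'
#' @param series a `trajectory_series`.
#' @param path destination file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
save_series <- function(series, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dir.exists(path)) stop(sprintf("'%s' is a directory", path), call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  nf <- n_frames(series)
  cols <- list(time = (seq_len(nf) - 1L) / series$rate)
  for (k in seq_len(n_markers(series))) {
    for (a in 1:3) {
      cols[[paste0(series$marker_names[k], "_", c("X", "Y", "Z")[a])]] <-
        series$positions[, k, a]
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate: %.10g", series$rate), con)
  utils::write.table(as.data.frame(cols, check.names = FALSE), con,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a marker weight configuration from JSON
#'
#' Format: `{"default": w, "weights": {"<marker>": w, ...}}`. Markers not
#' listed receive the declared default (1.0 when the file omits it). All
#' names must exist in `series`.
#'
#' @param path JSON file.
#' @param series the `trajectory_series` the weights will be used with.
#' @return numeric weight vector in series marker order (see
#'   [resolve_weights()]).
#' @export
load_weights <- function(path, series) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  default <- if (!is.null(cfg$default)) cfg$default else 1.0
  if (!is.numeric(default) || default < 0 || default > 1)
    stop("weight default must lie in [0, 1]", call. = FALSE)
  w <- cfg$weights
  if (length(w) == 0) return(rep(default, n_markers(series)))
  resolve_weights(weight_map(w), series, default = default)
}
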