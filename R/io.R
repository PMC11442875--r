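#' Read cell-index series from CSV
#'
#' Expects a header with columns `time_h`, `condition`, `et_ratio`, `ci`;
#' rows are grouped into one [ci_series()] per (condition, E:T ratio) well
#' and sorted by time.  Validation errors name the offending well and row.
#'
#' @param path CSV file path.
#' @param t_treat optional treatment time (hours) attached to every series.
#' @return A list of [ci_series()] (empty, with a warning, for a file with
#'   only a header).
#' @export
read_series_csv <- function(path, t_treat = NA_real_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_h", "condition", "et_ratio", "ci")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) {
    warning("file contains a header but no data rows; returning an empty list")
    return(list())
  }
  for (col in c("time_h", "et_ratio", "ci")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s' at data row %d", col,
                   if (length(bad)) bad[1] else which(is.na(v))[1]))
    df[[col]] <- v
  }
  key <- paste(df$condition, df$et_ratio, sep = "@")
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    sub <- df[rows, ]
    ord <- order(sub$time_h)
    sub <- sub[ord, ]
    dup <- which(diff(sub$time_h) == 0)
    if (length(dup) > 0L)
      stop(sprintf("duplicated timestamp %g h in well '%s' (E:T %g) at data row %d",
                   sub$time_h[dup[1] + 1], sub$condition[1], sub$et_ratio[1],
                   rows[ord][dup[1] + 1]))
    out[[length(out) + 1L]] <- ci_series(
      sub$time_h, sub$ci, condition = sub$condition[1],
      et_ratio = sub$et_ratio[1], t_treat = t_treat)
  }
  out
}

#' Write cell-index series to CSV
#'
#' The inverse of [read_series_csv()]: columns `time_h`, `condition`,
#' `et_ratio`, `ci`.
#'
#' @param series a [ci_series()] or list of them.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "ci_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(time_h = s$times, condition = s$condition,
               et_ratio = s$et_ratio, ci = s$ci)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a killing-time table to CSV
#'
#' @param kt a data frame from [killing_time_table()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_kt_table <- function(kt, path) {
  utils::write.csv(kt, path, row.names = FALSE)
  invisible(path)
}
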