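#' Read and write TCSPC histogram files
#'
#' Plain-text, vendor-neutral format: header lines `# key=value` carrying at
#' least `bin_width_ns` and `period_ns` (plus free-form annotations such as
#' `cell_id` and `group`), followed by two tab-separated columns,
#' `time_ns` (left bin edge) and `counts`, one row per bin. IRF files use
#' the same layout; raw IRF counts are normalized on load.
#'
#' @param path File path.
#' @return `read_histogram()` returns a [decay_histogram()];
#'   `read_irf()` an [instrument_response()].
#' @name histogram_io
NULL

parse_histogram_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("histogram file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  header <- list()
  for (h in lines[hdr_idx]) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      header[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 8)
    stop(sprintf("%s: fewer than 8 data rows", path), call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop(sprintf("%s: malformed data rows (expect time_ns<TAB>counts)", path),
         call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m))
    stop(sprintf("%s: non-numeric data values", path), call. = FALSE)
  for (k in c("bin_width_ns", "period_ns"))
    if (is.null(header[[k]]))
      stop(sprintf("%s: missing required header '# %s=...'", path, k), call. = FALSE)
  bw <- as.numeric(header$bin_width_ns)
  period <- as.numeric(header$period_ns)
  n <- nrow(m)
  if (abs(n * bw - period) / period > 1e-6)
    stop(sprintf("%s: n_bins x bin_width (%g) inconsistent with period (%g)",
                 path, n * bw, period), call. = FALSE)
  list(binning = time_binning(n, period), counts = m[, 2], header = header)
}

#' @rdname histogram_io
#' @export
read_histogram <- function(path) {
  p <- parse_histogram_file(path)
  meta <- p$header[setdiff(names(p$header), c("bin_width_ns", "period_ns"))]
  decay_histogram(p$counts, p$binning, meta = meta)
}

#' @rdname histogram_io
#' @export
read_irf <- function(path) {
  p <- parse_histogram_file(path)
  instrument_response(p$counts, p$binning)
}

write_hist_body <- function(binning, values, header, path) {
  hdr <- c(sprintf("# bin_width_ns=%.12g", binning$bin_width_ns),
           sprintf("# period_ns=%.12g", binning$period_ns),
           vapply(names(header), function(k) sprintf("# %s=%s", k, header[[k]]), ""))
  body <- sprintf("%.12g\t%.12g", bin_left_edges(binning), values)
  writeLines(c(hdr, body), path)
}

#' @rdname histogram_io
#' @param hist A [decay_histogram()] to write.
#' @export
write_histogram <- function(hist, path) {
  write_hist_body(hist$binning, hist$counts, hist$meta, path)
  invisible(path)
}

#' @rdname histogram_io
#' @param irf An [instrument_response()] to write (normalized weights).
#' @export
write_irf <- function(irf, path) {
  write_hist_body(irf$binning, irf$weights, list(kind = "irf"), path)
  invisible(path)
}
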