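#' Build the per-sample quality statistics report
#'
#' Summarises one processed sample in the 11 fields of the standard report:
#' total input pairs, overlapping and non-overlapping amplicon counts, the
#' average (unmasked) amplicon length, average Q and average meep over all
#' amplicons, then the same statistics restricted to the high-quality (HQ)
#' set plus the percentage of HQ amplicons that are overlapping. The
#' "average Q" and "average meep" fields are means over amplicons of the
#' per-amplicon statistic, and every average respects the spacer masks.
#'
#' @param amplicons A scored amplicon tibble ([score_amplicons()] output);
#'   may be empty.
#' @param total_pairs Total input pairs, including pairs that neither
#'   merged nor were stitched (discarded unmergeable pairs).
#' @param sample_id Label for the sample column of the report.
#' @return A one-row `quality_report` tibble. When no amplicon passes the
#'   filter the HQ averages are reported as 0 and `hq_empty` is `TRUE`.
#' @export
build_report <- function(amplicons, total_pairs, sample_id = "sample") {
  stopifnot(total_pairs >= nrow(amplicons))
  hq <- amplicons[amplicons$hq, , drop = FALSE]
  n_hq <- nrow(hq)
  avg0 <- function(x) if (length(x) == 0L) 0 else mean(x)
  out <- tibble::tibble(
    sample_id = sample_id,
    total_reads = as.integer(total_pairs),
    overlapping = sum(amplicons$overlapped),
    non_overlapping = sum(!amplicons$overlapped),
    avg_amplicon_len = avg0(amplicons$unmasked_len),
    avg_q_all = avg0(amplicons$avg_q),
    avg_meep_all = avg0(amplicons$meep),
    hq_count = n_hq,
    avg_len_hq = avg0(hq$unmasked_len),
    avg_q_hq = avg0(hq$avg_q),
    avg_meep_hq = avg0(hq$meep),
    pct_overlap_hq = if (n_hq == 0L) 0 else 100 * sum(hq$overlapped) / n_hq,
    hq_empty = n_hq == 0L
  )
  class(out) <- c("quality_report", class(out))
  out
}

report_columns <- c(
  "sample_id", "total_reads", "overlapping", "non_overlapping",
  "avg_amplicon_len", "avg_q_all", "avg_meep_all", "hq_count",
  "avg_len_hq", "avg_q_hq", "avg_meep_hq", "pct_overlap_hq", "hq_empty"
)

#' Write a quality report to TSV or JSON
#'
#' TSV output has a header row and one row per sample; JSON mirrors the
#' field names. Floating point fields are rounded to 3 decimals on output.
#'
#' @param report A [build_report()] tibble (one or more rows).
#' @param path Output file path.
#' @param fmt `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, fmt = c("tsv", "json")) {
  fmt <- match.arg(fmt)
  out <- dplyr::mutate(report[, report_columns],
                       dplyr::across(dplyr::where(is.double), ~ round(.x, 3)))
  if (fmt == "tsv") {
    readr::write_tsv(out, path)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a quality report back from TSV or JSON
#'
#' @param path File written by [write_report()].
#' @param fmt `"tsv"` or `"json"`.
#' @return A `quality_report` tibble.
#' @export
read_report <- function(path, fmt = c("tsv", "json")) {
  fmt <- match.arg(fmt)
  out <- if (fmt == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
  out <- out[, report_columns]
  class(out) <- c("quality_report", class(out))
  out
}
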