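#' Run the full merge–stitch–filter pipeline on one sample
#'
#' Orchestrates the whole preprocessing of a paired-end amplicon sample:
#'
#' 1. reads and pairs the two mate FASTQ files,
#' 2. builds the dataset-wide k-mer context table (pass 1 over both mates),
#' 3. merges each pair at its best overlap (pass 2),
#' 4. stitches non-overlapping pairs across an N spacer when
#'    `keep_nonoverlap` is set (otherwise they are discarded and counted),
#' 5. scores every amplicon (MEE, meep, average Q, spacer-mask aware) and
#'    applies the filter policy,
#' 6. writes `<prefix>.hq.fastq`, `<prefix>.lq.fastq`,
#'    `<prefix>.report.tsv` and `<prefix>.report.json`.
#'
#' Record conservation holds on every run: HQ + LQ + discarded unmergeable
#' pairs = total input pairs.
#'
#' @param fwd_path,rev_path Mate FASTQ files (synchronised order).
#' @param out_prefix Output path prefix; `NULL` skips writing files.
#' @param merge A [merge_params()].
#' @param stitch A [stitch_params()]; its `keep_nonoverlap` flag decides
#'   the fate of unmergeable pairs.
#' @param policy A [filter_policy()] (default: meep at 1%).
#' @param offset Quality encoding offset (default 33).
#' @param sample_id Sample label for the report; defaults to the forward
#'   file name stem.
#' @param quiet Suppress per-stage progress messages (written to stderr).
#' @return An `ampmerge_run` object: list with `report` (one-row
#'   [build_report()] tibble), `amplicons` (scored amplicon tibble),
#'   `n_pairs`, `n_discarded`, `policy` and the parameter objects.
#' @export
run_pipeline <- function(fwd_path, rev_path, out_prefix = NULL,
                         merge = merge_params(), stitch = stitch_params(),
                         policy = filter_policy("meep", 1), offset = 33L,
                         sample_id = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[ampmerge] ", ...)
  if (is.null(sample_id)) {
    sample_id <- sub("(\\.fastq|\\.fq)(\\.gz)?$", "", basename(fwd_path))
  }
  fwd <- read_fastq(fwd_path, offset)
  rev <- read_fastq(rev_path, offset)
  pairs <- pair_reads(fwd, rev)
  n_pairs <- nrow(pairs)
  say(n_pairs, " read pairs from '", basename(fwd_path), "' / '",
      basename(rev_path), "'")
  run_pipeline_pairs(pairs, out_prefix = out_prefix, merge = merge,
                     stitch = stitch, policy = policy, offset = offset,
                     sample_id = sample_id, quiet = quiet)
}

#' Run the pipeline on an in-memory pair table
#'
#' Same as [run_pipeline()] but starting from a pair tibble (e.g. straight
#' from [simulate_pairs()] + [pair_reads()]), skipping file input.
#'
#' @param pairs Pair tibble from [pair_reads()].
#' @inheritParams run_pipeline
#' @return An `ampmerge_run` object.
#' @export
run_pipeline_pairs <- function(pairs, out_prefix = NULL,
                               merge = merge_params(),
                               stitch = stitch_params(),
                               policy = filter_policy("meep", 1),
                               offset = 33L, sample_id = "sample",
                               quiet = FALSE) {
  say <- function(...) if (!quiet) message("[ampmerge] ", ...)
  n_pairs <- nrow(pairs)

  table <- build_kmer_table(c(pairs$seq_f, revcomp(pairs$seq_r)),
                            merge$kmer_size)
  say("k-mer table: ", length(table), " distinct canonical ",
      merge$kmer_size, "-mers")

  merged <- merge_pairs(pairs, table, merge)
  ok <- merged$overlapped
  say(sum(ok), " pairs merged; ", sum(!ok), " without acceptable overlap")

  amplicons <- merged[ok, , drop = FALSE]
  n_discarded <- 0L
  if (stitch$keep_nonoverlap) {
    stitched <- stitch_pairs(pairs[!ok, , drop = FALSE], stitch)
    amplicons <- dplyr::bind_rows(amplicons, stitched)
    say(nrow(stitched), " non-overlapping pairs stitched with ",
        stitch$n_spacer, "-N spacer")
  } else {
    n_discarded <- sum(!ok)
    if (n_discarded > 0L) say(n_discarded,
                              " non-overlapping pairs discarded")
  }

  amplicons <- score_amplicons(amplicons, policy)
  report <- build_report(amplicons, n_pairs, sample_id)
  say(report$hq_count, "/", nrow(amplicons), " amplicons pass the ",
      policy$mode, " filter at threshold ", policy$threshold)

  if (!is.null(out_prefix)) {
    hq <- amplicons[amplicons$hq, , drop = FALSE]
    lq <- amplicons[!amplicons$hq, , drop = FALSE]
    write_fastq(hq, paste0(out_prefix, ".hq.fastq"), offset)
    write_fastq(lq, paste0(out_prefix, ".lq.fastq"), offset)
    write_report(report, paste0(out_prefix, ".report.tsv"), "tsv")
    write_report(report, paste0(out_prefix, ".report.json"), "json")
    say("outputs written with prefix '", out_prefix, "'")
  }

  structure(list(report = report, amplicons = amplicons,
                 n_pairs = n_pairs, n_discarded = n_discarded,
                 policy = policy, merge = merge, stitch = stitch),
            class = "ampmerge_run")
}

#' @export
print.ampmerge_run <- function(x, ...) {
  r <- x$report
  cat("<ampmerge_run> sample '", r$sample_id, "'\n", sep = "")
  cat("  pairs: ", r$total_reads, " (", r$overlapping, " merged, ",
      r$non_overlapping, " stitched, ", x$n_discarded, " discarded)\n",
      sep = "")
  cat("  high quality: ", r$hq_count, " amplicons (",
      x$policy$mode, if (x$policy$mode == "meep") " <= " else " >= ",
      x$policy$threshold, ")\n", sep = "")
  invisible(x)
}

#' Tidy the amplicon-level results of a pipeline run
#'
#' @param x An `ampmerge_run`.
#' @param ... Unused.
#' @return One row per retained amplicon: identifier, overlap status and
#'   length, unmasked length, MEE, meep, average Q and the HQ verdict.
#' @method tidy ampmerge_run
#' @export
tidy.ampmerge_run <- function(x, ...) {
  dplyr::select(x$amplicons, "read_id", "overlapped", "overlap_len",
                "unmasked_len", "mee", "meep", "avg_q", "hq")
}

#' One-row summary of a pipeline run
#'
#' @param x An `ampmerge_run`.
#' @param ... Unused.
#' @return The sample quality report as a one-row tibble.
#' @method glance ampmerge_run
#' @export
glance.ampmerge_run <- function(x, ...) {
  x$report
}

#' Plot the quality landscape of a pipeline run
#'
#' Histogram of per-amplicon meep scores, split by overlap status and
#' coloured by the filter verdict, with the active meep threshold drawn
#' when the run filtered on meep.
#'
#' @param object An `ampmerge_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ampmerge_run
#' @export
autoplot.ampmerge_run <- function(object, ...) {
  d <- tidy(object)
  d$status <- ifelse(d$overlapped, "merged (overlapping)",
                     "stitched (non-overlapping)")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$meep, fill = .data$hq)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$status), ncol = 1) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f0e"),
      name = "high quality") +
    ggplot2::labs(x = "meep score (% expected errors)",
                  y = "amplicons",
                  title = paste0("Sample '", object$report$sample_id, "'"))
  if (object$policy$mode == "meep") {
    p <- p + ggplot2::geom_vline(xintercept = object$policy$threshold,
                                 linetype = "dashed")
  }
  p
}

#' Plot the simulator's per-cycle error model
#'
#' @param params A [sim_params()].
#' @return A ggplot of substitution probability against cycle.
#' @export
plot_error_model <- function(params = sim_params()) {
  d <- tibble::tibble(cycle = seq_len(params$read_len),
                      probability = error_rate(cycle, params))
  ggplot2::ggplot(d, ggplot2::aes(.data$cycle, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sequencing cycle",
                  y = "substitution probability per base")
}
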