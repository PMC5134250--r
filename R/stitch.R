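#' Stitch parameters
#'
#' @param n_spacer Number of `N` bases inserted between the mates
#'   (default 15).
#' @param spacer_phred Phred score written for each spacer base (default 2).
#'   The spacer is masked internally, so this value never enters quality
#'   metrics; it is only what downstream consumers see in the FASTQ.
#' @param keep_nonoverlap Retain non-overlapping pairs by stitching
#'   (default `FALSE`, i.e. discard, matching common practice).
#' @return A `stitch_params` object.
#' @export
stitch_params <- function(n_spacer = 15L, spacer_phred = 2L,
                          keep_nonoverlap = FALSE) {
  n_spacer <- as.integer(n_spacer)
  spacer_phred <- as.integer(spacer_phred)
  if (n_spacer < 0L) stop("n_spacer must be >= 0", call. = FALSE)
  if (spacer_phred < 0L || spacer_phred > 93L) {
    stop("spacer_phred must be in [0, 93]", call. = FALSE)
  }
  structure(list(n_spacer = n_spacer, spacer_phred = spacer_phred,
                 keep_nonoverlap = isTRUE(keep_nonoverlap)),
            class = "stitch_params")
}

#' Stitch non-overlapping pairs across an N spacer
#'
#' Joins each forward read to the reverse-complement of its reverse mate
#' with `n_spacer` `N` bases in between, carried at Phred `spacer_phred`.
#' The spacer positions are flagged in `spacer_mask` and are ignored by
#' every quality metric and statistic, so a stitched amplicon scores
#' exactly as the concatenation of its two mates would. The operation is
#' lossless: dropping the spacer and reverse-complementing the suffix
#' recovers both mates.
#'
#' @param pairs Pair tibble (see [pair_reads()]).
#' @param params A [stitch_params()].
#' @return Amplicon tibble with `overlapped = FALSE`, `overlap_len = 0`;
#'   the amplicon keeps the pair identifier.
#' @export
stitch_pairs <- function(pairs, params = stitch_params()) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quals = list(), spacer_mask = list(),
                          overlapped = logical(), overlap_len = integer()))
  }
  spacer <- strrep("N", params$n_spacer)
  tibble::tibble(
    read_id = pairs$pair_id,
    sequence = paste0(pairs$seq_f, spacer, revcomp(pairs$seq_r)),
    quals = purrr::map2(pairs$quals_f, pairs$quals_r,
      ~ as.integer(c(.x, rep(params$spacer_phred, params$n_spacer),
                     rev(.y)))),
    spacer_mask = purrr::map2(pairs$quals_f, pairs$quals_r,
      ~ c(rep(FALSE, length(.x)), rep(TRUE, params$n_spacer),
          rep(FALSE, length(.y)))),
    overlapped = FALSE,
    overlap_len = 0L
  )
}

#' Reconstruct the spacer mask of a stitched amplicon read back from FASTQ
#'
#' FASTQ cannot carry the in-memory spacer mask, so re-ingested stitched
#' amplicons arrive unmasked. This helper re-masks any run of at least
#' `n_spacer` consecutive `N` bases whose Phred scores all equal
#' `spacer_phred`. Sequencer-called `N`s at other qualities are left
#' unmasked.
#'
#' @param amplicons Amplicon tibble (e.g. [read_fastq()] output augmented
#'   with all-`FALSE` masks, or any table with `sequence` and `quals`).
#' @param params A [stitch_params()].
#' @return The tibble with a rebuilt `spacer_mask` list column.
#' @export
mask_spacer <- function(amplicons, params = stitch_params()) {
  amplicons$spacer_mask <- purrr::map2(
    amplicons$sequence, amplicons$quals,
    function(s, q) {
      mask <- rep(FALSE, nchar(s))
      if (params$n_spacer < 1L) return(mask)
      m <- gregexpr(paste0("N{", params$n_spacer, ",}"), s)[[1L]]
      if (m[1L] != -1L) {
        for (i in seq_along(m)) {
          idx <- m[i]:(m[i] + attr(m, "match.length")[i] - 1L)
          if (all(q[idx] == params$spacer_phred)) mask[idx] <- TRUE
        }
      }
      mask
    }
  )
  amplicons
}
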