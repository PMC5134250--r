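#' Per-base error probability from a Phred score
#'
#' A Phred score `Q` encodes a base-call error probability
#' `P = 10^(-Q/10)`: Q20 is a 1% chance of a miscall, Q2 is 63%.
#'
#' @param q Integer Phred score(s) in \[0, 93\].
#' @return Numeric error probabilities in (0, 1\].
#' @examples
#' phred_error_prob(c(2, 25, 40))
#' @export
phred_error_prob <- function(q) {
  if (any(q < 0 | q > 93)) {
    stop("Phred score out of range [0, 93]: ", q[q < 0 | q > 93][1L],
         call. = FALSE)
  }
  10^(-q / 10)
}

check_mask <- function(phreds, mask) {
  if (is.null(mask)) mask <- rep(FALSE, length(phreds))
  if (length(mask) != length(phreds)) {
    stop("mask length ", length(mask), " != quality length ",
         length(phreds), call. = FALSE)
  }
  if (all(mask) || length(phreds) == 0L) {
    stop("quality metrics need at least one unmasked position", call. = FALSE)
  }
  mask
}

#' Maximum expected error (MEE) of a read
#'
#' The sum of per-base error probabilities over unmasked positions: the
#' expected number of miscalled bases in the read. Masked positions (e.g.
#' the artificial N spacer of a stitched amplicon) are excluded entirely.
#'
#' @param phreds Integer Phred scores.
#' @param mask Optional logical vector, `TRUE` = excluded from the metric.
#' @return Expected number of errors (non-negative numeric scalar).
#' @examples
#' read_mee(rep(25, 100)) # 0.316 expected errors
#' @export
read_mee <- function(phreds, mask = NULL) {
  mask <- check_mask(phreds, mask)
  sum(phred_error_prob(phreds[!mask]))
}

#' meep score: expected errors as a percentage of read length
#'
#' `meep = MEE * 100 / length`, with the length counting unmasked positions
#' only, so a meep cutoff of 1 permits at most one expected error per 100
#' retained bases regardless of amplicon length or spacer content.
#'
#' @inheritParams read_mee
#' @return meep score in percent.
#' @export
meep_score <- function(phreds, mask = NULL) {
  mask <- check_mask(phreds, mask)
  read_mee(phreds, mask) * 100 / sum(!mask)
}

#' Average Phred score of a read
#'
#' Arithmetic mean of the unmasked Phred scores — the traditional quality
#' filter statistic. Note that because Phred is logarithmic, a high average
#' Q can coexist with a large expected error count (see [read_mee()]).
#'
#' @inheritParams read_mee
#' @return Mean Phred score.
#' @export
avg_q <- function(phreds, mask = NULL) {
  mask <- check_mask(phreds, mask)
  mean(phreds[!mask])
}

#' Define a quality filter policy
#'
#' @param mode `"meep"` (pass when meep score is at or below `threshold`,
#'   in percent) or `"avgq"` (pass when the mean Phred score is at or above
#'   `threshold`). Comparisons are inclusive at the threshold.
#' @param threshold Non-negative cutoff; percent for `"meep"`, Phred units
#'   for `"avgq"`. Defaults to 1 for meep and 20 for avgq.
#' @return A `filter_policy` object.
#' @examples
#' filter_policy("meep", 1)
#' filter_policy("avgq", 20)
#' @export
filter_policy <- function(mode = c("meep", "avgq"), threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "meep") 1 else 20
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  structure(list(mode = mode, threshold = threshold),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("<filter_policy> ",
      if (x$mode == "meep") paste0("meep <= ", x$threshold, "%")
      else paste0("avgQ >= ", x$threshold), "\n", sep = "")
  invisible(x)
}

#' Does a read pass a quality filter policy?
#'
#' @inheritParams read_mee
#' @param policy A [filter_policy()].
#' @return `TRUE` or `FALSE`. Scores exactly at the threshold pass.
#' @export
passes_filter <- function(phreds, policy, mask = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  switch(policy$mode,
    avgq = avg_q(phreds, mask) >= policy$threshold,
    meep = meep_score(phreds, mask) <= policy$threshold,
    stop("unknown filter mode: ", policy$mode, call. = FALSE)
  )
}

#' Add quality metrics and a filter verdict to an amplicon table
#'
#' Computes per-amplicon MEE, meep, average Q and unmasked length, honouring
#' each amplicon's spacer mask, and applies `policy` to set `hq`.
#'
#' @param amplicons Tibble with list columns `quals` and `spacer_mask`.
#' @param policy A [filter_policy()].
#' @return The input tibble with columns `unmasked_len`, `mee`, `meep`,
#'   `avg_q`, `hq` appended.
#' @export
score_amplicons <- function(amplicons, policy = filter_policy("meep", 1)) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(amplicons) == 0L) {
    return(dplyr::mutate(amplicons,
      unmasked_len = integer(), mee = numeric(), meep = numeric(),
      avg_q = numeric(), hq = logical()))
  }
  dplyr::mutate(amplicons,
    unmasked_len = purrr::map2_int(.data$quals, .data$spacer_mask,
                                   ~ sum(!.y)),
    mee   = purrr::map2_dbl(.data$quals, .data$spacer_mask, read_mee),
    meep  = purrr::map2_dbl(.data$quals, .data$spacer_mask, meep_score),
    avg_q = purrr::map2_dbl(.data$quals, .data$spacer_mask, avg_q),
    hq    = purrr::map2_lgl(.data$quals, .data$spacer_mask,
                            ~ passes_filter(.x, policy, .y))
  )
}
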