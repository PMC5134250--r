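#' Simulation parameters
#'
#' Controls the paired-end amplicon read simulator. The per-cycle
#' substitution rate follows a 4th-degree polynomial in the cycle index
#' `i`, `a + b * i^e`, mimicking the characteristic MiSeq profile of a low,
#' flat error floor with a steep rise towards cycle 300. With the defaults
#' and percent units the rate is ~0.003% at cycle 1 and ~14.6% at cycle
#' 300.
#'
#' @param read_len Read length in bases per mate (default 300, MiSeq
#'   2x300).
#' @param error_coeff_a Constant term of the polynomial (default 3e-3).
#' @param error_coeff_b Coefficient of the degree term (default 1.8e-9).
#' @param error_exponent Polynomial degree (default 4).
#' @param rate_unit `"percent"` (default: the polynomial value is a
#'   percentage, divided by 100 to give a probability) or `"probability"`.
#' @return A `sim_params` object.
#' @export
sim_params <- function(read_len = 300L, error_coeff_a = 3e-3,
                       error_coeff_b = 1.8e-9, error_exponent = 4L,
                       rate_unit = c("percent", "probability")) {
  rate_unit <- match.arg(rate_unit)
  structure(list(read_len = as.integer(read_len),
                 error_coeff_a = error_coeff_a,
                 error_coeff_b = error_coeff_b,
                 error_exponent = as.integer(error_exponent),
                 rate_unit = rate_unit),
            class = "sim_params")
}

#' Per-cycle substitution probability of the simulator error model
#'
#' @param i 1-based cycle index (vectorised).
#' @param params A [sim_params()].
#' @return Substitution probability per base, clamped to \[0, 0.75\] (0.75
#'   being the uniform-random ceiling for a 4-letter alphabet).
#' @examples
#' error_rate(c(1, 150, 300))
#' @export
error_rate <- function(i, params = sim_params()) {
  stopifnot(all(i >= 1))
  raw <- params$error_coeff_a + params$error_coeff_b * i^params$error_exponent
  p <- if (params$rate_unit == "percent") raw / 100 else raw
  pmin(pmax(p, 0), 0.75)
}

# Phred consistent with the injected error rate, capped to the MiSeq range
sim_phred <- function(i, params) {
  p <- pmax(error_rate(i, params), 1e-9)
  as.integer(pmin(pmax(round(-10 * log10(p)), 2L), 40L))
}

#' Generate random amplicon templates
#'
#' Uniform random ACGT sequences standing in for reference amplicons (e.g.
#' 16S hypervariable regions); pipeline behaviour depends only on template
#' lengths and injected errors, not on real taxonomic sequence content.
#' Deterministic given `seed`.
#'
#' @param lengths Integer template lengths in bases.
#' @param seed RNG seed.
#' @return Tibble with `template_id`, `length`, `sequence`.
#' @export
make_templates <- function(lengths, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      template_id = sprintf("template_%02d_len%d", seq_along(lengths),
                            as.integer(lengths)),
      length = as.integer(lengths),
      sequence = vapply(lengths, function(n)
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
              collapse = ""), character(1L))
    )
  })
}

# substitute bases at given positions with a uniformly random different base
inject_errors <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  chars
}

#' Simulate paired-end reads from amplicon templates
#'
#' Each pair reads the template from both ends: the forward mate is the
#' first `read_len` bases, the reverse mate the reverse complement of the
#' last `read_len` bases. Substitution errors are injected per cycle with
#' probability [error_rate()] (to a uniformly random different base), and
#' the Phred score at cycle `i` is `round(-10 log10(rate_i))`, capped to
#' \[2, 40\], so quality strings are analytically consistent with the
#' injected error process. Indels are not simulated. Fully deterministic
#' given `seed`.
#'
#' @param templates Template tibble from [make_templates()] or
#'   [read_template_fasta()]; every template must be at least `read_len`
#'   long.
#' @param n_pairs_per_template Pairs drawn from each template.
#' @param params A [sim_params()].
#' @param seed RNG seed.
#' @param min_overlap Minimum overlap used to decide the `expect_overlap`
#'   ground truth (`template length <= 2 * read_len - min_overlap`).
#' @return A list with `forward` and `reverse` read tibbles (ready for
#'   [pair_reads()]) and a `truth` tibble (`pair_id`, `template_id`,
#'   `template_len`, `error_positions_f`, `error_positions_r`,
#'   `expect_overlap`).
#' @export
simulate_pairs <- function(templates, n_pairs_per_template = 100L,
                           params = sim_params(), seed = 1L,
                           min_overlap = 10L) {
  L <- params$read_len
  if (any(templates$length < L)) {
    stop("all templates must be at least read_len = ", L, " bases",
         call. = FALSE)
  }
  p_cycle <- error_rate(seq_len(L), params)
  q_cycle <- sim_phred(seq_len(L), params)
  n_tpl <- nrow(templates)
  n_total <- n_tpl * n_pairs_per_template
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_total)
    k <- 0L
    for (t in seq_len(n_tpl)) {
      tpl <- templates$sequence[t]
      tlen <- templates$length[t]
      fwd_tpl <- strsplit(substr(tpl, 1L, L), "", fixed = TRUE)[[1L]]
      rev_tpl <- strsplit(revcomp(substr(tpl, tlen - L + 1L, tlen)), "",
                          fixed = TRUE)[[1L]]
      for (j in seq_len(n_pairs_per_template)) {
        k <- k + 1L
        err_f <- which(stats::runif(L) < p_cycle)
        err_r <- which(stats::runif(L) < p_cycle)
        rows[[k]] <- tibble::tibble(
          pair_id = sprintf("%s_pair%04d", templates$template_id[t], j),
          template_id = templates$template_id[t],
          template_len = tlen,
          seq_f = paste(inject_errors(fwd_tpl, err_f), collapse = ""),
          seq_r = paste(inject_errors(rev_tpl, err_r), collapse = ""),
          error_positions_f = list(err_f),
          error_positions_r = list(err_r),
          expect_overlap = tlen <= 2L * L - as.integer(min_overlap)
        )
      }
    }
    sim <- dplyr::bind_rows(rows)
  })
  list(
    forward = tibble::tibble(read_id = paste0(sim$pair_id, "/1"),
                             sequence = sim$seq_f,
                             quals = rep(list(q_cycle), n_total)),
    reverse = tibble::tibble(read_id = paste0(sim$pair_id, "/2"),
                             sequence = sim$seq_r,
                             quals = rep(list(q_cycle), n_total)),
    truth = sim[, c("pair_id", "template_id", "template_len",
                    "error_positions_f", "error_positions_r",
                    "expect_overlap")]
  )
}

#' Read amplicon templates from a FASTA file
#'
#' @param path FASTA file of template sequences.
#' @return Template tibble (`template_id`, `length`, `sequence`).
#' @export
read_template_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    template_id = sub("\\s.*$", "", names(x)),
    length = Biostrings::width(x),
    sequence = unname(as.character(x))
  )
}

#' Write amplicon templates to a FASTA file
#'
#' @param templates Template tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(templates, path) {
  x <- Biostrings::DNAStringSet(
    stats::setNames(templates$sequence, templates$template_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
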