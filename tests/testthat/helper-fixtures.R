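# Shared fixtures and independent oracles for the test suite.

# random read tibble with arbitrary ids
random_reads <- function(n, len, ids = sprintf("r%03d/1", seq_len(n))) {
  tibble::tibble(
    read_id = ids,
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1L)),
    quals = replicate(n, sample(0:41, len, replace = TRUE),
                      simplify = FALSE)
  )
}

# error-free mates from a template string: forward prefix, RC'd suffix
template_mates <- function(template, read_len, q = 40L, id = "p1") {
  tlen <- nchar(template)
  tibble::tibble(
    pair_id = id,
    seq_f = substr(template, 1L, read_len),
    quals_f = list(rep(q, read_len)),
    seq_r = revcomp(substr(template, tlen - read_len + 1L, tlen)),
    quals_r = list(rep(q, read_len))
  )
}

random_template <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive per-base loop oracle for expected errors (independent of read_mee)
oracle_mee <- function(phreds, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(phreds))
  total <- 0
  for (i in seq_along(phreds)) {
    if (!mask[i]) total <- total + 10^(-phreds[i] / 10)
  }
  total
}

# exhaustive brute-force overlap scorer, independent of find_best_overlap:
# enumerates every overlap length via substring comparison
oracle_best_overlap <- function(seq_f, seq_r_rc, min_overlap,
                                max_mismatch_frac) {
  nf <- nchar(seq_f)
  nr <- nchar(seq_r_rc)
  best <- NULL
  for (len in seq_len(min(nf, nr))) {
    if (len < min_overlap) next
    a <- substr(seq_f, nf - len + 1L, nf)
    b <- substr(seq_r_rc, 1L, len)
    mm <- sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
    if (mm / len > max_mismatch_frac) next
    if (is.null(best) || mm / len < best$rate ||
        (mm / len == best$rate && len > best$len)) {
      best <- list(len = len, mm = mm, rate = mm / len)
    }
  }
  best
}
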