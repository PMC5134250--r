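#' Merge parameters
#'
#' Tuning knobs of the context-aware merger. The defaults follow the
#' upstream context-aware paired-end merging scheme: a minimum overlap of
#' 10 bases, at most a 20% mismatch rate within the overlap, a Phred
#' difference of 19 before a quality call alone resolves a mismatch, and
#' 17-mers for the context vote.
#'
#' @param min_overlap Minimum acceptable overlap length in bases (>= 1).
#' @param max_mismatch_frac Maximum mismatch rate (mismatches / overlap
#'   length) for an overlap to be accepted, in \[0, 1\].
#' @param qdiff_threshold Phred difference at or above which the
#'   higher-quality base wins a mismatch outright.
#' @param kmer_size Odd k (>= 3) for the context vote.
#' @return A `merge_params` object.
#' @export
merge_params <- function(min_overlap = 10L, max_mismatch_frac = 0.2,
                         qdiff_threshold = 19L, kmer_size = 17L) {
  min_overlap <- as.integer(min_overlap)
  kmer_size <- as.integer(kmer_size)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  if (max_mismatch_frac < 0 || max_mismatch_frac > 1) {
    stop("max_mismatch_frac must be in [0, 1]", call. = FALSE)
  }
  if (kmer_size < 3L || kmer_size %% 2L == 0L) {
    stop("kmer_size must be odd and >= 3", call. = FALSE)
  }
  structure(list(min_overlap = min_overlap,
                 max_mismatch_frac = max_mismatch_frac,
                 qdiff_threshold = as.integer(qdiff_threshold),
                 kmer_size = kmer_size),
            class = "merge_params")
}

canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Build a dataset-wide k-mer count table
#'
#' Counts every k-mer of the supplied sequences (forward reads plus
#' reverse-complemented reverse reads, so both mates contribute in amplicon
#' orientation). k-mers containing `N` are skipped; counts are keyed by the
#' canonical form (the lexicographic minimum of a k-mer and its reverse
#' complement). These dataset-scope frequencies arbitrate overlap
#' mismatches whose quality scores are too close to call.
#'
#' @param sequences Character vector of DNA sequences.
#' @param k k-mer size; must not exceed the shortest sequence.
#' @return A `kmer_table`: named integer counts with attribute `k`.
#' @examples
#' build_kmer_table("AAAA", k = 3) # {"AAA": 2}
#' @export
build_kmer_table <- function(sequences, k) {
  k <- as.integer(k)
  sequences <- sequences[!is.na(sequences)]
  if (length(sequences) > 0L && k > min(nchar(sequences))) {
    stop("k = ", k, " exceeds the shortest sequence (",
         min(nchar(sequences)), " bases)", call. = FALSE)
  }
  kmers <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    substring(s, 1L:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  counts <- if (length(kmers) == 0L) {
    integer(0)
  } else {
    tab <- table(canonical_kmer(kmers))
    stats::setNames(as.integer(tab), names(tab))
  }
  structure(counts, k = k, class = "kmer_table")
}

kmer_count <- function(table, kmers) {
  if (length(kmers) == 0L) return(integer(0))
  v <- unclass(table)[canonical_kmer(kmers)]
  v[is.na(v)] <- 0L
  as.integer(v)
}

#' Find the best overlap between a forward read and an RC'd reverse read
#'
#' Scans every "inward" offset where a suffix of the forward read aligns to
#' a prefix of the reverse-complemented reverse read, with overlap lengths
#' between `min_overlap` and the shorter read. The best candidate minimises
#' the mismatch rate (count / overlap length), ties going to the longer
#' overlap; it is returned only if its rate is within `max_mismatch_frac`.
#'
#' @param seq_f Forward read sequence.
#' @param seq_r_rc Reverse read sequence, already reverse-complemented.
#' @param params A [merge_params()].
#' @return A list with `overlap_len`, `mismatch_count` and
#'   `mismatch_positions` (1-based within the overlap), or `NULL` when no
#'   acceptable overlap exists (a valid outcome, not an error).
#' @export
find_best_overlap <- function(seq_f, seq_r_rc, params = merge_params()) {
  f <- strsplit(seq_f, "", fixed = TRUE)[[1L]]
  r <- strsplit(seq_r_rc, "", fixed = TRUE)[[1L]]
  nf <- length(f)
  nr <- length(r)
  lmax <- min(nf, nr)
  if (lmax < params$min_overlap) return(NULL)
  best <- NULL
  best_rate <- Inf
  for (len in params$min_overlap:lmax) {
    mm <- which(f[(nf - len + 1L):nf] != r[1L:len])
    rate <- length(mm) / len
    # strict < keeps the longest overlap among equal rates (lengths ascend)
    if (rate <= params$max_mismatch_frac &&
        (is.null(best) || rate < best_rate ||
         (rate == best_rate && len > best$overlap_len))) {
      best <- list(overlap_len = len, mismatch_count = length(mm),
                   mismatch_positions = mm)
      best_rate <- rate
    }
  }
  best
}

# Context vote for one disputed column: sum the counts of every k-mer of the
# tentatively merged sequence that spans position pos with `base`
# substituted. k-mers running past the ends or containing N are skipped.
context_vote <- function(merged_chars, pos, base, table) {
  k <- attr(table, "k")
  merged_chars[pos] <- base
  n <- length(merged_chars)
  starts <- max(1L, pos - k + 1L):min(pos, n - k + 1L)
  starts <- starts[starts >= 1L & starts + k - 1L <= n]
  if (length(starts) == 0L) return(0L)
  kmers <- vapply(starts, function(s)
    paste(merged_chars[s:(s + k - 1L)], collapse = ""), character(1L))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  sum(kmer_count(table, kmers))
}

#' Resolve one disputed overlap column
#'
#' When the two mates disagree, a large quality gap (>= `qdiff_threshold`)
#' lets the higher-quality base replace the lower-quality one outright.
#' Otherwise the decision falls to the k-mer context: each candidate base is
#' substituted into the tentatively merged sequence and the candidate whose
#' spanning k-mers are more frequent dataset-wide wins. Remaining ties go
#' to the higher Phred, then to the forward base. An `N` always loses to a
#' called base. The chosen base keeps its own Phred score.
#'
#' @param base_f,base_r Disagreeing bases (single characters).
#' @param q_f,q_r Their Phred scores.
#' @param merged_chars Character vector of the tentatively merged sequence.
#' @param pos Position of the disputed column within `merged_chars`.
#' @param table A [build_kmer_table()] result.
#' @param params A [merge_params()].
#' @return List with `base` and `qual`.
#' @export
resolve_mismatch <- function(base_f, q_f, base_r, q_r, merged_chars, pos,
                             table, params = merge_params()) {
  if (base_f == "N" && base_r != "N") return(list(base = base_r, qual = q_r))
  if (base_r == "N" && base_f != "N") return(list(base = base_f, qual = q_f))
  if (abs(q_f - q_r) >= params$qdiff_threshold) {
    return(if (q_f >= q_r) list(base = base_f, qual = q_f)
           else list(base = base_r, qual = q_r))
  }
  vote_f <- context_vote(merged_chars, pos, base_f, table)
  vote_r <- context_vote(merged_chars, pos, base_r, table)
  if (vote_f > vote_r) return(list(base = base_f, qual = q_f))
  if (vote_r > vote_f) return(list(base = base_r, qual = q_r))
  if (q_f > q_r) return(list(base = base_f, qual = q_f))
  if (q_r > q_f) return(list(base = base_r, qual = q_r))
  list(base = base_f, qual = q_f)
}

# Merge one pair; returns a one-row amplicon tibble or NULL if no overlap.
merge_one <- function(pair_id, seq_f, quals_f, seq_r, quals_r, table,
                      params) {
  seq_r_rc <- revcomp(seq_r)
  quals_r_rc <- rev(quals_r)
  ov <- find_best_overlap(seq_f, seq_r_rc, params)
  if (is.null(ov)) return(NULL)
  f <- strsplit(seq_f, "", fixed = TRUE)[[1L]]
  r <- strsplit(seq_r_rc, "", fixed = TRUE)[[1L]]
  nf <- length(f)
  nr <- length(r)
  len <- ov$overlap_len
  f_idx <- (nf - len + 1L):nf           # overlap columns in forward read
  # agreeing columns: the agreed base at max(q_f, q_r); provisional call at
  # disputed columns is the higher-quality base (fwd on ties) and is then
  # revisited column by column via resolve_mismatch()
  ov_q_f <- quals_f[f_idx]
  ov_q_r <- quals_r_rc[1L:len]
  ov_base <- ifelse(ov_q_f >= ov_q_r, f[f_idx], r[1L:len])
  ov_qual <- pmax(ov_q_f, ov_q_r)
  merged <- c(f[seq_len(nf - len)], ov_base, r[(len + 1L):nr][seq_len(nr - len)])
  quals <- c(quals_f[seq_len(nf - len)], ov_qual,
             quals_r_rc[(len + 1L):nr][seq_len(nr - len)])
  for (j in ov$mismatch_positions) {
    pos <- nf - len + j
    res <- resolve_mismatch(f[f_idx[j]], ov_q_f[j], r[j], ov_q_r[j],
                            merged, pos, table, params)
    merged[pos] <- res$base
    quals[pos] <- res$qual
  }
  tibble::tibble(
    read_id = pair_id,
    sequence = paste(merged, collapse = ""),
    quals = list(as.integer(quals)),
    spacer_mask = list(rep(FALSE, length(merged))),
    overlapped = TRUE,
    overlap_len = len
  )
}

#' Merge overlapping read pairs
#'
#' Reverse-complements each reverse mate, finds the best overlap with its
#' forward mate and builds the merged amplicon: outside the overlap each
#' mate contributes its own bases; inside it, agreeing columns take the
#' agreed base at the higher of the two Phred scores and disagreeing
#' columns are settled by [resolve_mismatch()]. Pairs without an acceptable
#' overlap are reported with `overlapped = FALSE` and `NA` sequence so the
#' caller can stitch or discard them.
#'
#' @param pairs Pair tibble from [pair_reads()] or [simulate_pairs()].
#' @param table Optional [build_kmer_table()] result; built from the pairs
#'   themselves (both mates, amplicon orientation) when `NULL`.
#' @param params A [merge_params()].
#' @return Amplicon tibble: `read_id`, `sequence`, `quals`, `spacer_mask`,
#'   `overlapped`, `overlap_len`, one row per input pair, input order.
#' @export
merge_pairs <- function(pairs, table = NULL, params = merge_params()) {
  if (is.null(table)) {
    table <- build_kmer_table(c(pairs$seq_f, revcomp(pairs$seq_r)),
                              params$kmer_size)
  }
  rows <- purrr::pmap(
    list(pairs$pair_id, pairs$seq_f, pairs$quals_f,
         pairs$seq_r, pairs$quals_r),
    function(id, sf, qf, sr, qr) {
      m <- merge_one(id, sf, qf, sr, qr, table, params)
      if (is.null(m)) {
        tibble::tibble(read_id = id, sequence = NA_character_,
                       quals = list(NULL), spacer_mask = list(NULL),
                       overlapped = FALSE, overlap_len = 0L)
      } else {
        m
      }
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(read_id = character(), sequence = character(),
                          quals = list(), spacer_mask = list(),
                          overlapped = logical(), overlap_len = integer())
  }
  out
}
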