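#' Read a FASTQ file into a tibble of reads
#'
#' Parses a plain or gzip-compressed 4-line FASTQ file. Each record becomes a
#' row with the read identifier (the `@` stripped), the uppercased base
#' sequence, and the decoded per-base Phred scores as an integer vector in a
#' list column. Quality character `c` decodes to `utf8ToInt(c) - offset`.
#'
#' @param path Path to a FASTQ file; `.gz` suffixes are opened transparently.
#' @param offset Quality encoding offset (default 33, Sanger / modern
#'   Illumina).
#' @return A tibble with columns `read_id` (character), `sequence`
#'   (character) and `quals` (list of integer vectors).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path, call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble::tibble(
      read_id = character(), sequence = character(), quals = list()
    ))
  }
  if (length(lines) %% 4L != 0L) {
    stop("Malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  }
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seqs  <- lines[seq(2L, length(lines), by = 4L)]
  plus  <- lines[seq(3L, length(lines), by = 4L)]
  qstrs <- lines[seq(4L, length(lines), by = 4L)]
  bad_head <- which(!startsWith(heads, "@"))
  if (length(bad_head) > 0L) {
    stop("Malformed FASTQ record ", bad_head[1L], " in '", path,
         "': header does not start with '@'", call. = FALSE)
  }
  if (any(!startsWith(plus, "+"))) {
    stop("Malformed FASTQ '", path, "': separator line missing '+'",
         call. = FALSE)
  }
  ids <- substring(heads, 2L)
  seqs <- toupper(seqs)
  bad_len <- which(nchar(seqs) != nchar(qstrs))
  if (length(bad_len) > 0L) {
    stop("Malformed FASTQ record '", ids[bad_len[1L]], "' in '", path,
         "': sequence length ", nchar(seqs[bad_len[1L]]),
         " != quality length ", nchar(qstrs[bad_len[1L]]), call. = FALSE)
  }
  quals <- lapply(qstrs, function(q) utf8ToInt(q) - as.integer(offset))
  rng <- range(unlist(quals, use.names = FALSE), 0L)
  if (rng[1L] < 0L || rng[2L] > 93L) {
    stop("Phred score outside [0, 93] after decoding '", path,
         "' with offset ", offset,
         "; is the quality encoding offset correct?", call. = FALSE)
  }
  tibble::tibble(read_id = ids, sequence = seqs, quals = quals)
}

#' Write a tibble of reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, f), offset)` is the
#' identity on any valid read table.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quals`.
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @param offset Quality encoding offset (default 33).
#' @return The number of records written, invisibly.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  stopifnot(all(c("read_id", "sequence", "quals") %in% names(reads)))
  qall <- unlist(reads$quals, use.names = FALSE)
  if (length(qall) > 0L && (min(qall) < 0L || max(qall) > 93L)) {
    stop("Phred scores must be in [0, 93] to encode as FASTQ", call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  n <- nrow(reads)
  if (n > 0L) {
    qstr <- vapply(reads$quals, function(q) intToUtf8(q + as.integer(offset)),
                   character(1L))
    out <- character(4L * n)
    out[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$read_id)
    out[seq(2L, 4L * n, by = 4L)] <- reads$sequence
    out[seq(3L, 4L * n, by = 4L)] <- "+"
    out[seq(4L, 4L * n, by = 4L)] <- qstr
    writeLines(out, con)
  }
  invisible(n)
}

#' Reverse-complement DNA sequences
#'
#' Vectorised over character strings of `A`, `C`, `G`, `T`, `N`.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "AAAN"))
#' @export
revcomp <- function(sequence) {
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("Non-ACGTN character in sequence: '", sequence[bad][1L], "'",
         call. = FALSE)
  }
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", sequence))
}

#' Reverse-complement a read table
#'
#' Complements and reverses each sequence and reverses the matching quality
#' vector, so base-to-quality correspondence is preserved. Applying it twice
#' returns the original table.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quals`.
#' @return Tibble of the same shape.
#' @export
reverse_complement_reads <- function(reads) {
  reads$sequence <- revcomp(reads$sequence)
  reads$quals <- lapply(reads$quals, rev)
  reads
}

# Identifier stem: first whitespace token with a trailing /1 or /2 removed.
# Handles both classic "/1" suffixes and Casava 1.8 "id 1:N:0:..." comments.
read_id_stem <- function(read_id) {
  stem <- sub("\\s.*$", "", read_id)
  sub("/[12]$", "", stem)
}

#' Pair forward and reverse read tables positionally
#'
#' Mate files from Illumina instruments are order-synchronised, so pairing is
#' positional; identifier stems (ids with `/1`, `/2` or Casava comment fields
#' stripped) are verified row by row and any disagreement is a hard error.
#'
#' @param fwd,rev Read tibbles from [read_fastq()].
#' @return A tibble of pairs with columns `pair_id`, `seq_f`, `quals_f`,
#'   `seq_r`, `quals_r`.
#' @export
pair_reads <- function(fwd, rev) {
  if (nrow(fwd) != nrow(rev)) {
    stop("Unequal mate counts: ", nrow(fwd), " forward vs ", nrow(rev),
         " reverse reads", call. = FALSE)
  }
  stem_f <- read_id_stem(fwd$read_id)
  stem_r <- read_id_stem(rev$read_id)
  bad <- which(stem_f != stem_r)
  if (length(bad) > 0L) {
    stop("Mate identifier mismatch at record ", bad[1L], ": '",
         fwd$read_id[bad[1L]], "' vs '", rev$read_id[bad[1L]], "'",
         call. = FALSE)
  }
  tibble::tibble(
    pair_id = stem_f,
    seq_f = fwd$sequence, quals_f = fwd$quals,
    seq_r = rev$sequence, quals_r = rev$quals
  )
}
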