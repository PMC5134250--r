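test_that("k-mer tables canonicalise and skip N-containing k-mers", {
  t1 <- build_kmer_table("AAAA", 3)
  expect_equal(unclass(t1)[["AAA"]], 2L) # TTT canonicalises onto AAA
  expect_length(build_kmer_table("ANA", 3), 0)
  expect_length(build_kmer_table(character(0), 3), 0)
  expect_error(build_kmer_table(c("ACGTACGT", "ACG"), 5), "shortest")

  # a k-mer and its reverse complement accumulate in one bucket
  t2 <- build_kmer_table(c("ACGTT", revcomp("ACGTT")), 5)
  expect_equal(unclass(t2)[["AACGT"]], 2L)
})

test_that("best overlap minimises mismatch rate over all inward offsets", {
  ov <- find_best_overlap("ACGTACGTAA", "ACGTAAGGGG",
                          merge_params(min_overlap = 4))
  expect_equal(ov$overlap_len, 6)
  expect_equal(ov$mismatch_count, 0)

  # unrelated sequences: no candidate within the mismatch budget
  expect_null(find_best_overlap(strrep("A", 40), strrep("C", 40),
                                merge_params()))
  # reads shorter than min_overlap cannot overlap
  expect_null(find_best_overlap("ACGT", "ACGT", merge_params()))
})

test_that("overlap search agrees with the brute-force oracle", {
  set.seed(42)
  params <- merge_params(min_overlap = 5, max_mismatch_frac = 0.2)
  n_with_overlap <- 0
  for (i in 1:200) {
    # half the cases share a true overlap, half are unrelated
    if (i %% 2 == 0) {
      tpl <- random_template(sample(30:60, 1))
      len <- sample(20:min(35, nchar(tpl)), 1)
      f <- substr(tpl, 1, len)
      r <- substr(tpl, nchar(tpl) - len + 1, nchar(tpl))
    } else {
      f <- random_template(sample(20:60, 1))
      r <- random_template(sample(20:60, 1))
    }
    got <- find_best_overlap(f, r, params)
    want <- oracle_best_overlap(f, r, 5, 0.2)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_with_overlap <- n_with_overlap + 1
      expect_equal(got$overlap_len, want$len)
      expect_equal(got$mismatch_count, want$mm)
    }
  }
  expect_gt(n_with_overlap, 50) # the comparison exercised real overlaps
})

test_that("a large quality gap resolves a mismatch towards the high score", {
  tbl <- build_kmer_table(character(0), 3)
  ctx <- strsplit("ACGTACG", "")[[1]]
  r <- resolve_mismatch("A", 40L, "C", 10L, ctx, 4, tbl,
                        merge_params(kmer_size = 3))
  expect_equal(r, list(base = "A", qual = 40L))
  r2 <- resolve_mismatch("A", 10L, "C", 40L, ctx, 4, tbl,
                         merge_params(kmer_size = 3))
  expect_equal(r2, list(base = "C", qual = 40L))
  # inclusive at the threshold: a gap of exactly qdiff_threshold decides
  r3 <- resolve_mismatch("A", 29L, "C", 10L, ctx, 4, tbl,
                         merge_params(kmer_size = 3, qdiff_threshold = 19))
  expect_equal(r3$base, "A")
})

test_that("near-tie qualities fall back to the k-mer context vote", {
  params <- merge_params(kmer_size = 3)
  # dataset where the 'A'-context spans are far more frequent
  tbl <- build_kmer_table(c(rep("GGAGG", 12), rep("GGCGG", 3)), 3)
  ctx <- strsplit("GGAGG", "")[[1]]
  r <- resolve_mismatch("A", 30L, "C", 30L, ctx, 3, tbl, params)
  expect_equal(r$base, "A")
  rr <- resolve_mismatch("C", 30L, "A", 30L, ctx, 3, tbl, params)
  expect_equal(rr$base, "A") # vote is orientation-independent

  # empty table: tie falls to higher Phred, then the forward base
  empty <- build_kmer_table(character(0), 3)
  expect_equal(resolve_mismatch("A", 30L, "C", 31L, ctx, 3, empty,
                                params)$base, "C")
  expect_equal(resolve_mismatch("A", 30L, "C", 30L, ctx, 3, empty,
                                params)$base, "A")
  # N always loses to a called base, whatever the qualities
  expect_equal(resolve_mismatch("N", 40L, "C", 2L, ctx, 3, empty,
                                params)$base, "C")
  expect_equal(resolve_mismatch("G", 2L, "N", 40L, ctx, 3, empty,
                                params)$base, "G")
})

test_that("error-free mates reconstruct the template exactly", {
  set.seed(21)
  for (tlen in c(450, 471, 540, 590)) {
    tpl <- random_template(tlen)
    pairs <- template_mates(tpl, 300)
    m <- merge_pairs(pairs)
    expect_true(m$overlapped)
    expect_equal(m$sequence, tpl)
    expect_equal(m$overlap_len, 600 - tlen)
    expect_equal(lengths(m$quals), tlen)
    expect_false(any(m$spacer_mask[[1]]))
  }
})

test_that("mates from an over-long template do not merge", {
  set.seed(22)
  pairs <- template_mates(random_template(650), 300)
  m <- merge_pairs(pairs)
  expect_false(m$overlapped)
  expect_true(is.na(m$sequence))
  expect_equal(m$overlap_len, 0)
})

test_that("merged pairs satisfy the length identity and quality floor", {
  set.seed(23)
  tpl <- random_template(80)
  pairs <- template_mates(tpl, 50, q = 30L)
  # perturb qualities, keep sequences agreeing
  pairs$quals_f[[1]] <- sample(10:40, 50, replace = TRUE)
  pairs$quals_r[[1]] <- sample(10:40, 50, replace = TRUE)
  m <- merge_pairs(pairs)
  expect_equal(nchar(m$sequence), 50 + 50 - m$overlap_len)
  # overlap qualities are the per-column max of the two mates
  len <- m$overlap_len
  qf <- pairs$quals_f[[1]][(50 - len + 1):50]
  qr <- rev(pairs$quals_r[[1]])[1:len]
  expect_equal(m$quals[[1]][(50 - len + 1):50], pmax(qf, qr))
})

test_that("a single injected overlap mismatch takes the high-quality base", {
  set.seed(24)
  tpl <- random_template(450)
  pairs <- template_mates(tpl, 300, q = 40L)
  # corrupt one overlap base of the reverse mate and drop its quality:
  # template position 300 is overlap column 150, reverse-read position
  # (after RC) 149 -> raw reverse read position 300 - 149 = 151... work on
  # the RC'd strand then flip back
  rc <- strsplit(revcomp(pairs$seq_r), "")[[1]]
  pos_rc <- 150 # position within RC'd reverse read = template position 300
  truth <- rc[pos_rc]
  rc[pos_rc] <- setdiff(c("A", "C", "G", "T"), truth)[1]
  pairs$seq_r <- revcomp(paste(rc, collapse = ""))
  q <- rep(40L, 300)
  q[301 - pos_rc] <- 10L # same base on the raw strand
  pairs$quals_r <- list(q)
  m <- merge_pairs(pairs)
  expect_true(m$overlapped)
  expect_equal(m$sequence, tpl) # high-quality forward base wins
})

test_that("merging is deterministic", {
  set.seed(25)
  tpl <- random_template(460)
  pairs <- dplyr::bind_rows(template_mates(tpl, 300, id = "a"),
                            template_mates(random_template(470), 300,
                                           id = "b"))
  m1 <- merge_pairs(pairs)
  m2 <- merge_pairs(pairs)
  expect_identical(m1, m2)
})
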