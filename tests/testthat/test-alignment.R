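test_that("local alignment handles identity, all-mismatch and empty input", {
  sc <- scoring_params(match = 2)
  al <- local_align("ACGTACGTAC", "ACGTACGTAC", sc)
  expect_identical(al$score, 20L)
  expect_identical(al$cigar, "10M")
  expect_identical(al$pos_in_window, 0L)
  al <- local_align("AAAA", "TTTT", scoring_params())
  expect_identical(al$score, 0L)
  expect_true(is.na(al$pos_in_window))
  expect_true(is.na(al$cigar))
  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("banded local scores equal a full-matrix oracle when the band covers", {
  set.seed(301)
  sc <- scoring_params(band_width = 128)
  for (i in 1:60) {
    r <- rand_dna(sample(20:100, 1))
    w <- rand_dna(sample(20:100, 1))
    expect_identical(local_align(r, w, sc)$score,
                     as.integer(oracle_local_score(r, w, sc)),
                     label = paste("pair", i))
  }
})

test_that("semi-global alignment finds exact interior matches and minimal edits", {
  set.seed(302)
  w <- rand_dna(200)
  r <- substr(w, 51, 110)
  al <- semiglobal_align(r, w)
  expect_identical(al$edits, 0L)
  expect_identical(al$pos_in_window, 50L)
  expect_identical(al$cigar, "60M")
  expect_error(semiglobal_align(rand_dna(50), rand_dna(20)), "shorter")
  expect_error(semiglobal_align("", rand_dna(20)), "non-empty")
  # random instances vs an independent sliding edit-distance oracle
  sc <- scoring_params(band_width = 128)
  for (i in 1:60) {
    L <- sample(15:60, 1)
    r <- rand_dna(L); w <- rand_dna(L + sample(0:80, 1))
    expect_identical(semiglobal_align(r, w, sc)$edits,
                     as.integer(oracle_infix_edits(r, w)),
                     label = paste("pair", i))
  }
})

test_that("seed ranking orders by independently recomputed window scores", {
  set.seed(303)
  g <- rand_dna(4000)
  idx <- make_index(g)
  sc <- scoring_params()
  # singleton
  read <- substr(g, 101, 160)
  seeds <- find_mem_seeds(idx, read, 19)
  ranked <- rank_seeds(idx, read, seeds, sc, top_n = 8)
  expect_identical(nrow(ranked), nrow(seeds))
  expect_false(any(is.na(ranked$rank_score)))
  # empty in, empty out
  empty <- rank_seeds(idx, read, find_mem_seeds(idx, strrep("N", 60), 19), sc)
  expect_identical(nrow(empty), 0L)
  # multi-seed reads: scores recomputed with the oracle sort identically
  for (trial in 1:10) {
    p <- sample(3900, 2)
    read <- paste0(substr(g, p[1], p[1] + 29), substr(g, p[2], p[2] + 29))
    seeds <- find_kmer_seeds(idx, read, 13)
    ranked <- rank_seeds(idx, read, seeds, sc, top_n = 5)
    expect_lte(nrow(ranked), 5)
    expect_true(all(diff(ranked$rank_score) <= 0))
    rc <- revcomp(read)
    for (i in seq_len(nrow(ranked))) {
      oriented <- if (ranked$strand[i] == "+") read else rc
      win <- substr(idx$sequence, ranked$win_start[i] + 1, ranked$win_end[i])
      expect_identical(ranked$rank_score[i],
                       as.integer(oracle_local_score(oriented, win, sc)))
    }
  }
})

test_that("qualification thresholds are inclusive and stage-dependent", {
  qp <- qual_params(min_score_fraction = 0.3, min_coverage_fraction = 0.8,
                    max_edit_fraction = 0.1)
  sc <- scoring_params()  # match = +1
  mk <- function(stage, score = 0L, aligned = 0L, edits = 0L) {
    list(stage = stage, score = score, aligned_bases = aligned, edits = edits)
  }
  # perfect full-length local alignment qualifies for any fractions <= 1
  expect_true(is_qualified(mk("LOCAL", 100L, 100L), 100, qp, sc))
  # boundary: score exactly at threshold passes
  expect_true(is_qualified(mk("LOCAL", 30L, 80L), 100, qp, sc))
  expect_false(is_qualified(mk("LOCAL", 29L, 80L), 100, qp, sc))
  expect_false(is_qualified(mk("LOCAL", 30L, 79L), 100, qp, sc))
  # zero score never qualifies for a positive fraction
  expect_false(is_qualified(mk("LOCAL", 0L, 100L), 100, qp, sc))
  # semi-global and rescue stages qualify on edit fraction, inclusively
  expect_true(is_qualified(mk("SEMIGLOBAL", edits = 10L), 100, qp, sc))
  expect_false(is_qualified(mk("SEMIGLOBAL", edits = 11L), 100, qp, sc))
  expect_true(is_qualified(mk("MATE_RESCUE", edits = 10L), 100, qp, sc))
  expect_error(is_qualified(mk("UNALIGNED"), 100, qp, sc))
})

test_that("error-free planted reads align perfectly at their locus", {
  set.seed(304)
  g <- rand_dna(20000)
  idx <- make_index(g, "chr1")
  for (i in 1:10) {
    p <- sample(19000, 1)
    read <- substr(g, p + 1, p + 100)
    rec <- align_single(read, idx)
    expect_identical(rec$stage, "LOCAL")
    expect_true(rec$qualified)
    expect_identical(rec$pos, p)
    expect_identical(rec$cigar, "100M")
    expect_identical(rec$strand, "+")
    # and from the reverse strand
    rec <- align_single(revcomp(read), idx)
    expect_identical(rec$pos, p)
    expect_identical(rec$strand, "-")
    expect_identical(rec$cigar, "100M")
  }
})

test_that("substituted reads score exactly as the oracle on the true window", {
  set.seed(305)
  g <- rand_dna(20000)
  idx <- make_index(g)
  sc <- scoring_params()
  for (i in 1:10) {
    p <- sample(19000, 1)
    read <- substr(g, p + 1, p + 100)
    pos <- sample(5:95, 2)
    for (q in pos) {
      substr(read, q, q) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read, q, q))[1]
    }
    rec <- align_single(read, idx, sc)
    expect_true(rec$qualified)
    win <- substr(g, max(1, p - 40), min(nchar(g), p + 140))
    expect_identical(rec$score, as.integer(oracle_local_score(read, win, sc)))
  }
})

test_that("reads with no qualifying window anywhere are reported unaligned", {
  set.seed(306)
  g <- rand_dna(2000)
  idx <- make_index(g)
  sc <- scoring_params()
  qp <- qual_params()
  checked <- 0L
  for (i in 1:5) {
    read <- rand_dna(100)
    # exhaustive whole-genome oracle: does any window reach the threshold?
    best <- max(oracle_local_score(read, g, sc),
                oracle_local_score(revcomp(read), g, sc))
    if (best < qp$min_score_fraction * sc$match * 100) {
      rec <- align_single(read, idx, sc, qp)
      expect_identical(rec$stage, "UNALIGNED")
      expect_false(rec$qualified)
      expect_true(is.na(rec$pos))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 3L)  # random non-genomic reads rarely reach threshold
})

test_that("CIGAR strings conserve read length on every aligned record", {
  set.seed(307)
  g <- rand_dna(30000)
  idx <- make_index(g)
  cigar_read_len <- function(cigar) {
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
    sum(lens[ops %in% c("M", "I", "S")])
  }
  for (i in 1:40) {
    p <- sample(29000, 1)
    read <- substr(g, p + 1, p + sample(60:120, 1))
    # random corruption: substitutions, sometimes a small indel
    nmut <- sample(0:6, 1)
    for (q in sample(nchar(read) - 2, nmut)) {
      substr(read, q, q) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (i %% 4 == 0) {
      cut <- sample(10:40, 1)
      read <- paste0(substr(read, 1, cut), substr(read, cut + 3, nchar(read)))
    }
    rec <- align_single(read, idx)
    if (rec$stage != "UNALIGNED") {
      expect_identical(cigar_read_len(rec$cigar), nchar(read),
                       label = paste("trial", i))
    }
  }
})

test_that("the pipeline is deterministic and monotone in the score threshold", {
  set.seed(308)
  g <- rand_dna(10000)
  idx <- make_index(g)
  reads <- lapply(1:15, function(i) {
    p <- sample(9000, 1)
    r <- substr(g, p + 1, p + 100)
    for (q in sample(98, sample(0:25, 1))) {
      substr(r, q, q) <- sample(c("A", "C", "G", "T"), 1)
    }
    r
  })
  a <- lapply(reads, align_single, index = idx)
  b <- lapply(reads, align_single, index = idx)
  expect_identical(a, b)
  # raising min_score_fraction never converts UNALIGNED to aligned
  for (msf in c(0.3, 0.5, 0.7, 0.9)) {
    qp_lo <- qual_params(min_score_fraction = msf)
    for (r in reads) {
      lo <- align_single(r, idx, qp = qp_lo)
      if (lo$stage == "UNALIGNED") {
        hi <- align_single(r, idx,
                           qp = qual_params(min_score_fraction =
                                              min(1, msf + 0.2)))
        expect_identical(hi$stage, "UNALIGNED")
      }
    }
  }
})
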