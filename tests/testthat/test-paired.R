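test_that("seed pairing equals a brute-force filter over all combinations", {
  set.seed(401)
  g <- rand_dna(20000)
  idx <- make_index(g)
  sc <- scoring_params()
  qp <- qual_params(insert_min = 100, insert_max = 500)
  # single compatible pair at an in-range distance
  pp <- .plant_pair(g, 2000, 300)
  r1 <- rank_seeds(idx, pp$r1$seq, find_mem_seeds(idx, pp$r1$seq, 19), sc, 8)
  r2 <- rank_seeds(idx, pp$r2$seq, find_mem_seeds(idx, pp$r2$seq, 19), sc, 8)
  pairs <- pair_seeds(r1, r2, qp)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$implied_insert, 300L)
  # same geometry but an out-of-range insert: empty
  far <- .plant_pair(g, 2000, 900)
  f2 <- rank_seeds(idx, far$r2$seq, find_mem_seeds(idx, far$r2$seq, 19), sc, 8)
  expect_identical(nrow(pair_seeds(r1, f2, qp)), 0L)
  # randomized top-8 x top-8 sets vs exhaustive enumeration
  for (trial in 1:10) {
    p <- sample(15000, 2)
    s1 <- paste0(substr(g, p[1], p[1] + 39), substr(g, p[2], p[2] + 39))
    s2 <- revcomp(substr(g, p[1] + 200, p[1] + 279))
    k1 <- rank_seeds(idx, s1, find_kmer_seeds(idx, s1, 13), sc, 8)
    k2 <- rank_seeds(idx, s2, find_kmer_seeds(idx, s2, 13), sc, 8)
    got <- pair_seeds(k1, k2, qp)
    # brute force over all combinations
    want <- 0L
    for (i in seq_len(nrow(k1))) {
      for (j in seq_len(nrow(k2))) {
        if (k1$strand[i] == k2$strand[j]) next
        p1 <- k1$genome_pos[i] - k1$read_offset[i]
        p2 <- k2$genome_pos[j] - k2$read_offset[j]
        if (k1$strand[i] == "+") {
          ins <- (p2 + nchar(s2)) - p1
        } else {
          ins <- (p1 + nchar(s1)) - p2
        }
        if (ins >= 100 && ins <= 500) want <- want + 1L
      }
    }
    expect_identical(nrow(got), want, label = paste("trial", trial))
    if (nrow(got) > 1) {
      expect_true(all(diff(got$pair_weight) <= 0))
    }
  }
})

test_that("planted FR pairs map as proper pairs at their loci", {
  set.seed(402)
  g <- rand_dna(50000)
  idx <- make_index(g, "chr1")
  for (trial in 1:8) {
    fpos <- sample(40000, 1)
    ins <- sample(150:450, 1)
    pp <- .plant_pair(g, fpos, ins)
    res <- align_paired(pp$r1, pp$r2, idx)
    expect_true(res$proper)
    expect_true(res$rec1$qualified && res$rec2$qualified)
    expect_identical(res$rec1$stage, "LOCAL")
    expect_identical(res$rec1$pos, pp$pos1)
    expect_identical(res$rec2$pos, pp$pos2)
    expect_identical(res$rec1$strand, "+")
    expect_identical(res$rec2$strand, "-")
  }
})

test_that("a heavily mutated mate is recovered by mate rescue at its locus", {
  set.seed(403)
  g <- rand_dna(50000)
  idx <- make_index(g)
  pp <- .plant_pair(g, 10000, 300)
  # corrupt mate 2 at 20%: single-end alignment fails outright, but the
  # windowed semi-global search still recovers the position
  s2 <- strsplit(pp$r2$seq, "")[[1]]
  mut <- sample(100, 20)
  for (q in mut) s2[q] <- setdiff(c("A", "C", "G", "T"), s2[q])[1]
  pp$r2$seq <- paste(s2, collapse = "")
  single <- align_single(pp$r2, idx)
  expect_false(single$qualified)
  res <- align_paired(pp$r1, pp$r2, idx)
  expect_true(res$rec1$qualified)
  expect_identical(res$rec2$stage, "MATE_RESCUE")
  expect_lte(abs(res$rec2$pos - pp$pos2), 5)
  # 20 edits exceed the 10% edit budget, so the rescue is not qualified
  expect_false(res$rec2$qualified)
  expect_false(res$proper)
})

test_that("rescue searches only the implied window and matches the oracle", {
  set.seed(404)
  g <- rand_dna(30000)
  idx <- make_index(g)
  qp <- qual_params(insert_min = 100, insert_max = 500)
  pp <- .plant_pair(g, 5000, 300)
  anchor <- align_single(pp$r1, idx)
  resc <- rescue_mate(anchor, pp$r2, idx, qp = qp)
  expect_identical(resc$stage, "MATE_RESCUE")
  expect_true(resc$qualified)
  expect_identical(resc$pos, pp$pos2)
  expect_identical(resc$edits, 0L)
  # the reported placement minimizes edits over the whole implied window
  wstart <- anchor$gpos + qp$insert_min - 100
  wend <- anchor$gpos + qp$insert_max
  win <- substr(idx$sequence, wstart + 1, wend)
  expect_identical(resc$edits,
                   as.integer(oracle_infix_edits(revcomp(pp$r2$seq), win)))
  # an anchor at the reference end clips the mate window to nothing:
  # anchor at 29901 implies a mate window starting at 29901 + insert_min -
  # mate_len = 29901, truncated at G = 30000 to fewer than mate_len bases
  tail_anchor <- align_single(substr(g, 29902, 30000), idx)
  expect_true(tail_anchor$qualified)
  expect_identical(tail_anchor$pos, 29901L)
  resc2 <- rescue_mate(tail_anchor, pp$r2, idx, qp = qp)
  expect_identical(resc2$stage, "UNALIGNED")
})

test_that("non-genomic mate pairs are reported unaligned on both ends", {
  set.seed(405)
  g <- rand_dna(2000)
  idx <- make_index(g)
  sc <- scoring_params()
  qp <- qual_params()
  checked <- 0L
  for (i in 1:4) {
    r1 <- rand_dna(100); r2 <- rand_dna(100)
    best <- max(oracle_local_score(r1, g, sc),
                oracle_local_score(revcomp(r1), g, sc),
                oracle_local_score(r2, g, sc),
                oracle_local_score(revcomp(r2), g, sc))
    if (best < qp$min_score_fraction * sc$match * 100) {
      res <- align_paired(list(id = "a", seq = r1), list(id = "a", seq = r2),
                          idx, sc, qp)
      expect_identical(res$rec1$stage, "UNALIGNED")
      expect_identical(res$rec2$stage, "UNALIGNED")
      expect_false(res$proper)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 2L)
})

test_that("pair finalization sets SAM flags, mate fields and signed TLEN", {
  set.seed(406)
  g <- rand_dna(30000)
  idx <- make_index(g, "chr1")
  pp <- .plant_pair(g, 8000, 350)
  res <- align_paired(pp$r1, pp$r2, idx)
  fin <- finalize_pair(res)
  f1 <- fin[[1]]$flag; f2 <- fin[[2]]$flag
  expect_identical(bitwAnd(f1, 1L), 1L)          # paired
  expect_identical(bitwAnd(f1, 2L), 2L)          # proper
  expect_identical(bitwAnd(f1, 4L) + bitwAnd(f1, 8L), 0L)  # both mapped
  expect_identical(bitwAnd(f1, 64L), 64L)        # first in pair
  expect_identical(bitwAnd(f2, 128L), 128L)      # last in pair
  expect_identical(bitwAnd(f1, 32L), 32L)        # mate reversed
  expect_identical(bitwAnd(f2, 16L), 16L)        # self reversed
  expect_identical(fin[[1]]$rnext, "=")
  expect_identical(fin[[1]]$pnext, fin[[2]]$pos + 1L)
  expect_identical(fin[[1]]$tlen, 350L)
  expect_identical(fin[[2]]$tlen, -350L)
})
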