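#' Pair ranked seeds of two mates under the insert-size constraint
#'
#' Considers every combination of top-ranked seeds of the two mates in
#' forward-reverse (FR) orientation whose implied insert size -- measured
#' outer edge to outer edge from the plus-strand mate's leftmost base to the
#' minus-strand mate's rightmost base -- lies inside
#' `[insert_min, insert_max]`.  The pair weight is the sum of the two seed
#' rank scores; pairs are sorted by weight (descending), ties broken by
#' distance of the implied insert from the middle of the allowed window.
#'
#' @param ranked1,ranked2 ranked seed frames from [rank_seeds()] for mate 1
#'   and mate 2 (read lengths are carried as the `read_len` attribute).
#' @param qp a [qual_params()] object supplying the insert bounds.
#' @return Data frame with `i1`, `i2` (row indices into the ranked inputs),
#'   `pair_weight` and `implied_insert`.
#' @export
pair_seeds <- function(ranked1, ranked2, qp = qual_params()) {
  empty <- data.frame(i1 = integer(0), i2 = integer(0),
                      pair_weight = integer(0), implied_insert = integer(0))
  n1 <- nrow(ranked1); n2 <- nrow(ranked2)
  if (n1 == 0L || n2 == 0L) return(empty)
  L1 <- attr(ranked1, "read_len"); L2 <- attr(ranked2, "read_len")
  g <- expand.grid(i1 = seq_len(n1), i2 = seq_len(n2))
  s1 <- ranked1$strand[g$i1]; s2 <- ranked2$strand[g$i2]
  keep <- s1 != s2  # FR orientation: strands must be opposite
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) return(empty)
  # implied leftmost position of each mate from its seed diagonal
  p1 <- ranked1$genome_pos[g$i1] - ranked1$read_offset[g$i1]
  p2 <- ranked2$genome_pos[g$i2] - ranked2$read_offset[g$i2]
  plus_is_1 <- ranked1$strand[g$i1] == "+"
  pplus <- ifelse(plus_is_1, p1, p2)
  pminus <- ifelse(plus_is_1, p2, p1)
  lminus <- ifelse(plus_is_1, L2, L1)
  ins <- (pminus + lminus) - pplus
  keep <- ins >= qp$insert_min & ins <= qp$insert_max
  g <- g[keep, , drop = FALSE]
  ins <- ins[keep]
  if (nrow(g) == 0L) return(empty)
  w <- ranked1$rank_score[g$i1] + ranked2$rank_score[g$i2]
  mid <- (qp$insert_min + qp$insert_max) / 2
  o <- order(-w, abs(ins - mid), ranked1$genome_pos[g$i1],
             ranked2$genome_pos[g$i2])
  data.frame(i1 = g$i1[o], i2 = g$i2[o], pair_weight = w[o],
             implied_insert = as.integer(ins[o]))
}

# outer-edge insert size implied by two mapped records (global coords);
# NA unless strands are opposite
.pair_insert <- function(rec1, rec2) {
  if (is.na(rec1$gpos) || is.na(rec2$gpos)) return(NA_integer_)
  if (rec1$strand == rec2$strand) return(NA_integer_)
  plus <- if (rec1$strand == "+") rec1 else rec2
  minus <- if (rec1$strand == "+") rec2 else rec1
  as.integer((minus$gpos + minus$ref_span) - plus$gpos)
}

#' Rescue an unaligned mate from its partner's alignment
#'
#' Searches only the reference window implied by the qualified anchor
#' alignment, FR orientation and the insert-size bounds, using semi-global
#' alignment of the (appropriately oriented) mate.  The resulting record has
#' stage `MATE_RESCUE`; it is qualified when its edit count is within
#' `max_edit_fraction` of the mate length.  An empty window after clipping
#' to the reference bounds yields an unaligned record.
#'
#' @param anchor_record a qualified alignment record for the anchoring mate.
#' @param mate_read the mate to place: list with `id`, `seq`, optional
#'   `qual`, or a bare string.
#' @param index a `reference_index`.
#' @param scoring a [scoring_params()] object.
#' @param qp a [qual_params()] object.
#' @return An alignment record (stage `MATE_RESCUE` or `UNALIGNED`).
#' @export
rescue_mate <- function(anchor_record, mate_read, index,
                        scoring = scoring_params(), qp = qual_params()) {
  stopifnot(isTRUE(anchor_record$qualified))
  if (is.character(mate_read)) mate_read <- list(id = "mate", seq = mate_read)
  mseq <- toupper(mate_read$seq)
  mqual <- if (is.null(mate_read$qual)) NA_character_ else mate_read$qual
  L <- nchar(mseq)
  G <- nchar(index$sequence)
  if (anchor_record$strand == "+") {
    # mate on '-' strand; its rightmost base ends the fragment
    wstart <- anchor_record$gpos + qp$insert_min - L
    wend <- anchor_record$gpos + qp$insert_max
    mstrand <- "-"
  } else {
    # mate on '+' strand; it starts the fragment that ends at the anchor
    aend <- anchor_record$gpos + anchor_record$ref_span
    wstart <- aend - qp$insert_max
    wend <- aend - qp$insert_min + L
    mstrand <- "+"
  }
  wstart <- max(0L, as.integer(wstart))
  wend <- min(G, as.integer(wend))
  if (wend - wstart < L) return(.unaligned_record(mate_read$id, mseq, mqual))
  oriented <- if (mstrand == "+") mseq else revcomp_cpp(mseq)
  al <- semiglobal_align(oriented,
                         substr(index$sequence, wstart + 1L, wend), scoring)
  if (is.na(al$edits) || al$pos_in_window < 0L) {
    return(.unaligned_record(mate_read$id, mseq, mqual))
  }
  gpos <- wstart + al$pos_in_window
  loc <- global_to_local(index, gpos)
  rec <- list(read_id = mate_read$id, ref_name = loc$ref_name, pos = loc$pos,
              gpos = gpos, strand = mstrand, cigar = al$cigar,
              score = al$score, edits = al$edits, aligned_bases = L,
              ref_span = al$ref_end - al$pos_in_window,
              stage = "MATE_RESCUE", qualified = FALSE, mapq = 0L,
              read_seq = mseq, read_qual = mqual, read_len = L)
  rec$qualified <- is_qualified(rec, L, qp, scoring)
  rec$mapq <- if (rec$qualified) 60L else 0L
  rec
}

# one seed-pairing pass (MEM or k-mer seeds); returns list(rec1, rec2) for
# the first seed pair whose real alignments both qualify with an in-range
# insert, else NULL
.pair_stage <- function(index, read1, read2, seed_fun, scoring, qp,
                        stage_local) {
  s1 <- seed_fun(read1$seq); s2 <- seed_fun(read2$seq)
  r1 <- rank_seeds(index, read1$seq, s1, scoring, qp$top_n_seeds)
  r2 <- rank_seeds(index, read2$seq, s2, scoring, qp$top_n_seeds)
  pairs <- pair_seeds(r1, r2, qp)
  q1 <- if (is.null(read1$qual)) NA_character_ else read1$qual
  q2 <- if (is.null(read2$qual)) NA_character_ else read2$qual
  for (p in seq_len(nrow(pairs))) {
    i1 <- pairs$i1[p]; i2 <- pairs$i2[p]
    if (is.na(r1$aln_pos[i1]) || is.na(r2$aln_pos[i2])) next
    rec1 <- .record_at(index, r1, i1, stage_local, read1$id,
                       toupper(read1$seq), q1)
    rec2 <- .record_at(index, r2, i2, stage_local, read2$id,
                       toupper(read2$seq), q2)
    ok1 <- is_qualified(rec1, rec1$read_len, qp, scoring)
    ok2 <- is_qualified(rec2, rec2$read_len, qp, scoring)
    if (!ok1 || !ok2) next
    ins <- .pair_insert(rec1, rec2)
    if (is.na(ins) || ins < qp$insert_min || ins > qp$insert_max) next
    rec1$qualified <- TRUE; rec2$qualified <- TRUE
    rec1$mapq <- 60L; rec2$mapq <- 60L
    return(list(rec1 = rec1, rec2 = rec2))
  }
  NULL
}

#' Paired-end alignment cascade
#'
#' Implements the paired-end workflow: MEM seeds of both mates are
#' generated and ranked as in the single-end pipeline; top-ranked seeds are
#' paired under the insert-size constraint and the real alignments of the
#' first seed pair whose extensions both qualify (with an in-range actual
#' insert) are reported as a proper pair.  If no MEM seed pair succeeds the
#' pass is repeated with exact-match k-mer seeds.  Failing both, the mates
#' are aligned independently with the single-end cascade and a mate that
#' remains unaligned is rescued from its qualified partner's window.  The
#' proper-pair flag is set exactly when both mates are qualified with an
#' insert inside the configured bounds.
#'
#' @param read1,read2 mate records (lists with `id`, `seq`, optional
#'   `qual`), positionally paired.
#' @param index a `reference_index`.
#' @param scoring a [scoring_params()] object.
#' @param qp a [qual_params()] object.
#' @param min_mem_length minimum MEM seed length (default 19).
#' @param k exact-match k-mer length (defaults to the index's `k`).
#' @return List with alignment records `rec1`, `rec2` and logical `proper`.
#' @export
align_paired <- function(read1, read2, index, scoring = scoring_params(),
                         qp = qual_params(), min_mem_length = 19L,
                         k = index$k) {
  if (is.character(read1)) read1 <- list(id = "read/1", seq = read1)
  if (is.character(read2)) read2 <- list(id = "read/2", seq = read2)
  L1 <- nchar(read1$seq); L2 <- nchar(read2$seq)
  if (L1 >= min_mem_length && L2 >= min_mem_length) {
    res <- .pair_stage(index, read1, read2,
                       function(s) find_mem_seeds(index, s, min_mem_length),
                       scoring, qp, "LOCAL")
    if (!is.null(res)) return(c(res, list(proper = TRUE)))
  }
  if (L1 >= k && L2 >= k) {
    res <- .pair_stage(index, read1, read2,
                       function(s) find_kmer_seeds(index, s, k),
                       scoring, qp, "KMER_LOCAL")
    if (!is.null(res)) return(c(res, list(proper = TRUE)))
  }
  # fall back to independent single-end alignment plus mate rescue
  rec1 <- align_single(read1, index, scoring, qp, min_mem_length, k)
  rec2 <- align_single(read2, index, scoring, qp, min_mem_length, k)
  if (rec1$qualified && !rec2$qualified) {
    r <- rescue_mate(rec1, read2, index, scoring, qp)
    if (r$stage != "UNALIGNED") rec2 <- r
  } else if (rec2$qualified && !rec1$qualified) {
    r <- rescue_mate(rec2, read1, index, scoring, qp)
    if (r$stage != "UNALIGNED") rec1 <- r
  }
  ins <- if (rec1$qualified && rec2$qualified) .pair_insert(rec1, rec2)
         else NA_integer_
  proper <- !is.na(ins) && ins >= qp$insert_min && ins <= qp$insert_max
  list(rec1 = rec1, rec2 = rec2, proper = proper)
}

#' Attach SAM pairing fields to a mate pair
#'
#' Computes FLAG bits (0x1 paired, 0x2 proper, 0x4/0x8 unmapped, 0x10/0x20
#' strands, 0x40/0x80 first/last), RNEXT, PNEXT and TLEN for the two records
#' of a pair, so they serialize as valid paired SAM lines.
#'
#' @param pair result of [align_paired()].
#' @return List of the two records with `flag`, `rnext`, `pnext`, `tlen`
#'   fields set.
#' @export
finalize_pair <- function(pair) {
  r1 <- pair$rec1; r2 <- pair$rec2
  m1 <- .rec_mapped(r1); m2 <- .rec_mapped(r2)
  base <- 1L + if (pair$proper) 2L else 0L
  f1 <- base + (!m1) * 4L + (!m2) * 8L + 64L
  f2 <- base + (!m2) * 4L + (!m1) * 8L + 128L
  if (m1 && r1$strand == "-") { f1 <- f1 + 16L; f2 <- f2 + 32L }
  if (m2 && r2$strand == "-") { f2 <- f2 + 16L; f1 <- f1 + 32L }
  same_ref <- m1 && m2 && identical(r1$ref_name, r2$ref_name)
  r1$flag <- f1; r2$flag <- f2
  r1$rnext <- if (same_ref) "=" else if (m2) r2$ref_name else "*"
  r2$rnext <- if (same_ref) "=" else if (m1) r1$ref_name else "*"
  r1$pnext <- if (m2) r2$pos + 1L else 0L
  r2$pnext <- if (m1) r1$pos + 1L else 0L
  tlen <- if (same_ref) .pair_insert(r1, r2) else NA_integer_
  if (!is.na(tlen)) {
    left1 <- r1$gpos <= r2$gpos
    r1$tlen <- if (left1) tlen else -tlen
    r2$tlen <- if (left1) -tlen else tlen
  } else {
    r1$tlen <- 0L; r2$tlen <- 0L
  }
  list(r1, r2)
}
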