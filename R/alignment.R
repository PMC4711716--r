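#' Banded local alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment of a read against a reference window.  The DP
#' band spans diagonals `min(0, W - L) - band_width` to
#' `max(0, W - L) + band_width` (L = read length, W = window length), so it
#' always covers every placement of the read within the window plus
#' `band_width` of indel slack; a `band_width` at least as large as the
#' longer sequence makes the computation exactly the full matrix.
#'
#' @param read_seq read string.
#' @param ref_window reference window string.
#' @param scoring a [scoring_params()] object.
#' @return List with `score` (>= 0), `pos_in_window` (0-based start of the
#'   aligned reference segment, `NA` if the optimum is the empty alignment),
#'   `cigar` (over M/I/D/S, read orientation), plus `aligned` (read bases in
#'   M columns), `matches`, `edits`, `read_start`, `read_end`, `ref_end`.
#' @export
#' @examples
#' local_align("ACGTACGTAC", "ACGTACGTAC", scoring_params(match = 2))
local_align <- function(read_seq, ref_window, scoring = scoring_params()) {
  if (!nzchar(read_seq) || !nzchar(ref_window)) {
    stop("local_align requires non-empty sequences")
  }
  L <- nchar(read_seq); W <- nchar(ref_window)
  bw <- scoring$band_width
  res <- local_align_cpp(toupper(read_seq), toupper(ref_window),
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend,
                         min(0L, W - L) - bw, max(0L, W - L) + bw)
  list(score = res$score,
       pos_in_window = if (res$ref_start < 0) NA_integer_ else res$ref_start,
       cigar = if (nzchar(res$cigar)) res$cigar else NA_character_,
       aligned = res$aligned, matches = res$matches, edits = res$edits,
       read_start = if (res$read_start < 0) NA_integer_ else res$read_start,
       read_end = if (res$read_end < 0) NA_integer_ else res$read_end,
       ref_end = if (res$ref_end < 0) NA_integer_ else res$ref_end)
}

#' Banded semi-global alignment (whole read, free reference ends)
#'
#' Aligns the entire read end-to-end inside a reference window at least as
#' long as the read, with free leading/trailing gaps on the reference side
#' only.  The objective is the minimum unit-cost edit count over all
#' placements; the affine-gap score of the chosen alignment is reported for
#' record keeping.
#'
#' @inheritParams local_align
#' @return List with `score`, `pos_in_window`, `cigar` (M/I/D, consumes the
#'   whole read), `edits`, `matches`, `ref_end`.
#' @export
semiglobal_align <- function(read_seq, ref_window,
                             scoring = scoring_params()) {
  if (!nzchar(read_seq)) stop("semiglobal_align requires a non-empty read")
  L <- nchar(read_seq); W <- nchar(ref_window)
  if (W < L) stop("reference window shorter than read")
  bw <- scoring$band_width
  res <- semiglobal_align_cpp(toupper(read_seq), toupper(ref_window),
                              -bw, (W - L) + bw,
                              scoring$match, scoring$mismatch,
                              scoring$gap_open, scoring$gap_extend)
  list(score = res$score, pos_in_window = res$ref_start, cigar = res$cigar,
       edits = res$edits, matches = res$matches, ref_end = res$ref_end)
}

#' Rank seeds by banded local alignment score
#'
#' Each seed determines a potential mapping region on the genome; the read
#' is aligned locally against that window and the optimal score becomes the
#' seed's rank score.  Seeds are returned sorted by rank score (descending,
#' ties by ascending `genome_pos` then `read_offset`) and truncated to the
#' `top_n` best.  The window alignment computed here is retained in extra
#' columns so the extension step does not repeat it.
#'
#' @param index a `reference_index`.
#' @param read_seq read string.
#' @param seeds seed data frame from [find_mem_seeds()] or
#'   [find_kmer_seeds()].
#' @param scoring a [scoring_params()] object.
#' @param top_n number of seeds kept (default 8).
#' @return The seed data frame with `rank_score` filled and columns
#'   `win_start`, `aln_pos` (0-based global), `aln_cigar`, `aln_score`,
#'   `aln_aligned`, `aln_edits`, `aln_ref_end` added; read length is
#'   attached as attribute `read_len`.
#' @export
rank_seeds <- function(index, read_seq, seeds, scoring = scoring_params(),
                       top_n = 8L) {
  read_seq <- toupper(read_seq)
  L <- nchar(read_seq)
  n <- nrow(seeds)
  if (n == 0L) {
    out <- .fast_df(read_offset = integer(0), genome_pos = integer(0),
                    length = integer(0), kind = character(0),
                    strand = character(0), rank_score = integer(0),
                    win_start = integer(0), win_end = integer(0),
                    aln_pos = integer(0), aln_score = integer(0),
                    aln_cigar = character(0), aln_aligned = integer(0),
                    aln_edits = integer(0), aln_ref_end = integer(0))
    attr(out, "read_len") <- L
    return(out)
  }
  rc <- revcomp_cpp(read_seq)
  bw <- scoring$band_width
  G <- nchar(index$sequence)
  ro <- seeds$read_offset; gp <- seeds$genome_pos; strand <- seeds$strand
  win_start <- pmax(0L, gp - ro - bw)
  win_end <- pmin(G, gp - ro + L + bw)
  rank_score <- integer(n)
  aln_pos <- rep(NA_integer_, n); aln_score <- integer(n)
  aln_cigar <- rep(NA_character_, n); aln_aligned <- integer(n)
  aln_edits <- integer(n); aln_ref_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    oriented <- if (strand[i] == "+") read_seq else rc
    win <- substr(index$sequence, win_start[i] + 1L, win_end[i])
    W <- nchar(win)
    al <- local_align_cpp(oriented, win, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          min(0L, W - L) - bw, max(0L, W - L) + bw)
    rank_score[i] <- al$score
    aln_score[i] <- al$score
    aln_aligned[i] <- al$aligned
    aln_edits[i] <- al$edits
    if (al$ref_start >= 0L) {
      aln_pos[i] <- win_start[i] + al$ref_start
      aln_cigar[i] <- al$cigar
      aln_ref_end[i] <- win_start[i] + al$ref_end
    }
  }
  o <- head(order(-rank_score, gp, ro), top_n)
  out <- .fast_df(read_offset = ro[o], genome_pos = gp[o],
                  length = seeds$length[o], kind = seeds$kind[o],
                  strand = strand[o], rank_score = rank_score[o],
                  win_start = win_start[o], win_end = win_end[o],
                  aln_pos = aln_pos[o], aln_score = aln_score[o],
                  aln_cigar = aln_cigar[o], aln_aligned = aln_aligned[o],
                  aln_edits = aln_edits[o], aln_ref_end = aln_ref_end[o])
  attr(out, "read_len") <- L
  out
}

#' Qualification test for a candidate alignment
#'
#' Local-extension stages qualify on score and read coverage; semi-global
#' and mate-rescue stages qualify on edit fraction.  Boundary values pass
#' (comparisons are `>=` / `<=`).
#'
#' @param record an alignment record (stage must not be `"UNALIGNED"`).
#' @param read_len read length in bases.
#' @param qp a [qual_params()] object.
#' @param scoring a [scoring_params()] object (supplies the match score that
#'   anchors the score threshold).
#' @return Logical.
#' @export
is_qualified <- function(record, read_len, qp = qual_params(),
                         scoring = scoring_params()) {
  stopifnot(record$stage != "UNALIGNED")
  if (record$stage %in% c("LOCAL", "KMER_LOCAL")) {
    record$score >= qp$min_score_fraction * scoring$match * read_len &&
      record$aligned_bases >= qp$min_coverage_fraction * read_len
  } else {
    record$edits <= qp$max_edit_fraction * read_len
  }
}

# Build an alignment record from row i of a ranked-seed frame.
.record_at <- function(index, ranked, i, stage, read_id, read_seq,
                       read_qual) {
  gpos <- ranked$aln_pos[i]
  loc <- global_to_local(index, gpos)
  list(read_id = read_id, ref_name = loc$ref_name, pos = loc$pos,
       gpos = gpos, strand = ranked$strand[i], cigar = ranked$aln_cigar[i],
       score = ranked$aln_score[i], edits = ranked$aln_edits[i],
       aligned_bases = ranked$aln_aligned[i],
       ref_span = ranked$aln_ref_end[i] - gpos,
       stage = stage, qualified = FALSE, mapq = 0L,
       read_seq = read_seq, read_qual = read_qual,
       read_len = attr(ranked, "read_len"))
}

.unaligned_record <- function(read_id, read_seq, read_qual) {
  list(read_id = read_id, ref_name = NA_character_, pos = NA_integer_,
       gpos = NA_integer_, strand = NA_character_, cigar = NA_character_,
       score = NA_integer_, edits = NA_integer_, aligned_bases = 0L,
       ref_span = 0L, stage = "UNALIGNED", qualified = FALSE, mapq = 0L,
       read_seq = read_seq, read_qual = read_qual,
       read_len = nchar(read_seq))
}

# total order used to pick the reported alignment: score desc, then global
# pos asc, then '+' strand first -- makes serial/parallel output identical
.best_record <- function(records) {
  sc <- vapply(records, function(r) as.numeric(r$score), numeric(1))
  gp <- vapply(records, function(r) as.numeric(r$gpos), numeric(1))
  st <- vapply(records, function(r) if (r$strand == "+") 0 else 1, numeric(1))
  records[[order(-sc, gp, st)[1L]]]
}

.mapq_of <- function(records, best_score) {
  co <- sum(vapply(records, function(r) r$score == best_score, logical(1)))
  max(0L, 60L - 10L * (co - 1L))
}

# one extension pass over ranked seeds: local candidates, then semi-global
# rescue candidates from the same windows
.extend_stage <- function(index, read_id, read_seq, read_qual, ranked,
                          scoring, qp, stage_local, stage_semi) {
  L <- attr(ranked, "read_len")
  ok <- !is.na(ranked$aln_pos)
  cand <- list()
  seen <- character(0)
  for (i in which(ok)) {
    key <- paste(ranked$aln_pos[i], ranked$strand[i])
    if (key %in% seen) next
    seen <- c(seen, key)
    cand[[length(cand) + 1L]] <-
      .record_at(index, ranked, i, stage_local, read_id, read_seq, read_qual)
  }
  if (length(cand)) {
    qual <- vapply(cand, is_qualified, logical(1), read_len = L, qp = qp,
                   scoring = scoring)
    if (any(qual)) {
      best <- .best_record(cand[qual])
      best$qualified <- TRUE
      best$mapq <- .mapq_of(cand, best$score)
      return(best)
    }
  }
  # semi-global rescue from the same ranked seed windows
  rc <- revcomp_cpp(read_seq)
  bw <- scoring$band_width
  semi <- list()
  seen <- character(0)
  for (i in seq_len(nrow(ranked))) {
    ws <- ranked$win_start[i]; we <- ranked$win_end[i]
    W <- we - ws
    if (W < L) next
    key <- paste(ws, ranked$strand[i])
    if (key %in% seen) next
    seen <- c(seen, key)
    oriented <- if (ranked$strand[i] == "+") read_seq else rc
    al <- semiglobal_align_cpp(oriented,
                               substr(index$sequence, ws + 1L, we),
                               -bw, (W - L) + bw, scoring$match,
                               scoring$mismatch, scoring$gap_open,
                               scoring$gap_extend)
    if (is.na(al$edits) || al$ref_start < 0L) next
    gpos <- ws + al$ref_start
    loc <- global_to_local(index, gpos)
    semi[[length(semi) + 1L]] <-
      list(read_id = read_id, ref_name = loc$ref_name, pos = loc$pos,
           gpos = gpos, strand = ranked$strand[i], cigar = al$cigar,
           score = al$score, edits = al$edits, aligned_bases = L,
           ref_span = al$ref_end - al$ref_start, stage = stage_semi,
           qualified = FALSE, mapq = 0L, read_seq = read_seq,
           read_qual = read_qual, read_len = L)
  }
  if (length(semi)) {
    qual <- vapply(semi, is_qualified, logical(1), read_len = L, qp = qp,
                   scoring = scoring)
    if (any(qual)) {
      best <- .best_record(semi[qual])
      best$qualified <- TRUE
      best$mapq <- .mapq_of(semi, best$score)
      return(best)
    }
  }
  NULL
}

#' Single-end alignment cascade
#'
#' Implements the single-end workflow: MEM seeds are generated and ranked,
#' the top seeds are extended by banded local alignment and the best
#' qualified alignment is reported; failing that, a semi-global rescue is
#' attempted from the same ranked seed windows; failing that, the whole
#' procedure is repeated with exact-match k-mer seeds; and if nothing
#' qualifies the read is reported unaligned.
#'
#' @param read read record: a list with `id`, `seq` and optional `qual`, or
#'   a bare sequence string.
#' @param index a `reference_index`.
#' @param scoring a [scoring_params()] object.
#' @param qp a [qual_params()] object.
#' @param min_mem_length minimum MEM seed length (default 19).
#' @param k exact-match k-mer length (defaults to the index's `k`).
#' @return An alignment record: a list with `read_id`, `ref_name`, `pos`
#'   (0-based within `ref_name`), `strand`, `cigar`, `score`, `edits`,
#'   `stage` (`LOCAL`, `SEMIGLOBAL`, `KMER_LOCAL`, `KMER_SEMIGLOBAL` or
#'   `UNALIGNED`), `qualified` and `mapq`.
#' @export
align_single <- function(read, index, scoring = scoring_params(),
                         qp = qual_params(), min_mem_length = 19L,
                         k = index$k) {
  if (is.character(read)) read <- list(id = "read", seq = read)
  read_seq <- toupper(read$seq)
  read_qual <- if (is.null(read$qual)) NA_character_ else read$qual
  L <- nchar(read_seq)
  if (L >= min_mem_length) {
    seeds <- find_mem_seeds(index, read_seq, min_mem_length)
    ranked <- rank_seeds(index, read_seq, seeds, scoring, qp$top_n_seeds)
    rec <- .extend_stage(index, read$id, read_seq, read_qual, ranked,
                         scoring, qp, "LOCAL", "SEMIGLOBAL")
    if (!is.null(rec)) return(rec)
  }
  if (L >= k) {
    seeds <- find_kmer_seeds(index, read_seq, k)
    ranked <- rank_seeds(index, read_seq, seeds, scoring, qp$top_n_seeds)
    rec <- .extend_stage(index, read$id, read_seq, read_qual, ranked,
                         scoring, qp, "KMER_LOCAL", "KMER_SEMIGLOBAL")
    if (!is.null(rec)) return(rec)
  }
  .unaligned_record(read$id, read_seq, read_qual)
}
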