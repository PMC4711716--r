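# shared fixture builders and independent oracles

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_index <- function(seqs, names = paste0("ref", seq_along(seqs)),
                       k = 13L) {
  fa <- tempfile(fileext = ".fa")
  write_fasta(seqs, fa, names)
  build_index(fa, k = k)
}

write_temp_fastq <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                             quals = strrep("I", nchar(seqs))) {
  fq <- tempfile(fileext = ".fastq")
  write_fastq(ids, seqs, quals, fq)
  fq
}

# --- suffix array oracle: brute-force sort of all suffixes ------------------

oracle_suffix_array <- function(s) {
  n <- nchar(s)
  sufs <- substring(s, 1:(n + 1))  # last is the empty sentinel suffix
  order(sufs, method = "radix") - 1L
}

# --- maximal-exact-match oracle: diagonal run scan --------------------------
# every maximal match of `read` (this orientation) against `genome` with
# length >= min_len; columns read_offset, genome_pos, length (0-based)
oracle_max_matches <- function(genome, read, min_len) {
  gc <- strsplit(genome, "", fixed = TRUE)[[1]]
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  G <- length(gc); R <- length(rc)
  res <- list()
  for (d in (-(R - 1L)):(G - 1L)) {
    i0 <- max(0L, -d); i1 <- min(R - 1L, G - 1L - d)
    if (i1 < i0) next
    idx <- i0:i1
    eq <- rc[idx + 1L] == gc[idx + d + 1L] &
      rc[idx + 1L] != "N" & gc[idx + d + 1L] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_len)) {
      ro <- idx[starts[j]]
      res[[length(res) + 1L]] <- c(ro, ro + d, r$lengths[j])
    }
  }
  if (!length(res)) return(matrix(integer(0), 0, 3))
  m <- do.call(rbind, res)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# --- exhaustive k-mer window oracle ----------------------------------------
oracle_kmer_hits <- function(genome, kmer) {
  G <- nchar(genome); k <- nchar(kmer)
  if (G < k || grepl("N", kmer)) return(integer(0))
  wins <- substring(genome, 1:(G - k + 1L), k:G)
  which(wins == kmer) - 1L
}

# --- alignment score oracles (Biostrings, full-matrix) ----------------------
oracle_local_score <- function(read, ref, scoring) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  s <- Biostrings::pairwiseAlignment(
    read, ref, type = "local", substitutionMatrix = sm,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    scoreOnly = TRUE)
  max(0, s)
}

oracle_infix_edits <- function(read, ref) {
  m <- matrix(-1, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- 0
  -Biostrings::pairwiseAlignment(read, ref, type = "global-local",
                                 substitutionMatrix = m, gapOpening = 0,
                                 gapExtension = 1, scoreOnly = TRUE)
}

# fixture: an FR read pair planted at a known fragment start and insert
.plant_pair <- function(g, fpos, insert, read_len = 100L) {
  fpos <- as.integer(fpos); insert <- as.integer(insert)
  left <- substr(g, fpos + 1, fpos + read_len)
  right_start <- fpos + insert - read_len
  right <- revcomp(substr(g, right_start + 1, right_start + read_len))
  list(r1 = list(id = "p/1", seq = left, qual = strrep("I", read_len)),
       r2 = list(id = "p/2", seq = right, qual = strrep("I", read_len)),
       pos1 = fpos, pos2 = right_start)
}

# check a seed frame's own exact-match invariant by direct comparison
seeds_verify <- function(index, read, seeds) {
  rc <- revcomp(read)
  ok <- logical(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    r <- if (seeds$strand[i] == "+") read else rc
    sub_r <- substr(r, seeds$read_offset[i] + 1L,
                    seeds$read_offset[i] + seeds$length[i])
    sub_g <- substr(index$sequence, seeds$genome_pos[i] + 1L,
                    seeds$genome_pos[i] + seeds$length[i])
    ok[i] <- identical(sub_r, sub_g) && !grepl("N", sub_r)
  }
  ok
}
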