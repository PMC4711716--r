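#' Reverse complement of a DNA string
#' @param seq character scalar over A/C/G/T/N (case preserved in type, not
#'   case-sensitive; ambiguous characters become N).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) revcomp_cpp(seq)

#' Build an in-memory reference index
#'
#' Loads all sequences of a FASTA file, concatenates them with a single `N`
#' spacer (so no seed can span a record boundary), and builds a suffix array
#' over the concatenation.  All seed queries -- maximal-exact-match
#' enumeration and exact k-mer lookup -- are answered from the suffix array;
#' the k-mer position table of the design is realized implicitly as suffix
#' array range queries, which return the same complete, ascending position
#' lists without a second copy of the genome.
#'
#' @param fasta_path reference FASTA (one or more records).
#' @param k k-mer length for exact-match seed lookup, >= 1 (default 13).
#' @return An object of class `reference_index` with fields `names`,
#'   `lengths`, `offsets` (0-based global start of each record), `sequence`
#'   (concatenated, upper case), `suffix_array` (0-based, includes the empty
#'   suffix) and `k`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGTACGTACGT"), fa)
#' idx <- build_index(fa, k = 4)
#' idx$lengths
build_index <- function(fasta_path, k = 13L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGT]", "N", chr)
  nm <- sub("\\s.*$", "", names(seqs))
  lens <- nchar(chr)
  concat <- paste(chr, collapse = "N")
  if (nchar(concat) < k) stop("reference shorter than k")
  offsets <- cumsum(c(0L, head(lens, -1L) + 1L))  # +1 for the N spacer
  structure(list(names = nm, lengths = as.integer(lens),
                 offsets = as.integer(offsets), sequence = concat,
                 suffix_array = sa_build_cpp(concat), k = k),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat("reference_index:", length(x$names), "sequence(s),",
      sum(x$lengths), "bp, k =", x$k, "\n")
  invisible(x)
}

#' Genome positions of a k-mer
#'
#' Complete ascending list of exact occurrences of `kmer` in the indexed
#' genome (forward strand of the concatenated sequence).
#'
#' @param index a `reference_index`.
#' @param kmer query string.
#' @return Integer vector of 0-based global positions.
#' @export
kmer_positions <- function(index, kmer) {
  sa_find_cpp(index$sequence, index$suffix_array, toupper(kmer))
}

# translate a 0-based global position to (ref_name, local 0-based pos)
global_to_local <- function(index, gpos) {
  i <- findInterval(gpos, index$offsets)
  list(ref_name = index$names[i], pos = as.integer(gpos - index$offsets[i]))
}

# data.frame from pre-validated equal-length columns, skipping the checks
# of data.frame(); seeds are enumerated per read, so this is a hot path
.fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1L]])))
}

# combine forward/reverse seed matrices into one ordered frame
.seed_frame <- function(fwd, rev, kind) {
  ro <- c(fwd[, 1L], rev[, 1L])
  gp <- c(fwd[, 2L], rev[, 2L])
  len <- c(fwd[, 3L], rev[, 3L])
  strand <- rep(c("+", "-"), c(nrow(fwd), nrow(rev)))
  o <- order(ro, gp, strand)
  .fast_df(read_offset = ro[o], genome_pos = gp[o], length = len[o],
           kind = rep(kind, length(o)), strand = strand[o],
           rank_score = rep(NA_integer_, length(o)))
}

#' Enumerate maximal-exact-match (MEM) seeds of a read
#'
#' Returns every maximal exact match between the read and the genome on
#' both strands with length at least `min_mem_length`.  The reverse strand
#' is handled by seeding the reverse complement of the read, so for `-`
#' seeds `read_offset` indexes the reverse-complemented read.  `N` bases
#' never match.
#'
#' @param index a `reference_index`.
#' @param read_sequence read string (length >= `min_mem_length`).
#' @param min_mem_length minimum seed length (default 19).
#' @return A data frame of seeds ordered by `(read_offset, genome_pos,
#'   strand)` with columns `read_offset`, `genome_pos`, `length`, `kind`
#'   (`"MEM"`), `strand`, `rank_score` (`NA` until ranked).
#' @export
find_mem_seeds <- function(index, read_sequence, min_mem_length = 19L) {
  min_mem_length <- as.integer(min_mem_length)
  read_sequence <- toupper(read_sequence)
  if (nchar(read_sequence) < min_mem_length) {
    stop("read shorter than min_mem_length")
  }
  scan_k <- min(index$k, min_mem_length)
  fwd <- mem_seeds_cpp(index$sequence, index$suffix_array, read_sequence,
                       min_mem_length, scan_k)
  rev <- mem_seeds_cpp(index$sequence, index$suffix_array,
                       revcomp_cpp(read_sequence), min_mem_length, scan_k)
  .seed_frame(fwd, rev, "MEM")
}

#' Enumerate exact-match k-mer seeds of a read
#'
#' Fallback seed source used when MEM seeding fails: the read is sampled at
#' stride `k` into non-overlapping k-mers and every exact genome occurrence
#' of each sampled k-mer becomes a seed, on both strands.
#'
#' @param index a `reference_index`.
#' @param read_sequence read string (length >= `k`).
#' @param k k-mer length (defaults to the index's `k`).
#' @return A data frame of seeds in the same layout as [find_mem_seeds()],
#'   with `kind = "KMER"` and `length = k`.
#' @export
find_kmer_seeds <- function(index, read_sequence, k = index$k) {
  k <- as.integer(k)
  read_sequence <- toupper(read_sequence)
  if (k > nchar(read_sequence)) stop("k exceeds read length")
  fwd <- kmer_seeds_cpp(index$sequence, index$suffix_array, read_sequence, k)
  rev <- kmer_seeds_cpp(index$sequence, index$suffix_array,
                        revcomp_cpp(read_sequence), k)
  .seed_frame(fwd, rev, "KMER")
}
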