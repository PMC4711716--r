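#' Simulate a random genome sequence
#'
#' Bases are drawn i.i.d. with G+C probability `gc_content` (split evenly
#' between G and C, likewise A and T), so composition matches `gc_content`
#' in expectation.  Deterministic for a fixed seed.
#'
#' @param length genome length in bases, >= 1.
#' @param gc_content GC fraction in \[0, 1\] (default 0.5).
#' @param seed optional RNG seed (calls `set.seed`).
#' @return A single genome string.
#' @export
#' @examples
#' simulate_genome(50, seed = 1)
simulate_genome <- function(length, gc_content = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc_content >= 0, gc_content <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Write sequences to a FASTA file
#' @param sequences character vector of sequences.
#' @param path output path.
#' @param names record names (default `seq1`, `seq2`, ...).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path,
                        names = paste0("seq", seq_along(sequences))) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names[i]), con)
    writeLines(sequences[i], con)
  }
  invisible(path)
}

#' Write reads to a FASTQ file
#' @param ids,seqs,quals parallel character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  lines <- character(4L * length(ids))
  lines[seq(1L, by = 4L, length.out = length(ids))] <- paste0("@", ids)
  lines[seq(2L, by = 4L, length.out = length(ids))] <- seqs
  lines[seq(3L, by = 4L, length.out = length(ids))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(ids))] <- quals
  writeLines(lines, path)
  invisible(path)
}

# apply substitutions and indels to a template drawn from the genome;
# returns list(seq, mutations).  Deletions consume extra template, so the
# template passed in must carry `pad` spare bases beyond read_len.
.mutate_template <- function(template, read_len, subst_rate, indel_rate) {
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  out <- character(0)
  muts <- 0L
  i <- 1L
  bases <- c("A", "C", "G", "T")
  while (length(out) < read_len && i <= length(chars)) {
    r <- runif(1)
    if (indel_rate > 0 && r < indel_rate / 2) {         # deletion
      i <- i + 1L
      muts <- muts + 1L
    } else if (indel_rate > 0 && r < indel_rate) {      # insertion
      out <- c(out, sample(bases, 1L))
      muts <- muts + 1L
    } else {
      b <- chars[i]
      if (runif(1) < subst_rate) {
        b <- sample(setdiff(bases, b), 1L)
        muts <- muts + 1L
      }
      out <- c(out, b)
      i <- i + 1L
    }
  }
  if (length(out) < read_len) return(NULL)  # ran out of template; resample
  list(seq = paste(out[seq_len(read_len)], collapse = ""), mutations = muts)
}

#' Simulate reads with planted truth
#'
#' Draws read loci uniformly from the genome (both strands), applies
#' per-base substitutions and indels at the stated rates, and writes
#' single-end reads to `<out_prefix>.fastq` or FR mate pairs to
#' `<out_prefix>_1.fastq` / `<out_prefix>_2.fastq` with truncated-normal
#' insert sizes.  A truth table records the 0-based leftmost genome position
#' and strand of every read.  Deterministic for a fixed seed.
#'
#' @param genome genome string (e.g. from [simulate_genome()]).
#' @param n number of reads (or read pairs).
#' @param read_len read length (default 100).
#' @param subst_rate per-base substitution probability in \[0, 1).
#' @param indel_rate per-base indel probability in \[0, 1).
#' @param mode `"single"` or `"paired"`.
#' @param insert_mean,insert_sd insert-size distribution (paired mode).
#' @param insert_bounds length-2 vector; inserts are resampled until inside
#'   these bounds (truncation).
#' @param seed optional RNG seed.
#' @param unique_only if `TRUE`, reject loci whose error-free read sequence
#'   is not a unique substring of the genome/its reverse complement (makes
#'   exact-recovery assertions sharp).
#' @param out_prefix output path prefix (default: a tempfile).
#' @return List with `fastq` (one or two paths) and `truth`, a data frame
#'   with columns `read_id`, `mate`, `pos`, `strand`, `mutations`, `insert`.
#' @export
simulate_reads <- function(genome, n, read_len = 100L, subst_rate = 0.01,
                           indel_rate = 0, mode = c("single", "paired"),
                           insert_mean = 300, insert_sd = 30,
                           insert_bounds = c(100L, 500L), seed = NULL,
                           unique_only = FALSE, out_prefix = tempfile()) {
  mode <- match.arg(mode)
  G <- nchar(genome)
  stopifnot(read_len <= G, subst_rate >= 0, subst_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "paired") {
    if (insert_bounds[1] > insert_bounds[2] || insert_bounds[1] < read_len ||
        insert_bounds[1] > G) {
      stop("infeasible insert bounds")
    }
  }
  sa <- if (unique_only) sa_build_cpp(genome) else NULL
  is_unique <- function(s) {
    count_occ_cpp(genome, sa, s) + count_occ_cpp(genome, sa, revcomp_cpp(s)) == 1L
  }
  pad <- max(10L, ceiling(3 * indel_rate * read_len))
  ids <- sprintf("read%06d", seq_len(n))
  if (mode == "single") {
    seqs <- character(n); truth_pos <- integer(n)
    truth_strand <- character(n); muts <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        pos <- sample.int(G - read_len + 1L, 1L) - 1L
        template <- substr(genome, pos + 1L, min(G, pos + read_len + pad))
        if (unique_only &&
            !is_unique(substr(template, 1L, read_len))) next
        m <- .mutate_template(template, read_len, subst_rate, indel_rate)
        if (is.null(m)) next
        strand <- if (runif(1) < 0.5) "+" else "-"
        seqs[i] <- if (strand == "+") m$seq else revcomp_cpp(m$seq)
        truth_pos[i] <- pos; truth_strand[i] <- strand
        muts[i] <- m$mutations
        break
      }
    }
    fq <- paste0(out_prefix, ".fastq")
    write_fastq(ids, seqs, strrep("I", read_len), fq)
    truth <- data.frame(read_id = ids, mate = 1L, pos = truth_pos,
                        strand = truth_strand, mutations = muts,
                        insert = NA_integer_)
    return(list(fastq = fq, truth = truth))
  }
  # paired mode
  s1 <- character(n); s2 <- character(n)
  t1 <- integer(n); t2 <- integer(n)
  st1 <- character(n); st2 <- character(n)
  m1 <- integer(n); m2 <- integer(n); ins <- integer(n)
  lo <- max(insert_bounds[1], read_len)
  hi <- min(insert_bounds[2], G)
  for (i in seq_len(n)) {
    repeat {
      I <- round(rnorm(1, insert_mean, insert_sd))
      if (I < lo || I > hi) next
      fpos <- sample.int(G - I + 1L, 1L) - 1L
      left_t <- substr(genome, fpos + 1L, min(G, fpos + read_len + pad))
      right_start <- fpos + I - read_len
      right_t <- substr(genome, right_start + 1L,
                        min(G, right_start + read_len + pad))
      if (unique_only &&
          (!is_unique(substr(left_t, 1L, read_len)) ||
           !is_unique(substr(right_t, 1L, read_len)))) next
      ml <- .mutate_template(left_t, read_len, subst_rate, indel_rate)
      mr <- .mutate_template(right_t, read_len, subst_rate, indel_rate)
      if (is.null(ml) || is.null(mr)) next
      # FR pair: one mate forward at the fragment start, the other
      # reverse-complemented at the fragment end; mate 1 is either with
      # equal probability
      if (runif(1) < 0.5) {
        s1[i] <- ml$seq; st1[i] <- "+"; t1[i] <- fpos; m1[i] <- ml$mutations
        s2[i] <- revcomp_cpp(mr$seq); st2[i] <- "-"; t2[i] <- right_start
        m2[i] <- mr$mutations
      } else {
        s1[i] <- revcomp_cpp(mr$seq); st1[i] <- "-"; t1[i] <- right_start
        m1[i] <- mr$mutations
        s2[i] <- ml$seq; st2[i] <- "+"; t2[i] <- fpos; m2[i] <- ml$mutations
      }
      ins[i] <- I
      break
    }
  }
  fq1 <- paste0(out_prefix, "_1.fastq")
  fq2 <- paste0(out_prefix, "_2.fastq")
  write_fastq(ids, s1, strrep("I", read_len), fq1)
  write_fastq(ids, s2, strrep("I", read_len), fq2)
  truth <- rbind(
    data.frame(read_id = ids, mate = 1L, pos = t1, strand = st1,
               mutations = m1, insert = ins),
    data.frame(read_id = ids, mate = 2L, pos = t2, strand = st2,
               mutations = m2, insert = ins))
  list(fastq = c(fq1, fq2), truth = truth)
}

#' Block cost model
#'
#' Describes the distribution of per-block alignment costs used by the
#' makespan simulator, modelling the observation that per-read alignment
#' time varies with seed counts and rescue paths.
#'
#' @param distribution `"constant"`, `"lognormal"` or `"bimodal"`.
#' @param params distribution parameters: `cost` (constant); `meanlog`,
#'   `sdlog` (lognormal); `p_slow`, `cost_fast`, `cost_slow` (bimodal).
#' @param seed optional RNG seed.
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(distribution = c("constant", "lognormal", "bimodal"),
                       params = list(), seed = NULL) {
  distribution <- match.arg(distribution)
  defaults <- switch(distribution,
    constant = list(cost = 1),
    lognormal = list(meanlog = 0, sdlog = 1),
    bimodal = list(p_slow = 0.2, cost_fast = 1, cost_slow = 10))
  params <- utils::modifyList(defaults, params)
  structure(list(distribution = distribution, params = params, seed = seed),
            class = "cost_model")
}

#' Sample per-block costs from a cost model
#'
#' @param model a [cost_model()].
#' @param n_blocks number of blocks, >= 1.
#' @return Positive numeric vector of length `n_blocks`; deterministic for
#'   a fixed model seed.
#' @export
sample_block_costs <- function(model, n_blocks) {
  stopifnot(inherits(model, "cost_model"), n_blocks >= 1)
  if (!is.null(model$seed)) set.seed(model$seed)
  p <- model$params
  out <- switch(model$distribution,
    constant = rep(p$cost, n_blocks),
    lognormal = rlnorm(n_blocks, p$meanlog, p$sdlog),
    bimodal = ifelse(runif(n_blocks) < p$p_slow, p$cost_slow, p$cost_fast))
  stopifnot(all(out > 0))
  out
}

#' Score alignment records against a planted truth table
#'
#' A read is counted as correctly placed when it is reported qualified on
#' the true strand within `tol` bases of its planted position; the
#' tolerance absorbs indel left-shift ambiguity.
#'
#' @param records list of alignment records, or a data frame with columns
#'   `read_id`, `pos`, `strand`, `qualified` (and optionally `mate`).
#' @param truth truth table from [simulate_reads()].
#' @param tol positional tolerance in bases (default 5).
#' @param mate restrict scoring to one mate of the truth table (default:
#'   mate 1 for single-end truth).
#' @return List with `n`, `n_mapped`, `n_correct`, `mapped_rate`,
#'   `correct_rate` and the per-read logical vector `correct`.
#' @export
score_alignments <- function(records, truth, tol = 5L, mate = 1L) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- records_to_df(records)
  }
  tr <- truth[truth$mate == mate, , drop = FALSE]
  m <- match(tr$read_id, records$read_id)
  rec <- records[m, , drop = FALSE]
  mapped <- !is.na(rec$qualified) & rec$qualified
  correct <- mapped & !is.na(rec$pos) & rec$strand == tr$strand &
    abs(rec$pos - tr$pos) <= tol
  list(n = nrow(tr), n_mapped = sum(mapped, na.rm = TRUE),
       n_correct = sum(correct, na.rm = TRUE),
       mapped_rate = mean(mapped, na.rm = TRUE),
       correct_rate = mean(correct, na.rm = TRUE), correct = correct)
}

#' Flatten alignment records into a data frame
#' @param records list of alignment records.
#' @return Data frame with one row per record.
#' @export
records_to_df <- function(records) {
  data.frame(
    read_id = vapply(records, `[[`, character(1), "read_id"),
    ref_name = vapply(records, `[[`, character(1), "ref_name"),
    pos = vapply(records, `[[`, integer(1), "pos"),
    strand = vapply(records, `[[`, character(1), "strand"),
    cigar = vapply(records, `[[`, character(1), "cigar"),
    score = vapply(records, `[[`, integer(1), "score"),
    edits = vapply(records, `[[`, integer(1), "edits"),
    stage = vapply(records, `[[`, character(1), "stage"),
    qualified = vapply(records, `[[`, logical(1), "qualified"),
    mapq = vapply(records, `[[`, integer(1), "mapq"))
}
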