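#' SAM header for a reference index
#'
#' @param index a `reference_index`.
#' @return Character vector of header lines (`@HD`, one `@SQ` per reference
#'   record, `@PG`).
#' @export
sam_header <- function(index) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", index$names, index$lengths),
    sprintf("@PG\tID:blockalign\tPN:blockalign\tVN:%s",
            as.character(utils::packageVersion("blockalign"))))
}

# reference bases consumed by a CIGAR (M and D ops)
cigar_ref_span <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(0L)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  sum(lens[ops %in% c("M", "D")])
}

# read bases consumed by a CIGAR (M, I and S ops)
cigar_read_span <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(0L)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  sum(lens[ops %in% c("M", "I", "S")])
}

# Is this record reported as mapped in SAM?  Qualified alignments only.
.rec_mapped <- function(rec) {
  isTRUE(rec$qualified) && !is.na(rec$stage) && rec$stage != "UNALIGNED"
}

# Render one AlignmentRecord as a SAM body line.  Pairing fields (flag,
# rnext, pnext, tlen) may have been attached by finalize_pair(); otherwise
# single-end flags are derived here.
sam_line <- function(rec) {
  mapped <- .rec_mapped(rec)
  flag <- rec$flag
  if (is.null(flag)) flag <- if (mapped && rec$strand == "-") 16L else if (mapped) 0L else 4L
  if (mapped) {
    seq <- if (rec$strand == "-") revcomp(rec$read_seq) else rec$read_seq
    qual <- rec$read_qual
    if (!is.na(qual) && rec$strand == "-") {
      qual <- paste(rev(strsplit(qual, "", fixed = TRUE)[[1]]), collapse = "")
    }
    paste(rec$read_id, flag, rec$ref_name, rec$pos + 1L, rec$mapq, rec$cigar,
          if (is.null(rec$rnext)) "*" else rec$rnext,
          if (is.null(rec$pnext)) 0L else rec$pnext,
          if (is.null(rec$tlen)) 0L else rec$tlen,
          seq, if (is.na(qual)) "*" else qual, sep = "\t")
  } else {
    qual <- rec$read_qual
    paste(rec$read_id, flag, "*", 0L, 0L, "*",
          if (is.null(rec$rnext)) "*" else rec$rnext,
          if (is.null(rec$pnext)) 0L else rec$pnext,
          0L, rec$read_seq, if (is.na(qual)) "*" else qual, sep = "\t")
  }
}

#' Append alignment records to an intermediate SAM body file
#'
#' Intermediate files are headerless SAM bodies, one per worker; the
#' gatherer owns the header, which makes concatenation order-free.
#'
#' @param intermediate_path file to append to (created if absent).
#' @param records list of alignment records, as produced by
#'   [align_single()] / [align_paired()] (and, for paired output,
#'   [finalize_pair()]).
#' @param ref_lengths optional named vector of reference lengths; when
#'   supplied, any mapped record extending beyond its reference is refused
#'   with a validation error.
#' @return Number of lines appended (invisibly one per record).
#' @export
write_alignments <- function(intermediate_path, records, ref_lengths = NULL) {
  if (length(records) == 0L) {
    if (!file.exists(intermediate_path)) file.create(intermediate_path)
    return(0L)
  }
  if (!is.null(ref_lengths)) {
    for (rec in records) {
      if (.rec_mapped(rec)) {
        rl <- ref_lengths[[rec$ref_name]]
        if (is.null(rl) || is.na(rl)) {
          stop("record for read '", rec$read_id,
               "' names unknown reference '", rec$ref_name, "'")
        }
        if (rec$pos < 0L || rec$pos + cigar_ref_span(rec$cigar) > rl) {
          stop("record for read '", rec$read_id,
               "' extends beyond reference '", rec$ref_name,
               "' (pos ", rec$pos, ", length ", rl, ")")
        }
      }
    }
  }
  lines <- vapply(records, sam_line, character(1))
  con <- file(intermediate_path, "at")
  on.exit(close(con))
  writeLines(lines, con)
  length(lines)
}

#' Merge intermediate SAM bodies into a final SAM file
#'
#' Writes the header, appends each intermediate body in the order given
#' (completion order, when called by the gatherer), and deletes every
#' consumed intermediate file.
#'
#' @param output_path final SAM path (overwritten).
#' @param intermediate_paths intermediate body files, in completion order.
#' @param header character vector of SAM header lines.
#' @return Total number of body records written.
#' @export
merge_intermediate <- function(output_path, intermediate_paths, header) {
  missing <- intermediate_paths[!file.exists(intermediate_paths)]
  if (length(missing)) {
    stop("missing intermediate file(s): ", paste(missing, collapse = ", "))
  }
  writeLines(header, output_path)
  total <- 0L
  for (f in intermediate_paths) {
    total <- total + .append_sam_body(output_path, f)
    unlink(f)
  }
  total
}

# append one body file to output, returning its line count
.append_sam_body <- function(output_path, body_path) {
  n <- 0L
  con <- file(body_path, "rt")
  out <- file(output_path, "at")
  on.exit({ close(con); close(out) })
  repeat {
    lines <- readLines(con, n = 20000L)
    if (length(lines) == 0L) break
    writeLines(lines, out)
    n <- n + length(lines)
  }
  n
}

#' Read the body lines of a SAM file
#' @param path SAM file.
#' @return Character vector of body (non-`@`) lines.
#' @export
read_sam_body <- function(path) {
  lines <- readLines(path)
  lines[substr(lines, 1L, 1L) != "@"]
}
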