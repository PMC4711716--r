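#' Open a forward-only read stream over a FASTQ or FASTA file
#'
#' The stream keeps a cursor counting records already consumed.  It only
#' moves forward: block requests must target record ranges at or beyond the
#' cursor.  One stream is opened per process, so many processes can read the
#' same file concurrently through independent cursors.
#'
#' @param path file path.
#' @param format `"fastq"` (4-line records) or `"fasta"`.
#' @return An object of class `read_stream`.
#' @export
open_read_stream <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  s <- new.env(parent = emptyenv())
  s$path <- path
  s$format <- format
  s$con <- file(path, "rt")
  s$cursor <- 0L
  s$line <- 0L        # lines consumed, for error messages
  s$pending <- NULL   # pushed-back FASTA header line
  s$eof <- FALSE
  class(s) <- "read_stream"
  # validate the first record (if any), then rewind
  first <- tryCatch(stream_read(s, 1L), error = function(e) {
    close(s$con)
    stop(e)
  })
  close(s$con)
  s$con <- file(path, "rt")
  s$cursor <- 0L
  s$line <- 0L
  s$pending <- NULL
  s$eof <- FALSE
  s
}

#' Close a read stream
#' @param stream a `read_stream`.
#' @export
close_read_stream <- function(stream) {
  if (!is.null(stream$con) && isOpen(stream$con)) close(stream$con)
  invisible(NULL)
}

.parse_fastq_lines <- function(lines, first_line) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record at line ", first_line + n,
         " of input (record is not 4 lines)")
  }
  k <- n %/% 4L
  if (k == 0L) return(list(id = character(0), seq = character(0),
                           qual = character(0)))
  i1 <- seq(1L, n, by = 4L)
  hdr <- lines[i1]; seq <- lines[i1 + 1L]
  plus <- lines[i1 + 2L]; qual <- lines[i1 + 3L]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("malformed FASTQ header at line ", first_line + (bad[1] - 1L) * 4L + 1L,
         ": expected '@'")
  }
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop("malformed FASTQ separator at line ",
         first_line + (bad[1] - 1L) * 4L + 3L, ": expected '+'")
  }
  seq <- toupper(seq)
  bad <- which(nchar(seq) != nchar(qual) | nchar(seq) < 1L)
  if (length(bad)) {
    stop("sequence/quality length mismatch at line ",
         first_line + (bad[1] - 1L) * 4L + 4L)
  }
  bad <- grep("[^ACGTN]", seq)
  if (length(bad)) {
    stop("invalid base in sequence at line ",
         first_line + (bad[1] - 1L) * 4L + 2L)
  }
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  bad <- which(!nzchar(id))
  if (length(bad)) {
    stop("empty read id at line ", first_line + (bad[1] - 1L) * 4L + 1L)
  }
  list(id = id, seq = seq, qual = qual)
}

# read up to n records from a stream, advancing the cursor
stream_read <- function(stream, n) {
  if (n <= 0L || stream$eof) {
    return(list(id = character(0), seq = character(0), qual = character(0)))
  }
  if (stream$format == "fastq") {
    lines <- readLines(stream$con, n = 4L * n)
    if (length(lines) < 4L * n) stream$eof <- TRUE
    rec <- .parse_fastq_lines(lines, stream$line)
    stream$line <- stream$line + length(lines)
  } else {
    rec <- .read_fasta_records(stream, n)
  }
  stream$cursor <- stream$cursor + length(rec$id)
  rec
}

.read_fasta_records <- function(stream, n) {
  id <- character(0); seq <- character(0)
  repeat {
    if (length(id) >= n) break
    hdr <- stream$pending
    if (is.null(hdr)) {
      hdr <- readLines(stream$con, n = 1L)
      if (length(hdr) == 0L) { stream$eof <- TRUE; break }
      stream$line <- stream$line + 1L
    } else {
      stream$pending <- NULL
    }
    if (substr(hdr, 1L, 1L) != ">") {
      stop("malformed FASTA header at line ", stream$line, ": expected '>'")
    }
    chunks <- character(0)
    repeat {
      ln <- readLines(stream$con, n = 1L)
      if (length(ln) == 0L) { stream$eof <- TRUE; break }
      stream$line <- stream$line + 1L
      if (substr(ln, 1L, 1L) == ">") { stream$pending <- ln; break }
      chunks <- c(chunks, ln)
    }
    s <- toupper(paste(chunks, collapse = ""))
    if (nchar(s) < 1L) stop("empty sequence for FASTA record ending at line ",
                            stream$line)
    if (grepl("[^ACGTN]", s)) {
      stop("invalid base in FASTA record ending at line ", stream$line)
    }
    id <- c(id, sub("\\s.*$", "", substring(hdr, 2L)))
    seq <- c(seq, s)
  }
  list(id = id, seq = seq, qual = rep(NA_character_, length(id)))
}

# skip n records (cheap: no parsing for FASTQ beyond line counting)
stream_skip <- function(stream, n) {
  if (n <= 0L || stream$eof) return(invisible(0L))
  skipped <- 0L
  if (stream$format == "fastq") {
    lines <- readLines(stream$con, n = 4L * n)
    if (length(lines) < 4L * n) stream$eof <- TRUE
    stream$line <- stream$line + length(lines)
    skipped <- length(lines) %/% 4L
  } else {
    rec <- .read_fasta_records(stream, n)
    skipped <- length(rec$id)
  }
  stream$cursor <- stream$cursor + skipped
  invisible(skipped)
}

#' Read one block of reads, skipping ahead as needed
#'
#' Returns records `[target_index * block_size, target_index * block_size +
#' block_size)` of the file, skipping any records between the stream cursor
#' and the block start.  A request past the end of the file returns an empty
#' block; this is how workers discover that the input is exhausted.
#'
#' @param stream a `read_stream`.
#' @param target_index 0-based block index; the block start must lie at or
#'   beyond the current cursor (streams never rewind).
#' @param block_size records per block.
#' @return A list with `index`, and parallel vectors `id`, `seq`, `qual`
#'   (class `read_block`).  Only the final block of a file may be partial.
#' @export
read_block <- function(stream, target_index, block_size) {
  target_index <- as.integer(target_index)
  block_size <- as.integer(block_size)
  stopifnot(target_index >= 0L, block_size >= 1L)
  start <- target_index * block_size
  if (start < stream$cursor) {
    stop("backward seek requested: block ", target_index, " starts at record ",
         start, " but stream cursor is at ", stream$cursor)
  }
  stream_skip(stream, start - stream$cursor)
  rec <- stream_read(stream, block_size)
  structure(list(index = target_index, id = rec$id, seq = rec$seq,
                 qual = rec$qual), class = "read_block")
}

#' Read one synchronized block from a pair of mate files
#'
#' Both streams are skipped and read identically; the two record lists are
#' positionally aligned (record i of each is a mate pair).  Unequal record
#' counts are detected at the first block where one file runs short.
#'
#' @param stream1,stream2 `read_stream`s over the two mate files.
#' @inheritParams read_block
#' @return A list with `index`, `mates1`, `mates2` (class `paired_block`).
#' @export
read_pair_block <- function(stream1, stream2, target_index, block_size) {
  b1 <- read_block(stream1, target_index, block_size)
  b2 <- read_block(stream2, target_index, block_size)
  if (length(b1$id) != length(b2$id)) {
    stop("paired input files desynchronized at block ", target_index, ": ",
         length(b1$id), " vs ", length(b2$id), " records")
  }
  structure(list(index = as.integer(target_index),
                 mates1 = b1[c("id", "seq", "qual")],
                 mates2 = b2[c("id", "seq", "qual")]),
            class = "paired_block")
}

#' Count records in a FASTQ/FASTA file
#' @param path file path.
#' @param format `"fastq"` or `"fasta"`.
#' @return Integer record count.
#' @export
count_records <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  con <- file(path, "rt")
  on.exit(close(con))
  n <- 0L
  if (format == "fastq") {
    repeat {
      lines <- readLines(con, n = 40000L)
      if (length(lines) == 0L) break
      n <- n + length(lines)
    }
    if (n %% 4L != 0L) stop("truncated FASTQ file: ", path)
    n %/% 4L
  } else {
    repeat {
      lines <- readLines(con, n = 40000L)
      if (length(lines) == 0L) break
      n <- n + sum(substr(lines, 1L, 1L) == ">")
    }
    n
  }
}
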