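#' Initialize shared scheduler state
#'
#' The shared state lives in a directory visible to all worker processes on
#' one machine: a counter file holding the index of the first block not yet
#' claimed, a lock realized as an atomically created lock directory, and one
#' end-flag file per worker.  The counter is initialized to `P - 1`: blocks
#' `0 .. P-2` are pre-assigned (worker rank r starts on block r-1), so the
#' first claim returns `P - 1`.
#'
#' @param dir directory to hold the state (created if needed).
#' @param P total number of processes (gatherer + workers).
#' @return An object of class `shared_state`.
#' @export
init_shared_state <- function(dir, P) {
  P <- as.integer(P)
  stopifnot(P >= 2L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(as.character(P - 1L), file.path(dir, "next_block"))
  unlink(file.path(dir, "lock"), recursive = TRUE)
  unlink(Sys.glob(file.path(dir, "end_*")))
  structure(list(dir = dir, P = P), class = "shared_state")
}

.lock_acquire <- function(shared) {
  lock <- file.path(shared$dir, "lock")
  while (!suppressWarnings(dir.create(lock))) Sys.sleep(2e-4)
  invisible(lock)
}

.lock_release <- function(shared) {
  unlink(file.path(shared$dir, "lock"), recursive = TRUE)
}

#' Atomically claim the next unprocessed block
#'
#' Reads and increments the shared next-block counter under the lock; the
#' lock is held only for this read-modify-write, so contention is limited to
#' workers finishing a block at the same instant.
#'
#' @param shared a `shared_state`.
#' @return The claimed 0-based block index.
#' @export
claim_next_block <- function(shared) {
  cf <- file.path(shared$dir, "next_block")
  .lock_acquire(shared)
  on.exit(.lock_release(shared))
  v <- as.integer(readLines(cf, n = 1L))
  writeLines(as.character(v + 1L), cf)
  v
}

.end_flag_path <- function(shared, rank) {
  file.path(shared$dir, sprintf("end_%d", rank))
}

set_end_flag <- function(shared, rank) {
  file.create(.end_flag_path(shared, rank))
  invisible(NULL)
}

end_flag_set <- function(shared, rank) {
  file.exists(.end_flag_path(shared, rank))
}

#' Static distribution plan
#'
#' Splits `total_records` reads into `P - 1` contiguous half-open ranges of
#' `ceiling(M / (P - 1))` records (the last possibly shorter or empty):
#' effectively one block per worker, assigned up front.
#'
#' @param total_records number of reads M.
#' @param P total number of processes (gatherer + workers), >= 2.
#' @return Data frame with one row per worker rank: `rank`, `start`, `end`
#'   (0-based, half-open), partitioning `[0, M)`.
#' @export
static_plan <- function(total_records, P) {
  M <- as.integer(total_records); P <- as.integer(P)
  stopifnot(P >= 2L, M >= 0L)
  W <- P - 1L
  chunk <- if (M == 0L) 0L else as.integer(ceiling(M / W))
  start <- pmin(M, (seq_len(W) - 1L) * chunk)
  end <- pmin(M, seq_len(W) * chunk)
  data.frame(rank = seq_len(W), start = start, end = end)
}

# align the records of one block (or chunk); returns SAM-ready records
.align_block_records <- function(block, index, params, config) {
  scoring <- params$scoring; qp <- params$qp
  mm <- params$min_mem_length; k <- params$k
  if (config$mode == "single") {
    n <- length(block$id)
    worker_fun <- function(i) {
      align_single(list(id = block$id[i], seq = block$seq[i],
                        qual = block$qual[i]),
                   index, scoring, qp, mm, k)
    }
  } else {
    n <- length(block$mates1$id)
    worker_fun <- function(i) {
      pair <- align_paired(list(id = block$mates1$id[i],
                                seq = block$mates1$seq[i],
                                qual = block$mates1$qual[i]),
                           list(id = block$mates2$id[i],
                                seq = block$mates2$seq[i],
                                qual = block$mates2$qual[i]),
                           index, scoring, qp, mm, k)
      finalize_pair(pair)
    }
  }
  if (n == 0L) return(list())
  out <- if (config$T > 1L) {
    parallel::mclapply(seq_len(n), worker_fun, mc.cores = config$T,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n), worker_fun)
  }
  if (config$mode == "paired") out <- do.call(c, out)
  out
}

#' Run one alignment worker
#'
#' Workers open their own streams over the input file(s), align block
#' `rank - 1` first, then repeatedly claim the next block from the shared
#' counter (on-demand) or walk their pre-assigned record range (static),
#' appending results to their private intermediate file.  When the input is
#' exhausted the worker sets its end flag and returns.
#'
#' @param rank worker rank in `[1, P)`.
#' @param config a [scheduler_config()].
#' @param index a `reference_index`.
#' @param params list with `scoring`, `qp`, `min_mem_length`, `k`.
#' @param shared a `shared_state`.
#' @param input_paths character vector of one (single) or two (paired)
#'   FASTQ paths.
#' @param plan static plan from [static_plan()] (static distribution only).
#' @return A worker report: `rank`, `blocks_done`, `records_aligned`,
#'   `intermediate_path`.
#' @export
run_worker <- function(rank, config, index, params, shared, input_paths,
                       plan = NULL) {
  rank <- as.integer(rank)
  stopifnot(rank >= 1L, rank < config$P)
  inter <- file.path(shared$dir, sprintf("inter_%d.sam", rank))
  file.create(inter)
  ref_lengths <- stats::setNames(index$lengths, index$names)
  paired <- config$mode == "paired"
  s1 <- open_read_stream(input_paths[1], "fastq")
  s2 <- if (paired) open_read_stream(input_paths[2], "fastq") else NULL
  on.exit({
    close_read_stream(s1)
    if (!is.null(s2)) close_read_stream(s2)
  })
  blocks_done <- integer(0)
  records <- 0L
  log <- function(...) if (isTRUE(config$verbose)) {
    message(sprintf("[rank %d] ", rank), ...)
  }
  take <- function(target) {
    if (paired) read_pair_block(s1, s2, target, config$block_size)
    else read_block(s1, target, config$block_size)
  }
  nrec <- function(b) if (paired) length(b$mates1$id) else length(b$id)
  if (config$distribution == "ondemand") {
    my_block <- rank - 1L
    repeat {
      block <- take(my_block)
      if (nrec(block) == 0L) break
      log("claimed block ", my_block, " (", nrec(block), " records)")
      recs <- .align_block_records(block, index, params, config)
      records <- records + write_alignments(inter, recs, ref_lengths)
      blocks_done <- c(blocks_done, my_block)
      log("block ", my_block, " done")
      my_block <- claim_next_block(shared)
    }
  } else {
    rng <- plan[plan$rank == rank, , drop = FALSE]
    if (nrow(rng) != 1L) stop("no static range for rank ", rank)
    stream_skip(s1, rng$start)
    if (paired) stream_skip(s2, rng$start)
    cur <- rng$start
    while (cur < rng$end) {
      n <- min(config$block_size, rng$end - cur)
      block <- if (paired) {
        b1 <- stream_read(s1, n); b2 <- stream_read(s2, n)
        if (length(b1$id) != length(b2$id)) {
          stop("paired input files desynchronized near record ", cur)
        }
        list(mates1 = b1, mates2 = b2)
      } else {
        stream_read(s1, n)
      }
      got <- if (paired) length(block$mates1$id) else length(block$id)
      if (got == 0L) break
      recs <- .align_block_records(block, index, params, config)
      records <- records + write_alignments(inter, recs, ref_lengths)
      cur <- cur + got
    }
    blocks_done <- if (rng$end > rng$start) rank - 1L else integer(0)
  }
  report <- list(rank = rank, blocks_done = blocks_done,
                 records_aligned = records, intermediate_path = inter)
  jsonlite::write_json(report, file.path(shared$dir,
                                         sprintf("report_%d.json", rank)),
                       auto_unbox = TRUE)
  set_end_flag(shared, rank)
  log("end flag set")
  report
}

#' Run the rank-0 gatherer
#'
#' Polls the workers' end flags every `poll_interval` seconds; whenever a
#' flag is found set, the corresponding intermediate file is appended to the
#' output, deleted, and the flag cleared.  Returns once all `P - 1` workers
#' have been merged.  If worker jobs are supplied, a worker that exits
#' without setting its flag aborts the gather immediately; otherwise (and in
#' addition) a liveness timeout of `gather_timeout` seconds without progress
#' raises an error naming the missing ranks.
#'
#' @param shared a `shared_state`.
#' @param config a [scheduler_config()].
#' @param intermediate_paths intermediate file paths indexed by worker rank.
#' @param output_path final SAM path; must already contain the header.
#' @param jobs optional list of `parallel::mcparallel()` job objects, used
#'   to detect crashed workers early.
#' @return A gather report: `merged_order` (ranks in completion order),
#'   `total_records`, `worker_results` (collected job values, if any).
#' @export
run_gatherer <- function(shared, config, intermediate_paths, output_path,
                         jobs = NULL) {
  W <- config$P - 1L
  done <- logical(W)
  merged_order <- integer(0)
  total <- 0L
  collected <- list()
  jobs_left <- jobs
  last_progress <- Sys.time()
  while (sum(done) < W) {
    progress <- FALSE
    for (r in seq_len(W)) {
      if (!done[r] && end_flag_set(shared, r)) {
        total <- total + .append_sam_body(output_path, intermediate_paths[r])
        unlink(intermediate_paths[r])
        unlink(.end_flag_path(shared, r))  # end[i] = 0
        done[r] <- TRUE
        merged_order <- c(merged_order, r)
        progress <- TRUE
      }
    }
    if (length(jobs_left)) {
      fin <- suppressWarnings(parallel::mccollect(jobs_left, wait = FALSE))
      if (!is.null(fin)) {
        got <- names(fin)[!vapply(fin, is.null, logical(1))]
        for (nm in got) collected[[nm]] <- fin[[nm]]
        pids <- as.character(vapply(jobs_left, `[[`, integer(1), "pid"))
        jobs_left <- jobs_left[!(pids %in% got)]
      }
      bad <- vapply(collected, function(x) inherits(x, "try-error"),
                    logical(1))
      if (any(bad)) {
        stop("worker process failed: ",
             conditionMessage(attr(collected[[which(bad)[1]]],
                                   "condition")))
      }
    }
    if (progress) {
      last_progress <- Sys.time()
    } else {
      if (as.numeric(difftime(Sys.time(), last_progress, units = "secs")) >
          config$gather_timeout) {
        stop("gather timed out; no end flag from rank(s) ",
             paste(which(!done), collapse = ", "))
      }
      Sys.sleep(config$poll_interval)
    }
  }
  list(merged_order = merged_order, total_records = total,
       worker_results = collected, jobs_left = jobs_left)
}

#' Parallel alignment run
#'
#' Orchestrates one alignment: builds (or reuses) the reference index,
#' forks `P - 1` worker processes, runs the rank-0 gatherer in the calling
#' process, and produces a single SAM file containing every input read
#' exactly once.  The record multiset of the output is invariant to `P`,
#' `T`, `block_size` and the distribution policy; only the record order may
#' differ between configurations.
#'
#' @param config a [scheduler_config()].
#' @param genome_path reference FASTA.
#' @param read_paths one FASTQ (single-end) or two (paired-end).
#' @param output_path final SAM path.
#' @param scoring a [scoring_params()] object.
#' @param qp a [qual_params()] object.
#' @param min_mem_length minimum MEM seed length.
#' @param k exact-match k-mer length.
#' @param index optional pre-built `reference_index` (skips the build).
#' @param workdir directory for shared state and intermediate files
#'   (default: a fresh temporary directory, removed on exit).
#' @return A run report: `output_path`, `total_records`, `worker_reports`,
#'   `gather_report`, `config`.
#' @export
run_parallel <- function(config, genome_path, read_paths, output_path,
                         scoring = scoring_params(), qp = qual_params(),
                         min_mem_length = 19L, k = 13L, index = NULL,
                         workdir = NULL) {
  stopifnot(inherits(config, "scheduler_config"))
  if (config$mode == "paired" && length(read_paths) != 2L) {
    stop("paired mode requires two read files")
  }
  if (config$mode == "single" && length(read_paths) != 1L) {
    stop("single mode requires one read file")
  }
  if (is.null(index)) index <- build_index(genome_path, k = k)
  params <- list(scoring = scoring, qp = qp,
                 min_mem_length = as.integer(min_mem_length),
                 k = as.integer(k))
  own_workdir <- is.null(workdir)
  if (own_workdir) workdir <- tempfile("blockalign_run_")
  shared <- init_shared_state(workdir, config$P)
  W <- config$P - 1L
  inter <- file.path(workdir, sprintf("inter_%d.sam", seq_len(W)))
  plan <- NULL
  if (config$distribution == "static") {
    plan <- static_plan(count_records(read_paths[1], "fastq"), config$P)
  }
  writeLines(sam_header(index), output_path)
  jobs <- lapply(seq_len(W), function(r) {
    parallel::mcparallel(
      run_worker(r, config, index, params, shared, read_paths, plan),
      name = sprintf("worker_%d", r))
  })
  gather <- tryCatch(
    run_gatherer(shared, config, inter, output_path, jobs = jobs),
    error = function(e) {
      for (j in jobs) try(tools::pskill(j$pid), silent = TRUE)
      try(suppressWarnings(parallel::mccollect(jobs, wait = FALSE)),
          silent = TRUE)
      unlink(output_path)
      if (own_workdir) unlink(workdir, recursive = TRUE)
      stop("parallel run failed: ", conditionMessage(e), call. = FALSE)
    })
  leftovers <- if (length(gather$jobs_left)) {
    suppressWarnings(parallel::mccollect(gather$jobs_left))
  } else list()
  results <- c(gather$worker_results,
               leftovers[!vapply(leftovers, is.null, logical(1))])
  bad <- vapply(results, function(x) inherits(x, "try-error"), logical(1))
  if (any(bad)) {
    unlink(output_path)
    if (own_workdir) unlink(workdir, recursive = TRUE)
    stop("worker failed: ",
         conditionMessage(attr(results[[which(bad)[1]]], "condition")))
  }
  reports <- lapply(seq_len(W), function(r) {
    f <- file.path(workdir, sprintf("report_%d.json", r))
    if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE)
    else NULL
  })
  if (own_workdir) unlink(workdir, recursive = TRUE)
  list(output_path = output_path, total_records = gather$total_records,
       worker_reports = reports, gather_report = gather, config = config)
}

#' Simulate the makespan of the two distribution policies
#'
#' Given per-block alignment costs, computes the completion time of the
#' slowest worker under (a) the on-demand policy -- list scheduling with
#' block `r - 1` pre-assigned to worker `r` and subsequent blocks claimed in
#' index order by whichever worker finishes first -- and (b) the static
#' policy, which hands each worker one contiguous equal-count share.
#'
#' @param block_costs positive numeric vector of per-block costs.
#' @param workers number of workers, >= 1.
#' @param policy `"ondemand"` or `"static"`.
#' @return The makespan (same units as the costs).
#' @export
#' @examples
#' costs <- c(5, 1, 1, 1, 1, 1)
#' simulate_makespan(costs, workers = 2, policy = "ondemand")
#' simulate_makespan(costs, workers = 2, policy = "static")
simulate_makespan <- function(block_costs, workers,
                              policy = c("ondemand", "static")) {
  policy <- match.arg(policy)
  workers <- as.integer(workers)
  stopifnot(workers >= 1L, all(block_costs > 0))
  B <- length(block_costs)
  if (B == 0L) return(0)
  if (policy == "static") {
    chunk <- ceiling(B / workers)
    groups <- split(block_costs,
                    rep(seq_len(workers), each = chunk, length.out = B))
    return(max(vapply(groups, sum, numeric(1))))
  }
  finish <- numeric(workers)
  nb <- 0L
  for (r in seq_len(min(workers, B))) {  # pre-assigned block r - 1
    finish[r] <- block_costs[r]
    nb <- r
  }
  while (nb < B) {
    r <- which.min(finish)  # ties: lowest rank
    nb <- nb + 1L
    finish[r] <- finish[r] + block_costs[nb]
  }
  max(finish)
}
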