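test_that("the shared counter starts at P - 1 and increments under claims", {
  sh <- init_shared_state(tempfile("shared"), P = 4)
  expect_identical(claim_next_block(sh), 3L)
  expect_identical(claim_next_block(sh), 4L)
  expect_identical(claim_next_block(sh), 5L)
})

test_that("concurrent claims form a contiguous duplicate-free range", {
  sh <- init_shared_state(tempfile("shared"), P = 5)
  jobs <- lapply(1:4, function(w) {
    parallel::mcparallel({
      vals <- integer(25)
      for (i in 1:25) {
        Sys.sleep(stats::runif(1, 0, 5e-4))
        vals[i] <- claim_next_block(sh)
      }
      vals
    })
  })
  got <- unname(unlist(parallel::mccollect(jobs)))
  expect_identical(sort(got), 4:103)
})

test_that("static plans partition the records into equal contiguous shares", {
  p <- static_plan(100, 5)
  expect_identical(p$start, c(0L, 25L, 50L, 75L))
  expect_identical(p$end, c(25L, 50L, 75L, 100L))
  p0 <- static_plan(0, 4)
  expect_true(all(p0$start == 0L & p0$end == 0L))
  set.seed(501)
  for (i in 1:25) {
    M <- sample(0:500, 1); P <- sample(2:9, 1)
    p <- static_plan(M, P)
    expect_identical(nrow(p), P - 1L)
    covered <- unlist(mapply(function(s, e) seq_len(e - s) + s - 1L,
                             p$start, p$end, SIMPLIFY = FALSE))
    expect_identical(sort(covered), seq_len(M) - 1L)  # disjoint cover
  }
})

test_that("a single worker takes every block in order", {
  set.seed(502)
  g <- rand_dna(5000)
  idx <- make_index(g, "chr1")
  fq <- write_temp_fastq(vapply(1:7, function(i) {
    p <- sample(4000, 1); substr(g, p, p + 59)
  }, character(1)))
  sh <- init_shared_state(tempfile("shared"), P = 2)
  cfg <- scheduler_config(P = 2, block_size = 3)
  params <- list(scoring = scoring_params(), qp = qual_params(),
                 min_mem_length = 19L, k = 13L)
  rep1 <- run_worker(1, cfg, idx, params, sh, fq)
  expect_identical(rep1$blocks_done, c(0L, 1L, 2L))
  expect_identical(rep1$records_aligned, 7L)
  expect_true(file.exists(rep1$intermediate_path))
  expect_length(readLines(rep1$intermediate_path), 7)
})

test_that("an empty input leaves an empty intermediate file and a set flag", {
  idx <- make_index(rand_dna(1000))
  fq <- tempfile(fileext = ".fastq"); file.create(fq)
  sh <- init_shared_state(tempfile("shared"), P = 2)
  cfg <- scheduler_config(P = 2, block_size = 10)
  params <- list(scoring = scoring_params(), qp = qual_params(),
                 min_mem_length = 19L, k = 13L)
  rep1 <- run_worker(1, cfg, idx, params, sh, fq)
  expect_identical(rep1$blocks_done, integer(0))
  expect_identical(rep1$records_aligned, 0L)
  expect_length(readLines(rep1$intermediate_path), 0)
  # the gatherer sees the flag and merges the empty file immediately
  out <- tempfile(fileext = ".sam")
  writeLines(sam_header(idx), out)
  g <- run_gatherer(sh, cfg, rep1$intermediate_path, out)
  expect_identical(g$merged_order, 1L)
  expect_identical(g$total_records, 0L)
})

test_that("the gatherer times out when a worker never sets its flag", {
  sh <- init_shared_state(tempfile("shared"), P = 3)
  cfg <- scheduler_config(P = 3, poll_interval = 0.02, gather_timeout = 0.3)
  out <- tempfile(fileext = ".sam"); file.create(out)
  inter <- c(tempfile(), tempfile())
  file.create(inter)
  set_end_flag(sh, 1)  # rank 2 never reports
  expect_error(run_gatherer(sh, cfg, inter, out), "rank\\(s\\) 2")
})

test_that("two workers partition the blocks exactly", {
  set.seed(503)
  g <- rand_dna(20000)
  idx <- make_index(g, "chr1")
  sim <- simulate_reads(g, 60, read_len = 60, subst_rate = 0, seed = 99,
                        out_prefix = tempfile())
  out <- tempfile(fileext = ".sam")
  res <- run_parallel(scheduler_config(P = 3, block_size = 5), fa <- NULL,
                      sim$fastq, out, index = idx)
  done <- lapply(res$worker_reports, function(w) w$blocks_done)
  all_blocks <- sort(unlist(done))
  expect_identical(all_blocks, 0:11)                    # 60 / 5 = 12 blocks
  expect_identical(length(unlist(done)), 12L)           # no block twice
  expect_identical(res$total_records, 60L)
})

test_that("output record multisets are invariant to P, block size and policy", {
  set.seed(504)
  g <- rand_dna(20000)
  idx <- make_index(g, "chr1")
  sim <- simulate_reads(g, 80, read_len = 80, subst_rate = 0.02, seed = 7,
                        out_prefix = tempfile())
  bodies <- list()
  for (cfg in list(scheduler_config(P = 2, block_size = 5000),
                   scheduler_config(P = 3, block_size = 7),
                   scheduler_config(P = 3, block_size = 7,
                                    distribution = "static"),
                   scheduler_config(P = 5, block_size = 1))) {
    out <- tempfile(fileext = ".sam")
    res <- run_parallel(cfg, NULL, sim$fastq, out, index = idx)
    body <- read_sam_body(out)
    expect_length(body, 80)
    ids <- vapply(strsplit(body, "\t"), `[`, character(1), 1)
    expect_identical(sort(ids), sort(sim$truth$read_id))  # exactly once
    bodies[[length(bodies) + 1L]] <- sort(body)
  }
  for (i in 2:length(bodies)) expect_identical(bodies[[i]], bodies[[1]])
})

test_that("paired runs emit both mates once and stay synchronized", {
  set.seed(505)
  g <- rand_dna(30000)
  idx <- make_index(g, "chr1")
  sim <- simulate_reads(g, 30, mode = "paired", subst_rate = 0.01, seed = 8,
                        out_prefix = tempfile())
  out <- tempfile(fileext = ".sam")
  res <- run_parallel(scheduler_config(P = 3, block_size = 4,
                                       mode = "paired"),
                      NULL, sim$fastq, out, index = idx)
  body <- read_sam_body(out)
  expect_length(body, 60)  # one line per mate
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  expect_true(all(bitwAnd(flags, 1L) == 1L))
  expect_identical(sum(bitwAnd(flags, 64L) > 0), 30L)
  expect_identical(sum(bitwAnd(flags, 128L) > 0), 30L)
  # desynchronized mate files abort the run and leave no output behind
  short <- tempfile(fileext = ".fastq")
  lines <- readLines(sim$fastq[2])
  writeLines(lines[1:(length(lines) - 8)], short)
  out2 <- tempfile(fileext = ".sam")
  expect_error(
    run_parallel(scheduler_config(P = 3, block_size = 4, mode = "paired",
                                  gather_timeout = 10),
                 NULL, c(sim$fastq[1], short), out2, index = idx),
    "desynchronized")
  expect_false(file.exists(out2))
})

test_that("makespan simulation matches closed forms and the Graham bound", {
  # homogeneous blocks: both policies fill workers evenly
  expect_equal(simulate_makespan(rep(2, 12), 4, "ondemand"), 6)
  expect_equal(simulate_makespan(rep(2, 12), 4, "static"), 6)
  # hand-checkable heterogeneous instance: worker 2 absorbs the five cheap
  # blocks (makespan 5) while a static split hands worker 1 cost 5+1+1
  expect_equal(simulate_makespan(c(5, 1, 1, 1, 1, 1), 2, "ondemand"), 5)
  expect_equal(simulate_makespan(c(5, 1, 1, 1, 1, 1), 2, "static"), 7)
  set.seed(506)
  for (i in 1:200) {
    B <- sample(1:20, 1); W <- sample(1:8, 1)
    costs <- stats::runif(B, 0.1, 10)
    ms <- simulate_makespan(costs, W, "ondemand")
    expect_lte(ms, sum(costs) / W + max(costs) + 1e-9)
    expect_gte(ms, max(max(costs), sum(costs) / W) - 1e-9)
  }
})
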