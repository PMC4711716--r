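#' Alignment scoring parameters
#'
#' Scores for the dynamic-programming extension steps.  A gap of length L
#' costs `gap_open + L * gap_extend` (both negative).  `band_width` controls
#' the half-width of the DP band around the seed diagonal and the amount of
#' reference context added on each side of a seed's extension window.
#'
#' @param match match score, positive integer (default +1).
#' @param mismatch mismatch score, negative integer (default -3).
#' @param gap_open gap-opening score, negative integer (default -5).
#' @param gap_extend per-base gap-extension score, negative (default -2).
#' @param band_width DP band half-width in bases, >= 1 (default 32).
#' @return An object of class `scoring_params`.
#' @export
#' @examples
#' scoring_params(match = 2, mismatch = -4)
scoring_params <- function(match = 1L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, band_width = 32L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  band_width <- as.integer(band_width)
  stopifnot(match > 0L, mismatch < 0L, gap_open < 0L, gap_extend < 0L,
            band_width >= 1L)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, band_width = band_width),
            class = "scoring_params")
}

#' Alignment qualification parameters
#'
#' Thresholds deciding whether a candidate alignment is reported.  Local
#' (score-maximising) alignments qualify when their score reaches
#' `min_score_fraction * match * read_length` and at least
#' `min_coverage_fraction` of the read bases are aligned to the reference.
#' Semi-global and mate-rescue alignments qualify when their edit count does
#' not exceed `max_edit_fraction * read_length`.  All comparisons are
#' inclusive (a value exactly at a threshold passes).
#'
#' @param min_score_fraction fraction of the maximum attainable local score,
#'   in (0, 1] (default 0.30).
#' @param min_coverage_fraction minimum fraction of read bases aligned in a
#'   local alignment, in (0, 1] (default 0.80).
#' @param max_edit_fraction maximum edits per read base tolerated by the
#'   semi-global/rescue stages, in \[0, 1) (default 0.10).
#' @param top_n_seeds number of top-ranked seeds carried into extension and
#'   seed pairing (default 8).
#' @param insert_min,insert_max paired-end insert-size bounds, outer edge to
#'   outer edge (defaults 100 and 500).
#' @return An object of class `qual_params`.
#' @export
qual_params <- function(min_score_fraction = 0.30,
                        min_coverage_fraction = 0.80,
                        max_edit_fraction = 0.10,
                        top_n_seeds = 8L,
                        insert_min = 100L, insert_max = 500L) {
  top_n_seeds <- as.integer(top_n_seeds)
  insert_min <- as.integer(insert_min); insert_max <- as.integer(insert_max)
  stopifnot(min_score_fraction > 0, min_score_fraction <= 1,
            min_coverage_fraction > 0, min_coverage_fraction <= 1,
            max_edit_fraction >= 0, max_edit_fraction < 1,
            top_n_seeds >= 1L, insert_min <= insert_max)
  structure(list(min_score_fraction = min_score_fraction,
                 min_coverage_fraction = min_coverage_fraction,
                 max_edit_fraction = max_edit_fraction,
                 top_n_seeds = top_n_seeds,
                 insert_min = insert_min, insert_max = insert_max),
            class = "qual_params")
}

#' Scheduler configuration
#'
#' Configuration for a parallel alignment run.  `P` counts all processes
#' including the rank-0 gatherer, so `P - 1` workers align reads.  Under the
#' on-demand policy each worker starts with block `rank - 1` and then claims
#' blocks from the shared counter; under the static policy every worker
#' receives one contiguous equal share of the reads up front.
#'
#' @param P total number of processes (gatherer + workers), >= 2.
#' @param T threads per worker, parallelising over the records of the block
#'   currently held (default 1).
#' @param block_size reads claimed per scheduler transaction (default 5000).
#' @param mode `"single"` or `"paired"`.
#' @param distribution `"ondemand"` or `"static"`.
#' @param poll_interval gatherer polling period in seconds (default 0.05).
#' @param gather_timeout seconds without progress after which the gatherer
#'   declares missing workers dead (default 120).
#' @param verbose emit per-rank progress messages.
#' @return An object of class `scheduler_config`.
#' @export
scheduler_config <- function(P = 2L, T = 1L, block_size = 5000L,
                             mode = c("single", "paired"),
                             distribution = c("ondemand", "static"),
                             poll_interval = 0.05, gather_timeout = 120,
                             verbose = FALSE) {
  P <- as.integer(P); T <- as.integer(T); block_size <- as.integer(block_size)
  mode <- match.arg(mode)
  distribution <- match.arg(distribution)
  stopifnot(P >= 2L, T >= 1L, block_size >= 1L, poll_interval > 0,
            gather_timeout > 0)
  structure(list(P = P, T = T, block_size = block_size, mode = mode,
                 distribution = distribution, poll_interval = poll_interval,
                 gather_timeout = gather_timeout, verbose = verbose),
            class = "scheduler_config")
}
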