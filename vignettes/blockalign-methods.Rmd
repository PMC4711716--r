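---
title: "Methods: seed-and-extend alignment and on-demand block scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-and-extend alignment and on-demand block scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`blockalign` couples a sensitive seed-and-extend read aligner with a
work-distribution layer that hands out *blocks* of reads to worker
processes on demand.  This vignette describes the model behind both
halves, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## The alignment model

### Reference index

`build_index()` loads every FASTA record, concatenates them with a single
`N` spacer (so no exact match can span a record boundary, because `N`
never matches anything, not even another `N`) and builds a suffix array
over the concatenation.  All seed queries are answered from the suffix
array: the exact-position list of any k-mer is a binary-search range, so
the conceptual k-mer table is realized without a second copy of the
genome.  A plain comparison-sorted suffix array is entirely adequate at
the genome sizes this package targets (up to a few megabases); compressed
indexes (FM/BWT) buy nothing at this scale and are deliberately out of
scope.

### Seeding

Two seed sources feed the extension stages:

* **MEM seeds** (`find_mem_seeds()`): every maximal exact match between
  read and genome, on both strands, of length at least `min_mem_length`
  (default 19 bases, a typical anchor length for 100 bp reads).
  Enumeration anchors a k-mer at *every* read offset (with
  `scan_k = min(k, min_mem_length)`) and extends each genome occurrence
  maximally in both directions.  This is complete: a maximal match of
  length at least `min_mem_length` necessarily contains the scan k-mer
  starting at its first position.  Duplicates arising from different
  anchors of the same match are removed.
* **Exact-match k-mer seeds** (`find_kmer_seeds()`): a fallback used when
  the MEM stage fails, sampling the read at stride `k` (default 13) into
  non-overlapping k-mers and emitting every exact genome occurrence.
  Stride sampling (rather than overlapping k-mers) keeps the candidate
  list small; it is a deliberate design choice, exposed via `k`.

The reverse strand is handled by seeding the reverse complement of the
read, so the genome is stored once; for `-` seeds, `read_offset` indexes
the reverse-complemented read.

### Extension and qualification

Each seed implies a reference window
`[genome_pos - read_offset - band_width, genome_pos - read_offset +
read_len + band_width)`; the read is aligned against this window with a
banded Smith-Waterman (affine gaps: a gap of length L costs
`gap_open + L * gap_extend`), and seeds are *ranked* by this optimal
local score.  The band spans diagonals `min(0, W - L) - band_width`
through `max(0, W - L) + band_width`, which always covers every placement
of the read inside the window plus `band_width` of indel slack; choosing
`band_width` at least as large as the longer sequence reproduces the full
DP matrix exactly, which is how the banded kernel is tested against
full-matrix oracles.

The single-end cascade is:

1. rank MEM seeds, extend the top `top_n_seeds` (default 8) locally and
   report the best **qualified** alignment;
2. otherwise attempt a **semi-global rescue** from the same ranked seed
   windows;
3. otherwise repeat both steps with exact-match k-mer seeds;
4. otherwise report the read unaligned.

Qualification is stage-dependent.  Local alignments qualify when
`score >= min_score_fraction * match * read_len` **and** at least
`min_coverage_fraction` of the read bases are aligned; semi-global and
mate-rescue alignments qualify when the edit count is at most
`max_edit_fraction * read_len`.  All thresholds are inclusive, so a value
exactly at the boundary passes.  The defaults (0.30, 0.80, 0.10) were
chosen so that every branch of the cascade is reachable and testable with
synthetic reads; they are configuration, not fixed truths, and real
applications should tune them.

The semi-global stage minimizes the *unit-cost edit distance* over all
placements of the whole read inside the window (infix alignment), rather
than maximizing the affine score.  This matches the quantity its
qualification rule tests (an edit fraction) and makes the stage exactly
checkable against an independent sliding edit-distance oracle; the affine
score of the chosen alignment is still computed and recorded.

### Paired-end alignment

`align_paired()` mirrors the single-end procedure per mate and adds three
mechanisms:

* **seed pairing** (`pair_seeds()`): all combinations of top-ranked seeds
  in FR orientation whose *implied insert* — outer edge to outer edge,
  from the plus-strand mate's leftmost base to the minus-strand mate's
  rightmost base — lies inside `[insert_min, insert_max]` (defaults
  100-500 bp).  The pair weight is the sum of the two seed rank scores,
  the simplest monotone choice; ties prefer inserts closest to the middle
  of the allowed window.
* **pair qualification**: the first seed pair (in weight order) whose
  *actual* extensions both qualify with an in-range actual insert is
  reported as a proper pair.
* **mate rescue** (`rescue_mate()`): when the pair stages fail and
  exactly one mate qualifies on its own, the other mate is searched for
  *only* inside the window implied by the anchor's position, FR
  orientation and the insert bounds (clipped to the reference; an empty
  window yields an unaligned mate), using the semi-global kernel.

One representational subtlety: a rescue can locate a mate whose edit
count exceeds the rescue budget.  Such a record keeps its stage
(`MATE_RESCUE`) and position but carries `qualified = FALSE`, and the SAM
serializer reports it as unmapped.  Only `align_single()` maintains the
strict rule that unqualified means `UNALIGNED` with no position; the
paired API deliberately preserves the diagnostic position.

### Reporting

MAPQ is not defined by the underlying model, so the package uses a simple
monotone surrogate: 60 for a uniquely best qualified alignment,
decreasing by 10 for every additional co-optimal extended window, floored
at 0.  Tie-breaking everywhere is total and documented — score
descending, then position ascending, then `+` strand first — which is
what makes serial and parallel outputs byte-identical up to record order.
Insert size (TLEN) is reported outer-edge to outer-edge with the
conventional sign pair.

## The scheduling model

The workload is distributed over `P` processes: rank 0 is a dedicated
*gatherer* and ranks `1 .. P-1` are workers.  Shared state consists of a
single integer — the index of the first block of `block_size` reads not
yet claimed — protected by a lock, plus one end flag per worker.

Under the **on-demand** policy, worker `r` starts on block `r - 1`
(the counter is initialized to `P - 1`), and after finishing a block
atomically claims the next one.  The lock is held only for the
read-modify-write of the counter.  Every worker reads the input through
its own stream, skipping records belonging to other workers' blocks; an
empty block read is the termination signal.  Workers append to private
headerless intermediate SAM files; the gatherer polls the end flags every
`poll_interval` (default 50 ms), and on seeing one merges that worker's
intermediate file into the output and deletes it.  Because intermediate
files are headerless bodies and the gatherer owns the header,
concatenation is order-free, and the output record multiset is invariant
to `P`, `T`, `block_size` and the policy.

Under the **static** baseline each worker receives one contiguous share
of `ceiling(M / (P-1))` records up front — effectively one block per
worker — and the same gatherer/intermediate-file machinery is reused so
the two policies differ *only* in distribution.

In this package the lock is an atomically created lock directory, the
counter a file read and rewritten under it, and workers are forked
processes (`parallel::mcparallel`); the contract is what matters:
read-and-increment is atomic, the hold time covers only that operation,
and a bounded sleep spin prevents starvation.  `T > 1` parallelizes over
the records of the block currently held, preserving within-block record
order, so threading does not perturb the output multiset.  The gatherer
additionally watches for workers that exit without setting their flag and
enforces a liveness timeout (`gather_timeout`, default 120 s), failing
with the missing ranks rather than hanging.

`simulate_makespan()` quantifies the scheduling trade-off without
hardware: given per-block costs it computes the completion time of the
slowest worker under both policies (on-demand is classical list
scheduling with the pre-assignment above, and therefore obeys the Graham
bound `makespan <= sum(costs)/workers + max(costs)`).  Heterogeneous
costs — here lognormal, reflecting that per-read alignment time varies
with seed counts and rescue paths — are where on-demand distribution
wins; with homogeneous costs the two policies coincide.

`block_size` trades synchronization against adaptivity: larger blocks
mean fewer counter transactions but coarser load balancing.  The default
of 5,000 reads per block is a reasonable middle ground for realistic
inputs.

## The synthetic-data generator

`simulate_genome()` draws i.i.d. bases at a configurable GC content;
`simulate_reads()` plants reads (or FR pairs with truncated-normal
inserts, default mean 300, sd 30, bounds 100-500 — typical short-insert
library geometry) at uniform loci on both strands, applies per-base
substitutions and indels at configurable rates, and records the planted
position, strand, mutation count and insert of every read in a truth
table.  An optional unique-locus mode rejects loci whose error-free read
is not a unique substring of the genome (checked on both strands via the
suffix array), which makes 100%-recovery assertions exact rather than
probabilistic.  The accuracy scorer uses a positional tolerance of ±5 bp
to absorb indel placement ambiguity, which this package does not
canonicalize.

What the generator does **not** emulate: realistic base-quality
profiles (qualities are constant and passed through, never interpreted),
platform-specific error structure (homopolymer errors, quality-dependent
substitution spectra), repeat structure of real genomes, GC-coverage
bias, or chimeric fragments.  Tests passing on this generator therefore
demonstrate the correctness of the mechanics — seeding completeness, DP
optimality, scheduling soundness, output equivalence — not the mapping
accuracy that would be observed on real libraries.

## Numerical and degenerate-input choices

* Scoring defaults: match +1, mismatch −3, gap open −5, gap extend −2,
  band width 32 — standard short-read DP constants, all exposed in
  `scoring_params()`.
* DP tie-breaks are fixed (diagonal, then gap-in-read, then gap-in-ref;
  best cell first in row-major order; semi-global end column smallest),
  so identical inputs give byte-identical CIGARs.
* An all-mismatch local problem has optimum score 0 and is reported as an
  empty alignment, which never qualifies.
* Past-EOF block requests return an empty block rather than erroring —
  the scheduler's termination test.
* Paired-file desynchronization is detected at the first block where one
  file runs short, preserving streaming (no pre-scan).
* `N` handling is uniformly conservative: an `N` matches nothing in
  seeding and scores as a mismatch in extension.

## Problem sizes used in the tests

The test-suite properties run at sizes chosen to exercise every code
path while keeping a full run comfortable on a single core: the
end-to-end equivalence property uses a 100 kb genome and 10,000 reads at
1% substitutions across 18 scheduler configurations ({2, 4, 8} processes
× block sizes {1, 7, 5000} × both policies); oracle-equivalence checks
use 100+ random instances per kernel; recovery properties use 500
planted reads (error-free and at 2% substitutions) and 500 mate-rescue
trials.  `scripts/acceptance.R` recomputes the same quantities from
scratch at a 50 kb / 2,000-read scale.

## Known limitations

* The aligner reports one best alignment per read; secondary/multi-mapping
  output is out of scope, and MAPQ is a surrogate, not a probability.
* Gapped sensitivity is bounded by the band width and by edit-distance
  rescue; long indels (beyond `band_width`) will not be recovered.
* Color-space reads and base-quality-aware scoring are not supported.
* The scheduler is single-machine by design (forked workers over a
  filesystem lock); it models the multi-process architecture faithfully
  but does not attempt distributed-memory execution, and makespan
  comparisons between policies come from the simulator, not wall-clock
  benchmarks.
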