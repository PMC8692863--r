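# Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages(library(dplyr))

# Two-transcript toy on a 200-bp chromosome: one plus-strand, one
# minus-strand model with modest exons, for geometry tests.
toy_models <- function() {
  parse_transcript_table(tibble::tribble(
    ~transcript_id, ~exon_label, ~coord_a, ~coord_b,
    "PLUS-1",  "E1",  11L,  40L,
    "PLUS-1",  "E2",  81L, 120L,
    "PLUS-1",  "E3", 151L, 190L,
    "MINUS-1", "E1", 190L, 151L,
    "MINUS-1", "E2", 120L,  81L,
    "MINUS-1", "E3",  40L,  11L
  ), chrom = "chrT")
}

toy_genome <- function(seed = 42, len = 200L) {
  withr::with_seed(seed, jq_genome(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    chrom = "chrT", first_base = 1L
  ))
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Independent reverse complement (no Biostrings): lookup table + rev().
rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive ungapped local alignment oracle: best contiguous diagonal
# segment score over all offsets of query vs read, both orientations.
# Kadane's maximum-subarray on per-column match/mismatch scores.
ungapped_oracle_score <- function(query, read, match = 2, mismatch = -3) {
  best_for <- function(q, r) {
    q <- strsplit(q, "")[[1]]; r <- strsplit(r, "")[[1]]
    nq <- length(q); nr <- length(r)
    best <- 0
    for (off in (-nq + 1):(nr - 1)) {
      i <- max(1, 1 - off):min(nq, nr - off)
      col <- ifelse(q[i] == r[i + off] & q[i] != "N", match, mismatch)
      run <- 0
      for (s in col) {
        run <- max(0, run + s)
        best <- max(best, run)
      }
    }
    best
  }
  max(best_for(query, read), best_for(query, rc_oracle(read)))
}

# Brute-force base-membership overlap oracle.
overlap_oracle <- function(fs, fe, rs, re) {
  f <- seq(fs, fe); r <- seq(rs, re)
  n_in <- sum(f %in% r)
  if (n_in == 0) "disjoint"
  else if (n_in == length(f)) "feature_within_region"
  else if (all(r %in% f)) "feature_contains_region"
  else "partial_overlap"
}

# One cached surrogate genome over the packaged models, reused across
# tests that only vary read seeds.
fixture_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- simulate_genome(seed = 101, models = dscr_transcripts())
    g
  }
})
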