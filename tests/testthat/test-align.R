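test_that("alignment metrics follow the cover/identity definitions", {
  q <- "ACGTACGTAC"
  a <- local_align(q, paste0("TTTT", q, "GGGG"))
  expect_equal(a$query_cover_pct, 100)
  expect_equal(a$identity_pct, 100)
  expect_true(a$significant)

  # 48 of 50 query bases matched contiguously, no mismatch: cover 96 >= 95
  q50 <- random_dna(50, seed = 1)
  a48 <- local_align(q50, substr(q50, 2, 49))
  expect_equal(a48$query_cover_pct, 96)
  expect_equal(a48$identity_pct, 100)
  expect_true(a48$significant)

  # full-length alignment with 2 interior mismatches: identity 96 < 97
  mutate_at_pos <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      new <- setdiff(c("A", "C", "G", "T"), old)[1]
      substr(s, p, p) <- new
    }
    s
  }
  read2 <- mutate_at_pos(q50, c(20, 30))
  a2 <- local_align(q50, read2)
  expect_equal(a2$query_cover_pct, 100)
  expect_equal(a2$matches, 48L)
  expect_equal(a2$alignment_columns, 50L)
  expect_equal(a2$identity_pct, 96)
  expect_false(a2$significant)
})

test_that("the significance filter is inclusive at both thresholds", {
  p <- filter_params()
  grid <- tibble::tibble(
    query_cover_pct = c(95, 94.9, 100, 100, 95, 96),
    identity_pct = c(97, 100, 96.9, 100, 96.9, 97)
  )
  expect_equal(is_significant(grid, p),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_error(filter_params(min_query_cover = 0), "in \\(0, 100\\]")
})

test_that("orientation handling is symmetric: a read and its reverse complement score alike", {
  withr::with_seed(21, {
    for (i in 1:20) {
      q <- random_dna(30)
      r <- paste0(random_dna(10), substr(q, 3, 27), random_dna(10))
      fwd <- local_align(q, r)
      rev <- local_align(q, rc_oracle(r))
      expect_equal(rev$score, fwd$score)
      expect_equal(rev$identity_pct, fwd$identity_pct)
      expect_equal(rev$query_cover_pct, fwd$query_cover_pct)
      expect_equal(sort(c(rev$read_orientation, fwd$read_orientation)),
                   c("forward", "revcomp"))
      # spans are reported on the original read, so they mirror
      expect_equal(rev$read_start, nchar(r) - fwd$read_end + 1)
      expect_equal(rev$read_end, nchar(r) - fwd$read_start + 1)
    }
  })
})

test_that("local scores match an exhaustive ungapped-offset oracle on gap-free cases", {
  withr::with_seed(31, {
    n_checked <- 0
    for (i in 1:200) {
      q <- random_dna(sample(8:30, 1))
      r <- if (i %% 2 == 0) {
        random_dna(sample(15:60, 1))                       # unrelated pair
      } else {
        paste0(random_dna(5), q, random_dna(5))            # embedded copy
      }
      got <- local_align(q, r)
      oracle <- ungapped_oracle_score(q, r)
      expect_gte(got$score, oracle)
      # when the optimum found is gap-free, it must equal the oracle
      if (got$alignment_columns ==
          (got$query_end - got$query_start + 1) &&
          got$alignment_columns == (got$read_end - got$read_start + 1)) {
        expect_equal(got$score, oracle)
        n_checked <- n_checked + 1
      }
    }
    expect_gt(n_checked, 150)
  })
})

test_that("exon-interior reads cannot pass the filter against junction queries", {
  g <- fixture_genome()
  m <- dscr_transcripts()
  queries <- junction_queries(build_junctions(m), g) |>
    distinct(junction_id, .keep_all = TRUE)
  # reads drawn wholly inside single exons of every transcript
  sim <- simulate_reads(
    sim_scenario("interior", unique(m$transcript_id), junction_depth = 0,
                 exon_depth = 4, background_reads = 0, error_rate = 0,
                 seed = 5),
    m, g
  )
  aln <- align_reads(sim$reads, queries)
  expect_equal(sum(aln$significant), 0)
  # max contiguous query match is one flank: cover can never reach 95
  expect_true(all(aln$query_cover_pct[aln$identity_pct == 100] <= 60))
})

test_that("significant default-parameter alignments straddle the junction midpoint", {
  g <- fixture_genome()
  m <- dscr_transcripts()
  queries <- junction_queries(build_junctions(m), g) |>
    distinct(junction_id, .keep_all = TRUE)
  sim <- simulate_reads(
    sim_scenario("mid", c("DSCR4-202", "KCNJ6-201"), junction_depth = 4,
                 exon_depth = 0, background_reads = 0, error_rate = 0.002,
                 seed = 9),
    m, g
  )
  aln <- filter(align_reads(sim$reads, queries), significant)
  expect_gt(nrow(aln), 0)
  expect_true(all(aln$query_start <= 3))
  expect_true(all(aln$query_end >= 48))
})

test_that("degenerate aligner inputs are rejected", {
  expect_error(local_align("", "ACGT"), "non-empty")
  expect_error(local_align("ACGT", "ACXT"), "outside A/C/G/T/N")
  expect_error(scoring_scheme(match = -1), "> 0")
  expect_error(scoring_scheme(gap_open = 1), "< 0")
  # N never matches: an all-N read cannot produce a positive-score identity
  a <- local_align("ACGTACGTAC", "NNNNNNNNNN")
  expect_equal(a$matches, 0L)
  expect_false(a$significant)
})
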