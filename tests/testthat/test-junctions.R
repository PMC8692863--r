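test_that("junction catalogs have exon_count - 1 strand-aware junctions", {
  m <- dscr_transcripts()
  j <- build_junctions(m)
  n_ex <- count(m, transcript_id)
  n_jn <- count(j, transcript_id)
  merged <- left_join(n_ex, n_jn, by = "transcript_id",
                      suffix = c("_exons", "_junctions"))
  expect_equal(merged$n_junctions, merged$n_exons - 1)

  k201 <- filter(j, transcript_id == "KCNJ6-201")
  expect_equal(k201$junction_label, c("E1-E2", "E2-E3", "E3-E4"))
  expect_equal(nrow(filter(j, transcript_id == "DSCR4-203")), 5)
  expect_equal(filter(j, transcript_id == "DSCR4-203")$junction_label,
               c("E1-E2", "E2-E3", "E3-E4", "E4-E5", "E5-E6"))

  # reverse strand: donor is the lowest coordinate of the upstream exon
  expect_equal(k201$donor[1], 37915884L)
  expect_equal(k201$acceptor[1], 37840709L)

  plus <- build_junctions(parse_transcript_table(tibble::tribble(
    ~transcript_id, ~exon_label, ~coord_a, ~coord_b,
    "T1", "E1", 100L, 150L,
    "T1", "E2", 200L, 250L
  )))
  expect_equal(nrow(plus), 1)
  expect_equal(plus$donor, 150L)
  expect_equal(plus$acceptor, 200L)

  single <- parse_transcript_table(
    data.frame(transcript_id = "T1", exon_label = "E1",
               coord_a = 100, coord_b = 200)
  )
  expect_equal(nrow(build_junctions(single)), 0)
})

test_that("junction identity merges equal donor-acceptor pairs across isoforms", {
  j <- build_junctions(dscr_transcripts())
  # the terminal KCNJ6 junction: downstream exons E4 and E4b share a start
  e34_201 <- filter(j, transcript_id == "KCNJ6-201", junction_label == "E3-E4")
  e34_202 <- filter(j, transcript_id == "KCNJ6-202", junction_label == "E3-E4b")
  expect_equal(e34_201$junction_id, e34_202$junction_id)

  expect_equal(shared_junction_count(j, c("KCNJ6-201", "KCNJ6-202")), 2)
  expect_equal(shared_junction_count(
    j, c("KCNJ6-202", "DSCR4-201", "DSCR4-202", "DSCR4-203")), 1)

  sharing <- shared_junctions(j)
  # sharing is symmetric/transitive on identity: one row per identity whose
  # member set carries everyone splicing that exact donor-acceptor pair
  e1e2 <- filter(sharing, junction_id == "chr21:-:38121128-38120408")
  expect_setequal(e1e2$transcripts[[1]],
                  c("KCNJ6-202", "DSCR4-201", "DSCR4-202", "DSCR4-203"))
  expect_equal(sum(sharing$shared), 3)

  disjoint <- build_junctions(toy_models())
  expect_equal(shared_junction_count(disjoint, c("PLUS-1", "MINUS-1")), 0)
})

test_that("junction queries splice flanks in transcript orientation", {
  # plus strand, flank 2 over genome with exons AAAA|...|CCCC
  g <- jq_genome("AAAATTTTTTTTCCCC", chrom = "chrT")
  m <- parse_transcript_table(tibble::tribble(
    ~transcript_id, ~exon_label, ~coord_a, ~coord_b,
    "T1", "E1", 1L, 4L,
    "T1", "E2", 13L, 16L
  ), chrom = "chrT")
  q <- junction_queries(build_junctions(m), g, flank = 2)
  expect_equal(q$sequence, "AACC")

  # the mirrored minus-strand transcript must give the reverse complement
  m_rev <- parse_transcript_table(tibble::tribble(
    ~transcript_id, ~exon_label, ~coord_a, ~coord_b,
    "T1", "E1", 16L, 13L,
    "T1", "E2", 4L, 1L
  ), chrom = "chrT")
  q_rev <- junction_queries(build_junctions(m_rev), g, flank = 2)
  expect_equal(q_rev$sequence, rc_oracle("AACC"))

  # default flank 25 gives 50-bp queries on the whole packaged catalog
  qq <- junction_queries(build_junctions(dscr_transcripts()), fixture_genome())
  expect_true(all(nchar(qq$sequence) == 50))
  expect_true(all(qq$left_flank == 25 & qq$right_flank == 25))
  expect_false(any(qq$truncated))
})

test_that("queries equal the spliced-transcript window centered on the junction", {
  g <- fixture_genome()
  m <- dscr_transcripts()
  j <- build_junctions(m)
  q <- junction_queries(j, g, flank = 25)
  for (tid in unique(m$transcript_id)) {
    tx <- spliced_sequence(m, tid, g)
    ex <- filter(m, transcript_id == tid) |> arrange(exon_rank)
    jpos <- cumsum(interval_length(ex$start, ex$end))
    qt <- filter(q, transcript_id == tid) |> arrange(junction_rank)
    for (k in seq_len(nrow(qt))) {
      expect_equal(qt$sequence[k],
                   substr(tx, jpos[k] - 24, jpos[k] + 25))
    }
  }
  # independent reverse-complement oracle on a toy: minus-strand spliced
  # sequence equals rc of the plus-strand spliced extraction
  gt <- toy_genome()
  tm <- toy_models()
  plus_tx <- spliced_sequence(tm, "PLUS-1", gt)
  minus_tx <- spliced_sequence(tm, "MINUS-1", gt)
  expect_equal(minus_tx, rc_oracle(plus_tx))
})

test_that("flanks truncate to short exons with a warning, and record it", {
  g <- jq_genome(strrep("ACGT", 30), chrom = "chrT")
  m <- parse_transcript_table(tibble::tribble(
    ~transcript_id, ~exon_label, ~coord_a, ~coord_b,
    "T1", "E1", 1L, 10L,
    "T1", "E2", 61L, 120L
  ), chrom = "chrT")
  expect_warning(
    q <- junction_queries(build_junctions(m), g, flank = 25),
    "truncated"
  )
  expect_true(q$truncated)
  expect_equal(q$left_flank, 10L)
  expect_equal(q$right_flank, 25L)
  expect_equal(nchar(q$sequence), 35L)
  # out-of-bounds coordinates are an error
  off <- parse_transcript_table(tibble::tribble(
    ~transcript_id, ~exon_label, ~coord_a, ~coord_b,
    "T1", "E1", 1L, 10L,
    "T1", "E2", 100L, 200L
  ), chrom = "chrT")
  expect_error(
    suppressWarnings(junction_queries(build_junctions(off), g, flank = 25)),
    "outside the genome"
  )
})
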