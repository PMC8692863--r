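mock_alignment <- function(read_id, query_id, significant = TRUE) {
  tibble::tibble(query_id = query_id, read_id = read_id,
                 significant = significant)
}

test_that("support counts distinct significant reads per catalog junction", {
  j <- build_junctions(dscr_transcripts())
  catalog <- shared_junctions(j)
  ids <- catalog$junction_id
  aln <- dplyr::bind_rows(
    mock_alignment(paste0("r", 1:3), ids[1], TRUE),
    mock_alignment(paste0("r", 4:5), ids[1], FALSE),   # sub-threshold
    mock_alignment("r1", ids[1], TRUE)                 # same read again: one vote
  )
  sup <- count_junction_support(aln, catalog, "testis")
  expect_equal(nrow(sup), length(ids))                 # explicit zeros
  expect_equal(sup$n_reads[sup$junction_id == ids[1]], 3L)
  expect_true(all(sup$n_reads[sup$junction_id != ids[1]] == 0L))

  none <- count_junction_support(aln[0, ], catalog, "heart")
  expect_true(all(none$n_reads == 0L))

  expect_error(
    count_junction_support(mock_alignment("r1", "chr9:+:1-2"), catalog, "x"),
    "absent from the catalog"
  )
})

test_that("isoform calls implement the full / partial / none contract", {
  m <- dscr_transcripts()
  j <- build_junctions(m)
  catalog <- shared_junctions(j)

  # testis-like: all three DSCR4-202 junctions supported, one of them shared
  d202 <- filter(j, transcript_id == "DSCR4-202")
  aln <- dplyr::bind_rows(
    mock_alignment(paste0("a", 1:33), d202$junction_id[1]),
    mock_alignment("b1", d202$junction_id[2]),
    mock_alignment("c1", d202$junction_id[3])
  )
  sup <- count_junction_support(aln, catalog, "testis")
  calls <- call_isoforms(sup, j, catalog)
  testis <- filter(calls, transcript_id == "DSCR4-202")
  expect_equal(as.character(testis$status), "full")
  expect_true(testis$uniquely_confirmed)
  expect_setequal(testis$ambiguous_junctions[[1]], "E1-E2")

  # only the shared first junction supported: partial, not uniquely confirmed
  d203 <- filter(calls, transcript_id == "DSCR4-203")
  expect_equal(as.character(d203$status), "partial")
  expect_false(d203$uniquely_confirmed)

  # empty matrix: everything none
  empty <- count_junction_support(aln[0, ], catalog, "heart")
  all_none <- call_isoforms(empty, j, catalog)
  expect_true(all(all_none$status == "none"))
  expect_false(any(all_none$uniquely_confirmed))
})

test_that("the ambiguity flag set is exactly the multi-member identities", {
  j <- build_junctions(dscr_transcripts())
  sharing <- shared_junctions(j)
  flagged <- filter(sharing, shared)
  expect_equal(nrow(flagged), 3)
  # the KCNJ6 internal junctions and the promoter-proximal first junction
  expect_setequal(
    flagged$junction_id,
    c("chr21:-:37840658-37715131",   # E2-E3 of both KCNJ6 isoforms
      "chr21:-:37714211-37625484",   # E3-E4 / E3-E4b
      "chr21:-:38121128-38120408")   # first junction of KCNJ6-202 + DSCR4 trio
  )
  calls <- call_isoforms(
    count_junction_support(mock_alignment("r", j$junction_id[1])[0, ],
                           sharing, "s"),
    j, sharing
  )
  got_flags <- calls |>
    tidyr::unnest(ambiguous_junctions) |>
    distinct(transcript_id, ambiguous_junctions)
  # every transcript carrying a shared identity is flagged at that junction
  expect_setequal(
    paste(got_flags$transcript_id, got_flags$ambiguous_junctions),
    c("KCNJ6-201 E2-E3", "KCNJ6-201 E3-E4",
      "KCNJ6-202 E2-E3", "KCNJ6-202 E3-E4b", "KCNJ6-202 E1b-E1bis",
      "DSCR4-201 E1-E2", "DSCR4-202 E1-E2", "DSCR4-203 E1-E2")
  )
})

test_that("support and calls are monotone in added reads", {
  j <- build_junctions(dscr_transcripts())
  catalog <- shared_junctions(j)
  d201 <- filter(j, transcript_id == "DSCR4-201")
  base <- mock_alignment("r1", d201$junction_id[1])
  more <- dplyr::bind_rows(base,
                           mock_alignment("r2", d201$junction_id[1]),
                           mock_alignment("r3", d201$junction_id[2]))
  sup_a <- count_junction_support(base, catalog, "s")
  sup_b <- count_junction_support(more, catalog, "s")
  expect_true(all(sup_b$n_reads >= sup_a$n_reads))
  rank <- function(calls) {
    as.integer(factor(as.character(calls$status),
                      levels = c("none", "partial", "full")))
  }
  calls_a <- call_isoforms(sup_a, j, catalog)
  calls_b <- call_isoforms(sup_b, j, catalog)
  expect_true(all(rank(calls_b) >= rank(calls_a)))
  # conservation: matrix total equals distinct significant (read, junction) pairs
  expect_equal(sum(sup_b$n_reads),
               nrow(distinct(filter(more, significant), read_id, query_id)))
})

test_that("report cells follow the No / singular / asterisk dialect", {
  expect_equal(format_support_cell(0, FALSE), "No")
  expect_equal(format_support_cell(0, TRUE), "No")   # no asterisk on absence
  expect_equal(format_support_cell(1, FALSE), "1 alignment")
  expect_equal(format_support_cell(2, FALSE), "2 alignments")
  expect_equal(format_support_cell(33, TRUE), "33 alignments*")
})
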