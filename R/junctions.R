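#' Build the exon-junction catalog of transcript models
#'
#' Each pair of consecutive exons in transcript order yields one junction.
#' The donor is the genomic coordinate of the last exonic base of the
#' upstream exon *in transcript orientation* (for reverse-strand transcripts
#' that is the lowest coordinate of its normalized interval) and the acceptor
#' is the first exonic base of the downstream exon. Junction identity is the
#' coordinate tuple (chrom, strand, donor, acceptor): two isoforms splicing
#' the same donor to the same acceptor produce the *same* junction, whatever
#' their exon labels — which is what makes read support at such a junction
#' ambiguous between them.
#'
#' @param models A normalized exon tibble from [parse_transcript_table()].
#' @return A tibble with one row per transcript junction: `transcript_id`,
#'   `gene`, `junction_rank`, `junction_label` (e.g. `"E1-E2"`),
#'   `upstream_label`, `downstream_label`, `chrom`, `strand`, `donor`,
#'   `acceptor`, the flanking exon bounds (`upstream_start` .. ` downstream_end`,
#'   used for flank truncation), and the identity string `junction_id`
#'   (`chrom:strand:donor-acceptor`). Single-exon transcripts contribute no
#'   rows.
#' @examples
#' build_junctions(dscr_transcripts()) |> dplyr::count(transcript_id)
#' @export
build_junctions <- function(models) {
  assert_models(models)
  models |>
    group_by(.data$transcript_id) |>
    group_map(function(ex, key) {
      ex <- arrange(ex, .data$exon_rank)
      n <- nrow(ex)
      if (n < 2) return(NULL)
      up <- ex[-n, ]
      down <- ex[-1, ]
      minus <- up$strand == "-"
      tibble(
        transcript_id = key$transcript_id,
        gene = up$gene,
        junction_rank = seq_len(n - 1L),
        junction_label = paste0(up$exon_label, "-", down$exon_label),
        upstream_label = up$exon_label,
        downstream_label = down$exon_label,
        chrom = up$chrom,
        strand = up$strand,
        donor = ifelse(minus, up$start, up$end),
        acceptor = ifelse(minus, down$end, down$start),
        upstream_start = up$start,
        upstream_end = up$end,
        downstream_start = down$start,
        downstream_end = down$end
      )
    }) |>
    list_rbind() |>
    empty_junction_catalog_if_needed() |>
    mutate(junction_id = junction_identity(.data$chrom, .data$strand,
                                           .data$donor, .data$acceptor)) |>
    arrange(match(.data$transcript_id, unique(models$transcript_id)),
            .data$junction_rank)
}

junction_identity <- function(chrom, strand, donor, acceptor) {
  sprintf("%s:%s:%d-%d", chrom, strand, donor, acceptor)
}

# all-single-exon input: give the catalog its columns anyway
empty_junction_catalog_if_needed <- function(x) {
  if (nrow(x) > 0) return(x)
  tibble(
    transcript_id = character(), gene = character(),
    junction_rank = integer(), junction_label = character(),
    upstream_label = character(), downstream_label = character(),
    chrom = character(), strand = character(),
    donor = integer(), acceptor = integer(),
    upstream_start = integer(), upstream_end = integer(),
    downstream_start = integer(), downstream_end = integer()
  )
}

#' Merge junctions by identity and find those shared between isoforms
#'
#' Junctions with identical (chrom, strand, donor, acceptor) are merged into
#' one identity; the member transcripts are collected. Identities with more
#' than one member are the "shared" junctions whose read support cannot be
#' attributed to a single isoform (rendered with an asterisk in reports).
#'
#' @param junctions A junction tibble from [build_junctions()] (one or more
#'   transcripts' catalogs bound together).
#' @return A tibble with one row per junction identity: `junction_id`,
#'   `chrom`, `strand`, `donor`, `acceptor`, `transcripts` (list column),
#'   `n_transcripts`, `shared` (logical), and a representative
#'   `junction_label`.
#' @examples
#' shared_junctions(build_junctions(dscr_transcripts()))
#' @export
shared_junctions <- function(junctions) {
  junctions |>
    group_by(.data$junction_id, .data$chrom, .data$strand, .data$donor,
             .data$acceptor) |>
    summarise(
      transcripts = list(sort(unique(.data$transcript_id))),
      n_transcripts = length(unique(.data$transcript_id)),
      junction_label = .data$junction_label[1],
      .groups = "drop"
    ) |>
    mutate(shared = .data$n_transcripts > 1) |>
    arrange(match(.data$junction_id, unique(junctions$junction_id)))
}

#' Count junction identities present in every listed transcript
#'
#' @param junctions A junction tibble from [build_junctions()].
#' @param transcripts Character vector of transcript ids.
#' @return Number of junction identities that occur in the catalog of each
#'   of the given transcripts.
#' @examples
#' j <- build_junctions(dscr_transcripts())
#' shared_junction_count(j, c("KCNJ6-201", "KCNJ6-202"))
#' @export
shared_junction_count <- function(junctions, transcripts) {
  junctions |>
    filter(.data$transcript_id %in% transcripts) |>
    distinct(.data$junction_id, .data$transcript_id) |>
    count(.data$junction_id) |>
    filter(.data$n == length(unique(transcripts))) |>
    nrow()
}

#' Extract spliced junction-query sequences
#'
#' The query of a junction is the last `flank` transcript-oriented bases of
#' the upstream exon joined to the first `flank` bases of the downstream
#' exon (defaults 25 + 25 = 50 bp). Queries are always emitted in transcript
#' 5'->3' orientation: for reverse-strand transcripts the forward-strand
#' extraction is reverse-complemented. A flank is truncated to the exon
#' length when the exon is shorter than requested; the truncation is
#' recorded and a warning raised.
#'
#' @param junctions A junction tibble from [build_junctions()]. When several
#'   transcripts share a junction identity, pass the output as-is — queries
#'   are computed per row; deduplicate on `junction_id` for alignment (see
#'   [align_reads()]).
#' @param genome A `jq_genome` covering all exons.
#' @param flank Bases taken from the upstream exon (default 25).
#' @param flank_right Bases taken from the downstream exon (defaults to
#'   `flank`; asymmetric flanks are allowed).
#' @return The junction tibble with added columns `left_flank`,
#'   `right_flank` (actual, post-truncation), `truncated`, and `sequence`
#'   (uppercase, spliced, transcript-oriented).
#' @examples
#' genome <- simulate_genome(seed = 1)
#' junction_queries(build_junctions(dscr_transcripts()), genome) |>
#'   dplyr::select(transcript_id, junction_label, sequence)
#' @export
junction_queries <- function(junctions, genome, flank = 25L,
                             flank_right = flank) {
  stopifnot(flank >= 1, flank_right >= 1)
  up_len <- interval_length(junctions$upstream_start, junctions$upstream_end)
  down_len <- interval_length(junctions$downstream_start,
                              junctions$downstream_end)
  lf <- pmin(as.integer(flank), up_len)
  rf <- pmin(as.integer(flank_right), down_len)
  truncated <- lf < flank | rf < flank_right
  if (any(truncated)) {
    warn(sprintf(
      "%d junction quer%s truncated: flanking exon shorter than the flank.",
      sum(truncated), if (sum(truncated) == 1) "y" else "ies"
    ))
  }
  seqs <- pmap(
    list(junctions$strand, junctions$donor, junctions$acceptor, lf, rf),
    function(strand, donor, acceptor, lf, rf) {
      if (strand == "+") {
        paste0(genome_slice(genome, donor - lf + 1L, donor),
               genome_slice(genome, acceptor, acceptor + rf - 1L))
      } else {
        paste0(revcomp(genome_slice(genome, donor, donor + lf - 1L)),
               revcomp(genome_slice(genome, acceptor - rf + 1L, acceptor)))
      }
    }
  )
  junctions |>
    mutate(left_flank = lf, right_flank = rf, truncated = truncated,
           sequence = unlist(seqs))
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences of one transcript in transcript order,
#' reverse-complementing reverse-strand exons, giving the mature (spliced)
#' transcript sequence 5'->3'.
#'
#' @param models A normalized exon tibble.
#' @param transcript Transcript id to extract.
#' @param genome A `jq_genome` covering the exons.
#' @return Character string of the spliced sequence.
#' @export
spliced_sequence <- function(models, transcript, genome) {
  ex <- models |>
    filter(.data$transcript_id == transcript) |>
    arrange(.data$exon_rank)
  if (nrow(ex) == 0) abort(paste0("Unknown transcript: ", transcript))
  pieces <- pmap(list(ex$start, ex$end, ex$strand), function(start, end, strand) {
    s <- genome_slice(genome, start, end)
    if (strand == "-") revcomp(s) else s
  })
  paste0(unlist(pieces), collapse = "")
}

#' Write junction queries as FASTA
#'
#' Headers encode `transcript_id|junction_label|chrom|donor|acceptor|strand`.
#'
#' @param queries A query tibble from [junction_queries()].
#' @param path File path.
#' @return The input, invisibly.
#' @export
write_junction_fasta <- function(queries, path) {
  x <- Biostrings::DNAStringSet(queries$sequence)
  names(x) <- sprintf("%s|%s|%s|%d|%d|%s", queries$transcript_id,
                      queries$junction_label, queries$chrom, queries$donor,
                      queries$acceptor, queries$strand)
  Biostrings::writeXStringSet(x, path)
  invisible(queries)
}

#' Write the junction-sharing map as TSV
#'
#' @param sharing Output of [shared_junctions()].
#' @param path File path.
#' @return The input, invisibly.
#' @export
write_sharing_tsv <- function(sharing, path) {
  out <- sharing |>
    mutate(transcripts = map_chr(.data$transcripts, paste, collapse = ",")) |>
    select("junction_id", "junction_label", "chrom", "strand", "donor",
           "acceptor", "n_transcripts", "shared", "transcripts")
  readr::write_tsv(out, path)
  invisible(sharing)
}
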