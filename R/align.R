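#' Alignment scoring scheme
#'
#' Match/mismatch scores and affine gap penalties for the local aligner.
#' A gap of length k costs `gap_open + k * gap_extend`. Defaults are
#' BLASTN-like. `N` bases never match anything (including another `N`).
#'
#' @param match Positive match score (default +2).
#' @param mismatch Negative mismatch score (default -3).
#' @param gap_open Negative gap-opening score (default -5).
#' @param gap_extend Negative per-base gap-extension score (default -2).
#' @return A list of class `jq_scoring`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2) {
  if (match <= 0) abort("`match` must be > 0.")
  if (mismatch >= 0 || gap_open >= 0 || gap_extend >= 0) {
    abort("`mismatch`, `gap_open` and `gap_extend` must be < 0.")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "jq_scoring")
}

#' Significance filter for junction alignments
#'
#' An alignment is significant when it covers at least `min_query_cover`
#' percent of the query and at least `min_identity` percent of its columns
#' match; both thresholds are inclusive ("at least"). Defaults 95 / 97.
#'
#' @param min_query_cover Minimum query cover, percent.
#' @param min_identity Minimum identity, percent.
#' @return A list of class `jq_filter`.
#' @export
filter_params <- function(min_query_cover = 95, min_identity = 97) {
  if (min_query_cover <= 0 || min_query_cover > 100 ||
      min_identity <= 0 || min_identity > 100) {
    abort("Filter thresholds must be in (0, 100].")
  }
  structure(list(min_query_cover = min_query_cover,
                 min_identity = min_identity), class = "jq_filter")
}

# ACGTN substitution matrix: N is penalized against everything, itself
# included, so an N column can never count toward identity.
substitution_matrix <- function(scoring) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- scoring$match
  m
}

assert_dna <- function(x, what) {
  if (any(is.na(x)) || any(nchar(x) == 0)) {
    abort(paste0(what, " must be non-empty sequences."))
  }
  bad <- grepl("[^ACGTN]", toupper(x))
  if (any(bad)) {
    abort(paste0(what, " contain characters outside A/C/G/T/N."))
  }
  toupper(x)
}

#' Align reads against junction queries
#'
#' Every read is scored against every query with a local (Smith-Waterman,
#' affine-gap) aligner in both orientations; the better-scoring orientation
#' is kept (forward on ties), so each read contributes at most one alignment
#' per query — one read, one vote. Metrics follow BLAST conventions:
#' identity is matches over alignment columns including gap columns, and
#' query cover is the aligned query span over the full query length.
#'
#' @param reads Reads as a tibble with columns `read_id` and `seq`, a named
#'   character vector, or a [Biostrings::DNAStringSet].
#' @param queries A query tibble from [junction_queries()] (rows with equal
#'   `junction_id` are deduplicated — a shared junction is one query), or
#'   any tibble with columns `junction_id` and `sequence`.
#' @param scoring A [scoring_scheme()].
#' @param filter A [filter_params()]; sets the `significant` flag.
#' @return A tibble with one row per read x query: `query_id`, `read_id`,
#'   `read_orientation` (`"forward"`/`"revcomp"`), `score`, `query_start`,
#'   `query_end` (1-based on the query), `read_start`, `read_end` (1-based
#'   on the *original* read), `matches`, `alignment_columns`,
#'   `identity_pct`, `query_cover_pct`, `significant`.
#' @examples
#' align_reads(
#'   tibble::tibble(read_id = "r1", seq = "TTTTACGTACGTACTTTT"),
#'   tibble::tibble(junction_id = "q1", sequence = "ACGTACGTAC")
#' )
#' @export
align_reads <- function(reads, queries, scoring = scoring_scheme(),
                        filter = filter_params()) {
  reads <- as_read_tibble(reads)
  reads$seq <- assert_dna(reads$seq, "Reads")
  queries <- as_tibble(queries)
  if (!all(c("junction_id", "sequence") %in% names(queries))) {
    abort("`queries` needs columns junction_id and sequence.")
  }
  queries <- distinct(queries, .data$junction_id, .keep_all = TRUE)
  queries$sequence <- assert_dna(queries$sequence, "Queries")

  mat <- substitution_matrix(scoring)
  fwd <- Biostrings::DNAStringSet(reads$seq)
  names(fwd) <- reads$read_id
  rev <- Biostrings::reverseComplement(fwd)
  read_len <- nchar(reads$seq)

  purrr::map(seq_len(nrow(queries)), function(qi) {
    subject <- Biostrings::DNAString(queries$sequence[qi])
    qlen <- length(subject)
    a_f <- pairwise_local(fwd, subject, mat, scoring)
    a_r <- pairwise_local(rev, subject, mat, scoring)
    use_rev <- a_r$score > a_f$score      # forward wins ties
    best <- a_f
    best[use_rev, ] <- a_r[use_rev, ]
    # report read spans on the original read coordinates
    rs <- ifelse(use_rev, read_len - best$read_end + 1L, best$read_start)
    re <- ifelse(use_rev, read_len - best$read_start + 1L, best$read_end)
    tibble(
      query_id = queries$junction_id[qi],
      read_id = reads$read_id,
      read_orientation = ifelse(use_rev, "revcomp", "forward"),
      score = best$score,
      query_start = best$query_start,
      query_end = best$query_end,
      read_start = rs,
      read_end = re,
      matches = best$matches,
      alignment_columns = best$columns,
      identity_pct = 100 * best$matches / pmax(best$columns, 1L),
      query_cover_pct = 100 * (best$query_end - best$query_start + 1L) / qlen
    )
  }) |>
    list_rbind() |>
    mutate(significant = is_significant(
      pick("query_cover_pct", "identity_pct"), filter))
}

pairwise_local <- function(patterns, subject, mat, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = "local",
    substitutionMatrix = mat,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  matches <- Biostrings::nmatch(aln)
  # nmatch counts identical characters, so an N-N column would count as a
  # match; recount those alignments character-wise (N never matches).
  has_n <- grepl("N", as.character(patterns), fixed = TRUE) |
    grepl("N", as.character(subject), fixed = TRUE)
  if (any(has_n)) {
    ap <- as.character(Biostrings::alignedPattern(aln[has_n]))
    as_ <- as.character(Biostrings::alignedSubject(aln[has_n]))
    gap <- charToRaw("-")
    nn <- charToRaw("N")
    matches[has_n] <- vapply(seq_along(ap), function(i) {
      x <- charToRaw(ap[i]); y <- charToRaw(as_[i])
      sum(x == y & x != gap & x != nn)
    }, integer(1))
  }
  data.frame(
    score = BiocGenerics::score(aln),
    query_start = BiocGenerics::start(Biostrings::subject(aln)),
    query_end = BiocGenerics::end(Biostrings::subject(aln)),
    read_start = BiocGenerics::start(Biostrings::pattern(aln)),
    read_end = BiocGenerics::end(Biostrings::pattern(aln)),
    matches = as.integer(matches),
    columns = Biostrings::nchar(aln)
  )
}

as_read_tibble <- function(reads) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- tibble(
      read_id = names(reads) %||% paste0("read", seq_along(reads)),
      seq = as.character(reads)
    )
  } else if (is.character(reads)) {
    reads <- tibble(
      read_id = names(reads) %||% paste0("read", seq_along(reads)),
      seq = unname(reads)
    )
  } else {
    reads <- as_tibble(reads)
  }
  if (!all(c("read_id", "seq") %in% names(reads))) {
    abort("`reads` needs columns read_id and seq.")
  }
  if (anyDuplicated(reads$read_id)) abort("Duplicated read ids.")
  reads
}

#' Align one read against one query
#'
#' Single-pair convenience wrapper around [align_reads()].
#'
#' @param query,read Nucleotide strings (A/C/G/T/N).
#' @param scoring A [scoring_scheme()].
#' @param filter A [filter_params()].
#' @return A one-row alignment tibble (see [align_reads()]).
#' @export
local_align <- function(query, read, scoring = scoring_scheme(),
                        filter = filter_params()) {
  align_reads(tibble(read_id = "read", seq = read),
              tibble(junction_id = "query", sequence = query),
              scoring = scoring, filter = filter)
}

#' Apply the significance filter
#'
#' @param alignments An alignment tibble (needs `query_cover_pct` and
#'   `identity_pct`), e.g. from [align_reads()].
#' @param filter A [filter_params()].
#' @return Logical vector: both thresholds met (inclusive).
#' @export
is_significant <- function(alignments, filter = filter_params()) {
  alignments$query_cover_pct >= filter$min_query_cover &
    alignments$identity_pct >= filter$min_identity
}

#' Write alignment results as TSV
#'
#' @param alignments Output of [align_reads()].
#' @param path File path.
#' @param min_score Optional reporting floor: rows with `score` below it are
#'   dropped from the file (all rows kept by default).
#' @return The input, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path, min_score = NULL) {
  out <- alignments
  if (!is.null(min_score)) out <- filter(out, .data$score >= min_score)
  readr::write_tsv(out, path)
  invisible(alignments)
}
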