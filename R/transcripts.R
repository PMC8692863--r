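#' Length of a 1-based inclusive genomic interval
#'
#' Coordinates are 1-based and inclusive, so a single-base interval has
#' length 1. The pair may be given in either order (reverse-strand exon
#' tables are conventionally printed 5'->3' with descending coordinates);
#' the length is orientation-free.
#'
#' @param start,end Integer vectors of genomic coordinates (recycled).
#' @return Integer vector of lengths in nucleotides.
#' @examples
#' interval_length(100, 200)
#' interval_length(200, 100)  # same interval, printed in transcript order
#' @export
interval_length <- function(start, end) {
  if (any(start < 1 | end < 1)) {
    abort("Genomic coordinates are 1-based: start and end must be >= 1.")
  }
  as.integer(abs(end - start) + 1L)
}

#' Parse a printed exon-coordinate table into normalized transcript models
#'
#' Takes one row per exon with the two genomic coordinates *as printed*:
#' plus-strand transcripts list exons 5'->3' with ascending coordinates,
#' minus-strand transcripts with descending coordinates (first number greater
#' than the second). Strand is inferred from that direction, coordinates are
#' normalized to `start <= end`, and the printed exon order is kept as the
#' transcript 5'->3' order (`exon_rank`).
#'
#' @param rows A data frame with columns `transcript_id`, `exon_label`,
#'   `coord_a`, `coord_b`, and optionally `gene` and `chrom`.
#' @param chrom Chromosome name used when `rows` has no `chrom` column.
#' @return A tibble of normalized exons, one row per exon, with columns
#'   `transcript_id`, `gene`, `exon_label`, `exon_rank`, `chrom`, `start`,
#'   `end`, `strand`.
#' @details Validation errors are raised for transcripts with overlapping
#'   exons, mixed coordinate directions, non-monotonic exon order, or exons
#'   spread over several chromosomes.
#' @examples
#' parse_transcript_table(
#'   data.frame(transcript_id = "T1", exon_label = "E1",
#'              coord_a = 100, coord_b = 200)
#' )
#' @export
parse_transcript_table <- function(rows, chrom = "chr21") {
  rows <- as_tibble(rows)
  needed <- c("transcript_id", "exon_label", "coord_a", "coord_b")
  missing <- setdiff(needed, names(rows))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in exon table: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"gene" %in% names(rows)) {
    rows$gene <- sub("-[^-]*$", "", rows$transcript_id)
  }
  if (!"chrom" %in% names(rows)) rows$chrom <- chrom
  if (nrow(rows) == 0) abort("Exon table is empty.")

  models <- rows |>
    mutate(coord_a = as.integer(.data$coord_a),
           coord_b = as.integer(.data$coord_b)) |>
    group_by(.data$transcript_id) |>
    group_map(~ normalize_one_transcript(.x, .y$transcript_id)) |>
    list_rbind()

  # keep the input's transcript order, not alphabetical
  models[order(match(models$transcript_id, unique(rows$transcript_id)),
               models$exon_rank), ]
}

normalize_one_transcript <- function(ex, transcript_id) {
  if (length(unique(ex$chrom)) != 1) {
    abort(paste0(transcript_id, ": exons on more than one chromosome."))
  }
  dir <- sign(ex$coord_b - ex$coord_a)
  if (any(dir > 0) && any(dir < 0)) {
    abort(paste0(transcript_id,
                 ": mixed coordinate directions within one transcript."))
  }
  start <- pmin(ex$coord_a, ex$coord_b)
  end <- pmax(ex$coord_a, ex$coord_b)
  n <- nrow(ex)
  # direction of exon-to-exon progression settles strand for 1-bp exons too
  descending <- any(dir < 0) || (n > 1 && start[1] > start[n])
  if (n > 1) {
    ord <- if (descending) all(diff(start) < 0) else all(diff(start) > 0)
    if (!ord) {
      abort(paste0(transcript_id,
                   ": exon starts are not strictly monotonic in transcript order."))
    }
    lo <- sort(start)
    hi <- end[order(start)]
    if (any(utils::head(hi, -1) >= lo[-1])) {
      abort(paste0(transcript_id, ": overlapping exons."))
    }
  }
  tibble(
    transcript_id = transcript_id,
    gene = ex$gene,
    exon_label = ex$exon_label,
    exon_rank = seq_len(n),
    chrom = ex$chrom,
    start = start,
    end = end,
    strand = if (descending) "-" else "+"
  )
}

assert_models <- function(models) {
  needed <- c("transcript_id", "exon_label", "exon_rank", "chrom",
              "start", "end", "strand")
  missing <- setdiff(needed, names(models))
  if (length(missing) > 0) {
    abort(paste0("Not a transcript-model table; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(models)
}

#' Introns of transcript models
#'
#' Returns the gaps strictly between consecutive exons in transcript order,
#' as normalized 1-based inclusive intervals. Intron `i` lies between exon
#' `i` and exon `i + 1`. Single-exon transcripts contribute no rows.
#'
#' @param models A normalized exon tibble from [parse_transcript_table()].
#' @return A tibble with one row per intron: `transcript_id`, `intron_rank`,
#'   `upstream_label`, `downstream_label`, `chrom`, `start`, `end`, `strand`.
#' @details Abutting exons (a zero-length gap) are a validation error, not a
#'   silent merge: a transcript model with no intron between two listed exons
#'   is malformed.
#' @examples
#' m <- dscr_transcripts()
#' transcript_introns(m[m$transcript_id == "KCNJ6-202", ])
#' @export
transcript_introns <- function(models) {
  assert_models(models)
  models |>
    group_by(.data$transcript_id) |>
    group_map(function(ex, key) {
      ex <- arrange(ex, .data$exon_rank)
      n <- nrow(ex)
      if (n < 2) return(NULL)
      up <- ex[-n, ]
      down <- ex[-1, ]
      gap_start <- pmin(up$end, down$end) + 1L
      gap_end <- pmax(up$start, down$start) - 1L
      if (any(gap_start > gap_end)) {
        abort(paste0(key$transcript_id,
                     ": zero-length intron between abutting exons."))
      }
      tibble(
        transcript_id = key$transcript_id,
        intron_rank = seq_len(n - 1L),
        upstream_label = up$exon_label,
        downstream_label = down$exon_label,
        chrom = up$chrom,
        start = gap_start,
        end = gap_end,
        strand = up$strand
      )
    }) |>
    list_rbind()
}

#' The five KCNJ6/DSCR4 transcript models on 21q22.13
#'
#' Loads the packaged exon-coordinate table (GRCh38 coordinates, as printed
#' in the source annotation: all five isoforms are transcribed from the
#' reverse strand, so exons are listed 5'->3' with descending coordinates)
#' and returns the normalized models.
#'
#' Note that the KCNJ6-201 E1 entry (37,961,457-37,915,884) is kept exactly
#' as printed even though it overlaps the HR-DSCR interval; the discrepancy
#' with the region's "intergenic" description is visible through
#' [classify_overlap()] rather than silently corrected.
#'
#' @return A normalized exon tibble (see [parse_transcript_table()]).
#' @examples
#' dscr_transcripts() |> dplyr::count(transcript_id)
#' @export
dscr_transcripts <- function() {
  read_transcript_table(transcript_table_path())
}

#' Path to the packaged KCNJ6/DSCR4 exon table
#' @return File path of the TSV fixture.
#' @export
transcript_table_path <- function() {
  system.file("extdata", "dscr21_transcripts.tsv", package = "junctionr",
              mustWork = TRUE)
}

#' Read and write exon-coordinate tables
#'
#' The TSV dialect has columns `transcript_id`, `gene`, `exon_label`,
#' `coord_a`, `coord_b` (printed, possibly descending, coordinates) and an
#' optional `chrom`. `write_transcript_table()` writes normalized models back
#' in that dialect, restoring the printed orientation of reverse-strand
#' exons, so read -> write -> read round-trips.
#'
#' @param path File path.
#' @param chrom Chromosome used when the file has no `chrom` column.
#' @param models A normalized exon tibble.
#' @return `read_transcript_table()` a normalized exon tibble;
#'   `write_transcript_table()` the input, invisibly.
#' @export
read_transcript_table <- function(path, chrom = "chr21") {
  if (!file.exists(path)) abort(paste0("Transcript table not found: ", path))
  rows <- readr::read_tsv(path, show_col_types = FALSE)
  parse_transcript_table(rows, chrom = chrom)
}

#' @rdname read_transcript_table
#' @export
write_transcript_table <- function(models, path) {
  assert_models(models)
  out <- models |>
    arrange(match(.data$transcript_id, unique(models$transcript_id)),
            .data$exon_rank) |>
    mutate(
      coord_a = ifelse(.data$strand == "-", .data$end, .data$start),
      coord_b = ifelse(.data$strand == "-", .data$start, .data$end)
    ) |>
    select("transcript_id", "gene", "exon_label", "coord_a", "coord_b",
           "chrom")
  readr::write_tsv(out, path)
  invisible(models)
}

#' Read and write transcript models as BED12
#'
#' BED12 uses 0-based half-open coordinates and stores exons as blocks on
#' the forward strand; conversion to the package's 1-based inclusive,
#' transcript-ordered representation happens on read (reverse-strand block
#' order is flipped so `exon_rank` is transcript 5'->3'). Exon labels are
#' synthesized as `E1..En` in transcript order since BED12 carries none.
#'
#' @param path File path.
#' @param models A normalized exon tibble.
#' @param gene Optional gene label applied to all records on read.
#' @return `read_bed12()` a normalized exon tibble; `write_bed12()` the
#'   input, invisibly.
#' @export
read_bed12 <- function(path, gene = NULL) {
  if (!file.exists(path)) abort(paste0("BED12 file not found: ", path))
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$blocks)) {
    # plain BED: one exon per record
    gr$blocks <- IRanges::IRangesList(lapply(
      GenomicRanges::width(gr), function(w) IRanges::IRanges(1L, w)
    ))
  }
  purrr::map(seq_along(gr), function(i) {
    blocks <- gr$blocks[[i]]
    ex_start <- GenomicRanges::start(gr)[i] + IRanges::start(blocks) - 1L
    ex_end <- GenomicRanges::start(gr)[i] + IRanges::end(blocks) - 1L
    strand <- as.character(GenomicRanges::strand(gr))[i]
    if (strand == "*") strand <- "+"
    ord <- if (strand == "-") rev(seq_along(ex_start)) else seq_along(ex_start)
    tid <- gr$name[i] %||% paste0("tx", i)
    tibble(
      transcript_id = tid,
      gene = gene %||% sub("-[^-]*$", "", tid),
      exon_label = paste0("E", seq_along(ord)),
      exon_rank = seq_along(ord),
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      start = as.integer(ex_start[ord]),
      end = as.integer(ex_end[ord]),
      strand = strand
    )
  }) |>
    list_rbind()
}

#' @rdname read_bed12
#' @export
write_bed12 <- function(models, path) {
  assert_models(models)
  recs <- models |>
    group_by(.data$transcript_id) |>
    group_map(function(ex, key) {
      ex <- arrange(ex, .data$start)
      span_start <- min(ex$start)
      gr <- GenomicRanges::GRanges(
        seqnames = ex$chrom[1],
        ranges = IRanges::IRanges(span_start, max(ex$end)),
        strand = ex$strand[1]
      )
      gr$name <- key$transcript_id
      gr$blocks <- IRanges::IRangesList(IRanges::IRanges(
        ex$start - span_start + 1L, ex$end - span_start + 1L
      ))
      gr
    })
  gr <- suppressWarnings(do.call(c, recs))
  rtracklayer::export(gr, path, format = "BED")
  invisible(models)
}
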