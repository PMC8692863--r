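#' Genome sequence stores addressable by genomic coordinate
#'
#' A `jq_genome` wraps one chromosome's sequence together with the genomic
#' coordinate of its first base, so a surrogate sequence covering only a
#' sub-span of a chromosome (e.g. the 21q22.13 window of the simulator) can
#' be addressed with real 1-based GRCh38-style coordinates.
#'
#' @param seq A character string or [Biostrings::DNAString] of the sequence.
#' @param chrom Chromosome name.
#' @param first_base Genomic coordinate of the first base of `seq`.
#' @return An object of class `jq_genome`.
#' @export
jq_genome <- function(seq, chrom = "chr21", first_base = 1L) {
  seq <- Biostrings::DNAString(as.character(seq))
  structure(
    list(chrom = chrom, first_base = as.integer(first_base), seq = seq),
    class = "jq_genome"
  )
}

#' @export
print.jq_genome <- function(x, ...) {
  cat(sprintf("<jq_genome> %s:%d-%d (%s nt)\n", x$chrom, x$first_base,
              x$first_base + length(x$seq) - 1L,
              format(length(x$seq), big.mark = ",")))
  invisible(x)
}

#' Extract a forward-strand slice from a genome store
#'
#' @param genome A `jq_genome`.
#' @param start,end 1-based inclusive genomic coordinates.
#' @return Uppercase forward-strand sequence as a character string.
#' @export
genome_slice <- function(genome, start, end) {
  stopifnot(inherits(genome, "jq_genome"), start <= end)
  lo <- start - genome$first_base + 1L
  hi <- end - genome$first_base + 1L
  if (lo < 1 || hi > length(genome$seq)) {
    abort(sprintf(
      "Coordinates %d-%d outside the genome store (%s:%d-%d).",
      start, end, genome$chrom, genome$first_base,
      genome$first_base + length(genome$seq) - 1L
    ))
  }
  toupper(as.character(genome$seq[lo:hi]))
}

#' Read and write a genome store as FASTA
#'
#' `write_genome_fasta()` encodes the coordinate anchoring in the header as
#' `chrom:first-last`; `read_genome_fasta()` recovers it (a plain header
#' anchors the sequence at base 1 of the named chromosome).
#'
#' @param genome A `jq_genome`.
#' @param path File path.
#' @return `read_genome_fasta()` a `jq_genome`; `write_genome_fasta()` the
#'   input, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "jq_genome"))
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- sprintf("%s:%d-%d", genome$chrom, genome$first_base,
                      genome$first_base + length(genome$seq) - 1L)
  Biostrings::writeXStringSet(x, path)
  invisible(genome)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("Genome FASTA not found: ", path))
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) < 1) abort(paste0("Empty genome FASTA: ", path))
  header <- names(x)[1]
  m <- regmatches(header, regexec("^(\\S+):(\\d+)-(\\d+)", header))[[1]]
  if (length(m) == 4) {
    jq_genome(x[[1]], chrom = m[2], first_base = as.integer(m[3]))
  } else {
    jq_genome(x[[1]], chrom = sub("\\s.*$", "", header), first_base = 1L)
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
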