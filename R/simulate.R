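#' Simulation scenario for one sample
#'
#' Describes the read set of one simulated RNA-seq sample: which isoforms
#' are expressed, how many reads are planted across each of their junctions,
#' how many exon-interior reads per expressed transcript, how much
#' intergenic background, the read length and the per-base substitution
#' error rate. With a fixed seed a scenario is byte-deterministic.
#'
#' @param sample_name Sample label (e.g. a tissue).
#' @param expressed Character vector of expressed transcript ids.
#' @param junction_depth Reads planted across each junction of each
#'   expressed transcript.
#' @param exon_depth Exon-interior reads per expressed transcript.
#' @param background_reads Intergenic background reads.
#' @param read_length Read length in nt (default 100).
#' @param error_rate Per-base substitution probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A list of class `jq_scenario`.
#' @export
sim_scenario <- function(sample_name, expressed = character(),
                         junction_depth = 5L, exon_depth = 5L,
                         background_reads = 30L, read_length = 100L,
                         error_rate = 0.002, seed = 1L) {
  if (junction_depth < 0 || exon_depth < 0 || background_reads < 0) {
    abort("Read depths must be >= 0.")
  }
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("`error_rate` must be in [0, 0.5).")
  }
  structure(
    list(sample_name = sample_name, expressed = unique(expressed),
         junction_depth = as.integer(junction_depth),
         exon_depth = as.integer(exon_depth),
         background_reads = as.integer(background_reads),
         read_length = as.integer(read_length),
         error_rate = error_rate, seed = as.integer(seed)),
    class = "jq_scenario"
  )
}

#' Tissue-panel scenario presets
#'
#' Ready-made scenarios mirroring the qualitative presence/absence pattern
#' of the KCNJ6/DSCR4 tissue panel: the cerebral tissues express KCNJ6-201,
#' placenta expresses DSCR4-201, testis expresses DSCR4-201 and DSCR4-202,
#' and the remaining tissues are background-only. Expression is encoded at
#' whole-transcript level, so partial single-junction signals seen in real
#' tissue data (e.g. adrenal gland) are not emulated; absolute alignment
#' counts are not emulated either.
#'
#' @param name Preset name; see `scenario_preset_names()`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_scenario()] (depths, read length,
#'   error rate).
#' @return A `jq_scenario` (or, for `scenario_preset_names()`, a character
#'   vector).
#' @examples
#' scenario_preset("testis", seed = 7)
#' @export
scenario_preset <- function(name, seed = 1L, ...) {
  sets <- preset_expression_sets()
  if (!name %in% names(sets)) {
    abort(paste0("Unknown preset '", name, "'. Known presets: ",
                 paste(names(sets), collapse = ", ")))
  }
  sim_scenario(sample_name = name, expressed = sets[[name]], seed = seed, ...)
}

#' @rdname scenario_preset
#' @export
scenario_preset_names <- function() names(preset_expression_sets())

preset_expression_sets <- function() {
  list(
    "adrenal gland" = character(),
    "brain" = "KCNJ6-201",
    "cerebellum" = "KCNJ6-201",
    "cerebral cortex" = "KCNJ6-201",
    "heart" = character(),
    "liver" = character(),
    "placenta" = "DSCR4-201",
    "skeletal muscle" = character(),
    "skin" = character(),
    "testis" = c("DSCR4-201", "DSCR4-202"),
    "thymus" = character(),
    "thyroid" = character(),
    "white blood cells" = character(),
    "T21 blood cells" = character(),
    "normal control blood cells" = character()
  )
}

#' Default surrogate-genome span
#'
#' The 21q22.13 window (GRCh38 coordinates 37,600,000-38,130,000; 530,001
#' nt) covering all exons of the packaged KCNJ6/DSCR4 models.
#' @return A one-row region tibble.
#' @export
default_genome_span <- function() {
  named_region("21q22.13-window", "chr21", 37600000L, 38130000L)
}

#' Simulate a surrogate genome over a coordinate span
#'
#' Draws an i.i.d. uniform A/C/G/T sequence over the span and anchors it at
#' the span's genomic coordinates, so the resulting store is addressable
#' with the same GRCh38-style coordinates as the transcript models.
#' Deterministic per seed.
#'
#' @param span A one-row region tibble (default [default_genome_span()]).
#' @param seed Integer seed.
#' @param models Optional exon tibble; if given, the span must cover every
#'   exon (validation error otherwise).
#' @return A `jq_genome`.
#' @examples
#' g <- simulate_genome(seed = 1)
#' @export
simulate_genome <- function(span = default_genome_span(), seed = 1L,
                            models = NULL) {
  if (!is.null(models)) {
    assert_models(models)
    if (any(models$chrom != span$chrom) ||
        any(models$start < span$start) || any(models$end > span$end)) {
      abort("Genome span does not cover all model exons.")
    }
  }
  len <- span$end - span$start + 1L
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""
  ))
  jq_genome(seq, chrom = span$chrom, first_base = span$start)
}

#' Simulate an RNA-seq read set with ground truth
#'
#' Emits three read classes per scenario: junction reads drawn from the
#' spliced transcript sequence so that their footprint spans a junction with
#' at least `flank + 5` bases on each side (guaranteeing a filter-passing
#' alignment at zero error rate); exon-interior reads drawn from single
#' exons of expressed transcripts (exons at least one read long); and
#' background reads drawn from the genome outside every model exon.
#' Substitution errors are applied i.i.d. at the scenario's `error_rate`
#' and each read is emitted forward or reverse-complemented at random.
#'
#' @param scenario A [sim_scenario()].
#' @param models A normalized exon tibble; `expressed` must be a subset of
#'   its transcript ids.
#' @param genome A `jq_genome` covering the models.
#' @param flank Junction flank the downstream aligner will use (default 25);
#'   reads must be at least `2 * flank + 10` nt so spanning geometry can be
#'   guaranteed (validation error otherwise).
#' @return A list of class `jq_sim`: `reads`, a tibble with `read_id`,
#'   `seq`, `class` (`junction`/`exon`/`background`), `transcript_id`,
#'   `junction_id`, `orientation`, `n_errors`; and `truth`, a tibble of
#'   planted junction-spanning read counts per junction identity (`sample`,
#'   `junction_id`, `planted_reads`).
#' @examples
#' m <- dscr_transcripts()
#' g <- simulate_genome(seed = 1, models = m)
#' sim <- simulate_reads(sim_scenario("placenta", "DSCR4-201", seed = 2), m, g)
#' dplyr::count(sim$reads, class)
#' @export
simulate_reads <- function(scenario, models, genome, flank = 25L) {
  stopifnot(inherits(scenario, "jq_scenario"))
  assert_models(models)
  if (scenario$read_length < 2L * flank + 10L) {
    abort(sprintf(
      "read_length %d too short: need >= 2*flank+10 = %d to guarantee junction-spanning reads.",
      scenario$read_length, 2L * flank + 10L
    ))
  }
  unknown <- setdiff(scenario$expressed, unique(models$transcript_id))
  if (length(unknown) > 0) {
    abort(paste0("Expressed transcripts not in models: ",
                 paste(unknown, collapse = ", ")))
  }
  junctions <- build_junctions(models)
  L <- scenario$read_length

  with_seed(scenario$seed, {
    rows <- list()
    for (tid in scenario$expressed) {
      tx <- spliced_sequence(models, tid, genome)
      ex <- models |> filter(.data$transcript_id == tid) |>
        arrange(.data$exon_rank)
      jpos <- cumsum(interval_length(ex$start, ex$end))   # last base of each exon
      jn <- junctions |> filter(.data$transcript_id == tid)
      for (k in seq_len(nrow(jn))) {
        p <- jpos[k]
        lo <- max(flank + 5L, p + L - nchar(tx))  # left arm length bounds
        hi <- min(L - (flank + 5L), p)
        if (lo > hi) {
          abort(sprintf("%s %s: transcript too short to span the junction.",
                        tid, jn$junction_label[k]))
        }
        for (r in seq_len(scenario$junction_depth)) {
          arm <- if (lo == hi) lo else sample(lo:hi, 1)
          rows[[length(rows) + 1]] <- list(
            seq = str_sub(tx, p - arm + 1L, p - arm + L),
            class = "junction", transcript_id = tid,
            junction_id = jn$junction_id[k]
          )
        }
      }
      eligible <- which(interval_length(ex$start, ex$end) >= L)
      if (scenario$exon_depth > 0 && length(eligible) > 0) {
        for (r in seq_len(scenario$exon_depth)) {
          i <- if (length(eligible) == 1) eligible else sample(eligible, 1)
          elen <- interval_length(ex$start[i], ex$end[i])
          off <- sample.int(elen - L + 1L, 1)
          s <- genome_slice(genome, ex$start[i] + off - 1L,
                            ex$start[i] + off + L - 2L)
          if (ex$strand[i] == "-") s <- revcomp(s)
          rows[[length(rows) + 1]] <- list(
            seq = s, class = "exon", transcript_id = tid,
            junction_id = NA_character_
          )
        }
      }
    }
    if (scenario$background_reads > 0) {
      glen <- length(genome$seq)
      drawn <- 0L
      while (drawn < scenario$background_reads) {
        pos <- genome$first_base + sample.int(glen - L + 1L, 1) - 1L
        hit <- any(models$chrom == genome$chrom &
                     models$start <= pos + L - 1L & models$end >= pos)
        if (hit) next
        rows[[length(rows) + 1]] <- list(
          seq = genome_slice(genome, pos, pos + L - 1L),
          class = "background", transcript_id = NA_character_,
          junction_id = NA_character_
        )
        drawn <- drawn + 1L
      }
    }

    reads <- list_rbind(map(rows, as_tibble))
    if (nrow(reads) == 0) {
      reads <- tibble(seq = character(), class = character(),
                      transcript_id = character(), junction_id = character())
    }
    reads <- reads |>
      mutate(
        read_id = sprintf("%s|%s|%05d",
                          gsub("\\s+", "_", scenario$sample_name),
                          .data$class, row_number()),
        n_errors = 0L
      )
    if (nrow(reads) > 0) {
      mutated <- add_substitution_errors(reads$seq, scenario$error_rate)
      reads$seq <- mutated$seq
      reads$n_errors <- mutated$n_errors
      flip <- runif(nrow(reads)) < 0.5
      reads$seq[flip] <- revcomp(reads$seq[flip])
      reads$orientation <- ifelse(flip, "revcomp", "forward")
    } else {
      reads$orientation <- character()
    }

    truth <- junctions |>
      filter(.data$transcript_id %in% scenario$expressed) |>
      distinct(.data$junction_id) |>
      left_join(
        reads |> filter(.data$class == "junction") |>
          count(.data$junction_id, name = "planted_reads"),
        by = "junction_id"
      ) |>
      mutate(planted_reads = coalesce(.data$planted_reads, 0L),
             sample = scenario$sample_name, .before = 1)

    structure(
      list(reads = select(reads, "read_id", "seq", "class", "transcript_id",
                          "junction_id", "orientation", "n_errors"),
           truth = truth,
           scenario = scenario),
      class = "jq_sim"
    )
  })
}

add_substitution_errors <- function(seqs, rate) {
  if (rate == 0) return(list(seq = seqs, n_errors = integer(length(seqs))))
  bases <- c("A", "C", "G", "T")
  n_errors <- integer(length(seqs))
  out <- vapply(seq_along(seqs), function(i) {
    s <- strsplit(seqs[i], "")[[1]]
    hit <- which(runif(length(s)) < rate)
    n_errors[i] <<- length(hit)
    for (j in hit) s[j] <- sample(setdiff(bases, s[j]), 1)
    paste(s, collapse = "")
  }, character(1))
  list(seq = out, n_errors = n_errors)
}

#' @export
print.jq_sim <- function(x, ...) {
  cat(sprintf("<jq_sim> sample '%s': %d reads (%s)\n",
              x$scenario$sample_name, nrow(x$reads),
              paste(sprintf("%s=%d", names(table(x$reads$class)),
                            as.integer(table(x$reads$class))),
                    collapse = ", ")))
  invisible(x)
}

#' Write simulated reads as FASTQ / read FASTA-FASTQ read sets
#'
#' Qualities are constant (`I`, Phred 40) — the pipeline parses but never
#' uses them. `read_reads()` accepts FASTA or FASTQ (sniffed from the first
#' byte) and returns the read tibble shape used by [align_reads()].
#'
#' @param reads A read tibble (`read_id`, `seq`) or a `jq_sim`.
#' @param path File path.
#' @return `write_reads_fastq()` the input, invisibly; `read_reads()` a
#'   tibble with `read_id`, `seq`.
#' @export
write_reads_fastq <- function(reads, path) {
  if (inherits(reads, "jq_sim")) reads <- reads$reads
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(reads)
}

#' @rdname write_reads_fastq
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) abort(paste0("Read file not found: ", path))
  first <- readChar(path, 1)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)))
}

#' Write the simulator's ground truth as TSV
#' @param sim A `jq_sim`.
#' @param path File path.
#' @return The input, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "jq_sim"))
  readr::write_tsv(sim$truth, path)
  invisible(sim)
}
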