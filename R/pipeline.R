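#' Assemble a pipeline configuration
#'
#' Collects everything one end-to-end run needs. Input can be files
#' (transcript TSV/BED12, genome FASTA, reads FASTA/FASTQ) or be simulated
#' in-run by naming a scenario; every referenced path must exist when the
#' run starts. A config round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param models_path Transcript table path (TSV dialect or `.bed`); the
#'   packaged KCNJ6/DSCR4 table when `NULL`.
#' @param genome_path Genome FASTA path; when `NULL` a surrogate genome is
#'   simulated over [default_genome_span()] with `seed`.
#' @param reads_path Reads FASTA/FASTQ path; when `NULL`, reads are
#'   simulated from `scenario`.
#' @param scenario A [sim_scenario()], a preset name (see
#'   [scenario_preset()]), or `NULL` when `reads_path` is given.
#' @param out_dir Output directory for reports.
#' @param flank Junction flank in nt (default 25, i.e. 50-bp queries).
#' @param filter A [filter_params()].
#' @param scoring A [scoring_scheme()].
#' @param seed Integer seed for simulated inputs.
#' @return A list of class `jq_config`.
#' @export
pipeline_config <- function(models_path = NULL, genome_path = NULL,
                            reads_path = NULL, scenario = NULL,
                            out_dir = tempfile("junctionr_run_"),
                            flank = 25L, filter = filter_params(),
                            scoring = scoring_scheme(), seed = 1L) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario, seed = seed)
  if (is.null(reads_path) && is.null(scenario)) {
    abort("Provide either `reads_path` or a `scenario` to simulate reads.")
  }
  structure(
    list(models_path = models_path, genome_path = genome_path,
         reads_path = reads_path, scenario = scenario, out_dir = out_dir,
         flank = as.integer(flank), filter = filter, scoring = scoring,
         seed = as.integer(seed)),
    class = "jq_config"
  )
}

#' Run the junction-support pipeline end to end
#'
#' Stages: load (or simulate) models, genome and reads; build the junction
#' catalog and its sharing map; extract junction queries; align reads;
#' count significant support per junction; call isoform status; write
#' reports (junction FASTA, sharing TSV, alignment TSV, per-transcript
#' support tables, calls TSV/JSON, run manifest) under `out_dir`. Runs are
#' deterministic for a fixed config and seed. Any stage failure aborts with
#' a stage-tagged message.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return An object of class `jq_run`: list with `models`, `genome`,
#'   `junctions`, `sharing`, `queries`, `reads`, `alignments`, `support`,
#'   `calls`, `truth` (NULL for real reads), `config`, `files`.
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(scenario = "placenta", seed = 1))
#' glance(run)
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "jq_config"))
  say <- function(stage, fmt, ...) {
    if (!quiet) inform(paste0("[", stage, "] ", sprintf(fmt, ...)))
  }
  for (p in c(config$models_path, config$genome_path, config$reads_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("[input] Missing input file: ", p))
    }
  }

  models <- stage("models", function() {
    if (is.null(config$models_path)) {
      dscr_transcripts()
    } else if (grepl("\\.bed$", config$models_path, ignore.case = TRUE)) {
      read_bed12(config$models_path)
    } else {
      read_transcript_table(config$models_path)
    }
  })
  say("models", "%d transcripts, %d exons",
      length(unique(models$transcript_id)), nrow(models))

  genome <- stage("genome", function() {
    if (is.null(config$genome_path)) {
      simulate_genome(seed = config$seed, models = models)
    } else {
      read_genome_fasta(config$genome_path)
    }
  })
  say("genome", "%s:%d-%d", genome$chrom, genome$first_base,
      genome$first_base + length(genome$seq) - 1L)

  junctions <- stage("junctions", function() build_junctions(models))
  sharing <- stage("junctions", function() shared_junctions(junctions))
  queries <- stage("queries", function() {
    junction_queries(junctions, genome, flank = config$flank) |>
      distinct(.data$junction_id, .keep_all = TRUE)
  })
  say("queries", "%d junction identities (%d shared), %d-bp queries",
      nrow(queries), sum(sharing$shared), 2L * config$flank)

  truth <- NULL
  if (is.null(config$reads_path)) {
    sim <- stage("simulate", function() {
      simulate_reads(config$scenario, models, genome, flank = config$flank)
    })
    reads <- sim$reads
    truth <- sim$truth
    sample_name <- config$scenario$sample_name
  } else {
    reads <- stage("reads", function() read_reads(config$reads_path))
    sample_name <- sub("\\.(fastq|fq|fasta|fa)(\\.gz)?$", "",
                       basename(config$reads_path))
  }
  say("reads", "%d reads for sample '%s'", nrow(reads), sample_name)

  alignments <- stage("align", function() {
    align_reads(reads, queries, scoring = config$scoring,
                filter = config$filter)
  })
  say("align", "%d alignments, %d significant", nrow(alignments),
      sum(alignments$significant))

  support <- stage("support", function() {
    count_junction_support(alignments, queries, sample_name)
  })
  calls <- stage("call", function() {
    call_isoforms(support, junctions, sharing)
  })
  say("call", "full=%d partial=%d none=%d", sum(calls$status == "full"),
      sum(calls$status == "partial"), sum(calls$status == "none"))

  files <- stage("report", function() {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- character()
    write_junction_fasta(queries, file.path(config$out_dir, "junction_queries.fasta"))
    write_sharing_tsv(sharing, file.path(config$out_dir, "sharing.tsv"))
    write_alignments_tsv(alignments, file.path(config$out_dir, "alignments.tsv"))
    f <- c(file.path(config$out_dir,
                     c("junction_queries.fasta", "sharing.tsv", "alignments.tsv")),
           write_support_report(calls, support, junctions, config$out_dir,
                                sharing))
    if (!is.null(truth)) {
      tp <- file.path(config$out_dir, "ground_truth.tsv")
      readr::write_tsv(truth, tp)
      f <- c(f, tp)
    }
    manifest <- list(
      sample = sample_name, seed = config$seed, flank = config$flank,
      filter = unclass(config$filter), scoring = unclass(config$scoring),
      n_reads = nrow(reads), n_junction_identities = nrow(queries),
      n_alignments = nrow(alignments),
      n_significant = sum(alignments$significant),
      files = basename(f)
    )
    mp <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    c(f, mp)
  })
  say("report", "%d files under %s", length(files), config$out_dir)

  structure(
    list(models = models, genome = genome, junctions = junctions,
         sharing = sharing, queries = queries, reads = reads,
         alignments = alignments, support = support, calls = calls,
         truth = truth, config = config, files = files),
    class = "jq_run"
  )
}

stage <- function(name, fn) {
  tryCatch(fn(), error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^\\[", msg)) abort(msg) else abort(paste0("[", name, "] ", msg))
  })
}

#' @export
print.jq_run <- function(x, ...) {
  cat(sprintf("<jq_run> %d reads vs %d junction identities; %s\n",
              nrow(x$reads), nrow(x$queries),
              paste(sprintf("%s=%d", levels(x$calls$status),
                            as.integer(table(x$calls$status))),
                    collapse = " ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.jq_run <- function(x, ...) tidy(x$calls)

#' @exportS3Method generics::glance
glance.jq_run <- function(x, ...) {
  bind_cols(
    glance(x$calls),
    tibble(n_reads = nrow(x$reads),
           n_significant_alignments = sum(x$alignments$significant))
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.jq_run <- function(object, ...) {
  plot_support(object$support, object$junctions, object$sharing)
}

#' Write and read pipeline configurations as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` a `jq_config`;
#'   `write_pipeline_config()` the input, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "jq_config"))
  x <- list(
    models_path = config$models_path, genome_path = config$genome_path,
    reads_path = config$reads_path, out_dir = config$out_dir,
    flank = config$flank, seed = config$seed,
    filter = unclass(config$filter), scoring = unclass(config$scoring),
    scenario = if (!is.null(config$scenario)) unclass(config$scenario)
  )
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  x <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(x$scenario)) {
    s <- x$scenario
    scenario <- sim_scenario(s$sample_name, unlist(s$expressed) %||% character(),
                             s$junction_depth, s$exon_depth,
                             s$background_reads, s$read_length,
                             s$error_rate, s$seed)
  }
  pipeline_config(
    models_path = x$models_path, genome_path = x$genome_path,
    reads_path = x$reads_path, scenario = scenario,
    out_dir = x$out_dir, flank = x$flank,
    filter = filter_params(x$filter$min_query_cover, x$filter$min_identity),
    scoring = scoring_scheme(x$scoring$match, x$scoring$mismatch,
                             x$scoring$gap_open, x$scoring$gap_extend),
    seed = x$seed
  )
}
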