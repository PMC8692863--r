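#' Format a support count in the report dialect
#'
#' Zero renders `"No"`, one renders `"1 alignment"`, larger counts
#' `"<n> alignments"`; a trailing `*` marks junctions shared between
#' isoforms, whose support cannot be uniquely attributed.
#'
#' @param n Integer counts.
#' @param shared Logical, same length (recycled): junction shared?
#' @return Character vector of cells.
#' @examples
#' format_support_cell(c(0, 1, 33), c(FALSE, FALSE, TRUE))
#' @export
format_support_cell <- function(n, shared = FALSE) {
  cell <- case_when(
    n == 0 ~ "No",
    n == 1 ~ "1 alignment",
    .default = paste0(n, " alignments")
  )
  ifelse(n > 0 & shared, paste0(cell, "*"), cell)
}

#' Render one isoform's sample-by-junction support table
#'
#' Mirrors the classic summary-table shape: one row per sample, one column
#' per junction in transcript order (labelled `E1-E2`, ...), cells formatted
#' with [format_support_cell()].
#'
#' @param support A support tibble from [count_junction_support()].
#' @param junctions A junction tibble from [build_junctions()].
#' @param transcript Transcript id to render.
#' @param sharing Output of [shared_junctions()]; recomputed when omitted.
#' @return A tibble: `tissue` column plus one character column per junction.
#' @export
render_support_table <- function(support, junctions, transcript,
                                 sharing = NULL) {
  sharing <- sharing %||% shared_junctions(junctions)
  jn <- junctions |>
    filter(.data$transcript_id == transcript) |>
    arrange(.data$junction_rank) |>
    left_join(select(sharing, "junction_id", "shared"), by = "junction_id")
  if (nrow(jn) == 0) abort(paste0("No junctions for transcript ", transcript))
  wide <- support |>
    filter(.data$junction_id %in% jn$junction_id) |>
    left_join(select(jn, "junction_id", "junction_label", "shared"),
              by = "junction_id") |>
    mutate(cell = format_support_cell(.data$n_reads, .data$shared),
           junction_label = factor(.data$junction_label,
                                   levels = jn$junction_label)) |>
    select("sample", "junction_label", "cell") |>
    pivot_wider(names_from = "junction_label", values_from = "cell",
                names_expand = TRUE) |>
    rename(tissue = "sample")
  wide[match(unique(support$sample), wide$tissue), ]
}

#' Write the full support report to disk
#'
#' Writes one sample-by-junction TSV per transcript
#' (`support_<transcript>.tsv`), a per-isoform call TSV
#' (`isoform_calls.tsv`) and, optionally, the calls as JSON
#' (`isoform_calls.json`). Outputs are byte-deterministic given identical
#' inputs.
#'
#' @param calls A `jq_calls` tibble from [call_isoforms()].
#' @param support The support tibble the calls were made from.
#' @param junctions The junction tibble.
#' @param dir Output directory (created if needed).
#' @param sharing Output of [shared_junctions()]; recomputed when omitted.
#' @param json Also write `isoform_calls.json`?
#' @return Character vector of files written, invisibly.
#' @export
write_support_report <- function(calls, support, junctions, dir,
                                 sharing = NULL, json = TRUE) {
  sharing <- sharing %||% shared_junctions(junctions)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  for (tid in unique(junctions$transcript_id)) {
    path <- file.path(dir, paste0("support_", tid, ".tsv"))
    tab <- render_support_table(support, junctions, tid, sharing)
    tryCatch(readr::write_tsv(tab, path),
             error = function(e) abort(paste0(
               "Failed writing support table ", path, ": ", conditionMessage(e))))
    written <- c(written, path)
  }
  calls_path <- file.path(dir, "isoform_calls.tsv")
  readr::write_tsv(tidy(calls), calls_path)
  written <- c(written, calls_path)
  if (json) {
    json_path <- file.path(dir, "isoform_calls.json")
    jsonlite::write_json(tidy(calls), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, json_path)
  }
  invisible(written)
}

#' Heatmap of a junction support matrix
#'
#' @param support A support tibble (any number of samples).
#' @param junctions A junction tibble; orders the x axis and supplies
#'   labels.
#' @param sharing Output of [shared_junctions()]; recomputed when omitted.
#' @return A ggplot object: samples by junctions, tiles shaded by read
#'   count, shared junctions marked `*` in their axis label.
#' @export
plot_support <- function(support, junctions, sharing = NULL) {
  sharing <- sharing %||% shared_junctions(junctions)
  lab <- sharing |>
    mutate(axis_label = paste0(.data$junction_label,
                               ifelse(.data$shared, "*", "")))
  df <- support |>
    left_join(select(lab, "junction_id", "axis_label"), by = "junction_id") |>
    mutate(axis_label = factor(.data$axis_label,
                               levels = unique(lab$axis_label)))
  ggplot(df, aes(x = .data$axis_label, y = .data$sample,
                 fill = .data$n_reads)) +
    geom_tile(colour = "grey40") +
    geom_text(aes(label = ifelse(.data$n_reads > 0, .data$n_reads, "")),
              size = 3) +
    scale_fill_gradient(low = "white", high = "#de2d26") +
    labs(x = "exon junction (* shared between isoforms)", y = NULL,
         fill = "significant\nreads") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
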