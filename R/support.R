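#' Count significant junction support for one sample
#'
#' One row per catalog junction identity with the number of distinct reads
#' whose alignment to that junction passed the significance filter.
#' Junctions with no significant read get an explicit 0 (rendered "No" in
#' reports). An alignment referencing a junction absent from the catalog is
#' an error.
#'
#' @param alignments An alignment tibble from [align_reads()] (`query_id`
#'   must be junction identities).
#' @param catalog Junction identities: output of [shared_junctions()], a
#'   junction/query tibble with a `junction_id` column, or a character
#'   vector of identities.
#' @param sample Sample name attached to the counts.
#' @return A tibble `sample`, `junction_id`, `n_reads` in catalog order.
#' @export
count_junction_support <- function(alignments, catalog, sample) {
  ids <- if (is.character(catalog)) catalog else catalog$junction_id
  ids <- unique(ids)
  stray <- setdiff(unique(alignments$query_id), ids)
  if (length(stray) > 0) {
    abort(paste0("Alignments reference junctions absent from the catalog: ",
                 paste(stray, collapse = ", ")))
  }
  counts <- alignments |>
    filter(.data$significant) |>
    distinct(.data$query_id, .data$read_id) |>
    count(.data$query_id, name = "n_reads")
  tibble(sample = sample, junction_id = ids) |>
    left_join(counts, by = c(junction_id = "query_id")) |>
    mutate(n_reads = coalesce(.data$n_reads, 0L))
}

#' Call isoform status from a junction support matrix
#'
#' An isoform is `full` in a sample when every one of its junctions has at
#' least one significant read, `none` when no junction has any, `partial`
#' otherwise. Any junction whose identity belongs to more than one isoform
#' is flagged ambiguous (the report asterisk) whether or not it is
#' supported; `uniquely_confirmed` is TRUE when at least one *supported*
#' junction belongs to this isoform alone. Shared counts are never
#' apportioned between isoforms, only flagged.
#'
#' @param support A support tibble from [count_junction_support()] (several
#'   samples may be bound together).
#' @param junctions A junction tibble from [build_junctions()].
#' @param sharing Output of [shared_junctions()]; recomputed from
#'   `junctions` when omitted.
#' @return A tibble of class `jq_calls`: `sample`, `transcript_id`, `gene`,
#'   `status` (ordered factor none < partial < full), `n_junctions`,
#'   `n_supported`, `supported_junctions`, `ambiguous_junctions` (list
#'   columns of junction labels), `uniquely_confirmed`.
#' @examples
#' j <- build_junctions(dscr_transcripts())
#' empty <- count_junction_support(
#'   tibble::tibble(query_id = character(), read_id = character(),
#'                  significant = logical()),
#'   shared_junctions(j), "heart"
#' )
#' call_isoforms(empty, j)
#' @export
call_isoforms <- function(support, junctions, sharing = NULL) {
  sharing <- sharing %||% shared_junctions(junctions)
  missing <- setdiff(junctions$junction_id, sharing$junction_id)
  if (length(missing) > 0) {
    abort("`sharing` does not cover the junction catalog.")
  }
  ann <- junctions |>
    left_join(select(sharing, "junction_id", "n_transcripts"),
              by = "junction_id")
  calls <- support |>
    inner_join(ann, by = "junction_id", relationship = "many-to-many") |>
    group_by(.data$sample, .data$transcript_id, .data$gene) |>
    summarise(
      n_junctions = n(),
      n_supported = sum(.data$n_reads > 0),
      supported_junctions = list(.data$junction_label[.data$n_reads > 0]),
      ambiguous_junctions = list(.data$junction_label[.data$n_transcripts > 1]),
      uniquely_confirmed = any(.data$n_reads > 0 & .data$n_transcripts == 1),
      .groups = "drop"
    ) |>
    mutate(status = factor(
      case_when(
        .data$n_supported == 0 ~ "none",
        .data$n_supported == .data$n_junctions ~ "full",
        .default = "partial"
      ),
      levels = c("none", "partial", "full"), ordered = TRUE
    )) |>
    select("sample", "transcript_id", "gene", "status", "n_junctions",
           "n_supported", "supported_junctions", "ambiguous_junctions",
           "uniquely_confirmed") |>
    arrange(match(.data$transcript_id, unique(junctions$transcript_id)),
            .data$sample)
  class(calls) <- c("jq_calls", class(calls))
  calls
}

#' @exportS3Method generics::tidy
tidy.jq_calls <- function(x, ...) {
  as_tibble(x) |>
    mutate(
      supported_junctions = map_chr(.data$supported_junctions, paste,
                                    collapse = ","),
      ambiguous_junctions = map_chr(.data$ambiguous_junctions, paste,
                                    collapse = ",")
    )
}

#' @exportS3Method generics::glance
glance.jq_calls <- function(x, ...) {
  tibble(
    n_samples = length(unique(x$sample)),
    n_isoforms = length(unique(x$transcript_id)),
    n_full = sum(x$status == "full"),
    n_partial = sum(x$status == "partial"),
    n_none = sum(x$status == "none"),
    n_uniquely_confirmed = sum(x$uniquely_confirmed)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.jq_calls <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$transcript_id, y = .data$sample,
             fill = .data$status)) +
    geom_tile(colour = "grey30") +
    geom_point(data = ~ filter(.x, .data$uniquely_confirmed),
               shape = 8, size = 2) +
    scale_fill_manual(values = c(none = "grey92", partial = "#9ecae1",
                                 full = "#3182bd"), drop = FALSE) +
    labs(x = NULL, y = NULL, fill = "isoform status",
         caption = "* = at least one uniquely attributable junction supported") +
    theme_minimal()
}
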