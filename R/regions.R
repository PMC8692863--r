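#' Define a named genomic region
#'
#' @param name Region label.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates (either order).
#' @return A one-row tibble with columns `name`, `chrom`, `start`, `end`.
#' @examples
#' named_region("promoter", "chr21", 38121452, 38121361)
#' @export
named_region <- function(name, chrom, start, end) {
  lo <- min(start, end)
  hi <- max(start, end)
  if (lo < 1) abort("Region coordinates are 1-based: start must be >= 1.")
  tibble(name = name, chrom = chrom, start = as.integer(lo),
         end = as.integer(hi))
}

#' The highly restricted Down syndrome critical region (HR-DSCR)
#'
#' The ~34-kbp interval on distal 21q22.13 (GRCh38 37,929,229-37,963,130)
#' present in three copies in all partial-trisomy-21 individuals with a
#' Down syndrome diagnosis.
#'
#' @return A one-row region tibble (see [named_region()]).
#' @examples
#' interval_length(hr_dscr()$start, hr_dscr()$end)
#' @export
hr_dscr <- function() {
  named_region("HR-DSCR", "chr21", 37929229L, 37963130L)
}

#' Classify how features overlap a named region
#'
#' For each feature interval, reports exactly one of four mutually exclusive,
#' exhaustive relations against the region: `disjoint` (no shared base),
#' `feature_within_region` (region.start <= feature.start and feature.end <=
#' region.end; equal intervals report this value), `feature_contains_region`
#' (feature covers the whole region), or `partial_overlap` (some but not all
#' bases shared, neither containment). Features on a different chromosome
#' are `disjoint`, with a warning.
#'
#' @param features A data frame of intervals with columns `chrom`, `start`,
#'   `end` (e.g. exons from [parse_transcript_table()] or introns from
#'   [transcript_introns()]).
#' @param region A one-row region tibble from [named_region()].
#' @return The feature tibble with added columns `region` (its name) and
#'   `relation` (factor with the four levels above).
#' @examples
#' m <- dscr_transcripts()
#' classify_overlap(m[m$transcript_id == "DSCR4-202", ], hr_dscr())
#' @export
classify_overlap <- function(features, region) {
  features <- as_tibble(features)
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(features))) {
    abort("`features` needs columns chrom, start, end.")
  }
  stopifnot(nrow(region) == 1)
  if (any(features$chrom != region$chrom)) {
    warn(paste0("Feature(s) on a different chromosome than region '",
                region$name, "': reported as disjoint."))
  }
  relation <- overlap_relation(features$chrom, features$start, features$end,
                               region$chrom, region$start, region$end)
  features |>
    mutate(region = region$name,
           relation = factor(relation, levels = overlap_levels()))
}

overlap_levels <- function() {
  c("disjoint", "feature_within_region", "feature_contains_region",
    "partial_overlap")
}

overlap_relation <- function(f_chrom, f_start, f_end,
                             r_chrom, r_start, r_end) {
  dplyr::case_when(
    f_chrom != r_chrom ~ "disjoint",
    f_end < r_start | f_start > r_end ~ "disjoint",
    r_start <= f_start & f_end <= r_end ~ "feature_within_region",
    f_start <= r_start & r_end <= f_end ~ "feature_contains_region",
    .default = "partial_overlap"
  )
}
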