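#' QC a PCR primer pair
#'
#' Checks a forward/reverse primer pair against standard design criteria:
#' annealing temperature by the Wallace rule (Ta = 2(A+T) + 4(G+C) degrees
#' C) between 55 and 65 for each primer, pair difference below 2 degrees C,
#' GC content between 40 and 60 percent, and no secondary-structure
#' liability by a perfect-complementarity-run heuristic — a hairpin /
#' self-dimer flag when a primer contains a run of >= `dimer_run` bases
#' perfectly complementary to itself, and a cross-dimer flag for such a run
#' between the two primers. The pair passes iff every criterion passes.
#'
#' The Wallace rule is a deliberate simple default (documented, swappable by
#' checking `ta` yourself); no nearest-neighbour thermodynamics.
#'
#' @param forward,reverse Primer sequences, 10-40 nt, A/C/G/T only.
#' @param dimer_run Complementary-run length that triggers a flag
#'   (default 6).
#' @return A list of class `jq_primer_report`: `$primers`, a two-row tibble
#'   (`primer`, `sequence`, `length`, `ta`, `gc_pct`, `self_run`,
#'   `self_dimer`, `hairpin`, `ta_pass`, `gc_pass`); `$pair`, a one-row
#'   tibble (`delta_ta`, `delta_ta_pass`, `cross_run`, `cross_dimer`,
#'   `pass`).
#' @examples
#' primer_pair_qc("ATGCATGCATGCATGCATGC", "GGTTCCAAGGTTCCAAGGTT")
#' @export
primer_pair_qc <- function(forward, reverse, dimer_run = 6L) {
  primers <- c(forward = forward, reverse = reverse)
  for (p in primers) {
    if (is.na(p) || nchar(p) < 10 || nchar(p) > 40) {
      abort("Primers must be 10-40 nt long.")
    }
    if (grepl("[^ACGT]", toupper(p))) {
      abort("Primers must contain only A/C/G/T.")
    }
  }
  primers <- toupper(primers)
  stats <- map2(primers, names(primers), function(p, nm) {
    counts <- table(factor(strsplit(p, "")[[1]], levels = c("A", "C", "G", "T")))
    at <- counts[["A"]] + counts[["T"]]
    gc <- counts[["G"]] + counts[["C"]]
    ta <- 2 * at + 4 * gc
    self_run <- complementary_run(p, p)
    tibble(
      primer = nm, sequence = p, length = nchar(p),
      ta = ta, gc_pct = 100 * gc / nchar(p),
      self_run = self_run,
      self_dimer = self_run >= dimer_run,
      hairpin = self_run >= dimer_run,
      ta_pass = ta >= 55 & ta <= 65,
      gc_pass = gc / nchar(p) >= 0.40 & gc / nchar(p) <= 0.60
    )
  }) |> list_rbind()

  cross_run <- complementary_run(primers[["forward"]], primers[["reverse"]])
  delta_ta <- abs(diff(stats$ta))
  pair <- tibble(
    delta_ta = delta_ta,
    delta_ta_pass = delta_ta < 2,
    cross_run = cross_run,
    cross_dimer = cross_run >= dimer_run,
    pass = all(stats$ta_pass) && all(stats$gc_pass) &&
      !any(stats$self_dimer) && !any(stats$hairpin) &&
      delta_ta < 2 && cross_run < dimer_run
  )
  structure(list(primers = stats, pair = pair), class = "jq_primer_report")
}

# Longest run of perfect antiparallel complementarity between two primers:
# the longest common substring of `a` and the reverse complement of `b`.
complementary_run <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(revcomp(b), "")[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    hit <- which(y == x[i])
    cur[hit] <- 1L + c(0L, prev)[hit]
    best <- max(best, cur, 0L)
    prev <- cur
  }
  as.integer(best)
}

#' @export
print.jq_primer_report <- function(x, ...) {
  cat("<jq_primer_report>\n")
  print(x$primers)
  print(x$pair)
  invisible(x)
}
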