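#' The predefined overlap-fragment library
#'
#' Fusion PCR joins amplicons through primers carrying a fixed 5' overlap
#' tail. The shipped library covers common applications — fluorophore
#' anchors (GFP, YFP, mCherry/RFP, tdTomato) and Illumina adapter and primer
#' sequences — and is a plain two-column TSV under `inst/extdata` so users
#' can point `path` at an extended copy. Duplicated sequences between
#' entries are intentional (some applications share a tail).
#'
#' @param path Optional path to an alternative library TSV
#'   (columns `name`, `seq`).
#' @return A tibble with columns `name` and `seq`.
#' @export
overlap_library <- function(path = NULL) {
  path <- path %||% system.file("extdata", "overlap_fragments.tsv",
                                package = "stitchkit", mustWork = TRUE)
  tab <- as_tibble(read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE))
  stopifnot(all(c("name", "seq") %in% names(tab)))
  if (anyDuplicated(tab$name)) {
    abort("Overlap library names must be unique.",
          class = "stitchkit_parameter_error")
  }
  if (any(!nzchar(tab$seq)) || any(grepl("[^ACGT]", tab$seq))) {
    abort("Overlap sequences must be non-empty A/C/G/T strings.",
          class = "stitchkit_invalid_alphabet")
  }
  tab
}

#' Look up a predefined overlap fragment by name
#'
#' @param name Library entry name, e.g. `"GFP_Celegans"`.
#' @param library An [overlap_library()] tibble.
#' @return A one-row tibble (`name`, `seq`).
#' @examples
#' get_overlap("GFP")$seq
#' @export
get_overlap <- function(name, library = overlap_library()) {
  hit <- library[library$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) {
    abort(paste0("Unknown overlap fragment \"", name, "\". Valid names: ",
                 paste(library$name, collapse = ", ")),
          class = "stitchkit_lookup_error")
  }
  hit
}

#' Build a fusion primer from an overlap tail and a primer core
#'
#' The overlap tail always sits at the 5' end: the fusion primer is simply
#' `overlap + core`. Primer-size parameters constrain the core only, never
#' the full fusion oligo.
#'
#' @param overlap An overlap fragment: a one-row tibble from
#'   [get_overlap()], or a plain sequence string (may be empty).
#' @param core Non-empty primer core (5'->3').
#' @return The fusion primer sequence.
#' @examples
#' build_fusion_primer(get_overlap("GFP_Celegans"), "GTGGTCGTGGGTTTGATG")
#' @export
build_fusion_primer <- function(overlap, core) {
  if (is.data.frame(overlap)) overlap <- overlap$seq
  if (is.null(overlap)) overlap <- ""
  if (!nzchar(core)) {
    abort("`core` must be non-empty.", class = "stitchkit_contract_error")
  }
  paste0(overlap, core)
}

#' Enumerate compatible forward/reverse primer pairs
#'
#' Every forward x reverse combination is evaluated. A pair is compatible
#' when both primers pass their individual filters, the reverse primer lies
#' 3' of the forward one (positive product length), the Tm difference is at
#' most `max_tm_diff`, and the cross-dimer weighted score (scanned over the
#' full sequences, overlap tails included) does not exceed
#' `cutoffs$dimer_max`. The output keeps every combination, flagged, sorted
#' by ascending dimer score then descending product length.
#'
#' @param fwds,revs Annotated candidate tibbles from
#'   [enumerate_candidates()].
#' @param max_tm_diff Maximum Tm difference in Celsius (default 5).
#' @param cutoffs A [score_cutoffs()].
#' @param model A [thermo_model()].
#' @param three_prime_window,three_prime_weight Scan settings, as in
#'   [complementarity_scan()].
#' @return A tibble: `fwd_name`, `rev_name`, `fwd_start`, `rev_end`,
#'   `product_len`, `tm_fwd`, `tm_rev`, `tm_diff`, `dimer_matches`,
#'   `dimer_longest_run`, `dimer_run_dG`, `dimer_weighted`, `compatible`.
#' @export
compatible_pairs <- function(fwds, revs, max_tm_diff = 5,
                             cutoffs = score_cutoffs(),
                             model = thermo_model(),
                             three_prime_window = 5, three_prime_weight = 2) {
  if (nrow(fwds) == 0L || nrow(revs) == 0L) {
    return(tibble(
      fwd_name = character(), rev_name = character(),
      fwd_start = integer(), rev_end = integer(), product_len = integer(),
      tm_fwd = numeric(), tm_rev = numeric(), tm_diff = numeric(),
      dimer_matches = integer(), dimer_longest_run = integer(),
      dimer_run_dG = numeric(), dimer_weighted = numeric(),
      compatible = logical()
    ))
  }
  grid <- tidyr::expand_grid(f = seq_len(nrow(fwds)), r = seq_len(nrow(revs)))
  scans <- map2(grid$f, grid$r, function(i, j) {
    a <- fwds$full_seq[i]; b <- revs$full_seq[j]
    if (grepl("N", a) || grepl("N", b)) {
      tibble(best_offset = NA_integer_, total_matches = NA_integer_,
             longest_run = NA_integer_, run_dG = NA_real_,
             three_prime_matches = NA_integer_, weighted_score = NA_real_)
    } else {
      complementarity_scan(a, b, model = model,
                           three_prime_window = three_prime_window,
                           three_prime_weight = three_prime_weight)
    }
  })
  scans <- bind_rows(scans)
  out <- tibble(
    fwd_name = fwds$name[grid$f], rev_name = revs$name[grid$r],
    fwd_start = fwds$start[grid$f], rev_end = revs$end[grid$r],
    product_len = revs$end[grid$r] - fwds$start[grid$f] + 1L,
    tm_fwd = fwds$tm_celsius[grid$f], tm_rev = revs$tm_celsius[grid$r],
    tm_diff = abs(fwds$tm_celsius[grid$f] - revs$tm_celsius[grid$r]),
    dimer_matches = scans$total_matches,
    dimer_longest_run = scans$longest_run,
    dimer_run_dG = scans$run_dG,
    dimer_weighted = scans$weighted_score
  )
  out$compatible <- fwds$pass[grid$f] & revs$pass[grid$r] &
    out$product_len > 0L &
    !is.na(out$tm_diff) & out$tm_diff <= max_tm_diff &
    !is.na(out$dimer_weighted) & out$dimer_weighted <= cutoffs$dimer_max
  arrange(out, .data$dimer_weighted, desc(.data$product_len))
}
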