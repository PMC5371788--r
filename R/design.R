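#' Complementarity score cutoffs
#'
#' Maximum weighted scores a candidate (or pair) may reach before it is
#' flagged. Defaults are deliberately permissive screening values; all are
#' user-overridable to be more or less stringent. `hairpin_max` bounds the
#' hairpin stem length rather than a weighted score.
#'
#' @param self_max Max weighted self-complementarity (default 12).
#' @param three_prime_max Max 3'-window self matches (default 4).
#' @param overhang_max Max weighted overhang score (default 10).
#' @param dimer_max Max weighted cross-dimer score for a pair (default 12).
#' @param hairpin_max Max hairpin stem length in bases (default 6).
#' @return A `score_cutoffs` list.
#' @export
score_cutoffs <- function(self_max = 12, three_prime_max = 4,
                          overhang_max = 10, dimer_max = 12,
                          hairpin_max = 6) {
  vals <- c(self_max = self_max, three_prime_max = three_prime_max,
            overhang_max = overhang_max, dimer_max = dimer_max,
            hairpin_max = hairpin_max)
  if (any(vals < 0)) {
    abort("Score cutoffs must be non-negative.",
          class = "stitchkit_parameter_error")
  }
  structure(as.list(vals), class = "score_cutoffs")
}

#' Design parameters for a primer-design run
#'
#' Every tunable of the design form, with its default. Primer sizes refer to
#' the gene-specific core only and never include an attached overlap tail.
#'
#' @param design_forward,design_reverse Design primers on that side?
#'   Both `TRUE` by default.
#' @param fwd_size,rev_size Core primer length in bases (default 20;
#'   minimum 8).
#' @param search_area_5p,search_area_3p Search areas in bases measured from
#'   the 5' and 3' ends of the input (default 200).
#' @param gc_min,gc_max Allowed GC percent range (defaults 40-60).
#' @param tm_min,tm_max Allowed melting-temperature range in Celsius
#'   (defaults 45-55, on the Schildkraut-corrected 50 mM scale of the default model).
#' @param salt_mM Monovalent salt for Tm, 50 mM by default with a 10 mM
#'   option on the form; any positive value accepted programmatically.
#' @param primer_conc_nM Total strand concentration for Tm (default 250).
#' @param gc_clamp_fwd,gc_clamp_rev Require G or C at the 3' terminus?
#'   Default off.
#' @param increment_fwd,increment_rev Step between candidate start positions
#'   in bases (default 2).
#' @param cutoffs A [score_cutoffs()].
#' @param remove_n Excise N's from the input before design? Default `FALSE`.
#' @param exclude_repeats Reject candidates containing a homopolymer run of
#'   four or more bases or four or more consecutive identical dinucleotide
#'   units? Default `TRUE`.
#' @param overlap_selection `"none"` (default), `"named"` (pick from the
#'   predefined library), `"user_defined"`, or `"mutant"`.
#' @param overlap_name Library entry when `overlap_selection = "named"`.
#' @param overlap_seq Tail sequence when `overlap_selection = "user_defined"`.
#' @param mutant_seq Forward mutant oligo when `overlap_selection = "mutant"`.
#' @param overlap_on Which strand carries the overlap tail: `"reverse"`
#'   (default, the usual fusion-PCR layout), `"forward"` or `"both"`.
#' @param max_tm_diff Maximum forward/reverse Tm difference for a compatible
#'   pair, in Celsius (default 5).
#' @param three_prime_window,three_prime_weight Scoring window and weight
#'   passed to the complementarity scans.
#' @param nn_set Nearest-neighbor table, see [thermo_model()].
#' @return A `design_parameters` list.
#' @export
design_parameters <- function(design_forward = TRUE, design_reverse = TRUE,
                              fwd_size = 20, rev_size = 20,
                              search_area_5p = 200, search_area_3p = 200,
                              gc_min = 40, gc_max = 60,
                              tm_min = 45, tm_max = 55,
                              salt_mM = 50, primer_conc_nM = 250,
                              gc_clamp_fwd = FALSE, gc_clamp_rev = FALSE,
                              increment_fwd = 2, increment_rev = 2,
                              cutoffs = score_cutoffs(),
                              remove_n = FALSE, exclude_repeats = TRUE,
                              overlap_selection = c("none", "named",
                                                    "user_defined", "mutant"),
                              overlap_name = NULL, overlap_seq = NULL,
                              mutant_seq = NULL,
                              overlap_on = c("reverse", "forward", "both"),
                              max_tm_diff = 5,
                              three_prime_window = 5, three_prime_weight = 2,
                              nn_set = "santalucia1998") {
  overlap_selection <- match.arg(overlap_selection)
  overlap_on <- match.arg(overlap_on)
  if (fwd_size < 8 || rev_size < 8) {
    abort("Primer sizes must be at least 8 bases.",
          class = "stitchkit_parameter_error")
  }
  if (increment_fwd < 1 || increment_rev < 1) {
    abort("Increments must be at least 1 base.",
          class = "stitchkit_parameter_error")
  }
  if (gc_min > gc_max) {
    abort("`gc_min` must not exceed `gc_max`.",
          class = "stitchkit_parameter_error")
  }
  if (tm_min > tm_max) {
    abort("`tm_min` must not exceed `tm_max`.",
          class = "stitchkit_parameter_error")
  }
  stopifnot(inherits(cutoffs, "score_cutoffs"))
  structure(
    list(design_forward = design_forward, design_reverse = design_reverse,
         fwd_size = as.integer(fwd_size), rev_size = as.integer(rev_size),
         search_area_5p = as.integer(search_area_5p),
         search_area_3p = as.integer(search_area_3p),
         gc_min = gc_min, gc_max = gc_max, tm_min = tm_min, tm_max = tm_max,
         salt_mM = salt_mM, primer_conc_nM = primer_conc_nM,
         gc_clamp_fwd = gc_clamp_fwd, gc_clamp_rev = gc_clamp_rev,
         increment_fwd = as.integer(increment_fwd),
         increment_rev = as.integer(increment_rev),
         cutoffs = cutoffs, remove_n = remove_n,
         exclude_repeats = exclude_repeats,
         overlap_selection = overlap_selection,
         overlap_name = overlap_name, overlap_seq = overlap_seq,
         mutant_seq = mutant_seq, overlap_on = overlap_on,
         max_tm_diff = max_tm_diff,
         three_prime_window = three_prime_window,
         three_prime_weight = three_prime_weight,
         nn_set = nn_set),
    class = "design_parameters"
  )
}

params_model <- function(params) {
  thermo_model(set = params$nn_set, salt_mM = params$salt_mM,
               primer_conc_nM = params$primer_conc_nM)
}

#' Does a sequence contain repetitive runs?
#'
#' `TRUE` when the sequence contains a homopolymer stretch of four or more
#' identical bases (e.g. `CCCC`, `TTTT`) or four or more consecutive
#' identical dinucleotide units (e.g. `CGCGCGCG`, `TGTGTGTG`). Three
#' dinucleotide units (`CGCGCG`) do not qualify.
#'
#' @param seq Character vector of DNA strings.
#' @return Logical vector.
#' @examples
#' is_repetitive(c("ATTTTA", "ACGCGCGCGT", "CGCGCG"))
#' @export
is_repetitive <- function(seq) {
  grepl("(.)\\1{3}", seq) | grepl("(..)\\1{3}", seq)
}

#' Enumerate primer candidates in a search area
#'
#' Forward candidates start at the 5' end of the (cleaned) input and step
#' inward by `increment_fwd` while the whole core stays inside the first
#' `search_area_5p` bases; reverse candidates are the reverse complements of
#' windows stepped inward from the 3' end within `search_area_3p`. Before
#' filtering, the candidate count is `floor((area - size) / increment) + 1`.
#' Every candidate is fully annotated — GC%, Tm, self-complementarity,
#' 3' matches and hairpin on the gene-specific core, plus the tail-vs-core
#' overhang score when a tail is attached — and run through
#' [passes_filters()]; nothing is silently dropped, so reports can show
#' near-misses.
#'
#' @param rec An `input_sequence`.
#' @param params A [design_parameters()].
#' @param strand `"forward"` or `"reverse"`.
#' @param overlap_seq Optional overlap tail (5'->3') prepended to each
#'   candidate's core.
#' @return A tibble of annotated candidates (see [passes_filters()] for the
#'   filter columns).
#' @export
enumerate_candidates <- function(rec, params, strand = c("forward", "reverse"),
                                 overlap_seq = "") {
  strand <- match.arg(strand)
  stopifnot(inherits(rec, "input_sequence"),
            inherits(params, "design_parameters"))
  size <- if (strand == "forward") params$fwd_size else params$rev_size
  area <- if (strand == "forward") params$search_area_5p else params$search_area_3p
  inc <- if (strand == "forward") params$increment_fwd else params$increment_rev
  if (area > rec$length) {
    abort("Search area exceeds the sequence length.",
          class = "stitchkit_parameter_error")
  }
  if (area < size) {
    abort(paste0("Search area (", area, " bp) is smaller than the primer size (",
                 size, " bp) on the ", strand, " side."),
          class = "stitchkit_parameter_error")
  }
  n_cand <- (area - size) %/% inc + 1L
  offsets <- (seq_len(n_cand) - 1L) * inc
  if (strand == "forward") {
    start <- 1L + offsets
  } else {
    start <- rec$length - size + 1L - offsets
  }
  end <- start + size - 1L
  slice <- substring(rec$seq, start, end)
  core <- if (strand == "forward") slice else reverse_complement(slice)
  cands <- tibble(
    name = paste0(seq_len(n_cand), if (strand == "forward") "F" else "R"),
    strand = strand,
    start = start, end = end,
    core_seq = core,
    overlap_seq = overlap_seq,
    full_seq = paste0(overlap_seq, core)
  )
  cands <- annotate_candidates(cands, params)
  passes_filters(cands, params)
}

annotate_candidates <- function(cands, params) {
  model <- params_model(params)
  w <- params$three_prime_window
  w3 <- params$three_prime_weight
  metrics <- pmap(list(cands$core_seq, cands$full_seq, cands$overlap_seq),
                  function(core, full, ov) {
    has_n <- grepl("N", core)
    tm <- if (has_n || nchar(core) < 8) NA_real_ else melting_temperature(core, model)
    # self/3'/hairpin describe the gene-specific core; the tail's annealing
    # risks are screened by the overhang gate (tail vs core) here and by the
    # full-sequence dimer scan at pair stage
    self <- if (has_n) {
      tibble(best_offset = NA_integer_, total_matches = NA_integer_,
             longest_run = NA_integer_, run_dG = NA_real_,
             three_prime_matches = NA_integer_, weighted_score = NA_real_)
    } else {
      self_complementarity(core, model = model, three_prime_window = w,
                           three_prime_weight = w3)
    }
    hp <- hairpin_score(core, model = model)
    ovh <- if (nzchar(ov) && !grepl("N", paste0(ov, core))) {
      complementarity_scan(ov, core, model = model, three_prime_window = w,
                           three_prime_weight = w3)$weighted_score
    } else NA_real_
    tibble(
      length = nchar(core),
      gc_percent = gc_percent_of(core),
      tm_celsius = tm,
      self_matches = self$total_matches,
      self_longest_run = self$longest_run,
      self_run_dG = self$run_dG,
      self_three_prime = self$three_prime_matches,
      self_weighted = self$weighted_score,
      hairpin_stem = hp$stem_len,
      hairpin_dG = hp$stem_dG,
      overhang_weighted = ovh,
      contains_n = has_n
    )
  })
  dplyr::bind_cols(cands, bind_rows(metrics))
}

#' Apply the design filters to annotated candidates
#'
#' Appends one fail reason per violated rule — `gc_range`, `tm_range`,
#' `gc_clamp`, `repetitive`, `self_complementarity`, `three_prime`,
#' `hairpin`, `overhang`, `contains_n` — and sets `pass` to `TRUE` exactly
#' when no rule is violated. Candidates are annotated, never dropped.
#'
#' @param cands Annotated candidate tibble from [enumerate_candidates()].
#' @param params A [design_parameters()].
#' @return The candidate tibble with `pass` (logical) and `fail_reasons`
#'   (semicolon-separated string, empty when passing).
#' @export
passes_filters <- function(cands, params) {
  cutoffs <- params$cutoffs
  reasons <- pmap(
    list(cands$strand, cands$core_seq, cands$gc_percent, cands$tm_celsius,
         cands$self_weighted, cands$self_three_prime, cands$hairpin_stem,
         cands$overhang_weighted, cands$contains_n),
    function(strand, core, gc, tm, selfw, tp, hp, ovh, has_n) {
      r <- character()
      if (has_n) r <- c(r, "contains_n")
      if (!is.na(gc) && (gc < params$gc_min || gc > params$gc_max)) {
        r <- c(r, "gc_range")
      }
      if (!is.na(tm) && (tm < params$tm_min || tm > params$tm_max)) {
        r <- c(r, "tm_range")
      }
      clamp_on <- if (strand == "forward") params$gc_clamp_fwd else params$gc_clamp_rev
      if (clamp_on && !substr(core, nchar(core), nchar(core)) %in% c("G", "C")) {
        r <- c(r, "gc_clamp")
      }
      if (params$exclude_repeats && is_repetitive(core)) r <- c(r, "repetitive")
      if (!is.na(selfw) && selfw > cutoffs$self_max) r <- c(r, "self_complementarity")
      if (!is.na(tp) && tp > cutoffs$three_prime_max) r <- c(r, "three_prime")
      if (hp > cutoffs$hairpin_max) r <- c(r, "hairpin")
      if (!is.na(ovh) && ovh > cutoffs$overhang_max) r <- c(r, "overhang")
      r
    }
  )
  cands$fail_reasons <- map_chr(reasons, paste, collapse = ";")
  cands$pass <- cands$fail_reasons == ""
  cands
}

#' Design a mutagenesis primer set
#'
#' For site-directed mutagenesis by overlap extension the user supplies the
#' forward mutant oligo; its reverse complement is the reverse mutant oligo,
#' and a single flanking pair is picked: the best passing forward primer in
#' the 5' search area and the best passing reverse primer in the 3' area.
#' "Best" is the lowest weighted self score, ties broken by Tm closest to
#' the midpoint of the allowed range, then by proximity to the sequence end.
#'
#' @param rec An `input_sequence`.
#' @param mutant_fwd Non-empty forward mutant oligo (5'->3').
#' @param params A [design_parameters()].
#' @return A list: `mutant_fwd`, `mutant_rev`, `fwd` and `rev` (one-row
#'   candidate tibbles).
#' @export
design_mutant_pair <- function(rec, mutant_fwd, params = design_parameters()) {
  if (is.null(mutant_fwd) || !nzchar(mutant_fwd)) {
    abort("`mutant_fwd` must be non-empty.", class = "stitchkit_parameter_error")
  }
  if (grepl("[^ACGTN]", mutant_fwd)) {
    abort("Mutant oligo must be A/C/G/T/N.",
          class = "stitchkit_invalid_alphabet")
  }
  mutant_rev <- reverse_complement(mutant_fwd)
  pick_best <- function(strand) {
    cands <- enumerate_candidates(rec, params, strand)
    ok <- cands[cands$pass, , drop = FALSE]
    if (nrow(ok) == 0L) {
      near <- cands[order(nchar(cands$fail_reasons)), , drop = FALSE][1, ]
      abort(paste0("No passing ", strand, " primer in its search area; ",
                   "best near-miss ", near$name, " fails: ", near$fail_reasons),
            class = "stitchkit_design_failure")
    }
    tm_mid <- (params$tm_min + params$tm_max) / 2
    dist_end <- if (strand == "forward") ok$start else rec$length - ok$end
    ok[order(ok$self_weighted, abs(ok$tm_celsius - tm_mid), dist_end), ][1, ]
  }
  list(mutant_fwd = mutant_fwd, mutant_rev = mutant_rev,
       fwd = pick_best("forward"), rev = pick_best("reverse"))
}
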