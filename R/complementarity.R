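#' Ungapped complementarity scan of two primers
#'
#' Slides `a` (5'->3') along `b` (3'->5') through every ungapped offset and
#' counts antiparallel Watson-Crick matches, which is equivalent to sliding
#' `a` against `reverse_complement(b)` and counting equal characters. The
#' reported alignment is the offset with the most matches; ties go to the
#' offset with the longer contiguous run, then to the smaller offset, so the
#' result is deterministic. The longest matched run's duplex dG (37 C) and
#' the number of matches falling within `three_prime_window` bases of either
#' primer's 3' end complete the report, and the weighted score combines all
#' three (see [weighted_score()]).
#'
#' @param a,b Non-empty DNA strings over `A/C/G/T` (`N` never matches).
#' @param model A [thermo_model()] for the run dG.
#' @param three_prime_window Terminal window in bases (default 5).
#' @param three_prime_weight Multiplier on 3'-window matches in the weighted
#'   score (default 2).
#' @return A one-row tibble (`complementarity_report`): `best_offset`,
#'   `total_matches`, `longest_run`, `run_dG`, `three_prime_matches`,
#'   `weighted_score`.
#' @examples
#' complementarity_scan("ACGT", "ACGT")    # palindromic self-duplex
#' complementarity_scan("AAAA", "AAAA")    # A.A never pairs
#' @export
complementarity_scan <- function(a, b, model = thermo_model(),
                                 three_prime_window = 5,
                                 three_prime_weight = 2) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("complementarity_scan() requires non-empty sequences.",
          class = "stitchkit_contract_error")
  }
  av <- strsplit(a, "")[[1]]
  rb <- strsplit(reverse_complement(b), "")[[1]]
  la <- length(av); lb <- length(rb)
  best <- list(offset = 0L, matches = -1L, run = -1L, run_start = NA_integer_,
               run_len = 0L, match_idx_a = integer(), match_idx_m = integer())
  for (k in (1L - lb):(la - 1L)) {
    i <- max(1L, k + 1L):min(la, k + lb)
    m <- i - k                       # index into reverse-complemented b
    hit <- av[i] == rb[m] & av[i] != "N"
    total <- sum(hit)
    # longest contiguous run of matches and its start within `a`
    run_len <- 0L; run_start <- NA_integer_
    if (total > 0L) {
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      runs <- which(r$values)
      wbest <- runs[which.max(r$lengths[runs])]
      run_len <- r$lengths[wbest]
      run_start <- i[ends[wbest] - run_len + 1L]
    }
    if (total > best$matches ||
        (total == best$matches && run_len > best$run)) {
      best <- list(offset = k, matches = total, run = run_len,
                   run_start = run_start, run_len = run_len,
                   match_idx_a = i[hit], match_idx_m = m[hit])
    }
  }
  run_dG <- if (best$run >= 2) {
    duplex_delta_g(substr(a, best$run_start, best$run_start + best$run - 1L),
                   model)
  } else 0
  # 3' terminal matches: within the window at a's 3' end, or at b's 3' end
  # (b's last `w` bases are the first `w` positions of its reverse complement)
  w <- three_prime_window
  tp <- if (w >= 1) {
    sum(best$match_idx_a > la - w | best$match_idx_m <= w)
  } else 0L
  rep <- tibble(
    best_offset = best$offset,
    total_matches = as.integer(best$matches),
    longest_run = as.integer(best$run),
    run_dG = run_dG,
    three_prime_matches = as.integer(tp),
    weighted_score = 0
  )
  rep$weighted_score <- weighted_score(rep, three_prime_weight = three_prime_weight)
  rep
}

#' Self-complementarity of a primer
#'
#' Scans a primer against a second copy of itself; see
#' [complementarity_scan()].
#'
#' @inheritParams complementarity_scan
#' @param p Non-empty DNA string.
#' @return A one-row complementarity report tibble.
#' @examples
#' self_complementarity("GAATTC")  # palindrome: all 6 positions pair
#' @export
self_complementarity <- function(p, model = thermo_model(),
                                 three_prime_window = 5,
                                 three_prime_weight = 2) {
  complementarity_scan(p, p, model = model,
                       three_prime_window = three_prime_window,
                       three_prime_weight = three_prime_weight)
}

#' 3'-terminal complementarity count
#'
#' Number of matched positions at the best scan offset that fall within the
#' final `window` bases of either primer's 3' end. Matches near the
#' extension-competent terminus are the ones polymerase can act on, so they
#' are counted (and up-weighted) separately.
#'
#' @inheritParams complementarity_scan
#' @param window Terminal window in bases; `0` gives 0 by definition.
#' @return Integer count.
#' @export
three_prime_score <- function(a, b, window = 5, model = thermo_model()) {
  if (window < 1) return(0L)
  complementarity_scan(a, b, model = model,
                       three_prime_window = window)$three_prime_matches
}

#' Weighted complementarity score
#'
#' `W = total_matches + (w3 - 1) * three_prime_matches + 1` when the best
#' run's dG is below `stability_dG` (default -6 kcal/mol), else without the
#' bonus. The weighting only ever adds: a report with zero matches scores 0.
#'
#' @param report A one-row complementarity report tibble.
#' @param three_prime_weight Multiplier `w3` on 3'-window matches (default 2).
#' @param stability_dG dG threshold (kcal/mol) below which the stability
#'   bonus of 1 applies.
#' @return Numeric score, vectorised over report rows.
#' @export
weighted_score <- function(report, three_prime_weight = 2, stability_dG = -6) {
  ifelse(
    report$total_matches == 0L, 0,
    report$total_matches +
      (three_prime_weight - 1) * report$three_prime_matches +
      ifelse(report$run_dG < stability_dG, 1, 0)
  )
}

#' Overhang complementarity of a fusion tail
#'
#' A 5' overlap tail must not anneal to its own primer core, to the partner
#' primer, or to itself. Each pairing is scanned and the worst (highest
#' weighted score) report is returned, annotated with which pairing produced
#' it.
#'
#' @param overlap Non-empty overlap tail sequence (5'->3').
#' @param core Primer core the tail is attached to (may be `NULL`).
#' @param partner The partner primer's full sequence (may be `NULL`).
#' @inheritParams complementarity_scan
#' @return A one-row complementarity report tibble with a `versus` column
#'   (`"core"`, `"partner"` or `"self"`).
#' @export
overhang_score <- function(overlap, core = NULL, partner = NULL,
                           model = thermo_model(), three_prime_window = 5,
                           three_prime_weight = 2) {
  if (!nzchar(overlap)) {
    abort("`overlap` must be non-empty.", class = "stitchkit_contract_error")
  }
  targets <- list(self = overlap)
  if (!is.null(core) && nzchar(core)) targets$core <- core
  if (!is.null(partner) && nzchar(partner)) targets$partner <- partner
  reports <- imap(targets, function(t, nm) {
    r <- complementarity_scan(overlap, t, model = model,
                              three_prime_window = three_prime_window,
                              three_prime_weight = three_prime_weight)
    r$versus <- nm
    r
  })
  out <- bind_rows(reports)
  out[which.max(out$weighted_score), , drop = FALSE]
}
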