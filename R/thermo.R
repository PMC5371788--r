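#' Nearest-neighbor thermodynamic model
#'
#' Loads a nearest-neighbor parameter set from the plain-text tables shipped
#' with the package and combines it with the solution conditions used in
#' melting-temperature calculations. The default set is the unified
#' parameters of SantaLucia (1998); the older Breslauer (1986) table can be
#' selected instead. Tables live under `inst/extdata` as three-column TSVs
#' (`term`, `dH`, `dS`) so they remain auditable and swappable.
#'
#' @param set `"santalucia1998"` (default) or `"breslauer1986"`.
#' @param salt_mM Monovalent cation concentration in mM. The design form
#'   offers 50 (default) or 10; any positive value is accepted here.
#' @param primer_conc_nM Total strand concentration in nM (default 250).
#' @return A `thermo_model` list: `name`, `dH`/`dS` named vectors over the
#'   16 dinucleotide stacks (kcal/mol and cal/(mol*K)), per-terminal
#'   initiation terms, symmetry correction, `salt_mM`, `primer_conc_nM`.
#' @examples
#' m <- thermo_model()
#' m$dH[["CG"]]
#' @export
thermo_model <- function(set = c("santalucia1998", "breslauer1986"),
                         salt_mM = 50, primer_conc_nM = 250) {
  set <- match.arg(set)
  if (!is.numeric(salt_mM) || salt_mM <= 0) {
    abort("`salt_mM` must be a positive concentration in mM.",
          class = "stitchkit_parameter_error")
  }
  if (!is.numeric(primer_conc_nM) || primer_conc_nM <= 0) {
    abort("`primer_conc_nM` must be positive.",
          class = "stitchkit_parameter_error")
  }
  path <- system.file("extdata", paste0("nn_", set, ".tsv"),
                      package = "stitchkit", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stacks <- tab[!tab$term %in% c("init_AT", "init_GC", "sym"), ]
  pick <- function(term, col) tab[tab$term == term, col]
  structure(
    list(
      name = set,
      dH = setNames(stacks$dH, stacks$term),
      dS = setNames(stacks$dS, stacks$term),
      init_dH_AT = pick("init_AT", "dH"), init_dS_AT = pick("init_AT", "dS"),
      init_dH_GC = pick("init_GC", "dH"), init_dS_GC = pick("init_GC", "dS"),
      sym_dS = pick("sym", "dS"),
      salt_mM = salt_mM, primer_conc_nM = primer_conc_nM
    ),
    class = "thermo_model"
  )
}

GAS_CONSTANT <- 1.987  # cal/(mol*K)

stack_terms <- function(seq) {
  n <- nchar(seq)
  if (n < 2) return(character(0))
  substring(seq, 1:(n - 1), 2:n)
}

sum_nn <- function(seq, model) {
  st <- stack_terms(seq)
  list(dH = sum(model$dH[st]), dS = sum(model$dS[st]))
}

init_terms <- function(seq, model) {
  ends <- c(substr(seq, 1, 1), substr(seq, nchar(seq), nchar(seq)))
  dH <- sum(ifelse(ends %in% c("A", "T"), model$init_dH_AT, model$init_dH_GC))
  dS <- sum(ifelse(ends %in% c("A", "T"), model$init_dS_AT, model$init_dS_GC))
  list(dH = dH, dS = dS)
}

#' Nearest-neighbor melting temperature with salt correction
#'
#' Sums stack enthalpies and entropies over the primer, adds per-terminal
#' duplex initiation terms, and evaluates
#' `Tm = 1000 * dH / (dS + R * ln(C_T/4)) - 273.15 + 16.6 * log10([Na+])`
#' with `R = 1.987` cal/(mol*K) and `[Na+]` in mol/L from `model$salt_mM`.
#' Self-complementary primers get the symmetry entropy correction and use
#' `C_T` instead of `C_T/4`.
#'
#' @param seq A DNA string of length >= 8 without `N`. Vectorised.
#' @param model A [thermo_model()].
#' @return Melting temperature(s) in degrees Celsius.
#' @examples
#' melting_temperature("CGCAGAATGGAAGAAGAA")
#' @export
melting_temperature <- function(seq, model = thermo_model()) {
  stopifnot(inherits(model, "thermo_model"))
  vapply(seq, function(s) {
    if (grepl("N", s)) {
      abort("Tm is undefined for sequences containing N.",
            class = "stitchkit_invalid_base")
    }
    if (grepl("[^ACGT]", s)) {
      abort("Tm requires an A/C/G/T sequence.",
            class = "stitchkit_invalid_alphabet")
    }
    if (nchar(s) < 8) {
      abort("Tm calculation requires at least 8 bases.",
            class = "stitchkit_length_error")
    }
    nn <- sum_nn(s, model)
    ini <- init_terms(s, model)
    dH <- nn$dH + ini$dH
    dS <- nn$dS + ini$dS
    ct <- model$primer_conc_nM * 1e-9
    if (s == reverse_complement(s)) {
      dS <- dS + model$sym_dS
      ct_eff <- ct
    } else {
      ct_eff <- ct / 4
    }
    1000 * dH / (dS + GAS_CONSTANT * log(ct_eff)) - 273.15 +
      16.6 * log10(model$salt_mM / 1000)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Gibbs free energy of a complementary duplex run at 37 degrees C
#'
#' The run is given as the top strand (5'->3') of a contiguous fully
#' Watson-Crick-paired stretch; its partner is the reverse complement.
#' `dG = sum(dH_i - T * dS_i / 1000)` over the run's stacks, in kcal/mol at
#' `T = 310.15` K; duplex initiation terms are added only when
#' `include_initiation = TRUE` (they model full-duplex formation, not an
#' internal run inside a longer alignment). More negative means more stable.
#'
#' @param run_seq Top-strand DNA string of the paired run (may be empty).
#' @param model A [thermo_model()].
#' @param include_initiation Add per-terminal initiation terms? Default
#'   `FALSE`.
#' @return dG in kcal/mol (0 for runs shorter than 2 bases unless
#'   initiation is requested).
#' @examples
#' duplex_delta_g("ACGT")
#' @export
duplex_delta_g <- function(run_seq, model = thermo_model(),
                           include_initiation = FALSE) {
  stopifnot(inherits(model, "thermo_model"))
  if (grepl("[^ACGT]", run_seq) && nzchar(run_seq)) {
    abort("duplex_delta_g() requires an A/C/G/T run.",
          class = "stitchkit_contract_error")
  }
  t_k <- 310.15
  dg <- 0
  if (nchar(run_seq) >= 2) {
    nn <- sum_nn(run_seq, model)
    dg <- nn$dH - t_k * nn$dS / 1000
  }
  if (include_initiation && nzchar(run_seq)) {
    ini <- init_terms(run_seq, model)
    dg <- dg + ini$dH - t_k * ini$dS / 1000
  }
  dg
}

#' Best hairpin stem of a primer
#'
#' Scans all ways to fold the sequence back on itself without gaps: a stem
#' pairs positions `i + t` with `j - t` (Watson-Crick) for `t = 0, 1, ...`,
#' and every pair must leave an unpaired loop of at least `min_loop` bases
#' between the arms. The score is the longest such stem; the stem's duplex
#' dG (37 degrees C) is reported alongside.
#'
#' @param seq DNA string over `A/C/G/T/N` (`N` never pairs).
#' @param min_loop Minimum loop length in bases (default 3).
#' @param model A [thermo_model()] for the stem dG.
#' @return A one-row tibble: `stem_len`, `loop_len`, `stem_dG`, `score`
#'   (`score == stem_len`; all zeros when no fold exists).
#' @examples
#' hairpin_score("GGGGAAAACCCC")
#' @export
hairpin_score <- function(seq, min_loop = 3, model = thermo_model()) {
  n <- nchar(seq)
  empty <- tibble(stem_len = 0L, loop_len = NA_integer_, stem_dG = 0, score = 0L)
  if (n < 2 + min_loop) return(empty)
  chars <- strsplit(seq, "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", seq)
  comp_chars <- strsplit(comp, "")[[1]]
  best_len <- 0L; best_i <- NA_integer_; best_j <- NA_integer_
  for (i in 1:(n - 1 - min_loop)) {
    for (j in n:(i + 1 + min_loop)) {
      t <- 0L
      while (i + t < j - t &&
             (j - t) - (i + t) - 1L >= min_loop &&
             chars[i + t] == comp_chars[j - t] &&
             chars[i + t] != "N") {
        t <- t + 1L
      }
      if (t > best_len) {
        best_len <- t; best_i <- i; best_j <- j
      }
    }
  }
  if (best_len == 0L) return(empty)
  stem <- substr(seq, best_i, best_i + best_len - 1L)
  tibble(
    stem_len = best_len,
    loop_len = (best_j - best_len + 1L) - (best_i + best_len - 1L) - 1L,
    stem_dG = duplex_delta_g(stem, model),
    score = best_len
  )
}
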