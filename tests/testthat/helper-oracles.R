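# Independent oracles, coded separately from the package internals.
# These deliberately use their own parameter storage and loop structure so
# agreement with the package is a genuine cross-check, not a tautology.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_primer <- function(len_range = 18:25, gc_range = c(30, 70)) {
  repeat {
    s <- random_dna(sample(len_range, 1))
    gc <- 100 * mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    if (gc >= gc_range[1] && gc <= gc_range[2]) return(s)
  }
}

oracle_complement <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]
}

# --- melting temperature: brute-force dH/dS summation over the same unified
# parameter table and salt convention as the default model ----------------
ORACLE_NN <- data.frame(
  stack = c("AA", "TT", "AT", "TA", "CA", "TG", "GT", "AC", "CT", "AG",
            "GA", "TC", "CG", "GC", "GG", "CC"),
  dH = c(-7.9, -7.9, -7.2, -7.2, -8.5, -8.5, -8.4, -8.4, -7.8, -7.8,
         -8.2, -8.2, -10.6, -9.8, -8.0, -8.0),
  dS = c(-22.2, -22.2, -20.4, -21.3, -22.7, -22.7, -22.4, -22.4, -21.0,
         -21.0, -22.2, -22.2, -27.2, -24.4, -19.9, -19.9)
)

oracle_tm <- function(seq, salt_mM = 50, conc_nM = 250) {
  ch <- strsplit(seq, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(ch) - 1)) {
    row <- ORACLE_NN[ORACLE_NN$stack == paste0(ch[i], ch[i + 1]), ]
    dH <- dH + row$dH
    dS <- dS + row$dS
  }
  for (b in c(ch[1], ch[length(ch)])) {
    if (b %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
    else { dH <- dH + 0.1; dS <- dS - 2.8 }
  }
  rc <- paste(rev(vapply(ch, oracle_complement, "")), collapse = "")
  ct <- conc_nM * 1e-9
  if (identical(seq, rc)) { dS <- dS - 1.4 } else { ct <- ct / 4 }
  1000 * dH / (dS + 1.987 * log(ct)) - 273.15 + 16.6 * log10(salt_mM / 1000)
}

# --- independently coded reference Tm for the concordance harness: same
# published unified family, but with the entropy-based salt adjustment used
# by common design software instead of the Schildkraut shift ---------------
reference_tm <- function(seq, salt_mM = 50, conc_nM = 250) {
  ch <- strsplit(seq, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(ch) - 1)) {
    row <- ORACLE_NN[ORACLE_NN$stack == paste0(ch[i], ch[i + 1]), ]
    dH <- dH + row$dH
    dS <- dS + row$dS
  }
  for (b in c(ch[1], ch[length(ch)])) {
    if (b %in% c("A", "T")) { dH <- dH + 2.3; dS <- dS + 4.1 }
    else { dH <- dH + 0.1; dS <- dS - 2.8 }
  }
  dS <- dS + 0.368 * (length(ch) - 1) * log(salt_mM / 1000)
  1000 * dH / (dS + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

# --- exhaustive ungapped antiparallel scan --------------------------------
oracle_scan <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best_matches <- 0L
  best_run <- 0L
  for (k in (-lb):(la + lb)) {          # generous offset range, duplicates ok
    matches <- 0L; run <- 0L; cur <- 0L
    for (i in seq_len(la)) {
      j <- lb - (i - k) + 1             # antiparallel partner index in b
      if (j >= 1 && j <= lb && av[i] == oracle_complement(bv[j])) {
        matches <- matches + 1L
        cur <- cur + 1L
        run <- max(run, cur)
      } else {
        cur <- 0L
      }
    }
    if (matches > best_matches || (matches == best_matches && run > best_run)) {
      best_matches <- matches
      best_run <- run
    }
  }
  list(total_matches = best_matches, longest_run = best_run)
}

# --- exhaustive hairpin stem search over all substring-pair foldings ------
oracle_hairpin <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- 0L
  for (i in seq_len(n)) {
    for (len in seq_len(n - i + 1)) {
      for (k in seq_len(n - len + 1)) {
        if (k - (i + len - 1) - 1 < min_loop) next  # loop too small
        ok <- TRUE
        for (t in 0:(len - 1)) {
          if (ch[i + t] != oracle_complement(ch[k + len - 1 - t])) {
            ok <- FALSE
            break
          }
        }
        if (ok && len > best) best <- len
      }
    }
  }
  best
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE))
}
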