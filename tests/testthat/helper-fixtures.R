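new_input_sequence_for_test <- function(seq, id = "test") {
  read_fasta(paste0(">", id, "\n", seq))
}

# a deterministic annotated candidate row for pairing tests
fake_candidate <- function(name, strand, start, end, core, tm,
                           pass = TRUE, overlap = "") {
  tibble::tibble(
    name = name, strand = strand, start = as.integer(start),
    end = as.integer(end), core_seq = core, overlap_seq = overlap,
    full_seq = paste0(overlap, core), length = nchar(core),
    gc_percent = 50, tm_celsius = tm, self_matches = 0L,
    self_longest_run = 0L, self_run_dG = 0, self_three_prime = 0L,
    self_weighted = 0, hairpin_stem = 0L, hairpin_dG = 0,
    overhang_weighted = NA_real_, contains_n = FALSE,
    fail_reasons = if (pass) "" else "tm_range", pass = pass
  )
}
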