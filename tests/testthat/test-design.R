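params_quick <- function(...) {
  design_parameters(search_area_5p = 60, search_area_3p = 60,
                    fwd_size = 18, rev_size = 18, ...)
}

wide_open <- function(...) {
  design_parameters(
    gc_min = 0, gc_max = 100, tm_min = -Inf, tm_max = Inf,
    exclude_repeats = FALSE,
    cutoffs = score_cutoffs(self_max = Inf, three_prime_max = Inf,
                            overhang_max = Inf, dimer_max = Inf,
                            hairpin_max = Inf),
    ...
  )
}

test_that("candidate enumeration follows the closed-form count", {
  rec <- generate_fixture(seed = 41, length = 200)
  count_for <- function(area, size, inc, strand = "forward") {
    p <- design_parameters(search_area_5p = area, search_area_3p = area,
                           fwd_size = size, rev_size = size,
                           increment_fwd = inc, increment_rev = inc)
    nrow(enumerate_candidates(rec, p, strand))
  }
  expect_equal(count_for(30, 18, 2), 7L)
  expect_equal(count_for(20, 18, 1), 3L)
  expect_equal(count_for(18, 18, 2), 1L)
  set.seed(42)
  for (i in 1:25) {
    size <- sample(8:25, 1)
    area <- size + sample(0:60, 1)
    inc <- sample(1:5, 1)
    strand <- sample(c("forward", "reverse"), 1)
    expect_equal(count_for(area, size, inc, strand),
                 (area - size) %/% inc + 1L)
  }
  expect_error(count_for(17, 18, 2), class = "stitchkit_parameter_error")
  expect_error(count_for(1000, 18, 2), class = "stitchkit_parameter_error")
})

test_that("candidates re-locate in the input at their coordinates", {
  rec <- generate_fixture(seed = 43, length = 300)
  p <- params_quick()
  fwd <- enumerate_candidates(rec, p, "forward")
  rev <- enumerate_candidates(rec, p, "reverse")
  expect_equal(fwd$core_seq, substring(rec$seq, fwd$start, fwd$end))
  expect_equal(reverse_complement(rev$core_seq),
               substring(rec$seq, rev$start, rev$end))
  expect_equal(fwd$end - fwd$start + 1L, nchar(fwd$core_seq))
  # reverse candidates hug the 3' end within the search area
  expect_true(all(rev$start >= rec$length - p$search_area_3p + 1))
})

test_that("repetitive-sequence detection matches the published definition", {
  expect_true(is_repetitive("ACGCGCGCGT"))   # dinucleotide repeat
  expect_true(is_repetitive("ATTTTA"))       # homopolymer run
  expect_true(is_repetitive("CCCC"))
  expect_true(is_repetitive("TGTGTGTG"))
  expect_false(is_repetitive("ACGTACGA"))
  expect_false(is_repetitive("CGCGCG"))      # only three dinucleotide units
  expect_false(is_repetitive("AAATAAA"))
})

test_that("filters annotate rather than drop, one reason per rule", {
  rec <- new_input_sequence_for_test("ATTTTACCGGAACCGGAAAA")
  p <- design_parameters(search_area_5p = 20, search_area_3p = 20,
                         fwd_size = 10, rev_size = 10, gc_clamp_fwd = TRUE,
                         gc_max = 60)
  cands <- enumerate_candidates(rec, p, "forward")
  expect_equal(nrow(cands), 6L)           # nothing silently dropped
  first <- cands[1, ]                     # ATTTTACCGG: repeat, ends in G
  expect_match(first$fail_reasons, "repetitive")
  expect_false(grepl("gc_clamp", first$fail_reasons))

  # clamp violation: candidate ending in A/T
  clamped <- score_pinned_primer(rec, 11, 20, "forward",
                                 design_parameters(gc_clamp_fwd = TRUE))
  expect_match(clamped$fail_reasons, "gc_clamp")

  # gc_range violation
  gcrec <- new_input_sequence_for_test(strrep("GGCC", 10))
  rich <- score_pinned_primer(gcrec, 1, 12, "forward",
                              design_parameters(gc_max = 60))
  expect_match(rich$fail_reasons, "gc_range")

  expect_equal(sum(cands$pass == (cands$fail_reasons == "")), nrow(cands))
})

test_that("with every filter disabled all candidates pass", {
  rec <- generate_fixture(seed = 44, length = 400)
  p <- wide_open()
  for (strand in c("forward", "reverse")) {
    cands <- enumerate_candidates(rec, p, strand)
    expect_true(all(cands$pass))
    expect_true(all(cands$fail_reasons == ""))
  }
})

test_that("candidates spanning N are annotated, not rejected", {
  seq <- paste0(strrep("ACGGT", 6), "N", strrep("TGCCA", 6))
  rec <- new_input_sequence_for_test(seq)
  p <- design_parameters(search_area_5p = nchar(seq), search_area_3p = nchar(seq),
                         fwd_size = 40, rev_size = 40)
  cands <- enumerate_candidates(rec, p, "forward")
  spanning <- cands[grepl("N", cands$core_seq), ]
  expect_gt(nrow(spanning), 0L)
  expect_true(all(grepl("contains_n", spanning$fail_reasons)))
  expect_true(all(is.na(spanning$tm_celsius)))
})

test_that("mutant mode returns the rc oligo and one flanking pair", {
  expect_equal(design_mutant_pair(generate_fixture(seed = 45, length = 300),
                                  "GATTACA", wide_open())$mutant_rev,
               "TGTAATC")
  rec <- generate_fixture(seed = 46, length = 500)
  res <- design_mutant_pair(rec, "ACGTACGT", wide_open())
  expect_equal(res$mutant_rev, reverse_complement("ACGTACGT"))
  expect_equal(nrow(res$fwd), 1L)
  expect_equal(nrow(res$rev), 1L)
  expect_true(res$fwd$pass && res$rev$pass)
  # palindromic oligo is its own reverse
  expect_equal(design_mutant_pair(rec, "GAATTC", wide_open())$mutant_rev,
               "GAATTC")
  expect_error(design_mutant_pair(rec, ""), class = "stitchkit_parameter_error")
  # impossible constraints surface the best near-miss
  strict <- design_parameters(gc_min = 99, gc_max = 100)
  expect_error(design_mutant_pair(rec, "GATTACA", strict),
               class = "stitchkit_design_failure")
})
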