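test_that("summaries are min/avg/max over passing candidates only", {
  one <- fake_candidate("1F", "forward", 1, 18, "GTGGTCGTGGGTTTGATG", 50)
  s <- summarize_candidates(one)
  expect_true(all(s$minimum == s$average & s$average == s$maximum))

  expect_equal(nrow(summarize_candidates(empty <- one[0, ])), 0L)

  two <- dplyr::bind_rows(
    fake_candidate("1F", "forward", 1, 18, "GTGGTCGTGGGTTTGATG", 55),
    fake_candidate("2F", "forward", 3, 20, "GGTCGTGGGTTTGATGGA", 59)
  )
  s2 <- summarize_candidates(two)
  expect_equal(s2$average[s2$metric == "tm"], 57)
  expect_true(all(s2$minimum <= s2$average & s2$average <= s2$maximum))

  # failing candidates are excluded from the summary
  mixed <- dplyr::bind_rows(two,
    fake_candidate("3F", "forward", 5, 22, "TCGTGGGTTTGATGGAAC", 80,
                   pass = FALSE))
  expect_equal(summarize_candidates(mixed), s2)
})

test_that("pinned primers are scored in place and never auto-rejected", {
  rec <- new_input_sequence_for_test(strrep("ACGGTTGCAC", 6))
  p <- design_parameters()
  pin <- score_pinned_primer(rec, 1, 18, "forward", p)
  expect_equal(pin$core_seq, substr(rec$seq, 1, 18))
  expect_equal(nrow(pin), 1L)

  rpin <- score_pinned_primer(rec, 1, 18, "reverse", p)
  expect_equal(rpin$core_seq, reverse_complement(substr(rec$seq, 1, 18)))

  expect_error(score_pinned_primer(rec, 50, 70, "forward", p),
               class = "stitchkit_parameter_error")
  expect_error(score_pinned_primer(rec, 0, 10, "forward", p),
               class = "stitchkit_parameter_error")
})

test_that("fixture generation is seeded, GC-targeted and repeat-aware", {
  a <- generate_fixture(seed = 1, length = 200)
  b <- generate_fixture(seed = 1, length = 200)
  expect_identical(a$seq, b$seq)
  expect_false(identical(generate_fixture(seed = 2, length = 200)$seq, a$seq))

  big <- generate_fixture(seed = 3, length = 10000, gc_fraction = 0.5)
  gc <- composition_profile(big, 10000, 10000)$gc_percent_global
  expect_gt(gc, 48); expect_lt(gc, 52)

  withrep <- generate_fixture(seed = 4, length = 100, repeat_insert = "TTTT")
  at <- attr(withrep, "repeat_at")
  expect_true(is_repetitive(substr(withrep$seq, at, at + 3)))

  withn <- generate_fixture(seed = 5, length = 100, n_count = 4)
  expect_equal(unname(composition_profile(withn, 100, 100)$counts[["N"]]), 4L)
})

test_that("run_design writes the default tables and optional artifacts", {
  rec <- generate_fixture(seed = 61, length = 400)
  out1 <- withr::local_tempdir()
  res <- run_design(rec, design_parameters(search_area_5p = 80,
                                           search_area_3p = 80),
                    out_dir = out1)
  tsvs <- c("forward_primers.tsv", "reverse_primers.tsv", "pairs.tsv")
  expect_true(all(file.exists(file.path(out1, tsvs))))
  expect_false(file.exists(file.path(out1, "design_bundle.json")))
  expect_true(file.exists(file.path(out1, "design_log.txt")))
  log <- readLines(file.path(out1, "design_log.txt"))
  expect_true(any(grepl("salt_mM = 50", log)))

  out2 <- withr::local_tempdir()
  res2 <- run_design(rec, design_parameters(search_area_5p = 80,
                                            search_area_3p = 80),
                     out_dir = out2, outputs = "all")
  for (f in c(tsvs, "composition.tsv", "summary.tsv", "primer_map.tsv",
              "primer_map.bed", "design_bundle.json")) {
    expect_true(file.exists(file.path(out2, f)), info = f)
  }

  # the BED track is 0-based half-open while the map stays 1-based inclusive
  map <- read.delim(file.path(out2, "primer_map.tsv"))
  bed <- read.delim(file.path(out2, "primer_map.bed"), header = FALSE)
  expect_equal(bed$V2, map$start - 1L)
  expect_equal(bed$V3, map$end)
  expect_equal(nrow(map), nrow(res2$design$forward) + nrow(res2$design$reverse))

  expect_error(run_design(tempfile(fileext = ".fa"), design_parameters(),
                          out_dir = withr::local_tempdir()),
               class = "stitchkit_malformed_input")
})

test_that("the JSON bundle round-trips the TSV tables exactly", {
  rec <- generate_fixture(seed = 62, length = 300)
  out <- withr::local_tempdir()
  run_design(rec, design_parameters(search_area_5p = 60, search_area_3p = 60),
             out_dir = out, outputs = "all")
  bundle <- jsonlite::read_json(file.path(out, "design_bundle.json"),
                                simplifyVector = TRUE)
  for (pair in list(c("forward_primers", "forward_primers.tsv"),
                    c("reverse_primers", "reverse_primers.tsv"),
                    c("pairs", "pairs.tsv"))) {
    tsv <- read.delim(file.path(out, pair[2]), na.strings = "NA")
    js <- as.data.frame(bundle[[pair[1]]])
    expect_equal(nrow(js), nrow(tsv))
    for (col in intersect(names(tsv), names(js))) {
      if (is.numeric(tsv[[col]])) {
        expect_equal(as.numeric(js[[col]]), as.numeric(tsv[[col]]),
                     tolerance = 1e-12, info = paste(pair[1], col))
      }
    }
  }
})

test_that("a design with zero passing primers warns but still writes tables", {
  rec <- generate_fixture(seed = 63, length = 200)
  p <- design_parameters(search_area_5p = 60, search_area_3p = 60,
                         gc_min = 99, gc_max = 100)
  out <- withr::local_tempdir()
  expect_warning(run_design(rec, p, out_dir = out), "No primer passed")
  fwd <- read.delim(file.path(out, "forward_primers.tsv"))
  expect_true("name" %in% names(fwd))
  expect_false(any(fwd$pass))
})

test_that("tidy, glance and the plot builders work on a design object", {
  rec <- generate_fixture(seed = 64, length = 400)
  des <- design_primers(rec, design_parameters(search_area_5p = 80,
                                               search_area_3p = 80))
  td <- tidy(des)
  expect_equal(nrow(td), nrow(des$forward) + nrow(des$reverse))
  g <- glance(des)
  expect_equal(g$n_forward, nrow(des$forward))
  expect_equal(g$n_pairs_compatible, sum(des$pairs$compatible))
  expect_s3_class(ggplot2::autoplot(des), "ggplot")
  expect_s3_class(ggplot2::autoplot(des$composition), "ggplot")
  expect_s3_class(plot_design_summary(des), "ggplot")
})
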