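#' Run a full primer design
#'
#' The in-memory engine behind [run_design()]: reads and cleans the input,
#' attaches any overlap tail, enumerates and filters candidates on both
#' strands, enumerates compatible pairs, and computes the composition
#' profile, per-strand summary statistics, and the primer map.
#'
#' @param x FASTA path, FASTA text, or an `input_sequence`.
#' @param params A [design_parameters()].
#' @param window,step Composition-profile window and step (defaults 50 and 1).
#' @return A `stitch_design` object: list with `sequence`, `params`,
#'   `forward`, `reverse`, `pairs`, `composition`, `summary`, `map`, and
#'   (in mutant mode) `mutant`.
#' @examples
#' rec <- generate_fixture(seed = 7, length = 400)
#' des <- design_primers(rec, design_parameters(search_area_5p = 100,
#'                                              search_area_3p = 100))
#' head(tidy(des))
#' @export
design_primers <- function(x, params = design_parameters(),
                           window = 50, step = 1) {
  rec <- if (inherits(x, "input_sequence")) x else read_fasta(x)
  rec <- clean_sequence(rec, remove_n = params$remove_n)
  model <- params_model(params)

  ov_fwd <- ""; ov_rev <- ""; mutant <- NULL
  if (params$overlap_selection == "named") {
    ov <- get_overlap(params$overlap_name)$seq
  } else if (params$overlap_selection == "user_defined") {
    if (is.null(params$overlap_seq) || !nzchar(params$overlap_seq)) {
      abort("`overlap_seq` required for a user-defined overlap.",
            class = "stitchkit_parameter_error")
    }
    ov <- toupper(params$overlap_seq)
  } else {
    ov <- ""
  }
  if (nzchar(ov)) {
    if (params$overlap_on %in% c("forward", "both")) ov_fwd <- ov
    if (params$overlap_on %in% c("reverse", "both")) ov_rev <- ov
  }

  if (params$overlap_selection == "mutant") {
    mutant <- design_mutant_pair(rec, params$mutant_seq, params)
    fwd <- mutant$fwd
    rev <- mutant$rev
  } else {
    fwd <- if (params$design_forward) {
      enumerate_candidates(rec, params, "forward", overlap_seq = ov_fwd)
    } else empty_candidates()
    rev <- if (params$design_reverse) {
      enumerate_candidates(rec, params, "reverse", overlap_seq = ov_rev)
    } else empty_candidates()
  }

  pairs <- compatible_pairs(
    fwd, rev, max_tm_diff = params$max_tm_diff, cutoffs = params$cutoffs,
    model = model, three_prime_window = params$three_prime_window,
    three_prime_weight = params$three_prime_weight
  )
  structure(
    list(
      sequence = rec, params = params, forward = fwd, reverse = rev,
      pairs = pairs,
      composition = composition_profile(rec, window = min(window, rec$length),
                                        step = step),
      summary = summarize_candidates(bind_rows(fwd, rev)),
      map = primer_map(bind_rows(fwd, rev)),
      mutant = mutant
    ),
    class = "stitch_design"
  )
}

empty_candidates <- function() {
  tibble(
    name = character(), strand = character(), start = integer(),
    end = integer(), core_seq = character(), overlap_seq = character(),
    full_seq = character(), length = integer(), gc_percent = numeric(),
    tm_celsius = numeric(), self_matches = integer(),
    self_longest_run = integer(), self_run_dG = numeric(),
    self_three_prime = integer(), self_weighted = numeric(),
    hairpin_stem = integer(), hairpin_dG = numeric(),
    overhang_weighted = numeric(), contains_n = logical(),
    fail_reasons = character(), pass = logical()
  )
}

#' @export
print.stitch_design <- function(x, ...) {
  cat("<stitch_design> ", x$sequence$id, " (", x$sequence$length, " bp)\n",
      sep = "")
  cat("  forward candidates: ", nrow(x$forward), " (",
      sum(x$forward$pass), " passing)\n", sep = "")
  cat("  reverse candidates: ", nrow(x$reverse), " (",
      sum(x$reverse$pass), " passing)\n", sep = "")
  cat("  compatible pairs:   ", sum(x$pairs$compatible), " of ",
      nrow(x$pairs), " combinations\n", sep = "")
  invisible(x)
}

#' Summary statistics of passing candidates
#'
#' Average, minimum and maximum per strand for primer GC%, Tm, weighted
#' self-complementarity, start position, core length and hairpin stem,
#' computed over passing candidates only. An empty passing set yields an
#' explicitly empty (zero-row) summary, never zeros.
#'
#' @param cands Annotated candidate tibble (both strands may be mixed).
#' @return A tibble: `strand`, `metric`, `minimum`, `average`, `maximum`.
#' @export
summarize_candidates <- function(cands) {
  ok <- cands[cands$pass, , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(tibble(strand = character(), metric = character(),
                  minimum = numeric(), average = numeric(),
                  maximum = numeric()))
  }
  metrics <- c(gc_percent = "gc_percent", tm = "tm_celsius",
               weighted_self = "self_weighted", start = "start",
               length = "length", hairpin = "hairpin_stem")
  ok |>
    select("strand", dplyr::all_of(unname(metrics))) |>
    stats::setNames(c("strand", names(metrics))) |>
    tidyr::pivot_longer(-"strand", names_to = "metric", values_to = "value") |>
    group_by(.data$strand, .data$metric) |>
    summarise(minimum = min(.data$value, na.rm = TRUE),
              average = mean(.data$value, na.rm = TRUE),
              maximum = max(.data$value, na.rm = TRUE),
              .groups = "drop")
}

#' Primer map entries
#'
#' One row per designed primer with its footprint on the input's forward
#' strand, sorted by start coordinate (1-based inclusive).
#'
#' @param cands Annotated candidate tibble.
#' @param category Map category for all rows; defaults to each candidate's
#'   strand.
#' @return A tibble: `name`, `start`, `end`, `strand`, `category`, `pass`.
#' @export
primer_map <- function(cands, category = NULL) {
  if (nrow(cands) == 0L) {
    return(tibble(name = character(), start = integer(), end = integer(),
                  strand = character(), category = character(),
                  pass = logical()))
  }
  tibble(
    name = cands$name, start = cands$start, end = cands$end,
    strand = cands$strand,
    category = category %||% cands$strand,
    pass = cands$pass
  ) |> arrange(.data$start)
}

#' Score a user-pinned primer
#'
#' Replaces an interactive "draw a primer here" facility: the user names a
#' window on the input (useful for exon/intron boundaries) and gets the full
#' metric annotation for it. The candidate is never auto-rejected — its
#' `fail_reasons` are informational.
#'
#' @param rec An `input_sequence`.
#' @param start,end 1-based inclusive coordinates on the forward strand.
#' @param strand `"forward"` or `"reverse"`.
#' @param params A [design_parameters()].
#' @param name Row name for the report (default `"pinned"`).
#' @return A one-row annotated candidate tibble.
#' @export
score_pinned_primer <- function(rec, start, end,
                                strand = c("forward", "reverse"),
                                params = design_parameters(),
                                name = "pinned") {
  strand <- match.arg(strand)
  stopifnot(inherits(rec, "input_sequence"))
  if (start < 1 || end > rec$length || start > end) {
    abort("Pinned coordinates must satisfy 1 <= start <= end <= length.",
          class = "stitchkit_parameter_error")
  }
  slice <- substr(rec$seq, start, end)
  core <- if (strand == "forward") slice else reverse_complement(slice)
  cand <- tibble(name = name, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 core_seq = core, overlap_seq = "", full_seq = core)
  passes_filters(annotate_candidates(cand, params), params)
}

#' Generate a reproducible synthetic input sequence
#'
#' Draws an i.i.d. sequence with the requested GC fraction, optionally
#' plants `N`s at random positions and a repeat motif at a known position.
#' The same seed always yields the same record.
#'
#' @param seed Integer seed.
#' @param length Sequence length in bases (>= 50).
#' @param gc_fraction Expected GC fraction (default 0.5).
#' @param n_count Number of `N`s to plant (default 0).
#' @param repeat_insert Optional motif (e.g. `"TTTT"`) overwritten into the
#'   sequence; its 1-based start is recorded in the `repeat_at` attribute.
#' @param id Record id.
#' @return An `input_sequence` (with attribute `repeat_at` when a repeat was
#'   planted).
#' @examples
#' generate_fixture(seed = 1, length = 60)
#' @export
generate_fixture <- function(seed, length = 1000, gc_fraction = 0.5,
                             n_count = 0, repeat_insert = NULL,
                             id = "synthetic_fixture") {
  stopifnot(length >= 50)
  withr::with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    chars <- sample(names(p), length, replace = TRUE, prob = p)
    repeat_at <- NA_integer_
    if (!is.null(repeat_insert) && nzchar(repeat_insert)) {
      k <- nchar(repeat_insert)
      repeat_at <- sample.int(length - k + 1L, 1L)
      chars[repeat_at:(repeat_at + k - 1L)] <- strsplit(repeat_insert, "")[[1]]
    }
    if (n_count > 0) {
      chars[sample.int(length, n_count)] <- "N"
    }
    rec <- new_input_sequence(id = id, seq = paste(chars, collapse = ""))
    attr(rec, "repeat_at") <- repeat_at
    rec
  })
}

#' Write all selected outputs of a design run
#'
#' Runs [design_primers()] and writes the result files into `out_dir`.
#' Forward-primer, reverse-primer and pair tables are always written;
#' composition, summary, primer map (TSV and BED) and the JSON bundle are
#' added on request. A log file records every parameter value used. TSVs
#' are UTF-8, tab-separated, `.` decimal, with a header row. With zero
#' passing primers the tables are written empty-but-headered with a warning.
#'
#' @param x FASTA path, FASTA text, or `input_sequence`.
#' @param params A [design_parameters()].
#' @param out_dir Output directory (created if needed).
#' @param outputs Character vector from `c("tables", "pairs", "composition",
#'   "summary", "map", "json")`, or `"all"`. Tables and pairs are always
#'   produced.
#' @param window,step Composition window/step, see [design_primers()].
#' @return Invisibly, a list with the `stitch_design` object and the file
#'   `manifest` (named character vector of written paths).
#' @export
run_design <- function(x, params = design_parameters(), out_dir = ".",
                       outputs = c("tables", "pairs"), window = 50, step = 1) {
  if ("all" %in% outputs) {
    outputs <- c("tables", "pairs", "composition", "summary", "map", "json")
  }
  outputs <- union(outputs, c("tables", "pairs"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  des <- design_primers(x, params, window = window, step = step)
  if (sum(des$forward$pass) + sum(des$reverse$pass) == 0L) {
    warn("No primer passed all filters; tables contain only headers/near-misses.")
  }
  manifest <- character()
  wtsv <- function(df, file) {
    path <- file.path(out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    manifest[[file]] <<- path
  }
  wtsv(candidate_table(des$forward), "forward_primers.tsv")
  wtsv(candidate_table(des$reverse), "reverse_primers.tsv")
  wtsv(des$pairs, "pairs.tsv")
  if ("composition" %in% outputs) {
    wtsv(des$composition$windows, "composition.tsv")
  }
  if ("summary" %in% outputs) wtsv(des$summary, "summary.tsv")
  if ("map" %in% outputs) {
    wtsv(des$map, "primer_map.tsv")
    bed <- data.frame(
      chrom = des$sequence$id,
      start = des$map$start - 1L,      # BED is 0-based half-open
      end = des$map$end,
      name = des$map$name,
      score = 0L,
      strand = ifelse(des$map$strand == "forward", "+", "-")
    )
    path <- file.path(out_dir, "primer_map.bed")
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, fileEncoding = "UTF-8")
    manifest[["primer_map.bed"]] <- path
  }
  if ("json" %in% outputs) {
    path <- file.path(out_dir, "design_bundle.json")
    jsonlite::write_json(
      list(
        sequence = list(id = des$sequence$id, length = des$sequence$length,
                        removed_n_positions = des$sequence$removed_n_positions),
        parameters = params_as_list(params),
        forward_primers = candidate_table(des$forward),
        reverse_primers = candidate_table(des$reverse),
        pairs = des$pairs,
        composition = des$composition$windows,
        summary = des$summary,
        map = des$map
      ),
      path, auto_unbox = TRUE, digits = NA, null = "null"
    )
    manifest[["design_bundle.json"]] <- path
  }
  log_path <- file.path(out_dir, "design_log.txt")
  writeLines(c(
    paste0("stitchkit design run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("input: ", des$sequence$id, " (", des$sequence$length, " bp)"),
    paste0(names(unlist(params_as_list(params))), " = ",
           unlist(params_as_list(params)))
  ), log_path)
  manifest[["design_log.txt"]] <- log_path
  invisible(list(design = des, manifest = manifest))
}

candidate_table <- function(cands) {
  cols <- c("name", "start", "end", "strand", "core_seq", "full_seq",
            "length", "gc_percent", "tm_celsius", "self_matches",
            "self_longest_run", "self_run_dG", "self_three_prime",
            "self_weighted", "hairpin_stem", "hairpin_dG",
            "overhang_weighted", "pass", "fail_reasons")
  cands[, cols, drop = FALSE]
}

params_as_list <- function(params) {
  p <- unclass(params)
  p$cutoffs <- unclass(p$cutoffs)
  p[!vapply(p, is.null, logical(1))]
}
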