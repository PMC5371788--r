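#' Read a single-sequence FASTA input
#'
#' Reads exactly one DNA record, either from a FASTA file on disk or from
#' FASTA-formatted text passed directly. The sequence is uppercased, line
#' breaks and blank lines are ignored, and the description after the first
#' whitespace of the header is kept as metadata. Only the IUPAC subset
#' `A/C/G/T/N` is accepted; alignment gaps (`-`) and other codes are
#' rejected.
#'
#' @param x Path to a FASTA file, or a character string of FASTA text
#'   (anything containing a newline or starting with `>` is treated as text).
#' @return An `input_sequence` object: a list with fields `id`, `desc`,
#'   `seq`, `length` and `removed_n_positions` (empty until
#'   [clean_sequence()] runs with `remove_n = TRUE`).
#' @examples
#' rec <- read_fasta(">myo3 promoter fragment\nACGTACGTAA")
#' rec$id
#' rec$length
#' @export
read_fasta <- function(x) {
  if (length(x) != 1L || !is.character(x) || !nzchar(x)) {
    abort("`x` must be a single non-empty FASTA path or FASTA text.",
          class = "stitchkit_malformed_input")
  }
  is_text <- grepl("\n", x) || startsWith(x, ">")
  path <- x
  if (is_text) {
    if (!startsWith(trimws(x), ">")) {
      abort("FASTA text must begin with a '>' header line.",
            class = "stitchkit_malformed_input")
    }
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(x, path)
  } else if (!file.exists(x)) {
    abort(paste0("FASTA file not found: ", x),
          class = "stitchkit_malformed_input")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Could not parse FASTA input: ", conditionMessage(e)),
            class = "stitchkit_malformed_input")
    }
  )
  if (length(set) == 0L) {
    abort("FASTA input contains no record.",
          class = "stitchkit_malformed_input")
  }
  if (length(set) > 1L) {
    abort(paste0("Input must contain exactly one sequence; found ",
                 length(set), " records."),
          class = "stitchkit_single_sequence_contract")
  }
  header <- names(set)[[1]]
  id <- sub("\\s.*$", "", header)
  desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
  seq <- toupper(gsub("[[:space:]]", "", as.character(set[[1]])))
  bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
  if (length(bad) > 0L) {
    abort(paste0("Sequence contains characters outside A/C/G/T/N: ",
                 paste(bad, collapse = ", ")),
          class = "stitchkit_invalid_alphabet")
  }
  new_input_sequence(id = id, desc = desc, seq = seq)
}

new_input_sequence <- function(id, seq, desc = "", removed_n_positions = integer()) {
  structure(
    list(id = id, desc = desc, seq = seq, length = nchar(seq),
         removed_n_positions = as.integer(removed_n_positions)),
    class = "input_sequence"
  )
}

#' @export
print.input_sequence <- function(x, ...) {
  cat("<input_sequence> ", x$id, " (", x$length, " bp)\n", sep = "")
  shown <- if (x$length > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat("  ", shown, "\n", sep = "")
  n_left <- length(gregexpr("N", x$seq, fixed = TRUE)[[1]])
  if (length(x$removed_n_positions) > 0) {
    cat("  N's removed at original positions: ",
        paste(x$removed_n_positions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Remove or report undesignated bases (N) in the input
#'
#' With `remove_n = TRUE` every `N` is excised from the sequence and its
#' original 1-based position recorded in `removed_n_positions`. With
#' `remove_n = FALSE` the record is returned unchanged, and positions of any
#' `N`s are attached as the `n_positions` attribute so reports can flag
#' candidates that span them.
#'
#' @param rec An `input_sequence` from [read_fasta()].
#' @param remove_n Excise N's? Default `FALSE`.
#' @return An `input_sequence`.
#' @examples
#' rec <- read_fasta(">s\nACNNGT")
#' clean_sequence(rec, remove_n = TRUE)$seq
#' @export
clean_sequence <- function(rec, remove_n = FALSE) {
  stopifnot(inherits(rec, "input_sequence"))
  pos <- which(strsplit(rec$seq, "")[[1]] == "N")
  if (!remove_n) {
    attr(rec, "n_positions") <- as.integer(pos)
    return(rec)
  }
  if (length(pos) == 0L) return(rec)
  out <- new_input_sequence(
    id = rec$id, desc = rec$desc,
    seq = gsub("N", "", rec$seq, fixed = TRUE),
    removed_n_positions = sort(unique(c(rec$removed_n_positions, pos)))
  )
  out
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised over `x`.
#'
#' @param x Character vector of DNA strings over `A/C/G/T/N`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AGTCGACCTGCAGGCATGCAAGCT")
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  if (any(grepl("[^ACGTN]", x))) {
    abort("reverse_complement() accepts only A/C/G/T/N.",
          class = "stitchkit_invalid_alphabet")
  }
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Base composition and sliding-window GC%/AT% profile
#'
#' Counts each base over the whole record and computes GC and AT percentages
#' in sliding windows. Windows start at every `step` bases from position 1;
#' the final windows that run off the 3' end are truncated and flagged
#' `partial`. Percentages use the (possibly truncated) window length as the
#' denominator, so a window containing `N` has `gc_percent + at_percent`
#' below 100.
#'
#' @param rec An `input_sequence`.
#' @param window Window width in bases (default 50).
#' @param step Step between window starts in bases (default 1).
#' @return A `composition_profile`: list with `counts` (named vector for
#'   A, C, G, T, N), `gc_percent_global`, `windows` (tibble with `start`,
#'   `end`, `gc_percent`, `at_percent`, `partial`), `window_size`, `step`.
#' @examples
#' rec <- read_fasta(">s\nGATCGATCGGCC")
#' composition_profile(rec, window = 4, step = 4)$windows
#' @export
composition_profile <- function(rec, window = 50, step = 1) {
  stopifnot(inherits(rec, "input_sequence"))
  n <- rec$length
  if (window < 1 || window > n) {
    abort("`window` must lie in [1, sequence length].",
          class = "stitchkit_parameter_error")
  }
  if (step < 1) abort("`step` must be >= 1.", class = "stitchkit_parameter_error")
  chars <- strsplit(rec$seq, "")[[1]]
  counts <- vapply(c("A", "C", "G", "T", "N"),
                   function(b) sum(chars == b), integer(1))
  gc_global <- 100 * (counts[["G"]] + counts[["C"]]) / n
  is_gc <- chars %in% c("G", "C")
  is_at <- chars %in% c("A", "T")
  cum_gc <- c(0L, cumsum(is_gc))
  cum_at <- c(0L, cumsum(is_at))
  starts <- seq.int(1L, n, by = step)
  ends <- pmin(starts + window - 1L, n)
  len <- ends - starts + 1L
  windows <- tibble(
    start = starts, end = ends,
    gc_percent = 100 * (cum_gc[ends + 1L] - cum_gc[starts]) / len,
    at_percent = 100 * (cum_at[ends + 1L] - cum_at[starts]) / len,
    partial = len < window
  )
  structure(
    list(counts = counts, gc_percent_global = gc_global, windows = windows,
         window_size = as.integer(window), step = as.integer(step),
         sequence_id = rec$id, sequence_length = n),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> ", x$sequence_id, " (", x$sequence_length,
      " bp), window ", x$window_size, " step ", x$step, "\n", sep = "")
  cat("  global GC%: ", round(x$gc_percent_global, 2), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname tidy
#' @param x A `composition_profile`.
#' @param ... Unused.
#' @export
tidy.composition_profile <- function(x, ...) x$windows

gc_percent_of <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}
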