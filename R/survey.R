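#' Built-in cox1 primer registry
#'
#' The six primers used in the published PCR/gel-sizing survey of the cox1
#' intron, exactly as printed (5'->3'; degenerate IUPAC codes allowed).
#' cox1-3/cox1-6 flank the canonical insertion site and yield products of
#' 800 bp (intron absent) or ~1.8 kb (intron present); cox1-1/cox1-4 are the
#' alternative flanking pair (750 bp / 1735 bp as published — note those two
#' printed sizes differ by 985 bp, not by the 967-bp intron length, a
#' rounding/geometry ambiguity in the source sizes that this package reports
#' but does not resolve); cox1-8 and cox1-10 are internal sequencing primers.
#'
#' @return A tibble with columns `name`, `sequence`, `role`.
#' @export
primer_registry <- function() {
  tibble(
    name = c("cox1-1", "cox1-3", "cox1-4", "cox1-6", "cox1-8", "cox1-10"),
    sequence = c(
      "AYGAMAAATCYGGTYGATGG",
      "CATCTCTTTYTGTTCTTCGGT",
      "ACCGRATCCAGGCAGAATGRG",
      "AGCTGGAAGTTCTCCAAAAGT",
      "GTAGAGTCTTATAAGGTAGT",
      "TGACTACTATCAAAGTAGA"
    ),
    role = c("forward", "forward", "reverse", "reverse",
             "sequencing", "sequencing")
  )
}

#' Construct a primer pair
#'
#' Both primers are given 5'->3' as synthesized; the reverse primer anneals
#' to the coding strand as its reverse complement (standard PCR convention).
#' Registry names from [primer_registry()] or raw IUPAC sequences are
#' accepted.
#'
#' @param forward,reverse Primer names or sequences.
#' @param name Optional pair label.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward = "cox1-3", reverse = "cox1-6", name = NULL) {
  reg <- primer_registry()
  resolve <- function(x) {
    if (x %in% reg$name) return(reg$sequence[match(x, reg$name)])
    x <- normalize_seq(x)
    if (!nzchar(x) || grepl("[^ACGTRYSWKMBDHVN]", x)) {
      abort("Primer must be a registry name or an IUPAC nucleotide string.",
            class = "cctrace_input_error")
    }
    x
  }
  structure(
    list(forward = resolve(forward), reverse = resolve(reverse),
         name = name %||% paste(forward, reverse, sep = "/")),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F: %s\n  R: %s\n",
              x$name, x$forward, x$reverse))
  invisible(x)
}

#' In-silico PCR on an ungapped template
#'
#' Matches the forward primer on the template and the reverse primer as its
#' reverse complement downstream, with IUPAC degeneracy (`Y` matches `C`/`T`,
#' `R` matches `A`/`G`, ...). Amplicon length is counted *inclusive of both
#' primer footprints* — the convention required for the published 800-bp
#' intron-less product to be self-consistent with the primer positions.
#' All placements up to `max_product` are reported.
#'
#' @param template Ungapped nucleotide string.
#' @param pair A [primer_pair()].
#' @param max_mismatches Mismatch budget per primer (default 0).
#' @param max_product Largest product size reported (default 5000 bp).
#' @return A tibble with columns `start`, `end`, `length` (empty when no
#'   amplicon forms).
#' @export
insilico_pcr <- function(template, pair = primer_pair(), max_mismatches = 0,
                         max_product = 5000) {
  template <- normalize_seq(template)
  if (grepl("-", template, fixed = TRUE)) {
    abort("Template must be ungapped.", class = "cctrace_input_error")
  }
  subj <- Biostrings::DNAString(template)
  fwd_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pair$forward), subj,
    max.mismatch = max_mismatches, fixed = FALSE
  )
  rev_hits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(pair$reverse)), subj,
    max.mismatch = max_mismatches, fixed = FALSE
  )
  out <- tidyr::expand_grid(
    start = Biostrings::start(fwd_hits),
    rev_start = Biostrings::start(rev_hits)
  )
  fwd_width <- nchar(pair$forward)
  rev_width <- nchar(pair$reverse)
  out <- out |>
    mutate(end = .data$rev_start + rev_width - 1L,
           length = .data$end - .data$start + 1L) |>
    dplyr::filter(.data$rev_start > .data$start + fwd_width - 1L,
                  .data$length <= max_product) |>
    select("start", "end", "length") |>
    arrange(.data$length)
  out
}

#' Classify intron presence from an amplicon size
#'
#' Mirrors the published gel-sizing logic: a product within `tolerance` of
#' the expected intron-less size is `absent`; a product at least
#' `threshold_delta` larger is `present`; anything between is `ambiguous`;
#' no product is `no_amplicon`.
#'
#' @param amplicon_length Numeric vector of product sizes (`NA` = none).
#' @param expected_intronless_length Expected intron-less product (bp).
#' @param threshold_delta Size excess (bp) above which the product is called
#'   intron-containing (default 500).
#' @param tolerance Gel-sizing tolerance around the intron-less size
#'   (default 100 bp).
#' @return Character vector in
#'   `{present, absent, no_amplicon, ambiguous}`.
#' @export
classify_presence <- function(amplicon_length, expected_intronless_length,
                              threshold_delta = 500, tolerance = 100) {
  stopifnot(expected_intronless_length > 0)
  dplyr::case_when(
    is.na(amplicon_length) ~ "no_amplicon",
    abs(amplicon_length - expected_intronless_length) <= tolerance ~ "absent",
    amplicon_length >= expected_intronless_length + threshold_delta ~ "present",
    TRUE ~ "ambiguous"
  )
}

#' Extract the inserted intron from a genomic sequence
#'
#' Given an intron-less exon reference and the ungapped position of the exon
#' base immediately 5' of the canonical insertion site, the inserted segment
#' is the extra sequence between the two exon flanks. Flanks must match the
#' reference within `max_mismatches` each.
#'
#' @param sequence Ungapped sequence possibly carrying an insertion.
#' @param exon_reference Ungapped intron-less reference.
#' @param insertion_point Number of reference bases 5' of the insertion site.
#' @param max_mismatches Per-flank mismatch budget (default 0).
#' @return A list with elements `intron` (string, possibly empty) and
#'   `length` (bp).
#' @export
extract_intron <- function(sequence, exon_reference, insertion_point,
                           max_mismatches = 0) {
  sequence <- normalize_seq(sequence)
  exon_reference <- normalize_seq(exon_reference)
  len <- nchar(sequence) - nchar(exon_reference)
  if (len < 0) {
    abort("Sequence is shorter than the exon reference.",
          class = "cctrace_extraction_error")
  }
  ip <- as.integer(insertion_point)
  stopifnot(ip >= 0, ip <= nchar(exon_reference))
  mism <- function(a, b) {
    if (!nchar(a)) return(0L)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  flank5 <- mism(substr(sequence, 1L, ip), substr(exon_reference, 1L, ip))
  flank3 <- mism(substr(sequence, ip + len + 1L, nchar(sequence)),
                 substr(exon_reference, ip + 1L, nchar(exon_reference)))
  if (flank5 > max_mismatches || flank3 > max_mismatches) {
    abort(sprintf(
      "Exon flanks mismatch the reference (5': %d, 3': %d, budget %d).",
      flank5, flank3, max_mismatches
    ), class = "cctrace_extraction_error")
  }
  list(intron = substr(sequence, ip + 1L, ip + len), length = len)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest forward-strand open reading frame
#'
#' Longest ATG-initiated, stop-terminated ORF across the three forward
#' frames; length includes the stop codon; ties broken by smallest start.
#'
#' @param seq Ungapped nucleotide string.
#' @return A list with `start` (1-based, `NA` if none) and `length` (bp, 0
#'   if none).
#' @export
longest_orf <- function(seq) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  best_start <- NA_integer_
  best_len <- 0L
  for (off in 0:2) {
    if (off + 3L > n) next
    starts <- seq.int(off + 1L, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    atg_idx <- which(codons == "ATG")
    for (a in atg_idx) {
      s <- stop_idx[stop_idx >= a]
      if (!length(s)) next
      len <- (s[1] - a + 1L) * 3L
      if (len > best_len || (len == best_len && !is.na(best_start) &&
                             starts[a] < best_start)) {
        best_len <- len
        best_start <- starts[a]
      }
    }
  }
  list(start = best_start, length = best_len)
}

#' In-silico intron survey over a set of sequences
#'
#' Runs [insilico_pcr()] on each taxon's (ungapped) genomic sequence,
#' classifies intron presence from the smallest amplicon, and — when an exon
#' reference is supplied — extracts the intron and measures its longest ORF.
#'
#' @param sequences Named character vector of ungapped sequences, or a data
#'   frame with columns `taxon` and `sequence`.
#' @param pair A [primer_pair()].
#' @param expected_intronless_length Expected intron-less amplicon (bp).
#' @param exon_reference,insertion_point Optional, for intron extraction
#'   (see [extract_intron()]).
#' @inheritParams insilico_pcr
#' @inheritParams classify_presence
#' @return A tibble (one row per taxon): `taxon`, `amplicon_length`,
#'   `classification`, `intron_length`, `orf_length`.
#' @export
survey_introns <- function(sequences, pair = primer_pair(),
                           expected_intronless_length = 800,
                           threshold_delta = 500, tolerance = 100,
                           exon_reference = NULL, insertion_point = NULL,
                           max_mismatches = 0) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$taxon)
  }
  purrr::imap(sequences, function(seq, tx) {
    hits <- insilico_pcr(seq, pair, max_mismatches = max_mismatches)
    amp <- if (nrow(hits)) hits$length[1] else NA_integer_
    cls <- classify_presence(amp, expected_intronless_length,
                             threshold_delta, tolerance)
    intron_len <- NA_integer_
    orf_len <- NA_integer_
    if (!is.null(exon_reference) && !is.null(insertion_point)) {
      ext <- tryCatch(
        extract_intron(seq, exon_reference, insertion_point,
                       max_mismatches = max_mismatches),
        cctrace_extraction_error = function(e) NULL
      )
      if (!is.null(ext)) {
        intron_len <- ext$length
        if (ext$length > 0) orf_len <- longest_orf(ext$intron)$length
      }
    }
    tibble(taxon = tx, amplicon_length = amp, classification = cls,
           intron_length = intron_len, orf_length = orf_len)
  }) |> bind_rows()
}
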