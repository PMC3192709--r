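normalize_seq <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

#' Exon alignment with an intron insertion frame
#'
#' An `aligned_locus` is a tibble with one row per taxon (columns `taxon`,
#' `sequence`, `intron_present`) carrying, as attributes, the signed
#' [coord_frame()] anchored at the declared intron insertion column. The
#' aligned sequences are the *exon* alignment only: the intron itself is never
#' part of it. `intron_present` may be `NA` (unknown); unknown taxa are
#' excluded from diagnostic-site evaluation rather than imputed.
#'
#' @param taxon Character vector of unique taxon labels.
#' @param sequence Aligned sequences over `A`,`C`,`G`,`T`,`-`,`N` (plus IUPAC
#'   ambiguity codes); lowercase and `U` are normalized.
#' @param insertion_column 1-based alignment column immediately 5' of the
#'   intron insertion point.
#' @param intron_present Logical vector (recycled), `NA` = unknown.
#' @param reference Reference row for the coordinate frame: a taxon label, an
#'   explicit aligned sequence, or `NULL` to use the first intron-lacking
#'   taxon (falling back to the first row).
#' @return An `aligned_locus` tibble.
#' @export
aligned_locus <- function(taxon, sequence, insertion_column,
                          intron_present = NA, reference = NULL) {
  taxon <- as.character(taxon)
  sequence <- normalize_seq(as.character(sequence))
  if (length(taxon) != length(sequence)) {
    abort("`taxon` and `sequence` lengths differ.", class = "cctrace_input_error")
  }
  if (anyDuplicated(taxon)) {
    abort(sprintf("Duplicate taxon labels: %s.",
                  paste(unique(taxon[duplicated(taxon)]), collapse = ", ")),
          class = "cctrace_input_error")
  }
  widths <- nchar(sequence)
  if (length(unique(widths)) > 1L) {
    abort("Ragged alignment: sequences differ in length.",
          class = "cctrace_format_error")
  }
  bad <- grepl("[^ACGTUNRYSWKMBDHV-]", sequence)
  if (any(bad)) {
    abort(sprintf("Non-nucleotide characters in sequences for: %s.",
                  paste(taxon[bad], collapse = ", ")),
          class = "cctrace_format_error")
  }
  intron_present <- rep_len(as.logical(intron_present), length(taxon))
  ref_seq <- resolve_reference(reference, taxon, sequence, intron_present)
  out <- tibble(taxon = taxon, sequence = sequence,
                intron_present = intron_present)
  attr(out, "frame") <- coord_frame(ref_seq, insertion_column)
  class(out) <- c("aligned_locus", class(out))
  out
}

resolve_reference <- function(reference, taxon, sequence, intron_present) {
  if (is.null(reference)) {
    i <- which(!is.na(intron_present) & !intron_present)
    return(if (length(i)) sequence[i[1]] else sequence[1])
  }
  if (reference %in% taxon) return(sequence[match(reference, taxon)])
  if (nchar(reference) == nchar(sequence[1])) return(normalize_seq(reference))
  abort("`reference` must be a taxon label or an aligned sequence of matching width.",
        class = "cctrace_input_error")
}

#' @export
print.aligned_locus <- function(x, ...) {
  frame <- attr(x, "frame")
  cat(sprintf("<aligned_locus> %d taxa x %d columns, insertion after column %d\n",
              nrow(x), nchar(x$sequence[1]), frame$insertion_column))
  NextMethod()
}

# dplyr verbs strip attributes; re-attach the frame when the core columns
# survive so piped workflows keep the coordinate system.
locus_keep_frame <- function(out, template) {
  if (all(c("taxon", "sequence") %in% names(out))) {
    attr(out, "frame") <- attr(template, "frame")
    class(out) <- unique(c("aligned_locus", class(out)))
  }
  out
}

#' @export
`[.aligned_locus` <- function(x, ...) locus_keep_frame(NextMethod(), x)

#' Character matrix view of an aligned locus
#'
#' Rows are taxa (named), columns are alignment columns.
#' @param locus An [aligned_locus()].
#' @return A character matrix.
#' @export
locus_matrix <- function(locus) {
  m <- do.call(rbind, strsplit(locus$sequence, "", fixed = TRUE))
  rownames(m) <- locus$taxon
  m
}

# States of a set of taxa at one signed position.
states_at <- function(locus, signed_pos, taxa = locus$taxon) {
  col <- signed_to_column(locus, signed_pos)
  m <- locus_matrix(locus)
  setNames(m[taxa, col], taxa)
}

#' Read and write exon alignments
#'
#' `read_alignment()` parses an aligned FASTA file into an [aligned_locus()];
#' sequences are upper-cased and `U` mapped to `T`. `write_alignment()` writes
#' one back out.
#'
#' @inheritParams aligned_locus
#' @param path FASTA file path.
#' @param locus An `aligned_locus`.
#' @return `read_alignment()`: an `aligned_locus`; `write_alignment()`: the
#'   path, invisibly.
#' @export
read_alignment <- function(path, insertion_column, intron_present = NA,
                           reference = NULL) {
  # read raw, then normalize (lowercase, RNA U) in aligned_locus(): a strict
  # DNA reader would silently drop U codes instead of mapping them to T
  seqs <- Biostrings::readBStringSet(path)
  aligned_locus(
    taxon = names(seqs),
    sequence = as.character(seqs),
    insertion_column = insertion_column,
    intron_present = intron_present,
    reference = reference
  )
}

#' @rdname read_alignment
#' @export
write_alignment <- function(locus, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(locus$sequence, locus$taxon)), path
  )
  invisible(path)
}

#' Read a rooted phylogeny, preserving polychotomies
#'
#' Thin wrapper over [ape::read.tree()] that keeps multifurcations as written
#' (they are never arbitrarily resolved) and validates tip-label uniqueness.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort("Could not parse newick tree.",
                           class = "cctrace_format_error")
  if (anyDuplicated(tree$tip.label)) {
    abort("Duplicate tip labels in tree.", class = "cctrace_input_error")
  }
  tree
}

#' Read a per-taxon intron presence/absence table
#'
#' Two-column TSV (`taxon`, `present`) with presence coded as `1`/`0`,
#' `+`/`-`, `TRUE`/`FALSE`, or `?`/`NA` for unknown.
#'
#' @param path TSV file path.
#' @param tree Optional [ape::phylo]; if given, every taxon in the table must
#'   resolve to a tip, otherwise a reconciliation error lists the strays.
#' @return A tibble with columns `taxon` (character) and `present` (logical).
#' @export
read_intron_states <- function(path, tree = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("taxon", "present") %in% names(raw))) {
    abort("States file needs columns `taxon` and `present`.",
          class = "cctrace_format_error")
  }
  states <- tibble(
    taxon = raw$taxon,
    present = parse_presence(raw$present)
  )
  if (!is.null(tree)) {
    missing <- setdiff(states$taxon, tree$tip.label)
    if (length(missing)) {
      abort(sprintf("Taxa in states file absent from tree: %s.",
                    paste(missing, collapse = ", ")),
            class = "cctrace_reconciliation_error")
    }
  }
  states
}

parse_presence <- function(x) {
  x <- trimws(as.character(x))
  # − is the typographic minus sign sometimes used in tables
  out <- rep(NA, length(x))
  out[x %in% c("1", "+", "TRUE", "true", "T", "present")] <- TRUE
  out[x %in% c("0", "-", "−", "FALSE", "false", "F", "absent")] <- FALSE
  unknown <- is.na(out) & !(x %in% c("?", "NA", "", "unknown"))
  if (any(unknown)) {
    abort(sprintf("Unrecognized presence codes: %s.",
                  paste(unique(x[unknown]), collapse = ", ")),
          class = "cctrace_format_error")
  }
  out
}

#' Read a C-to-U RNA editing site list
#'
#' TSV with column `position` (signed exon positions, nonzero, distinct) and
#' optionally `edited_base`. Edit positions are an *input*: the package does
#' not predict them.
#'
#' @param path TSV file path.
#' @return Integer vector of signed edit positions.
#' @export
read_edit_sites <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!"position" %in% names(raw)) {
    abort("Edit-site file needs a `position` column.",
          class = "cctrace_format_error")
  }
  pos <- as.integer(raw$position)
  if (any(is.na(pos)) || any(pos == 0L)) {
    abort("Edit positions must be nonzero integers.",
          class = "cctrace_input_error")
  }
  if (anyDuplicated(pos)) {
    abort("Edit positions must be distinct.", class = "cctrace_input_error")
  }
  pos
}
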