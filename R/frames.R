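#' Signed exon coordinate frame anchored at an intron insertion site
#'
#' Footprints of intron homing are described in the literature by signed exon
#' positions relative to the insertion point: `+k` is the k-th exon nucleotide
#' 3' (downstream) of the insertion site, `-k` the k-th nucleotide 5' of it;
#' there is no position 0. Positions are counted on a designated ungapped
#' *reference row* of the alignment (typically the reconstructed ancestor or
#' an intron-lacking taxon), so alignment columns that are gaps in the
#' reference carry no signed position.
#'
#' `insertion_column` is the 1-based index of the alignment column immediately
#' 5' of the insertion point, i.e. `-1` maps to `insertion_column` and (for an
#' ungapped reference) `+1` maps to `insertion_column + 1`.
#'
#' @param reference Aligned reference sequence (single string, may contain
#'   `-` gaps) on which signed positions are counted.
#' @param insertion_column 1-based alignment column immediately 5' of the
#'   insertion point.
#' @return An object of class `coord_frame`.
#' @export
coord_frame <- function(reference, insertion_column) {
  stopifnot(is.character(reference), length(reference) == 1L)
  reference <- normalize_seq(reference)
  width <- nchar(reference)
  insertion_column <- as.integer(insertion_column)
  if (is.na(insertion_column) || insertion_column < 1L ||
      insertion_column >= width) {
    abort(sprintf(
      "`insertion_column` must lie in [1, %d] (alignment width %d).",
      width - 1L, width
    ), class = "cctrace_range_error")
  }
  structure(
    list(reference = reference, insertion_column = insertion_column),
    class = "coord_frame"
  )
}

#' @export
print.coord_frame <- function(x, ...) {
  cat(sprintf(
    "<coord_frame> width %d, insertion point after column %d (%d 5' / %d 3' reference positions)\n",
    nchar(x$reference), x$insertion_column,
    length(frame_columns(x, "5prime")), length(frame_columns(x, "3prime"))
  ))
  invisible(x)
}

# Non-gap reference columns on one side of the insertion point, ordered
# outward from the insertion site (element k is signed position +-k).
frame_columns <- function(frame, side = c("3prime", "5prime")) {
  side <- match.arg(side)
  chars <- strsplit(frame$reference, "", fixed = TRUE)[[1]]
  if (side == "3prime") {
    cols <- seq(frame$insertion_column + 1L, length(chars))
    cols[chars[cols] != "-"]
  } else {
    cols <- seq(frame$insertion_column, 1L)
    cols[chars[cols] != "-"]
  }
}

#' Map signed exon positions to alignment columns and back
#'
#' `signed_to_column()` converts signed positions (counted on the frame's
#' reference row, skipping its gap columns) to 1-based alignment column
#' indices; `column_to_signed()` is its inverse and returns `NA` for columns
#' that are gaps in the reference. The two are bijective over non-gap columns.
#'
#' @param frame A [coord_frame()], or any object with a frame (an
#'   `aligned_locus`).
#' @param signed_pos Integer vector of nonzero signed positions.
#' @param column Integer vector of 1-based alignment columns.
#' @return An integer vector.
#' @export
signed_to_column <- function(frame, signed_pos) {
  frame <- as_coord_frame(frame)
  signed_pos <- as.integer(signed_pos)
  if (any(signed_pos == 0L, na.rm = TRUE)) {
    abort("Signed position 0 does not exist.", class = "cctrace_range_error")
  }
  up <- frame_columns(frame, "5prime")
  down <- frame_columns(frame, "3prime")
  out <- rep(NA_integer_, length(signed_pos))
  pos3 <- !is.na(signed_pos) & signed_pos > 0L
  pos5 <- !is.na(signed_pos) & signed_pos < 0L
  bad <- (pos3 & signed_pos > length(down)) | (pos5 & -signed_pos > length(up))
  if (any(bad)) {
    abort(sprintf(
      "Signed position(s) %s lie beyond the alignment (%d 5' / %d 3' reference positions available).",
      paste(signed_pos[bad], collapse = ", "), length(up), length(down)
    ), class = "cctrace_range_error")
  }
  out[pos3] <- down[signed_pos[pos3]]
  out[pos5] <- up[-signed_pos[pos5]]
  out
}

#' @rdname signed_to_column
#' @export
column_to_signed <- function(frame, column) {
  frame <- as_coord_frame(frame)
  column <- as.integer(column)
  up <- frame_columns(frame, "5prime")
  down <- frame_columns(frame, "3prime")
  out <- rep(NA_integer_, length(column))
  m3 <- match(column, down)
  m5 <- match(column, up)
  out[!is.na(m3)] <- m3[!is.na(m3)]
  out[!is.na(m5)] <- -m5[!is.na(m5)]
  out
}

as_coord_frame <- function(x) {
  if (inherits(x, "coord_frame")) return(x)
  if (inherits(x, "aligned_locus")) return(attr(x, "frame"))
  abort("Expected a `coord_frame` or `aligned_locus`.",
        class = "cctrace_input_error")
}

# Signed positions available in a frame within a +/- window, ordered
# upstream-to-downstream.
frame_positions <- function(frame, window) {
  frame <- as_coord_frame(frame)
  n5 <- min(window, length(frame_columns(frame, "5prime")))
  n3 <- min(window, length(frame_columns(frame, "3prime")))
  c(rev(seq_len(n5) * -1L), seq_len(n3))
}
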