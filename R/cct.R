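#' Call diagnostic sites for a focal intron-containing clade
#'
#' A signed position is *diagnostic* when (a) every member of the focal clade
#' carries the same concrete base there, (b) that shared state differs from
#' the reconstructed ancestral state, and (c) the derived state's occurrence
#' among intron-lacking taxa is tallied into a homoplasy flag. Sites whose
#' derived state recurs in intron-lacking taxa (at or above
#' `homoplasy_threshold` occurrences) are returned flagged; flagged sites are
#' excluded from co-conversion bounds downstream. Taxa with unknown intron
#' status are excluded from the intron-lacking comparison set rather than
#' imputed. Ambiguity codes other than a concrete `A`/`C`/`G`/`T` never count
#' as a shared focal state (conservative footprint calling).
#'
#' @param locus An [aligned_locus()].
#' @param ancestor An `ancestral_seq` from [reconstruct_ancestor()].
#' @param focal_clade Character vector of intron-containing taxa. Any
#'   user-declared taxon set is allowed (footprints can be shared across
#'   separate acquisition clades), but intron-lacking members are an error.
#' @param edit_sites Integer vector of signed C-to-U editing positions.
#' @param window Scan limit on `|signed position|` (default 200; all known
#'   cox1 footprints lie within +-81).
#' @param reading_frame Optional codon position (1, 2 or 3) of signed
#'   position `+1`; when supplied, non-edit sites at third codon positions
#'   are labelled `synonymous`, otherwise `other`.
#' @param homoplasy_threshold Number of intron-lacking occurrences of the
#'   derived state at which a site is flagged (default 1: any occurrence).
#' @return A tibble of class `diagnostic_sites`: `position`,
#'   `ancestral_state`, `derived_state`, `site_class`, `homoplasy_flag`,
#'   `n_lacking_derived`.
#' @export
call_diagnostic_sites <- function(locus, ancestor, focal_clade,
                                  edit_sites = integer(), window = 200,
                                  reading_frame = NULL,
                                  homoplasy_threshold = 1) {
  missing_taxa <- setdiff(focal_clade, locus$taxon)
  if (length(missing_taxa)) {
    abort(sprintf("Focal taxa absent from locus: %s.",
                  paste(missing_taxa, collapse = ", ")),
          class = "cctrace_input_error")
  }
  present <- locus$intron_present[match(focal_clade, locus$taxon)]
  if (any(!present, na.rm = TRUE)) {
    abort(sprintf("Focal clade contains intron-lacking taxa: %s.",
                  paste(focal_clade[!is.na(present) & !present], collapse = ", ")),
          class = "cctrace_input_error")
  }
  lacking <- locus$taxon[!is.na(locus$intron_present) & !locus$intron_present]
  positions <- frame_positions(locus, window)
  m <- locus_matrix(locus)
  cols <- signed_to_column(locus, positions)
  anc <- ancestor_state(ancestor, positions)

  rows <- purrr::map(seq_along(positions), function(i) {
    focal_states <- m[focal_clade, cols[i]]
    state <- unique(focal_states)
    if (length(state) != 1L || !(state %in% BASES)) return(NULL)
    if (!(anc[i] %in% BASES) || state == anc[i]) return(NULL)
    n_lack <- sum(m[lacking, cols[i]] == state)
    tibble(
      position = positions[i],
      ancestral_state = anc[i],
      derived_state = state,
      site_class = classify_site(positions[i], edit_sites, reading_frame),
      homoplasy_flag = n_lack >= homoplasy_threshold,
      n_lacking_derived = n_lack
    )
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(position = integer(), ancestral_state = character(),
                  derived_state = character(), site_class = character(),
                  homoplasy_flag = logical(), n_lacking_derived = integer())
  }
  class(out) <- c("diagnostic_sites", class(out))
  out
}

classify_site <- function(position, edit_sites, reading_frame) {
  if (position %in% edit_sites) return("edit_site")
  if (is.null(reading_frame)) return("other")
  # map signed positions (no 0) onto consecutive integers with +1 -> 1
  u <- position + (position < 0)
  codon_pos <- ((u - 1 + reading_frame - 1) %% 3) + 1
  if (codon_pos == 3) "synonymous" else "other"
}

#' Estimate co-conversion tract bounds from diagnostic sites
#'
#' The *minimum* tract length on each side is the farthest non-homoplastic
#' diagnostic position (0 when there is none) — the operational definition
#' under which the published minimum lengths (35, 54, 63, 81 bp and so on)
#' all equal their farthest diagnostic site. An *upper* bound on the tract
#' endpoint exists only when a candidate donor group is supplied: it is the
#' first position beyond the lower bound at which the focal clade
#' demonstrably retains the native (ancestral) state while the donor group
#' differs from it; otherwise the endpoint is unbounded (`Inf`). The
#' endpoint interval `(lower, upper)` is open on both sides.
#'
#' @param sites A `diagnostic_sites` tibble from [call_diagnostic_sites()].
#' @param locus,focal_clade,ancestor As in [call_diagnostic_sites()]; needed
#'   only when `donor_group` is supplied.
#' @param donor_group Optional character vector of taxa representing the
#'   putative donor lineage.
#' @param window Scan limit for the donor-retention search.
#' @return An object of class `cct_report`.
#' @export
cct_bounds <- function(sites, locus = NULL, focal_clade = NULL,
                       ancestor = NULL, donor_group = NULL, window = 200) {
  clean <- dplyr::filter(sites, !.data$homoplasy_flag)
  pos3 <- clean$position[clean$position > 0]
  pos5 <- clean$position[clean$position < 0]
  lower3 <- if (length(pos3)) max(pos3) else 0L
  lower5 <- if (length(pos5)) max(-pos5) else 0L

  upper3 <- upper5 <- Inf
  if (!is.null(donor_group)) {
    if (is.null(locus) || is.null(focal_clade) || is.null(ancestor)) {
      abort("`locus`, `focal_clade` and `ancestor` are required when `donor_group` is supplied.",
            class = "cctrace_input_error")
    }
    upper3 <- donor_retained_bound(locus, focal_clade, ancestor, donor_group,
                                   lower3, window, side = 1L)
    upper5 <- donor_retained_bound(locus, focal_clade, ancestor, donor_group,
                                   lower5, window, side = -1L)
  }

  kept <- dplyr::filter(sites,
                        (.data$position > 0 & .data$position < upper3) |
                          (.data$position < 0 & -.data$position < upper5))
  structure(
    list(
      focal_clade = focal_clade %||% attr(sites, "focal_clade"),
      sites = kept,
      lower_bound_3prime = lower3,
      upper_bound_3prime = upper3,
      lower_bound_5prime = lower5,
      upper_bound_5prime = upper5,
      endpoint_interval = c(lower = lower3, upper = upper3),
      donor_group = donor_group
    ),
    class = "cct_report"
  )
}

# First position beyond `lower` (on side +1 = 3', -1 = 5') where the focal
# clade uniformly retains the ancestral base while the donor group uniformly
# carries a different concrete base.
donor_retained_bound <- function(locus, focal_clade, ancestor, donor_group,
                                 lower, window, side) {
  positions <- frame_positions(locus, window)
  positions <- positions[sign(positions) == side & abs(positions) > lower]
  positions <- positions[order(abs(positions))]
  m <- locus_matrix(locus)
  for (p in positions) {
    col <- signed_to_column(locus, p)
    anc <- ancestor_state(ancestor, p)
    if (!(anc %in% BASES)) next
    focal_states <- unique(m[focal_clade, col])
    donor_states <- unique(m[donor_group, col])
    if (length(focal_states) == 1L && focal_states == anc &&
        length(donor_states) == 1L && donor_states %in% BASES &&
        donor_states != anc) {
      return(abs(p))
    }
  }
  Inf
}

#' @export
print.cct_report <- function(x, ...) {
  up3 <- if (is.finite(x$upper_bound_3prime)) paste0(x$upper_bound_3prime, " bp") else "unbounded"
  cat("<cct_report>\n")
  cat(sprintf("  3' tract: minimum %d bp, endpoint in (%s, %s)\n",
              x$lower_bound_3prime, x$lower_bound_3prime, up3))
  cat(sprintf("  5' tract: minimum %d bp\n", x$lower_bound_5prime))
  cat(sprintf("  %d diagnostic site(s), %d flagged homoplastic\n",
              nrow(x$sites), sum(x$sites$homoplasy_flag)))
  invisible(x)
}

#' Test an intron-lacking taxon for the retroprocessing signature
#'
#' RNA-mediated intron loss (retroprocessing) copies the edited mRNA back
#' into the gene, converting genomic `C` to `T` at C-to-U editing sites
#' downstream of the former intron. An intron-lacking gene that *never*
#' carried the intron instead retains `C` at those sites. The verdict is
#' `retro_signature` when at least one downstream edit site with ancestral
#' `C` carries `T`; `no_signature` when all such sites retain `C`; and
#' `indeterminate` when the taxon is not intron-lacking or no informative
#' state is observed.
#'
#' @param locus An [aligned_locus()].
#' @param taxon A single taxon label.
#' @param ancestor An `ancestral_seq`.
#' @param edit_sites Signed editing positions.
#' @param window Downstream window in bp within which edit sites are
#'   examined (default 600).
#' @return An object of class `retro_report`.
#' @export
retro_signature <- function(locus, taxon, ancestor, edit_sites,
                            window = 600) {
  stopifnot(length(taxon) == 1L)
  if (!taxon %in% locus$taxon) {
    abort(sprintf("Unknown taxon %s.", taxon), class = "cctrace_input_error")
  }
  present <- locus$intron_present[match(taxon, locus$taxon)]
  info <- sort(edit_sites[edit_sites > 0 & edit_sites <= window])
  info <- info[ancestor_state(ancestor, info) == "C"]
  observed <- if (length(info)) {
    unname(locus_matrix(locus)[taxon, signed_to_column(locus, info)])
  } else {
    character()
  }
  states <- tibble(
    position = info,
    ancestral_state = rep("C", length(info)),
    observed_state = observed
  )
  note <- NULL
  if (is.na(present) || isTRUE(present)) {
    verdict <- "indeterminate"
    note <- if (isTRUE(present)) "taxon is intron-containing" else "intron status unknown"
  } else if (any(states$observed_state == "T")) {
    verdict <- "retro_signature"
  } else if (nrow(states) > 0 && all(states$observed_state == "C")) {
    verdict <- "no_signature"
  } else {
    verdict <- "indeterminate"
    note <- "no informative edit-site state observed"
  }
  structure(
    list(taxon = taxon, states = states, verdict = verdict, note = note),
    class = "retro_report"
  )
}

#' @export
print.retro_report <- function(x, ...) {
  cat(sprintf("<retro_report> %s: %s", x$taxon, x$verdict))
  if (!is.null(x$note)) cat(sprintf(" (%s)", x$note))
  cat(sprintf("\n  %d informative downstream edit site(s)\n", nrow(x$states)))
  invisible(x)
}

#' Screen every taxon for the retroprocessing signature
#'
#' Vectorized wrapper over [retro_signature()].
#'
#' @inheritParams retro_signature
#' @return A tibble with one row per taxon: `taxon`, `verdict`,
#'   `n_informative`, `n_converted`.
#' @export
retro_screen <- function(locus, ancestor, edit_sites, window = 600) {
  purrr::map(locus$taxon, function(tx) {
    rep <- retro_signature(locus, tx, ancestor, edit_sites, window)
    tibble(taxon = tx, verdict = rep$verdict,
           n_informative = nrow(rep$states),
           n_converted = sum(rep$states$observed_state == "T"))
  }) |> bind_rows()
}

#' Does an intron-lacking taxon retain the clade's co-conversion tract?
#'
#' `TRUE` when the taxon lacks the intron yet matches the focal clade's
#' derived state at *every* non-homoplastic diagnostic site — the footprint
#' expected of secondary intron loss with full tract retention. Mismatching
#' sites are attached as the `"mismatches"` attribute.
#'
#' @param locus An [aligned_locus()].
#' @param taxon A single taxon label.
#' @param cct_report A `cct_report` from [cct_bounds()].
#' @return Logical scalar with attribute `mismatches` (tibble of `position`,
#'   `expected_derived`, `observed`).
#' @export
intron_loss_with_cct <- function(locus, taxon, cct_report) {
  stopifnot(length(taxon) == 1L)
  present <- locus$intron_present[match(taxon, locus$taxon)]
  sites <- dplyr::filter(cct_report$sites, !.data$homoplasy_flag)
  if (!nrow(sites)) {
    return(structure(FALSE, mismatches = tibble(
      position = integer(), expected_derived = character(),
      observed = character())))
  }
  m <- locus_matrix(locus)
  observed <- m[taxon, signed_to_column(locus, sites$position)]
  mism <- tibble(position = sites$position,
                 expected_derived = sites$derived_state,
                 observed = unname(observed)) |>
    dplyr::filter(.data$expected_derived != .data$observed)
  ok <- isFALSE(as.logical(present)) && nrow(mism) == 0L
  structure(ok, mismatches = mism)
}
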