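BASES <- c("A", "C", "G", "T")

#' Reconstruct the ancestral exon sequence around the insertion site
#'
#' Per-column minimum-change (Fitch/Sankoff, unit cost) reconstruction of the
#' root state on a rooted tree, polychotomies allowed. When the minimum-change
#' root state set is ambiguous, ties are resolved by the majority state among
#' intron-lacking taxa, then alphabetically. Without a tree, the ancestor is
#' the strict-majority consensus of intron-lacking taxa (plurality with
#' alphabetical tie-break). Columns that are entirely gaps/`N` reconstruct as
#' `N`. Gaps, `N` and ambiguity codes at tips are treated as missing
#' (compatible with every base) for the parsimony step.
#'
#' @param locus An [aligned_locus()].
#' @param tree Optional rooted [ape::phylo] whose tips cover the locus taxa.
#' @param window Maximum `|signed position|` reconstructed (default 200).
#' @return A tibble of class `ancestral_seq` with columns `position`,
#'   `column`, `state`.
#' @export
reconstruct_ancestor <- function(locus, tree = NULL, window = 200) {
  positions <- frame_positions(locus, window)
  cols <- signed_to_column(locus, positions)
  m <- locus_matrix(locus)
  lacking <- locus$taxon[!is.na(locus$intron_present) & !locus$intron_present]

  state <- vapply(seq_along(cols), function(i) {
    column <- m[, cols[i]]
    if (is.null(tree)) {
      consensus_state(column[lacking])
    } else {
      root_state(tree, column, lacking)
    }
  }, character(1))

  out <- tibble(position = positions, column = cols, state = state)
  class(out) <- c("ancestral_seq", class(out))
  out
}

consensus_state <- function(states) {
  states <- states[states %in% BASES]
  if (!length(states)) return("N")
  tab <- table(factor(states, levels = BASES))
  names(tab)[which.max(tab)] # which.max takes the first (alphabetical) maximum
}

# Unit-cost Sankoff on a rooted (possibly multifurcating) ape tree for one
# alignment column; returns the tie-broken minimum-change root state.
root_state <- function(tree, column, lacking) {
  taxa <- names(column)
  missing_tree <- setdiff(taxa, tree$tip.label)
  if (length(missing_tree)) {
    abort(sprintf("Tree tips do not cover locus taxa: %s.",
                  paste(missing_tree, collapse = ", ")),
          class = "cctrace_reconciliation_error")
  }
  if (!any(column %in% BASES)) return("N")
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra)) tree <- ape::drop.tip(tree, extra, collapse.singles = TRUE)

  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cost <- matrix(Inf, nrow = 4L, ncol = nnode)
  tip_states <- column[tree$tip.label]
  for (i in seq_len(ntip)) {
    s <- tip_states[i]
    cost[, i] <- if (s %in% BASES) ifelse(BASES == s, 0, Inf) else 0
  }
  root <- ntip + 1L
  for (v in (ntip + seq_len(tree$Nnode))) cost[, v] <- 0
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    # min over child states of cost(child, t) + (s != t)
    contrib <- vapply(seq_len(4L), function(s) {
      min(cost[, child] + (seq_len(4L) != s))
    }, numeric(1))
    cost[, parent] <- cost[, parent] + contrib
  }
  minimal <- BASES[cost[, root] == min(cost[, root])]
  if (length(minimal) == 1L) return(minimal)
  # tie: majority among intron-lacking taxa restricted to the tied states,
  # then alphabetical
  lack_states <- column[intersect(lacking, names(column))]
  lack_states <- lack_states[lack_states %in% minimal]
  if (length(lack_states)) {
    tab <- table(factor(lack_states, levels = minimal))
    return(names(tab)[which.max(tab)])
  }
  minimal[1]
}

# State of an ancestral_seq at given signed positions ("N" outside the
# reconstructed window).
ancestor_state <- function(ancestor, positions) {
  i <- match(positions, ancestor$position)
  out <- ancestor$state[i]
  out[is.na(i)] <- "N"
  out
}

#' @export
print.ancestral_seq <- function(x, ...) {
  cat(sprintf("<ancestral_seq> %d signed positions (%+d .. %+d)\n",
              nrow(x), min(x$position), max(x$position)))
  NextMethod()
}
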