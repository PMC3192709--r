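as_tip_states <- function(tree, tip_states) {
  if (is.data.frame(tip_states)) {
    tip_states <- setNames(tip_states$present, tip_states$taxon)
  }
  strays <- setdiff(names(tip_states), tree$tip.label)
  if (length(strays)) {
    abort(sprintf("State taxa absent from tree: %s.",
                  paste(strays, collapse = ", ")),
          class = "cctrace_reconciliation_error")
  }
  out <- setNames(rep(NA, length(tree$tip.label)), tree$tip.label)
  out[names(tip_states)] <- as.logical(tip_states)
  out
}

node_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

# Subtree status wrt the "marked" state: "A" = contains marked, none of the
# other state; "U" = all unknown; "M" = contains the other state.
subtree_status <- function(tree, states, marked = FALSE) {
  ntip <- length(tree$tip.label)
  status <- character(ntip + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(ntip)) {
    s <- states[tree$tip.label[i]]
    status[i] <- if (is.na(s)) "U" else if (s == marked) "A" else "M"
  }
  for (v in unique(po[, 1])) {
    kid_status <- status[node_children(tree, v)]
    status[v] <- if (any(kid_status == "M")) "M"
    else if (any(kid_status == "A")) "A" else "U"
  }
  status
}

double_factorial_resolutions <- function(k) {
  if (k <= 2) return(1)
  prod(seq(3, 2 * k - 3, by = 2))
}

# All rooted binary resolutions over items 1..k, as nested index pairs.
enumerate_resolutions <- function(k) {
  gen <- function(items) {
    if (length(items) == 1L) return(list(items))
    out <- list()
    rest <- items[-1]
    for (sz in seq_len(length(rest))) {
      for (pick in combn_list(rest, sz - 1L)) {
        left <- c(items[1], pick)
        right <- setdiff(items, left)
        if (!length(right)) next
        for (lt in gen(left)) for (rt in gen(right)) {
          out[[length(out) + 1L]] <- list(lt, rt)
        }
      }
    }
    out
  }
  gen(seq_len(k))
}

combn_list <- function(x, m) {
  if (m == 0L) return(list(integer()))
  if (m > length(x)) return(list())
  apply(combn(length(x), m), 2, function(i) x[i], simplify = FALSE)
}

# Contribution of one (possibly forced-split) polychotomy resolution:
# number of maximal marked-state clades among its children, given child
# statuses. Marked-only clades count 1, all-unknown clades 0, mixed recurse.
resolution_counts <- function(statuses, forced_split) {
  k <- length(statuses)
  h <- function(node) {
    leaves <- unlist(node)
    st <- statuses[leaves]
    if (!any(st == "M")) return(if (any(st == "A")) 1L else 0L)
    if (length(leaves) == 1L) return(0L) # M leaf: inner count added by caller
    h(node[[1]]) + h(node[[2]])
  }
  vapply(enumerate_resolutions(k), function(res) {
    if (forced_split) h(res[[1]]) + h(res[[2]]) else h(res)
  }, integer(1))
}

# Closed-form min/max contribution of a polychotomy (exact; see vignette).
closed_form_counts <- function(statuses, forced_split) {
  a <- sum(statuses == "A"); u <- sum(statuses == "U")
  m <- sum(statuses == "M")
  if (m >= 1 && !forced_split) {
    # the M child anchors the clade of grouped A/U children
    return(c(min = as.integer(a > 0), max = a))
  }
  if (m >= 1 && forced_split) {
    return(c(min = as.integer(a > 0), max = a))
  }
  # no mixed child: the node splits into exactly two clades
  if (a == 0) return(c(min = 0L, max = 0L))
  if (a == 1) return(c(min = 1L, max = 1L))
  c(min = if (u > 0) 1L else 2L, max = 2L)
}

# min/max number of marked-state event edges below `node`, over all binary
# resolutions of polychotomies, with unknown tips optimized. Returns
# list(min, max, resolutions, placements) where placements lists the tip
# sets under each event edge for one minimizing scenario.
event_range <- function(tree, states, node, marked = FALSE,
                        resolution_cap = 10000, forced_split_at_top = TRUE) {
  status <- subtree_status(tree, states, marked = marked)
  ntip <- length(tree$tip.label)
  tips_under <- function(v) tree$tip.label[subtree_tips(tree, v)]

  recurse <- function(v, at_top) {
    kids <- node_children(tree, v)
    if (!length(kids)) {
      return(list(min = 0L, max = 0L, resolutions = 1, placements = list()))
    }
    st <- status[kids]
    res_min <- 0L; res_max <- 0L; n_res <- 1
    placements <- list()
    for (kid in kids[st == "M"]) {
      inner <- recurse(kid, FALSE)
      res_min <- res_min + inner$min; res_max <- res_max + inner$max
      n_res <- n_res * inner$resolutions
      placements <- c(placements, inner$placements)
    }
    a_kids <- kids[st == "A"]; u_kids <- kids[st == "U"]
    k <- length(kids)
    forced <- at_top && forced_split_at_top
    if (k <= 2L && !(forced && all(st != "M"))) {
      res_min <- res_min + length(a_kids)
      res_max <- res_max + length(a_kids)
      placements <- c(placements, lapply(a_kids, tips_under))
    } else {
      n_here <- double_factorial_resolutions(k)
      cnt <- if (n_here * n_res <= resolution_cap) {
        counts <- resolution_counts(st, forced_split = forced && all(st != "M"))
        c(min = min(counts), max = max(counts))
      } else {
        closed_form_counts(st, forced_split = forced && all(st != "M"))
      }
      n_res <- n_res * n_here
      res_min <- res_min + cnt[["min"]]
      res_max <- res_max + cnt[["max"]]
      placements <- c(placements, min_placements(st, a_kids, u_kids,
                                                 tips_under,
                                                 forced && all(st != "M")))
    }
    list(min = res_min, max = res_max, resolutions = n_res,
         placements = placements)
  }

  top_status <- status[node]
  if (top_status == "A") {
    # everything under the node carries the marked state
    if (forced_split_at_top) {
      return(recurse(node, TRUE))
    }
    return(list(min = 1L, max = 1L, resolutions = 1,
                placements = list(tips_under(node))))
  }
  if (top_status == "U") {
    return(list(min = 0L, max = 0L, resolutions = 1, placements = list()))
  }
  recurse(node, TRUE)
}

min_placements <- function(st, a_kids, u_kids, tips_under, forced) {
  if (!length(a_kids)) return(list())
  if (!forced || any(st == "M")) {
    # one grouped clade of all A/U children
    return(list(unlist(lapply(c(a_kids, u_kids), tips_under))))
  }
  if (length(a_kids) == 1L || length(u_kids) > 0L) {
    return(list(unlist(lapply(c(a_kids, u_kids), tips_under))))
  }
  list(tips_under(a_kids[1]),
       unlist(lapply(a_kids[-1], tips_under)))
}

#' Loss-count range under a single constrained intron gain (Dollo)
#'
#' Given one intron gain at `gain_node`, the Dollo minimum number of losses
#' is the number of maximal intron-lacking subtrees below the gain node
#' (unknown tips assigned whichever state minimizes the count). On trees
#' with polychotomies the count depends on how each polychotomy is resolved;
#' the range over all binary resolutions is returned, by exhaustive
#' enumeration up to `resolution_cap` resolutions and by an exact
#' per-polychotomy closed form beyond it (loss counts are additive across
#' polychotomies).
#'
#' @param tree Rooted [ape::phylo], polychotomies allowed.
#' @param tip_states Named logical (`TRUE` present / `FALSE` absent /
#'   `NA` unknown) or a data frame with columns `taxon`, `present`.
#' @param gain_node Node at which the single gain is placed (tip/node label
#'   or node number); must be ancestral to every intron-bearing tip.
#' @param resolution_cap Enumeration budget (default 10000).
#' @return A list: `min`, `max`, `placements` (tip sets under each loss
#'   edge of one minimizing scenario), `resolutions` (number of distinct
#'   polychotomy resolutions the range spans).
#' @export
min_losses_single_gain <- function(tree, tip_states, gain_node,
                                   resolution_cap = 10000) {
  states <- as_tip_states(tree, tip_states)
  node <- resolve_node(tree, gain_node)
  present_tips <- which(states[tree$tip.label])
  outside <- setdiff(present_tips, subtree_tips(tree, node))
  if (length(outside)) {
    abort(sprintf("Intron-bearing tip(s) outside the gain node's subtree: %s.",
                  paste(tree$tip.label[outside], collapse = ", ")),
          class = "cctrace_model_violation")
  }
  out <- event_range(tree, states, node, marked = FALSE,
                     resolution_cap = resolution_cap,
                     forced_split_at_top = TRUE)
  list(min = out$min, max = out$max, placements = out$placements,
       resolutions = out$resolutions)
}

#' Minimum number of independent intron gains with no losses
#'
#' Each maximal intron-bearing subtree requires one gain; over polychotomy
#' resolutions, intron-bearing children of a polychotomy can be united into
#' a single clade, so the minimum over resolutions is reported.
#'
#' @inheritParams min_losses_single_gain
#' @return A list: `gains`, `placements` (tip sets under each gain), `max`
#'   (gain count when no polychotomy resolution unites any clades),
#'   `resolutions`.
#' @export
min_gains_no_loss <- function(tree, tip_states, resolution_cap = 10000) {
  states <- as_tip_states(tree, tip_states)
  root <- length(tree$tip.label) + 1L
  out <- event_range(tree, states, root, marked = TRUE,
                     resolution_cap = resolution_cap,
                     forced_split_at_top = FALSE)
  list(gains = out$min, max = out$max, placements = out$placements,
       resolutions = out$resolutions)
}

#' Compare intron gain/loss scenarios by event counts
#'
#' One row per scenario: a single Dollo-constrained gain at each candidate
#' node (with the loss range over polychotomy resolutions) and the
#' free-gains/no-loss alternative. Counts only — this mirrors a parsimony
#' argument, not a likelihood computation.
#'
#' @inheritParams min_losses_single_gain
#' @param candidate_gain_nodes Vector of node labels/numbers for the
#'   single-gain model.
#' @return A tibble with columns `model`, `gain_node`, `gain_count`,
#'   `loss_count_min`, `loss_count_max`, `feasible`,
#'   `resolutions_enumerated`, `event_placements` (list-column).
#' @export
compare_scenarios <- function(tree, tip_states, candidate_gain_nodes,
                              resolution_cap = 10000) {
  if (!length(candidate_gain_nodes)) {
    abort("Need at least one candidate gain node.",
          class = "cctrace_input_error")
  }
  states <- as_tip_states(tree, tip_states)
  any_present <- any(states, na.rm = TRUE)
  single <- purrr::map(candidate_gain_nodes, function(gn) {
    res <- tryCatch(
      min_losses_single_gain(tree, states, gn, resolution_cap),
      cctrace_model_violation = function(e) NULL
    )
    feasible <- any_present && !is.null(res)
    tibble(
      model = "single_gain_at_node",
      gain_node = as.character(gn),
      gain_count = 1L,
      loss_count_min = if (feasible) res$min else NA_integer_,
      loss_count_max = if (feasible) res$max else NA_integer_,
      feasible = feasible,
      resolutions_enumerated = if (feasible) res$resolutions else NA_real_,
      event_placements = list(if (feasible) res$placements else list())
    )
  }) |> bind_rows()
  free <- min_gains_no_loss(tree, states, resolution_cap)
  bind_rows(single, tibble(
    model = "free_gains_no_loss",
    gain_node = NA_character_,
    gain_count = free$gains,
    loss_count_min = 0L, loss_count_max = 0L,
    feasible = any_present,
    resolutions_enumerated = free$resolutions,
    event_placements = list(free$placements)
  ))
}

#' Intron / co-conversion-tract co-occurrence
#'
#' 2x2 contingency table of intron presence against tract presence across
#' taxa scored for both, with a two-sided exact (hypergeometric) association
#' p-value and the list of discordant taxa (tract without intron, or intron
#' without tract). Tables with an empty margin are flagged degenerate and
#' given p = 1.
#'
#' @param intron_calls,cct_calls Named logical vectors (taxon -> state) or
#'   data frames with columns `taxon` and `present`.
#' @return A list of class `cooccurrence`: `table`, `p_value`, `degenerate`,
#'   `discordant` (tibble), `n`.
#' @export
cct_cooccurrence <- function(intron_calls, cct_calls) {
  to_named <- function(x) {
    if (is.data.frame(x)) setNames(as.logical(x$present), x$taxon) else x
  }
  intron_calls <- to_named(intron_calls)
  cct_calls <- to_named(cct_calls)
  taxa <- intersect(names(intron_calls), names(cct_calls))
  keep <- taxa[!is.na(intron_calls[taxa]) & !is.na(cct_calls[taxa])]
  if (length(keep) < 2L) {
    abort("Need both calls for at least 2 taxa.", class = "cctrace_input_error")
  }
  tab <- table(
    intron = factor(intron_calls[keep], levels = c(TRUE, FALSE)),
    cct = factor(cct_calls[keep], levels = c(TRUE, FALSE))
  )
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  discordant <- tibble(
    taxon = keep[intron_calls[keep] != cct_calls[keep]],
    intron = intron_calls[keep[intron_calls[keep] != cct_calls[keep]]],
    cct = cct_calls[keep[intron_calls[keep] != cct_calls[keep]]]
  )
  structure(
    list(table = tab, p_value = p, degenerate = degenerate,
         discordant = discordant, n = length(keep)),
    class = "cooccurrence"
  )
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf("<cooccurrence> n = %d, exact two-sided p = %.3g%s\n",
              x$n, x$p_value, if (x$degenerate) " (degenerate table)" else ""))
  print(x$table)
  if (nrow(x$discordant)) {
    cat("Discordant taxa:", paste(x$discordant$taxon, collapse = ", "), "\n")
  }
  invisible(x)
}
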