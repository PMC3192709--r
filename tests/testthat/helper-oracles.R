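# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

BASES4 <- c("A", "C", "G", "T")

# Exhaustive ORF scan: every ATG, paired with the first in-frame stop.
oracle_orf <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  best <- 0L
  best_start <- NA_integer_
  for (i in seq_len(max(0, n - 5))) {
    if (paste(chars[i:(i + 2)], collapse = "") != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      codon <- paste(chars[j:(j + 2)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        len <- j + 2L - i + 1L
        if (len > best) {
          best <- len
          best_start <- i
        }
        break
      }
      j <- j + 3L
    }
  }
  list(start = best_start, length = best)
}

# Minimum-change root states by enumerating every internal-node assignment.
oracle_root_states <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_sets <- lapply(tip_states[tree$tip.label], function(s) {
    if (s %in% BASES4) s else BASES4
  })
  grids <- rep(list(BASES4), nnode)
  assignments <- expand.grid(grids, stringsAsFactors = FALSE)
  cost_of <- function(internal) {
    state_of <- function(v) {
      if (v <= ntip) NULL else internal[[v - ntip]]
    }
    total <- 0L
    for (k in seq_len(nrow(tree$edge))) {
      p <- internal[[tree$edge[k, 1] - ntip]]
      child <- tree$edge[k, 2]
      if (child <= ntip) {
        if (!(p %in% tip_sets[[child]])) total <- total + 1L
      } else {
        if (p != internal[[child - ntip]]) total <- total + 1L
      }
    }
    total
  }
  costs <- apply(assignments, 1, function(row) cost_of(as.list(row)))
  root_states <- assignments[[1]][costs == min(costs)]
  sort(unique(root_states))
}

# All rooted binary resolutions of a multifurcating tree, built by
# sequential tip regrafting (independent of the package's split recursion).
# Trees are nested lists of tip labels.
phylo_to_nested <- function(tree, node = length(tree$tip.label) + 1L) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  lapply(kids, function(k) phylo_to_nested(tree, k))
}

resolve_nested <- function(x) {
  if (!is.list(x)) return(list(x))
  kid_options <- lapply(x, resolve_nested)
  combos <- expand.grid(lapply(kid_options, seq_along))
  out <- list()
  for (r in seq_len(nrow(combos))) {
    kids <- lapply(seq_along(kid_options),
                   function(i) kid_options[[i]][[combos[r, i]]])
    for (shape in binary_shapes(kids)) {
      out[[length(out) + 1L]] <- shape
    }
  }
  out
}

# all rooted binary trees over a list of subtrees, by leaf insertion over
# atomic indices (children are units: insertion never descends into them)
binary_shapes <- function(kids) {
  if (length(kids) == 1L) return(kids)
  lapply(shapes_over_indices(length(kids)), substitute_kids, kids = kids)
}

shapes_over_indices <- function(k) {
  shapes <- list(list(1L, 2L))
  if (k == 2L) return(shapes)
  for (i in 3:k) {
    new_shapes <- list()
    for (s in shapes) {
      for (ins in insert_everywhere(s, i)) {
        new_shapes[[length(new_shapes) + 1L]] <- ins
      }
    }
    shapes <- new_shapes
  }
  shapes
}

insert_everywhere <- function(tree, leaf) {
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (side in 1:2) {
      for (sub in insert_everywhere(tree[[side]], leaf)) {
        copy <- tree
        copy[[side]] <- sub
        out[[length(out) + 1L]] <- copy
      }
    }
  }
  out
}

substitute_kids <- function(shape, kids) {
  if (!is.list(shape)) return(kids[[shape]])
  list(substitute_kids(shape[[1]], kids), substitute_kids(shape[[2]], kids))
}

nested_tips <- function(x) {
  if (!is.list(x)) return(x)
  unlist(lapply(x, nested_tips))
}

nested_edges <- function(x) {
  # list of tip sets, one per edge (edge identified by its subtree)
  if (!is.list(x)) return(list(x))
  out <- list(nested_tips(x))
  c(out, unlist(lapply(x, nested_edges), recursive = FALSE))
}

# Dollo minimum losses on one resolved (nested) tree by enumerating subsets
# of candidate loss edges in increasing size. Candidate edges subtend no
# present tip; every absent tip must sit under a chosen edge.
oracle_losses_resolved <- function(nested, states) {
  # drop the first entry: it is the gain node itself, not an edge below it
  edge_sets <- nested_edges(nested)[-1]
  has_present <- vapply(edge_sets, function(tips)
    any(states[tips] %in% TRUE), logical(1))
  candidates <- edge_sets[!has_present]
  absent_tips <- names(states)[states %in% FALSE]
  absent_tips <- intersect(absent_tips, nested_tips(nested))
  if (!length(absent_tips)) return(0L)
  for (k in seq_along(candidates)) {
    for (pick in utils::combn(length(candidates), k, simplify = FALSE)) {
      covered <- unique(unlist(candidates[pick]))
      if (all(absent_tips %in% covered)) return(k)
    }
  }
  stop("no covering subset found")
}

# min/max Dollo losses over all polychotomy resolutions, gain at `node`.
oracle_loss_range <- function(tree, states, node) {
  nested <- phylo_to_nested(tree, node)
  if (!is.list(nested)) nested <- list(nested)
  counts <- vapply(resolve_nested(nested), function(res)
    oracle_losses_resolved(res, states), integer(1))
  c(min = min(counts), max = max(counts))
}

# Minimum gains with no losses: brute force over subsets of gain edges of a
# resolved tree; min over resolutions.
oracle_gains_resolved <- function(nested, states) {
  edges <- nested_edges(nested)
  has_absent <- vapply(edges, function(tips)
    any(states[tips] %in% FALSE), logical(1))
  candidates <- edges[!has_absent]
  present_tips <- names(states)[states %in% TRUE]
  present_tips <- intersect(present_tips, nested_tips(nested))
  if (!length(present_tips)) return(0L)
  for (k in seq_along(candidates)) {
    for (pick in utils::combn(length(candidates), k, simplify = FALSE)) {
      covered <- unique(unlist(candidates[pick]))
      if (all(present_tips %in% covered)) return(k)
    }
  }
  stop("no covering subset found")
}

oracle_min_gains <- function(tree, states) {
  nested <- phylo_to_nested(tree)
  counts <- vapply(resolve_nested(nested), function(res)
    oracle_gains_resolved(res, states), integer(1))
  min(counts)
}

# Two-sided exact hypergeometric association p-value for a 2x2 table.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]) # intron-present margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1]) # tract-present margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random multifurcating rooted tree over n tips (recursive partitioning),
# kept small enough for exhaustive resolution enumeration.
rand_polytree <- function(n, max_groups = 4) {
  labels <- paste0("t", seq_len(n))
  build <- function(tips) {
    if (length(tips) == 1L) return(tips)
    if (length(tips) == 2L) {
      return(paste0("(", tips[1], ",", tips[2], ")"))
    }
    g <- sample(2:min(max_groups, length(tips)), 1)
    grp <- sample(rep(seq_len(g), length.out = length(tips)))
    parts <- vapply(seq_len(g), function(i) build(tips[grp == i]),
                    character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(sample(labels)), ";"))
}

# number of binary resolutions of a multifurcating tree
n_resolutions <- function(tree) {
  ntip <- length(tree$tip.label)
  prod(vapply((ntip + 1L):(ntip + tree$Nnode), function(v) {
    k <- sum(tree$edge[, 1] == v)
    if (k <= 2) 1 else prod(seq(3, 2 * k - 3, by = 2))
  }, numeric(1)))
}

random_sequence <- function(n) paste(sample(BASES4, n, replace = TRUE),
                                     collapse = "")
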