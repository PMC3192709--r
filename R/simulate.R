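# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the homing/loss forward simulator
#'
#' Describes a forward simulation of exon evolution on a rooted phylogeny
#' under Jukes-Cantor substitution, punctuated by an explicit schedule of
#' intron events applied at branch midpoints:
#' \describe{
#'   \item{homing}{horizontal capture — the intron invades an intron-lacking
#'     recipient branch and the donor lineage's exon states are copied over
#'     the recipient's at every position in `[-L5, +L3]` around the
#'     insertion site (contiguous co-conversion, polarity outward from the
#'     insertion point).}
#'   \item{vertical_origin}{the intron appears on a branch with no
#'     co-conversion (models an acquisition whose tract is not simulated).}
#'   \item{retro_loss}{RNA-mediated loss — the intron is removed and every
#'     C-to-U edit site within `(0, retro_window]` that currently carries
#'     `C` is converted to `T`, the retroprocessing signature.}
#' }
#' Events are identified by the *child node* of the branch they sit on (tip
#' label, internal node label, or node number). The schedule is a data frame
#' with columns `kind`, `branch`, and optionally `donor` (another lineage,
#' or `"external"` with `donor_seq` set), `L5`, `L3`.
#'
#' @param tree A rooted [ape::phylo], a newick string, or an integer tip
#'   count (a Yule tree is then drawn under the seed).
#' @param seq_length Root exon length in bp (ignored when `root_seq` given).
#' @param root_seq Optional explicit root exon sequence.
#' @param rate Expected substitutions per site per unit branch length
#'   (Jukes-Cantor). Plant mitochondrial exons are near-invariant; 0 is the
#'   exact, noiseless regime.
#' @param insertion_point Ungapped exon position immediately 5' of the
#'   intron insertion site (default: the midpoint of the root sequence).
#' @param intron_length Intron length in bp (default 967).
#' @param orf_length Length of the endonuclease ORF embedded in the intron,
#'   stop codon included (default 840; 0 disables the ORF).
#' @param events Event schedule (see Details); `NULL` for none.
#' @param donor_seq External donor exon sequence for `donor = "external"`.
#' @param edit_sites Signed positions of C-to-U editing sites.
#' @param retro_window Downstream window (bp) for retroprocessing C-to-T
#'   conversion (default 600).
#' @param embed_primers Optional [primer_pair()]; the root sequence is then
#'   built to contain concrete footprints of both primers spanning the
#'   insertion site so the in-silico survey applies end-to-end.
#' @param intronless_amplicon Amplicon size (bp, primer-inclusive) between
#'   the embedded footprints (default 800).
#' @param seed Integer seed (mandatory; the single RNG stream for the run).
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, seq_length = 900, root_seq = NULL, rate = 0,
                       insertion_point = NULL, intron_length = 967,
                       orf_length = 840, events = NULL, donor_seq = NULL,
                       edit_sites = integer(), retro_window = 600,
                       embed_primers = NULL, intronless_amplicon = 800,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory.", class = "cctrace_config_error")
  }
  if (!is.null(events)) {
    events <- as_tibble(events)
    needed <- setdiff(c("kind", "branch"), names(events))
    if (length(needed)) {
      abort(sprintf("Event schedule lacks column(s): %s.",
                    paste(needed, collapse = ", ")),
            class = "cctrace_config_error")
    }
    if (!all(events$kind %in% c("homing", "vertical_origin", "retro_loss"))) {
      abort("Event kinds must be homing, vertical_origin or retro_loss.",
            class = "cctrace_config_error")
    }
    for (col in c("L5", "L3")) {
      if (!col %in% names(events)) events[[col]] <- 0L
      events[[col]] <- dplyr::coalesce(as.integer(events[[col]]), 0L)
      if (any(events[[col]] < 0)) {
        abort("Tract lengths L5/L3 must be >= 0.",
              class = "cctrace_config_error")
      }
    }
    if (!"donor" %in% names(events)) events$donor <- NA_character_
  }
  structure(
    list(tree = tree, seq_length = seq_length, root_seq = root_seq,
         rate = rate, insertion_point = insertion_point,
         intron_length = intron_length, orf_length = orf_length,
         events = events, donor_seq = donor_seq, edit_sites = edit_sites,
         retro_window = retro_window, embed_primers = embed_primers,
         intronless_amplicon = intronless_amplicon, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate an intron sequence carrying a single embedded ORF
#'
#' Returns a sequence of `intron_length` bp whose longest forward-strand ORF
#' (ATG-initiated, stop-terminated, stop included) is exactly `orf_length`
#' bp, with no longer ORF anywhere on the forward strand. The construction
#' keeps the ORF interior free of `A` outside the start codon (so no
#' spurious ATG or stop arises inside it) and scrubs ATG triplets from the
#' flanks, then verifies the result by an exhaustive frame scan.
#'
#' @param intron_length Total length (bp).
#' @param orf_length ORF length including the stop codon; divisible by 3 and
#'   at most `intron_length - 6`. 0 yields an unconstrained random sequence.
#' @param seed Integer seed.
#' @return A nucleotide string.
#' @export
embed_orf <- function(intron_length = 967, orf_length = 840, seed = 1) {
  if (orf_length == 0) {
    return(with_seed(seed,
      paste(sample(BASES, intron_length, replace = TRUE), collapse = "")))
  }
  if (orf_length %% 3 != 0 || orf_length > intron_length - 6) {
    abort("`orf_length` must be divisible by 3 and <= intron_length - 6.",
          class = "cctrace_config_error")
  }
  with_seed(seed, {
    for (attempt in 1:50) {
      flank_total <- intron_length - orf_length
      f5 <- sample.int(flank_total - 3L, 1L)
      f3 <- flank_total - f5
      interior <- paste(sample(c("C", "G", "T"),
                               orf_length - 6L, replace = TRUE),
                        collapse = "")
      orf <- paste0("ATG", interior, sample(STOP_CODONS, 1L))
      seq <- paste0(scrub_atg(random_dna(f5)), orf,
                    scrub_atg(random_dna(f3)))
      if (longest_orf(seq)$length == orf_length) return(seq)
    }
    abort("Could not realize the requested ORF geometry.",
          class = "cctrace_config_error")
  })
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

scrub_atg <- function(x) {
  while (grepl("ATG", x, fixed = TRUE)) x <- sub("ATG", "ATC", x, fixed = TRUE)
  x
}

resolve_node <- function(tree, x) {
  ntip <- length(tree$tip.label)
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > ntip + tree$Nnode) {
      abort(sprintf("Node %d out of range.", x), class = "cctrace_config_error")
    }
    return(x)
  }
  i <- match(x, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(x, tree$node.label)
    if (!is.na(j)) return(ntip + j)
  }
  abort(sprintf("Unknown branch/node '%s'.", x), class = "cctrace_config_error")
}

# Tips descending from a node (the node itself when it is a tip).
subtree_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, subtree_tips, tree = tree))
}

#' Simulate a ground-truthed intron homing/loss data set
#'
#' Evolves the root exon sequence tip-ward under Jukes-Cantor, applying the
#' configured homing, vertical-origin and retroprocessing-loss events at
#' branch midpoints in schedule order. Homing donors are snapshotted at
#' their own branch midpoints. The output bundles the resulting exon
#' alignment (gap-free, with the true root as coordinate reference), the
#' per-taxon intron sequence, the tree, and a truth table recording each
#' event's converted positions and loss-signature positions. Byte-identical
#' given the same configuration and seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `cox1_sim`: list with elements `locus`
#'   ([aligned_locus()]), `introns` (named character), `tree`, `truth`
#'   (tibble), `root_seq`, `insertion_point`, `config`.
#' @export
simulate_locus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    tree <- build_sim_tree(config$tree)
    rooted <- build_root_seq(config)
    root_chars <- rooted$chars
    L <- length(root_chars)
    ip <- as.integer(config$insertion_point %||% rooted$insertion_point %||%
                       (L %/% 2L))
    if (ip < 1L || ip >= L) {
      abort("`insertion_point` outside the root sequence.",
            class = "cctrace_config_error")
    }

    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    edges <- tree$edge
    elen <- tree$edge.length %||% rep(1, nrow(edges))
    # Jukes-Cantor via the uniformization identity: with probability
    # 1 - exp(-4d/3) a site is redrawn uniformly from all four bases
    # (possibly silently), giving P(observed change) = 3/4 (1 - exp(-4d/3)).
    # The redraw is state-independent, so per-half-branch draws can be fixed
    # up front and reused identically by the baseline and event passes.
    p_half <- 1 - exp(-4 * (config$rate * elen / 2) / 3)
    halves <- lapply(seq_len(nrow(edges)), function(k) {
      lapply(1:2, function(h) {
        hit <- which(stats::runif(L) < p_half[k])
        list(pos = hit, base = sample(BASES, length(hit), replace = TRUE))
      })
    })
    apply_half <- function(chars, mut) {
      if (length(mut$pos)) chars[mut$pos] <- mut$base
      chars
    }

    preorder <- order(match(edges[, 1], c(root, edges[, 2])))
    # baseline pass: no events, for donor midpoint snapshots
    base_mid <- vector("list", nrow(edges))
    node_seq <- vector("list", nnode)
    node_seq[[root]] <- root_chars
    for (k in preorder) {
      mid <- apply_half(node_seq[[edges[k, 1]]], halves[[k]][[1]])
      base_mid[[k]] <- mid
      node_seq[[edges[k, 2]]] <- apply_half(mid, halves[[k]][[2]])
    }

    events <- config$events
    edge_of <- function(node) which(edges[, 2] == node)
    ev_edges <- if (is.null(events)) integer() else
      vapply(events$branch, function(b) {
        e <- edge_of(resolve_node(tree, b))
        if (!length(e)) abort(sprintf("'%s' is the root; events need a branch.", b),
                              class = "cctrace_config_error")
        e
      }, integer(1))

    signed_index <- function(p) if (p > 0) ip + p else ip + p + 1L

    # event pass
    node_seq2 <- vector("list", nnode)
    intron_at <- rep(FALSE, nnode)
    node_seq2[[root]] <- root_chars
    truth <- list()
    for (k in preorder) {
      parent <- edges[k, 1]; child <- edges[k, 2]
      chars <- apply_half(node_seq2[[parent]], halves[[k]][[1]])
      has_intron <- intron_at[parent]
      for (i in which(ev_edges == k)) {
        ev <- events[i, ]
        if (ev$kind == "homing") {
          if (has_intron) {
            abort(sprintf("Homing onto intron-bearing branch '%s'.", ev$branch),
                  class = "cctrace_config_error")
          }
          donor_chars <- if (identical(ev$donor, "external")) {
            if (is.null(config$donor_seq)) {
              abort("External homing donor requires `donor_seq`.",
                    class = "cctrace_config_error")
            }
            strsplit(normalize_seq(config$donor_seq), "")[[1]]
          } else {
            de <- edge_of(resolve_node(tree, ev$donor))
            if (!length(de)) abort("Donor cannot be the root.",
                                   class = "cctrace_config_error")
            base_mid[[de]]
          }
          tract <- c(if (ev$L5 > 0) -(seq_len(min(ev$L5, ip))),
                     if (ev$L3 > 0) seq_len(min(ev$L3, L - ip)))
          idx <- vapply(tract, signed_index, integer(1))
          converted <- tract[donor_chars[idx] != chars[idx]]
          chars[idx] <- donor_chars[idx]
          has_intron <- TRUE
          truth[[length(truth) + 1L]] <- tibble(
            event = length(truth) + 1L, kind = "homing",
            branch = as.character(ev$branch), L5 = ev$L5, L3 = ev$L3,
            converted = list(sort(converted)), loss_positions = list(integer())
          )
        } else if (ev$kind == "vertical_origin") {
          has_intron <- TRUE
          truth[[length(truth) + 1L]] <- tibble(
            event = length(truth) + 1L, kind = "vertical_origin",
            branch = as.character(ev$branch), L5 = 0L, L3 = 0L,
            converted = list(integer()), loss_positions = list(integer())
          )
        } else { # retro_loss
          if (!has_intron) {
            abort(sprintf("retro_loss on intron-lacking branch '%s'.", ev$branch),
                  class = "cctrace_config_error")
          }
          sites <- config$edit_sites
          sites <- sites[sites > 0 & sites <= config$retro_window]
          idx <- vapply(sites, signed_index, integer(1))
          conv <- sites[chars[idx] == "C"]
          chars[vapply(conv, signed_index, integer(1))] <- "T"
          has_intron <- FALSE
          truth[[length(truth) + 1L]] <- tibble(
            event = length(truth) + 1L, kind = "retro_loss",
            branch = as.character(ev$branch), L5 = 0L, L3 = 0L,
            converted = list(integer()), loss_positions = list(sort(conv))
          )
        }
      }
      intron_at[child] <- has_intron
      node_seq2[[child]] <- apply_half(chars, halves[[k]][[2]])
    }

    tip_seqs <- vapply(seq_len(ntip),
                       function(i) paste(node_seq2[[i]], collapse = ""),
                       character(1))
    intron_present <- intron_at[seq_len(ntip)]
    intron_seq <- if (any(intron_present)) {
      embed_orf(config$intron_length, config$orf_length,
                seed = sample.int(.Machine$integer.max, 1L))
    } else NULL

    locus <- aligned_locus(
      taxon = tree$tip.label, sequence = tip_seqs,
      insertion_column = ip, intron_present = intron_present,
      reference = paste(root_chars, collapse = "")
    )
    structure(
      list(
        locus = locus,
        introns = if (is.null(intron_seq)) character() else
          setNames(rep(intron_seq, sum(intron_present)),
                   tree$tip.label[intron_present]),
        tree = tree,
        truth = if (length(truth)) bind_rows(truth) else tibble(
          event = integer(), kind = character(), branch = character(),
          L5 = integer(), L3 = integer(), converted = list(),
          loss_positions = list()),
        root_seq = paste(root_chars, collapse = ""),
        insertion_point = ip,
        config = config
      ),
      class = "cox1_sim"
    )
  })
}

build_sim_tree <- function(tree) {
  if (inherits(tree, "phylo")) {
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
    if (is.null(tree)) abort("Could not parse newick tree.",
                             class = "cctrace_config_error")
  } else if (is.numeric(tree) && length(tree) == 1L) {
    tree <- ape::rphylo(as.integer(tree), birth = 1, death = 0)
  } else {
    abort("`tree` must be a phylo, a newick string, or a tip count.",
          class = "cctrace_config_error")
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

build_root_seq <- function(config) {
  if (!is.null(config$root_seq)) {
    return(list(chars = strsplit(normalize_seq(config$root_seq), "")[[1]],
                insertion_point = NULL))
  }
  L <- config$seq_length
  chars <- strsplit(random_dna(L), "")[[1]]
  ip <- NULL
  pair <- config$embed_primers
  if (!is.null(pair)) {
    amp <- config$intronless_amplicon
    margin <- 20L
    if (L < amp + 2L * margin) {
      abort("`seq_length` too short to embed the primer footprints.",
            class = "cctrace_config_error")
    }
    fwd <- instantiate_iupac(pair$forward)
    rev_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(instantiate_iupac(pair$reverse))))
    s <- margin + 1L
    e <- s + amp - 1L
    chars[s:(s + nchar(fwd) - 1L)] <- strsplit(fwd, "")[[1]]
    chars[(e - nchar(rev_rc) + 1L):e] <- strsplit(rev_rc, "")[[1]]
    ip <- (s + e) %/% 2L
  }
  list(chars = chars, insertion_point = ip)
}

IUPAC_CHOICES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# A concrete realization of a degenerate IUPAC primer (first listed base:
# deterministic, so embedded footprints are reproducible without RNG use).
instantiate_iupac <- function(x) {
  paste(vapply(strsplit(x, "")[[1]],
               function(ch) IUPAC_CHOICES[[ch]][1], character(1)),
        collapse = "")
}

#' @export
print.cox1_sim <- function(x, ...) {
  cat(sprintf("<cox1_sim> %d tips, %d bp exon, %d event(s), %d intron-bearing taxa\n",
              nrow(x$locus), nchar(x$root_seq), nrow(x$truth),
              sum(x$locus$intron_present)))
  invisible(x)
}

#' Full genomic sequences from a simulation
#'
#' Intron-bearing taxa get the intron inserted at the insertion point;
#' others are their exon sequence. The natural input to [survey_introns()].
#'
#' @param sim A `cox1_sim` from [simulate_locus()].
#' @return Named character vector of ungapped sequences.
#' @export
genomic_sequences <- function(sim) {
  ip <- sim$insertion_point
  setNames(vapply(seq_len(nrow(sim$locus)), function(i) {
    exon <- sim$locus$sequence[i]
    tx <- sim$locus$taxon[i]
    if (isTRUE(sim$locus$intron_present[i])) {
      paste0(substr(exon, 1L, ip), sim$introns[[tx]],
             substr(exon, ip + 1L, nchar(exon)))
    } else exon
  }, character(1)), sim$locus$taxon)
}
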