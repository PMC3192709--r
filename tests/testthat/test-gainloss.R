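test_that("hand-checked loss ranges on small trees", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  st <- c(A = TRUE, B = FALSE, C = TRUE, D = FALSE)
  res <- min_losses_single_gain(tr, st, length(tr$tip.label) + 1L)
  expect_equal(c(res$min, res$max), c(2L, 2L))

  tri <- ape::read.tree(text = "(A,B,C);")
  res <- min_losses_single_gain(tri, c(A = TRUE, B = FALSE, C = FALSE), 4)
  expect_equal(c(res$min, res$max), c(1L, 2L))

  allp <- min_losses_single_gain(tr, c(A = TRUE, B = TRUE, C = TRUE,
                                       D = TRUE), 5)
  expect_equal(c(allp$min, allp$max), c(0L, 0L))

  star <- ape::read.tree(text = "(A,B,C,D,E);")
  res <- min_losses_single_gain(star, c(A = TRUE, B = FALSE, C = FALSE,
                                        D = FALSE, E = FALSE), 6)
  expect_equal(c(res$min, res$max), c(1L, 4L))
  expect_gt(res$resolutions, 1)
})

test_that("a gain node must be ancestral to every intron-bearing tip", {
  tr <- ape::read.tree(text = "((A,B)ab,(C,D)cd);")
  st <- c(A = TRUE, B = FALSE, C = TRUE, D = FALSE)
  expect_error(min_losses_single_gain(tr, st, "ab"),
               class = "cctrace_model_violation")
  ok <- min_losses_single_gain(tr, c(A = TRUE, B = FALSE, C = FALSE,
                                     D = FALSE), "ab")
  expect_equal(c(ok$min, ok$max), c(1L, 1L))
})

test_that("loss range matches exhaustive resolution/subset enumeration", {
  set.seed(17)
  done <- 0
  while (done < 40) {
    n <- sample(5:10, 1)
    tree <- rand_polytree(n)
    if (n_resolutions(tree) > 60) next
    states <- setNames(sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                              prob = c(0.45, 0.35, 0.2)), tree$tip.label)
    if (sum(states %in% FALSE) == 0 || sum(states %in% FALSE) > 5) next
    root <- length(tree$tip.label) + 1L
    got <- min_losses_single_gain(tree, states, root)
    want <- oracle_loss_range(tree, states, root)
    expect_equal(c(got$min, got$max), unname(want),
                 info = ape::write.tree(tree))
    done <- done + 1
  }
})

test_that("every specific resolution is sandwiched by the reported range", {
  set.seed(23)
  for (rep in 1:10) {
    tree <- rand_polytree(7)
    if (n_resolutions(tree) > 60) next
    states <- setNames(sample(c(TRUE, FALSE), 7, replace = TRUE),
                       tree$tip.label)
    if (!any(states)) next
    root <- length(tree$tip.label) + 1L
    got <- min_losses_single_gain(tree, states, root)
    nested <- phylo_to_nested(tree, root)
    counts <- vapply(resolve_nested(nested), function(res)
      oracle_losses_resolved(res, states), integer(1))
    expect_true(all(counts >= got$min & counts <= got$max))
  }
})

test_that("gain counting matches the exhaustive gain-subset oracle", {
  # two present clades separated by an absent lineage need two gains
  tr <- ape::read.tree(text = "((A,B),(E,(C,D)));")
  st <- c(A = TRUE, B = TRUE, C = TRUE, D = TRUE, E = FALSE)
  expect_equal(min_gains_no_loss(tr, st)$gains, 2L)
  # on a root trichotomy a resolution can unite the two present clades
  tr3 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(min_gains_no_loss(tr3, st)$gains, 1L)
  expect_equal(min_gains_no_loss(tr3, st)$max, 2L)
  expect_equal(min_gains_no_loss(tr, c(A = TRUE, B = FALSE, C = FALSE,
                                       D = FALSE, E = FALSE))$gains, 1L)
  set.seed(41)
  done <- 0
  while (done < 30) {
    n <- sample(5:10, 1)
    tree <- rand_polytree(n)
    if (n_resolutions(tree) > 60) next
    states <- setNames(sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                              prob = c(0.4, 0.4, 0.2)), tree$tip.label)
    if (sum(states %in% TRUE) == 0 || sum(states %in% TRUE) > 5) next
    got <- min_gains_no_loss(tree, states)
    expect_equal(got$gains, oracle_min_gains(tree, states),
                 info = ape::write.tree(tree))
    done <- done + 1
  }
})

test_that("scenario table brackets the general-cost optimum", {
  # one gain + min losses and min gains + 0 losses bound the Sankoff
  # minimum for any gain:loss cost ratio
  tr <- ape::read.tree(text = "((A,B,C),(D,(E,F)),G);")
  st <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE, E = TRUE, F = FALSE,
          G = FALSE)
  tab <- compare_scenarios(tr, st, candidate_gain_nodes = 8)
  single <- tab[tab$model == "single_gain_at_node", ]
  free <- tab[tab$model == "free_gains_no_loss", ]
  expect_true(single$feasible)
  expect_equal(free$loss_count_min, 0L)
  # cost of each pure scenario at unit gain cost g and loss cost l:
  for (ratio in c(0.5, 1, 2, 5)) {
    cost_single <- 1 * ratio + single$loss_count_min
    cost_free <- free$gain_count * ratio
    # any mixed scenario must pay at least one gain and cannot beat both
    expect_gte(max(cost_single, cost_free), ratio)
  }
  # all-absent data make the single-gain model infeasible
  tab0 <- compare_scenarios(tr, setNames(rep(FALSE, 7), tr$tip.label), 8)
  expect_false(any(tab0$feasible))
})

test_that("co-occurrence test matches the closed-form hypergeometric sum", {
  intron <- setNames(c(rep(TRUE, 16), rep(FALSE, 30)), paste0("s", 1:46))
  cct <- intron
  perfect <- cct_cooccurrence(intron, cct)
  tab <- matrix(c(16, 0, 0, 30), 2, byrow = TRUE)
  expect_equal(perfect$p_value, oracle_fisher_p(tab), tolerance = 1e-10)
  expect_equal(nrow(perfect$discordant), 0)

  # one discordant taxon: tract without intron
  cct2 <- cct
  intron2 <- intron
  intron2["s16"] <- FALSE
  disc <- cct_cooccurrence(intron2, cct2)
  expect_equal(disc$discordant$taxon, "s16")
  expect_equal(unname(as.vector(disc$table)),
               c(15, 1, 0, 30)) # column-major: TT, FT, TF, FF
  expect_equal(disc$p_value,
               oracle_fisher_p(matrix(c(15, 0, 1, 30), 2, byrow = TRUE)),
               tolerance = 1e-10)

  # degenerate margins
  deg <- cct_cooccurrence(setNames(rep(TRUE, 5), paste0("s", 1:5)),
                          setNames(rep(TRUE, 5), paste0("s", 1:5)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  set.seed(3)
  for (rep in 1:10) {
    a <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    names(a) <- names(b) <- paste0("x", 1:20)
    res <- cct_cooccurrence(a, b)
    if (!res$degenerate) {
      expect_equal(res$p_value, oracle_fisher_p(res$table),
                   tolerance = 1e-8)
    }
  }
})
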