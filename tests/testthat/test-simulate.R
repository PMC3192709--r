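fixed_tree <- "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);"

test_that("rate zero with no events conserves the root everywhere", {
  cfg <- sim_config(tree = fixed_tree, seq_length = 300, rate = 0, seed = 3)
  sim <- simulate_locus(cfg)
  expect_true(all(sim$locus$sequence == sim$root_seq))
  expect_true(all(!sim$locus$intron_present))
  expect_equal(nrow(sim$truth), 0)
})

test_that("homing copies the donor tract and marks the recipient subtree", {
  set.seed(21)
  root <- random_sequence(300)
  donor <- root
  # donor differs at +27 and +35 (and nowhere else)
  for (p in c(27, 35)) {
    i <- 150 + p
    substr(donor, i, i) <- setdiff(BASES4, substr(root, i, i))[1]
  }
  cfg <- sim_config(tree = fixed_tree, root_seq = root, rate = 0,
                    insertion_point = 150, donor_seq = donor,
                    events = data.frame(kind = "homing", branch = "D",
                                        donor = "external", L5 = 0, L3 = 35),
                    seed = 8)
  sim <- simulate_locus(cfg)
  expect_equal(sim$locus$intron_present,
               sim$locus$taxon == "D")
  expect_equal(sim$truth$converted[[1]], c(27L, 35L))
  d <- sim$locus$sequence[sim$locus$taxon == "D"]
  others <- sim$locus$sequence[sim$locus$taxon != "D"]
  expect_true(all(others == root))
  diffs <- which(strsplit(d, "")[[1]] != strsplit(root, "")[[1]])
  expect_equal(diffs, 150 + c(27, 35))
})

test_that("homing onto an internal branch marks the whole subtree", {
  cfg <- sim_config(tree = "((A:1,B:1)ab:1,(C:1,D:1)cd:1);", rate = 0,
                    events = data.frame(kind = "homing", branch = "ab",
                                        donor = "C", L5 = 0, L3 = 20),
                    seq_length = 200, seed = 5)
  sim <- simulate_locus(cfg)
  expect_equal(sort(sim$locus$taxon[sim$locus$intron_present]), c("A", "B"))
  expect_equal(sort(names(sim$introns)), c("A", "B"))
})

test_that("retroprocessing loss removes the intron and converts edit sites", {
  root <- paste(rep("A", 300), collapse = "")
  substr(root, 170, 170) <- "C" # +20 relative to insertion point 150
  substr(root, 250, 250) <- "C" # +100
  cfg <- sim_config(tree = "((A:1,B:1)ab:1,(C:1,(D:1,E:1)de:1):1);",
                    root_seq = root, rate = 0, insertion_point = 150,
                    events = data.frame(
                      kind = c("vertical_origin", "retro_loss"),
                      branch = c("ab", "A"), donor = NA,
                      L5 = 0, L3 = 0),
                    edit_sites = c(20L, 100L, -30L), retro_window = 600,
                    seed = 2)
  sim <- simulate_locus(cfg)
  expect_equal(sim$locus$intron_present,
               sim$locus$taxon == "B")
  a <- sim$locus$sequence[sim$locus$taxon == "A"]
  expect_equal(substr(a, 170, 170), "T")
  expect_equal(substr(a, 250, 250), "T")
  expect_equal(sim$truth$loss_positions[[2]], c(20L, 100L))
  # upstream edit sites and non-C sites are untouched
  expect_equal(substr(a, 121, 121), substr(root, 121, 121))
})

test_that("illegal event placements are config errors", {
  base <- function(events) {
    sim_config(tree = fixed_tree, seq_length = 200, rate = 0,
               events = events, seed = 1)
  }
  expect_error(
    simulate_locus(base(data.frame(
      kind = c("homing", "homing"), branch = c("D", "D"),
      donor = c("A", "A"), L5 = 0, L3 = 10))),
    class = "cctrace_config_error")
  expect_error(
    simulate_locus(base(data.frame(kind = "retro_loss", branch = "D",
                                   donor = NA, L5 = 0, L3 = 0))),
    class = "cctrace_config_error")
  expect_error(
    simulate_locus(base(data.frame(kind = "homing", branch = "Z",
                                   donor = "A", L5 = 0, L3 = 10))),
    class = "cctrace_config_error")
  expect_error(sim_config(tree = fixed_tree, seed = 1,
                          events = data.frame(kind = "homing", branch = "D",
                                              L5 = -1, L3 = 5)),
               class = "cctrace_config_error")
  expect_error(sim_config(tree = fixed_tree), class = "cctrace_config_error")
})

test_that("identical configurations are byte-identical across runs", {
  cfg <- sim_config(tree = 8, seq_length = 900, rate = 0.01,
                    embed_primers = primer_pair(),
                    events = data.frame(kind = "vertical_origin",
                                        branch = "t1", donor = NA,
                                        L5 = 0, L3 = 0),
                    seed = 99)
  s1 <- simulate_locus(cfg)
  s2 <- simulate_locus(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_locus(sim_config(tree = 8, seq_length = 900, rate = 0.01,
                                  embed_primers = primer_pair(),
                                  seed = 100))
  expect_false(identical(s1$locus$sequence, s3$locus$sequence))
})

test_that("pairwise divergence follows the Jukes-Cantor expectation", {
  # two tips separated by total path 2t: expected fraction of differing
  # sites is 3/4 (1 - exp(-8 rt / 3)); check the mean over replicates
  # against a 3-SD binomial envelope
  rate <- 0.05
  L <- 400
  reps <- 120
  p_exp <- 0.75 * (1 - exp(-8 * rate / 3))
  diffs <- vapply(seq_len(reps), function(i) {
    sim <- simulate_locus(sim_config(tree = "(A:1,B:1);", seq_length = L,
                                     rate = rate, seed = 1000 + i))
    mean(strsplit(sim$locus$sequence[1], "")[[1]] !=
           strsplit(sim$locus$sequence[2], "")[[1]])
  }, numeric(1))
  se <- sqrt(p_exp * (1 - p_exp) / (L * reps))
  expect_lt(abs(mean(diffs) - p_exp), 3 * se)
})

test_that("truth-table conversions equal observed differences at rate zero", {
  set.seed(77)
  for (L3 in c(10, 35, 81)) {
    root <- random_sequence(300)
    donor <- root
    for (p in seq(3, 120, by = 3)) {
      i <- 150 + p
      substr(donor, i, i) <- setdiff(BASES4, substr(root, i, i))[1]
    }
    sim <- simulate_locus(sim_config(
      tree = fixed_tree, root_seq = root, rate = 0, insertion_point = 150,
      donor_seq = donor,
      events = data.frame(kind = "homing", branch = "D", donor = "external",
                          L5 = 0, L3 = L3),
      seed = L3))
    d <- sim$locus$sequence[sim$locus$taxon == "D"]
    observed <- which(strsplit(d, "")[[1]] != strsplit(root, "")[[1]]) - 150L
    expect_equal(sim$truth$converted[[1]], observed)
    expect_true(all(sim$truth$converted[[1]] <= L3))
  }
})
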