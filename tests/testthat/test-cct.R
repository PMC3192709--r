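# Builds a locus from explicit signed-position overrides on a constant
# background (AAA...), mirroring how footprints are described in the field.
override_locus <- function(n_focal = 3, n_lacking = 4, width = 200,
                           ins = 100, focal_ov = list(), lacking_ov = list()) {
  anc <- rep("A", width)
  anc[seq(2, width, by = 2)] <- "G" # avoid an all-A background
  idx <- function(p) if (p > 0) ins + p else ins + p + 1
  taxa <- c(paste0("F", seq_len(n_focal)), paste0("L", seq_len(n_lacking)))
  seqs <- vapply(taxa, function(tx) {
    chars <- anc
    ovs <- if (startsWith(tx, "F")) focal_ov else lacking_ov[[tx]] %||% list()
    for (o in ovs) chars[idx(o[[1]])] <- o[[2]]
    paste(chars, collapse = "")
  }, character(1))
  aligned_locus(taxa, seqs, insertion_column = ins,
                intron_present = startsWith(taxa, "F"),
                reference = paste(anc, collapse = ""))
}

test_that("diagnostic sites require a shared derived focal state", {
  locus <- override_locus(
    focal_ov = list(list(12, "T"), list(35, "C"), list(-20, "T")),
    lacking_ov = list()
  )
  anc <- reconstruct_ancestor(locus)
  sites <- call_diagnostic_sites(locus, anc, paste0("F", 1:3))
  expect_setequal(sites$position, c(12, 35, -20))
  expect_true(all(!sites$homoplasy_flag))
  # a site where only part of the clade is derived is not diagnostic
  locus2 <- override_locus(focal_ov = list(list(12, "T")))
  m <- locus_matrix(locus2)
  seqs <- locus2$sequence
  substr(seqs[1], signed_to_column(locus2, 12), signed_to_column(locus2, 12)) <- "C"
  locus2$sequence <- seqs
  sites2 <- call_diagnostic_sites(locus2, reconstruct_ancestor(locus2),
                                  paste0("F", 1:3))
  expect_equal(nrow(sites2), 0)
})

test_that("derived states recurring in intron-lacking taxa are flagged", {
  locus <- override_locus(
    focal_ov = list(list(-11, "C"), list(35, "T")),
    lacking_ov = list(L2 = list(list(-11, "C")))
  )
  anc <- reconstruct_ancestor(locus)
  sites <- call_diagnostic_sites(locus, anc, paste0("F", 1:3))
  expect_true(sites$homoplasy_flag[sites$position == -11])
  expect_false(sites$homoplasy_flag[sites$position == 35])
  rep <- cct_bounds(sites)
  expect_equal(rep$lower_bound_3prime, 35)
  expect_equal(rep$lower_bound_5prime, 0) # flagged -11 contributes nothing
  # a laxer occurrence threshold unflags the singleton
  sites2 <- call_diagnostic_sites(locus, anc, paste0("F", 1:3),
                                  homoplasy_threshold = 2)
  expect_false(sites2$homoplasy_flag[sites2$position == -11])
})

test_that("focal clades containing intron-lacking taxa are rejected", {
  locus <- override_locus()
  anc <- reconstruct_ancestor(locus)
  expect_error(call_diagnostic_sites(locus, anc, c("F1", "L1")),
               class = "cctrace_input_error")
  expect_error(call_diagnostic_sites(locus, anc, c("F1", "nope")),
               class = "cctrace_input_error")
})

test_that("site classes: edit sites and codon-position synonymy", {
  locus <- override_locus(
    focal_ov = list(list(20, "T"), list(27, "T"), list(26, "T"))
  )
  anc <- reconstruct_ancestor(locus)
  sites <- call_diagnostic_sites(locus, anc, paste0("F", 1:3),
                                 edit_sites = 20, reading_frame = 1)
  expect_equal(sites$site_class[sites$position == 20], "edit_site")
  # frame 1 at +1 means +27 is a third codon position, +26 is not
  expect_equal(sites$site_class[sites$position == 27], "synonymous")
  expect_equal(sites$site_class[sites$position == 26], "other")
  sites2 <- call_diagnostic_sites(locus, anc, paste0("F", 1:3))
  expect_true(all(sites2$site_class[sites2$position != 20] == "other"))
})

test_that("endpoint upper bound needs donor-retained evidence", {
  locus <- override_locus(
    n_lacking = 5,
    focal_ov = list(list(42, "T"), list(63, "C")),
    lacking_ov = list(L5 = list(list(70, "T")))
  )
  # L5 acts as the donor-group representative, but is intron-lacking here;
  # rebuild with an intron-bearing donor instead
  locus$intron_present[locus$taxon == "L5"] <- TRUE
  anc <- reconstruct_ancestor(locus)
  sites <- call_diagnostic_sites(locus, anc, paste0("F", 1:3))
  no_donor <- cct_bounds(sites)
  expect_equal(no_donor$lower_bound_3prime, 63)
  expect_equal(no_donor$upper_bound_3prime, Inf)
  with_donor <- cct_bounds(sites, locus = locus,
                           focal_clade = paste0("F", 1:3),
                           ancestor = anc, donor_group = "L5")
  expect_equal(with_donor$endpoint_interval,
               c(lower = 63, upper = 70))
})

test_that("no diagnostic sites give zero bounds and an unbounded interval", {
  locus <- override_locus()
  sites <- call_diagnostic_sites(locus, reconstruct_ancestor(locus),
                                 paste0("F", 1:3))
  rep <- cct_bounds(sites)
  expect_equal(rep$lower_bound_3prime, 0)
  expect_equal(rep$lower_bound_5prime, 0)
  expect_equal(unname(rep$endpoint_interval), c(0, Inf))
})

test_that("retro verdicts follow downstream edit-site states", {
  locus <- override_locus(
    n_lacking = 3,
    focal_ov = list(list(20, "T")),
    lacking_ov = list(L2 = list(list(20, "T")),
                      L3 = list(list(20, "N")))
  )
  # ancestral C at the +20 edit site
  seqs <- locus$sequence
  ref <- attr(locus, "frame")$reference
  col <- signed_to_column(locus, 20)
  substr(ref, col, col) <- "C"
  for (i in which(locus$taxon %in% c("L1"))) substr(seqs[i], col, col) <- "C"
  locus$sequence <- seqs
  attr(locus, "frame") <- coord_frame(ref, 100)
  anc <- reconstruct_ancestor(locus)
  expect_equal(anc$state[anc$position == 20], "C")
  expect_equal(retro_signature(locus, "L1", anc, 20)$verdict, "no_signature")
  expect_equal(retro_signature(locus, "L2", anc, 20)$verdict, "retro_signature")
  expect_equal(retro_signature(locus, "L3", anc, 20)$verdict, "indeterminate")
  expect_equal(retro_signature(locus, "F1", anc, 20)$verdict, "indeterminate")
  # upstream edit sites are never informative
  expect_equal(retro_signature(locus, "L2", anc, -20)$verdict, "indeterminate")
})

test_that("tract retention in an intron-lacking taxon is recognized", {
  fx <- make_fixtures("cynomorium_loss")
  sub <- fx$locus[fx$locus$taxon %in% fx$sites_taxa, ]
  anc <- reconstruct_ancestor(sub)
  sites <- call_diagnostic_sites(sub, anc, fx$focal_clade,
                                 edit_sites = fx$edit_sites)
  rep <- cct_bounds(sites)
  verdicts <- vapply(fx$locus$taxon, function(tx)
    as.logical(intron_loss_with_cct(fx$locus, tx, rep)), logical(1))
  expect_equal(names(verdicts)[verdicts], "Cynomorium_songaricum")
  # a taxon matching 8 of 9 sites fails, with the mismatch reported
  seqs <- fx$locus$sequence
  i <- which(fx$locus$taxon == "Cynomorium_songaricum")
  col <- signed_to_column(fx$locus, 35)
  substr(seqs[i], col, col) <- "C" # revert +35 to ancestral
  fx$locus$sequence <- seqs
  res <- intron_loss_with_cct(fx$locus, "Cynomorium_songaricum", rep)
  expect_false(as.logical(res))
  expect_equal(attr(res, "mismatches")$position, 35L)
})
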