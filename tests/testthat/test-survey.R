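# A template with exact cox1-3/cox1-6 footprints spaced so the inclusive
# product size is `amplicon`, with `pad` bases either side.
primer_template <- function(amplicon = 800, pad = 25, insert = NULL,
                            seed = 5) {
  pair <- primer_pair()
  fwd <- chartr("Y", "C", pair$forward)
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pair$reverse)))
  set.seed(seed)
  middle_len <- amplicon - nchar(fwd) - nchar(rev_rc)
  middle <- random_sequence(middle_len)
  if (!is.null(insert)) {
    at <- middle_len %/% 2
    middle <- paste0(substr(middle, 1, at), insert,
                     substr(middle, at + 1, middle_len))
  }
  paste0(random_sequence(pad), fwd, middle, rev_rc, random_sequence(pad))
}

test_that("amplicons are sized inclusive of both primer footprints", {
  expect_equal(insilico_pcr(primer_template(800))$length, 800)
  insert <- random_sequence(967)
  expect_equal(insilico_pcr(primer_template(800, insert = insert))$length,
               800 + 967)
  expect_equal(nrow(insilico_pcr(random_sequence(500))), 0)
})

test_that("degenerate primer positions follow the IUPAC table", {
  probe <- function(template) {
    nrow(insilico_pcr(paste0("GGGG", template, "GGGG",
                             "TTTTTTTTTT", "GGAATTGG"),
                      primer_pair("CAY", "CCAATTCC")))
  }
  expect_equal(probe("CAC"), 1)
  expect_equal(probe("CAT"), 1)
  expect_equal(probe("CAA"), 0)
})

test_that("a mismatch budget rescues imperfect primer sites", {
  template <- primer_template(800)
  mutated <- template
  substr(mutated, 30, 30) <- if (substr(template, 30, 30) == "A") "C" else "A"
  expect_equal(nrow(insilico_pcr(mutated)), 0)
  expect_equal(insilico_pcr(mutated, max_mismatches = 1)$length, 800)
})

test_that("gel classification separates the published size classes", {
  expect_equal(classify_presence(800, 800, 500), "absent")
  expect_equal(classify_presence(1767, 800, 500), "present")
  expect_equal(classify_presence(1000, 800, 500), "ambiguous")
  expect_equal(classify_presence(NA, 800, 500), "no_amplicon")
  expect_equal(classify_presence(c(820, 1800), 800), c("absent", "present"))
})

test_that("extract_intron recovers the inserted segment exactly", {
  set.seed(9)
  ref <- random_sequence(400)
  intron <- random_sequence(967)
  with_intron <- paste0(substr(ref, 1, 180), intron, substr(ref, 181, 400))
  got <- extract_intron(with_intron, ref, 180)
  expect_equal(got$length, 967)
  expect_equal(got$intron, intron)
  expect_equal(extract_intron(ref, ref, 180)$length, 0)
  # oracle: the insert is whatever an alignment-free prefix/suffix diff isolates
  prefix <- 180
  suffix <- nchar(ref) - prefix
  oracle_insert <- substr(with_intron, prefix + 1,
                          nchar(with_intron) - suffix)
  expect_equal(got$intron, oracle_insert)
  # flank corruption beyond the budget is an error
  bad <- with_intron
  substr(bad, 5, 7) <- "NNN"
  expect_error(extract_intron(bad, ref, 180),
               class = "cctrace_extraction_error")
  expect_equal(extract_intron(bad, ref, 180, max_mismatches = 3)$length, 967)
})

test_that("longest_orf agrees with the exhaustive scanner", {
  expect_equal(longest_orf("ATGTAA")$length, 6)
  expect_equal(longest_orf("CCCCCC")$length, 0)
  set.seed(31)
  for (rep in 1:40) {
    seq <- random_sequence(500)
    expect_equal(longest_orf(seq)$length, oracle_orf(seq)$length)
  }
})

test_that("embed_orf realizes the requested ORF geometry", {
  for (s in c(1, 7, 99)) {
    intron <- embed_orf(967, 840, seed = s)
    expect_equal(nchar(intron), 967)
    expect_equal(oracle_orf(intron)$length, 840)
  }
  expect_equal(nchar(embed_orf(100, 0, 3)), 100)
  expect_error(embed_orf(100, 99, 1), class = "cctrace_config_error")
  expect_error(embed_orf(100, 98, 1), class = "cctrace_config_error")
  expect_identical(embed_orf(967, 840, 4), embed_orf(967, 840, 4))
})

test_that("survey_introns ties amplicons, extraction and ORFs together", {
  cfg <- sim_config(tree = "((A:1,B:1):1,(C:1,D:1):1);", rate = 0,
                    embed_primers = primer_pair(), seq_length = 900,
                    events = data.frame(kind = "homing", branch = "C",
                                        donor = "A", L5 = 0, L3 = 35),
                    seed = 12)
  sim <- simulate_locus(cfg)
  calls <- survey_introns(genomic_sequences(sim),
                          exon_reference = sim$root_seq,
                          insertion_point = sim$insertion_point)
  expect_equal(calls$classification,
               ifelse(sim$locus$intron_present, "present", "absent"))
  expect_equal(calls$amplicon_length[calls$classification == "absent"][1], 800)
  expect_equal(calls$amplicon_length[calls$classification == "present"],
               800 + 967)
  expect_equal(calls$intron_length[calls$classification == "present"], 967)
  expect_equal(calls$orf_length[calls$classification == "present"], 840)
})
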