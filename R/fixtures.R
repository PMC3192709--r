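# Toy data sets encoding published co-conversion footprint patterns as
# explicit state overrides on a conserved random background. Backgrounds are
# seeded, overrides are fixed, so every fixture is deterministic in content
# at the positions that matter regardless of seed.

FIXTURE_NAMES <- c("solanoideae9", "acanthaceae", "musaceae", "brunfelsia",
                   "cynomorium_loss", "retro_loss")

# Canonical short 3' tract: seven differences within the first 20 bp
# downstream of the insertion site, the farthest being the +20 C-to-U
# editing-site difference (ancestral C, derived T).
CANONICAL_TRACT <- tibble::tibble(
  position = c(3L, 6L, 9L, 12L, 15L, 18L, 20L),
  ancestral = c("A", "G", "T", "C", "A", "G", "C"),
  derived = c("G", "A", "C", "T", "G", "A", "T")
)

#' Build a named toy data set with a known footprint pattern
#'
#' Each fixture is a small exon alignment (220 columns, insertion point
#' after column 110) in which a focal intron-containing clade carries a
#' published footprint pattern over a conserved background, together with a
#' tree, a presence/absence table and an edit-site list:
#' \describe{
#'   \item{solanoideae9}{the canonical seven-difference 20-bp tract plus the
#'     two additional downstream differences at +27 (G to A) and +35 (C to
#'     T), and two homoplastic sites (-11, +60) whose derived state recurs
#'     in intron-lacking taxa.}
#'   \item{acanthaceae}{canonical tract plus shared derived changes at +30,
#'     +35 and +54.}
#'   \item{musaceae}{a monocot backbone in which the two Musaceae carry
#'     eudicot-signature states at +42, +45, +57, +60 and +63, with a
#'     eudicot donor group differing from the monocot native state at the
#'     next informative position +70.}
#'   \item{brunfelsia}{canonical tract plus a single downstream reversion at
#'     +81 (T to C) and a homoplastic +60.}
#'   \item{cynomorium_loss}{the solanoideae9 pattern plus one taxon lacking
#'     the intron yet carrying all nine derived states — the
#'     loss-with-tract-retention case. `sites_taxa` names the taxa from
#'     which diagnostic sites should be called (the loss candidate is
#'     screened against the resulting report, not used to call it).}
#'   \item{retro_loss}{one intron-lacking taxon carrying T at the +20
#'     editing site (the retroprocessing signature) next to taxa retaining
#'     the ancestral C.}
#' }
#'
#' @param name One of the fixture names above.
#' @param seed Seed for the conserved background sequence (default 1234);
#'   footprint positions and states are fixed overrides.
#' @return A list: `name`, `locus` ([aligned_locus()]), `tree`
#'   ([ape::phylo]), `states` (tibble), `edit_sites`, `focal_clade`,
#'   `donor_group`, `sites_taxa`, `loss_candidate`, `description`.
#' @export
make_fixtures <- function(name, seed = 1234) {
  if (!name %in% FIXTURE_NAMES) {
    abort(sprintf("Unknown fixture '%s'. Options: %s.", name,
                  paste(FIXTURE_NAMES, collapse = ", ")),
          class = "cctrace_input_error")
  }
  switch(name,
    solanoideae9 = fixture_solanoideae(seed, with_loss_taxon = FALSE),
    cynomorium_loss = fixture_solanoideae(seed, with_loss_taxon = TRUE),
    acanthaceae = fixture_acanthaceae(seed),
    musaceae = fixture_musaceae(seed),
    brunfelsia = fixture_brunfelsia(seed),
    retro_loss = fixture_retro_loss(seed)
  )
}

FIXTURE_LEN <- 220L
FIXTURE_INS <- 110L

fixture_scaffold <- function(seed, anc_overrides) {
  anc <- with_seed(seed, strsplit(random_dna(FIXTURE_LEN), "")[[1]])
  for (i in seq_len(nrow(anc_overrides))) {
    anc[signed_idx(anc_overrides$position[i])] <- anc_overrides$ancestral[i]
  }
  anc
}

signed_idx <- function(p) {
  ifelse(p > 0, FIXTURE_INS + p, FIXTURE_INS + p + 1L)
}

apply_overrides <- function(chars, positions, states) {
  chars[signed_idx(positions)] <- states
  chars
}

assemble_fixture <- function(name, seed, anc_overrides, taxa, newick,
                             edit_sites, focal_clade, donor_group = NULL,
                             sites_taxa = NULL, loss_candidate = NULL,
                             description = "") {
  anc <- fixture_scaffold(seed, anc_overrides)
  seqs <- vapply(seq_len(nrow(taxa)), function(i) {
    ov <- taxa$overrides[[i]]
    chars <- if (nrow(ov)) apply_overrides(anc, ov$position, ov$state) else anc
    paste(chars, collapse = "")
  }, character(1))
  locus <- aligned_locus(
    taxon = taxa$taxon, sequence = seqs,
    insertion_column = FIXTURE_INS,
    intron_present = taxa$present,
    reference = paste(anc, collapse = "")
  )
  list(
    name = name,
    locus = locus,
    tree = ape::read.tree(text = newick),
    states = tibble(taxon = taxa$taxon, present = taxa$present),
    edit_sites = edit_sites,
    focal_clade = focal_clade,
    donor_group = donor_group,
    sites_taxa = sites_taxa %||% taxa$taxon,
    loss_candidate = loss_candidate,
    description = description
  )
}

ov <- function(position, state) tibble(position = position, state = state)
no_ov <- function() tibble(position = integer(), state = character())

fixture_solanoideae <- function(seed, with_loss_taxon) {
  extended <- tibble(position = c(27L, 35L),
                     ancestral = c("G", "C"), derived = c("A", "T"))
  homopl <- tibble(position = c(-11L, 60L),
                   ancestral = c("T", "G"), derived = c("C", "T"))
  anc_overrides <- bind_rows(
    CANONICAL_TRACT[c("position", "ancestral")],
    extended[c("position", "ancestral")],
    homopl[c("position", "ancestral")]
  )
  derived_all <- bind_rows(
    ov(CANONICAL_TRACT$position, CANONICAL_TRACT$derived),
    ov(extended$position, extended$derived),
    ov(homopl$position, homopl$derived)
  )
  derived_clean <- bind_rows(
    ov(CANONICAL_TRACT$position, CANONICAL_TRACT$derived),
    ov(extended$position, extended$derived)
  )
  focal <- c("Hyoscyamus_niger", "Physochlaina_orientalis",
             "Scopolia_carniolica", "Mandragora_officinarum")
  taxa <- tibble(
    taxon = c(focal, "Atropa_belladonna", "Nicotiana_tabacum",
              "Solanum_lycopersicum", "Capsicum_annuum", "Petunia_axillaris"),
    present = c(rep(TRUE, 4), rep(FALSE, 5)),
    overrides = c(rep(list(derived_all), 4),
                  list(no_ov()),
                  list(ov(-11L, "C")),   # homoplastic carrier at -11
                  list(no_ov()),
                  list(ov(60L, "T")),    # homoplastic carrier at +60
                  list(no_ov()))
  )
  newick <- paste0(
    "((Hyoscyamus_niger,Physochlaina_orientalis,Scopolia_carniolica),",
    "Mandragora_officinarum,Atropa_belladonna,",
    "(Nicotiana_tabacum,Petunia_axillaris,",
    "(Solanum_lycopersicum,Capsicum_annuum))",
    if (with_loss_taxon) ",Cynomorium_songaricum" else "", ");"
  )
  sites_taxa <- taxa$taxon
  loss_candidate <- NULL
  if (with_loss_taxon) {
    taxa <- bind_rows(taxa, tibble(
      taxon = "Cynomorium_songaricum", present = FALSE,
      overrides = list(derived_clean)
    ))
    loss_candidate <- "Cynomorium_songaricum"
  }
  assemble_fixture(
    name = if (with_loss_taxon) "cynomorium_loss" else "solanoideae9",
    seed = seed, anc_overrides = anc_overrides, taxa = taxa,
    newick = newick, edit_sites = 20L, focal_clade = focal,
    sites_taxa = sites_taxa, loss_candidate = loss_candidate,
    description = paste(
      "Canonical 20-bp tract (7 differences incl. the +20 edit site) plus",
      "+27/+35; homoplastic -11/+60 flagged; minimum 3' tract 35 bp."
    )
  )
}

fixture_acanthaceae <- function(seed) {
  extra <- tibble(position = c(30L, 35L, 54L),
                  ancestral = c("C", "C", "G"), derived = c("A", "T", "A"))
  anc_overrides <- bind_rows(CANONICAL_TRACT[c("position", "ancestral")],
                             extra[c("position", "ancestral")])
  derived <- bind_rows(ov(CANONICAL_TRACT$position, CANONICAL_TRACT$derived),
                       ov(extra$position, extra$derived))
  focal <- c("Sanchezia_speciosa", "Justicia_americana",
             "Barleria_cristata", "Thunbergia_alata")
  taxa <- tibble(
    taxon = c(focal, "Sesamum_indicum", "Olea_europaea",
              "Antirrhinum_majus", "Salvia_officinalis"),
    present = c(rep(TRUE, 4), rep(FALSE, 4)),
    overrides = c(rep(list(derived), 4), rep(list(no_ov()), 4))
  )
  newick <- paste0(
    "(((Sanchezia_speciosa,Justicia_americana,Barleria_cristata),",
    "Thunbergia_alata),(Sesamum_indicum,Olea_europaea,",
    "Antirrhinum_majus,Salvia_officinalis));"
  )
  assemble_fixture(
    name = "acanthaceae", seed = seed, anc_overrides = anc_overrides,
    taxa = taxa, newick = newick, edit_sites = 20L, focal_clade = focal,
    description = "Canonical tract plus +30/+35/+54; minimum 3' tract 54 bp."
  )
}

fixture_musaceae <- function(seed) {
  extra <- tibble(position = c(42L, 45L, 57L, 60L, 63L),
                  ancestral = c("C", "G", "C", "G", "A"),
                  derived = c("A", "T", "T", "T", "G"))
  retained <- tibble(position = 70L, ancestral = "G", donor = "T")
  anc_overrides <- bind_rows(CANONICAL_TRACT[c("position", "ancestral")],
                             extra[c("position", "ancestral")],
                             retained[c("position", "ancestral")])
  derived_focal <- bind_rows(
    ov(CANONICAL_TRACT$position, CANONICAL_TRACT$derived),
    ov(extra$position, extra$derived)
  )
  derived_donor <- bind_rows(derived_focal, ov(70L, "T"))
  focal <- c("Musa_acuminata", "Musella_lasiocarpa")
  donors <- c("Hydrocotyle_vulgaris", "Polygala_myrtifolia")
  taxa <- tibble(
    taxon = c(focal, donors, "Zingiber_officinale", "Maranta_leuconeura",
              "Oryza_sativa", "Elaeis_guineensis"),
    present = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 4)),
    overrides = c(rep(list(derived_focal), 2), rep(list(derived_donor), 2),
                  rep(list(no_ov()), 4))
  )
  newick <- paste0(
    "((((Musa_acuminata,Musella_lasiocarpa),Zingiber_officinale,",
    "Maranta_leuconeura),(Oryza_sativa,Elaeis_guineensis)),",
    "(Hydrocotyle_vulgaris,Polygala_myrtifolia));"
  )
  assemble_fixture(
    name = "musaceae", seed = seed, anc_overrides = anc_overrides,
    taxa = taxa, newick = newick, edit_sites = 20L, focal_clade = focal,
    donor_group = donors,
    description = paste(
      "Eudicot-signature states at +42/+45/+57/+60/+63 on a monocot",
      "backbone; donors differ at +70 where Musaceae retain the native",
      "state: endpoint interval (63, 70)."
    )
  )
}

fixture_brunfelsia <- function(seed) {
  extra <- tibble(position = c(60L, 81L),
                  ancestral = c("G", "T"), derived = c("T", "C"))
  anc_overrides <- bind_rows(CANONICAL_TRACT[c("position", "ancestral")],
                             extra[c("position", "ancestral")])
  derived <- bind_rows(ov(CANONICAL_TRACT$position, CANONICAL_TRACT$derived),
                       ov(extra$position, extra$derived))
  focal <- "Brunfelsia_jamaicensis"
  taxa <- tibble(
    taxon = c(focal, "Brunfelsia_americana", "Brunfelsia_uniflora",
              "Nicotiana_tabacum", "Petunia_axillaris",
              "Solanum_lycopersicum"),
    present = c(TRUE, rep(FALSE, 5)),
    overrides = c(list(derived), list(no_ov()), list(no_ov()),
                  list(ov(60L, "T")),  # +60 is homoplastic in the family
                  list(no_ov()), list(no_ov()))
  )
  newick <- paste0(
    "(((Brunfelsia_jamaicensis,Brunfelsia_americana,Brunfelsia_uniflora),",
    "(Nicotiana_tabacum,Petunia_axillaris)),Solanum_lycopersicum);"
  )
  assemble_fixture(
    name = "brunfelsia", seed = seed, anc_overrides = anc_overrides,
    taxa = taxa, newick = newick, edit_sites = 20L, focal_clade = focal,
    description = paste(
      "Canonical tract plus a single +81 reversion (T to C); +60 flagged",
      "homoplastic; minimum 3' tract 81 bp."
    )
  )
}

fixture_retro_loss <- function(seed) {
  anc_overrides <- CANONICAL_TRACT[c("position", "ancestral")]
  derived <- ov(CANONICAL_TRACT$position, CANONICAL_TRACT$derived)
  taxa <- tibble(
    taxon = c("Hyoscyamus_niger", "Scopolia_carniolica",
              "Nicotiana_tabacum", "Solanum_lycopersicum", "Datura_metel"),
    present = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    overrides = c(list(derived), list(derived), list(no_ov()),
                  list(no_ov()),
                  list(ov(20L, "T")))  # retroprocessing signature at +20
  )
  newick <- paste0(
    "((Hyoscyamus_niger,Scopolia_carniolica),Datura_metel,",
    "(Nicotiana_tabacum,Solanum_lycopersicum));"
  )
  assemble_fixture(
    name = "retro_loss", seed = seed, anc_overrides = anc_overrides,
    taxa = taxa, newick = newick, edit_sites = 20L,
    focal_clade = c("Hyoscyamus_niger", "Scopolia_carniolica"),
    loss_candidate = "Datura_metel",
    description = paste(
      "One intron-lacking taxon with T at the +20 editing site (ancestral",
      "C): retroprocessing signature; other intron-lacking taxa retain C."
    )
  )
}

#' Write a fixture bundle to plain-text files
#'
#' Writes `exons.fasta`, `tree.nwk`, `states.tsv` and `edit_sites.tsv`
#' under `dir`.
#'
#' @param fixture A bundle from [make_fixtures()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(fixture$locus, file.path(dir, "exons.fasta"))
  ape::write.tree(fixture$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(fixture$states, file.path(dir, "states.tsv"))
  readr::write_tsv(tibble(position = fixture$edit_sites, edited_base = "C"),
                   file.path(dir, "edit_sites.tsv"))
  invisible(dir)
}
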