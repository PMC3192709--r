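#' Pipeline configuration
#'
#' Exactly one of (a) input file paths (`alignment`, `states`, and
#' optionally `tree`, `edits`) with `insertion_column`, or (b) a
#' [sim_config()] in `simulation`, must be supplied.
#'
#' @param alignment,tree,states,edits Input file paths (FASTA / newick /
#'   TSV / TSV).
#' @param insertion_column 1-based alignment column immediately 5' of the
#'   insertion point (file-input mode).
#' @param simulation A [sim_config()] (simulation mode).
#' @param focal_clades Named list of taxon vectors; `NULL` derives one clade
#'   per maximal intron-bearing group from presence calls.
#' @param donor_group Optional donor taxon set for endpoint upper bounds.
#' @param primers A [primer_pair()] for the survey stage.
#' @param expected_intronless_length Expected intron-less amplicon (bp).
#' @param window Diagnostic scan window (bp).
#' @param gain_nodes Candidate gain nodes for [compare_scenarios()];
#'   `NULL` uses the tree root.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (and driving the
#'   simulation when in simulation mode).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignment = NULL, tree = NULL, states = NULL,
                            edits = NULL, insertion_column = NULL,
                            simulation = NULL, focal_clades = NULL,
                            donor_group = NULL, primers = primer_pair(),
                            expected_intronless_length = 800, window = 200,
                            gain_nodes = NULL, out_dir, seed = 1,
                            log_level = "info") {
  file_mode <- !is.null(alignment)
  sim_mode <- !is.null(simulation)
  if (file_mode == sim_mode) {
    abort("Supply exactly one of `alignment` (file mode) or `simulation`.",
          class = "cctrace_config_error")
  }
  if (file_mode) {
    if (is.null(states)) {
      abort("File mode requires `states`.", class = "cctrace_config_error")
    }
    if (is.null(insertion_column)) {
      abort("File mode requires `insertion_column`.",
            class = "cctrace_config_error")
    }
  }
  structure(
    list(alignment = alignment, tree = tree, states = states, edits = edits,
         insertion_column = insertion_column, simulation = simulation,
         focal_clades = focal_clades, donor_group = donor_group,
         primers = primers,
         expected_intronless_length = expected_intronless_length,
         window = window, gain_nodes = gain_nodes, out_dir = out_dir,
         seed = as.integer(seed), log_level = log_level),
    class = "pipeline_config"
  )
}

stage_log <- function(config, stage, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[cctrace:%s] %s", stage, sprintf(...)))
}

#' Run the full footprint pipeline
#'
#' ingest/simulate -> survey -> ancestral reconstruction -> diagnostic
#' sites and CCT bounds per focal clade -> retroprocessing screen ->
#' gain/loss scenario comparison -> flat-text reports. All outputs are TSV
#' plus a plain-text summary and a JSON run manifest (inputs, hashes, seed,
#' package version); no timestamps, so identical runs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulation)) {
    stage_log(config, "simulate", "seed %d", config$simulation$seed)
    sim <- simulate_locus(config$simulation)
    locus <- sim$locus
    tree <- sim$tree
    edit_sites <- config$simulation$edit_sites
    readr::write_tsv(
      sim$truth |>
        mutate(converted = map_chr(.data$converted, paste, collapse = ","),
               loss_positions = map_chr(.data$loss_positions, paste,
                                        collapse = ",")),
      file.path(config$out_dir, "truth.tsv"))
  } else {
    stage_log(config, "ingest", "alignment %s", config$alignment)
    sim <- NULL
    tree <- if (!is.null(config$tree)) read_tree(config$tree) else NULL
    states <- read_intron_states(config$states, tree = tree)
    if (!nrow(states)) {
      abort("States file is empty.", class = "cctrace_config_error")
    }
    locus <- read_alignment(config$alignment, config$insertion_column)
    locus$intron_present <- states$present[match(locus$taxon, states$taxon)]
    edit_sites <- if (!is.null(config$edits)) read_edit_sites(config$edits)
                  else integer()
  }

  # survey: real in-silico PCR when genomic sequences exist, otherwise
  # presence calls carried through from the states table
  if (!is.null(sim) && length(sim$introns) &&
      !is.null(config$simulation$embed_primers)) {
    stage_log(config, "survey", "in-silico PCR with %s", config$primers$name)
    calls <- survey_introns(
      genomic_sequences(sim), pair = config$primers,
      expected_intronless_length = config$expected_intronless_length,
      exon_reference = sim$root_seq, insertion_point = sim$insertion_point
    )
  } else {
    stage_log(config, "survey", "presence calls from states")
    calls <- tibble(
      taxon = locus$taxon, amplicon_length = NA_integer_,
      classification = dplyr::case_when(
        is.na(locus$intron_present) ~ "ambiguous",
        locus$intron_present ~ "present",
        TRUE ~ "absent"),
      intron_length = NA_integer_, orf_length = NA_integer_
    )
  }
  readr::write_tsv(calls, file.path(config$out_dir, "intron_calls.tsv"))

  stage_log(config, "cct", "window +/-%d bp", config$window)
  ancestor <- reconstruct_ancestor(locus, window = config$window)
  clades <- config$focal_clades %||% derive_focal_clades(locus, tree)
  reports <- imap(clades, function(clade, label) {
    sites <- call_diagnostic_sites(locus, ancestor, clade,
                                   edit_sites = edit_sites,
                                   window = config$window)
    rep <- cct_bounds(sites, locus = locus, focal_clade = clade,
                      ancestor = ancestor, donor_group = config$donor_group,
                      window = config$window)
    readr::write_tsv(tidy(rep),
                     file.path(config$out_dir,
                               sprintf("cct_report_%s.tsv", label)))
    rep
  })

  stage_log(config, "retro", "screening %d taxa", nrow(locus))
  retro <- retro_screen(locus, ancestor, edit_sites)
  readr::write_tsv(retro, file.path(config$out_dir, "retro_signatures.tsv"))

  stage_log(config, "gainloss", "scenario comparison")
  gainloss <- NULL
  if (!is.null(tree)) {
    gain_nodes <- config$gain_nodes %||% (length(tree$tip.label) + 1L)
    gainloss <- compare_scenarios(
      tree, tibble(taxon = locus$taxon, present = locus$intron_present),
      gain_nodes)
    readr::write_tsv(
      gainloss |>
        mutate(event_placements = map_chr(
          .data$event_placements,
          function(p) paste(map_chr(p, paste, collapse = ","),
                            collapse = ";"))),
      file.path(config$out_dir, "gainloss.tsv"))
  }

  write_summary(config, locus, clades, reports, retro, gainloss)
  write_manifest(config)
  stage_log(config, "done", "reports in %s", config$out_dir)
  invisible(list(locus = locus, sim = sim, ancestor = ancestor,
                 intron_calls = calls, cct_reports = reports, retro = retro,
                 gainloss = gainloss, out_dir = config$out_dir))
}

# Maximal intron-bearing tip groups (tree clades when a tree is given,
# otherwise one clade of all intron-bearing taxa).
derive_focal_clades <- function(locus, tree) {
  bearing <- locus$taxon[!is.na(locus$intron_present) & locus$intron_present]
  if (!length(bearing)) return(list())
  if (is.null(tree)) return(list(clade1 = bearing))
  states <- setNames(locus$intron_present, locus$taxon)[tree$tip.label]
  groups <- min_gains_no_loss(tree, setNames(locus$intron_present,
                                             locus$taxon))$placements
  groups <- map(groups, intersect, y = bearing)
  groups <- groups[lengths(groups) > 0]
  setNames(groups, paste0("clade", seq_along(groups)))
}

write_summary <- function(config, locus, clades, reports, retro, gainloss) {
  path <- file.path(config$out_dir, "summary.txt")
  lines <- c(
    "cctrace pipeline summary",
    sprintf("taxa: %d; intron-bearing: %d; unknown: %d",
            nrow(locus), sum(locus$intron_present, na.rm = TRUE),
            sum(is.na(locus$intron_present))),
    ""
  )
  for (label in names(reports)) {
    rep <- reports[[label]]
    up <- if (is.finite(rep$upper_bound_3prime))
      as.character(rep$upper_bound_3prime) else "unbounded"
    lines <- c(lines, sprintf(
      "%s (%s): %d diagnostic site(s), 3' tract >= %d bp, endpoint in (%d, %s)",
      label, paste(clades[[label]], collapse = ","),
      sum(!rep$sites$homoplasy_flag), rep$lower_bound_3prime,
      rep$lower_bound_3prime, up))
  }
  lines <- c(lines, "",
             sprintf("retroprocessing signatures: %d of %d intron-lacking taxa",
                     sum(retro$verdict == "retro_signature"),
                     sum(!is.na(locus$intron_present) & !locus$intron_present)))
  if (!is.null(gainloss)) {
    single <- dplyr::filter(gainloss, .data$model == "single_gain_at_node",
                            .data$feasible)
    if (nrow(single)) {
      lines <- c(lines, sprintf(
        "single gain at %s: %d-%d losses; free gains: %d, no losses",
        single$gain_node[1], single$loss_count_min[1],
        single$loss_count_max[1],
        gainloss$gain_count[gainloss$model == "free_gains_no_loss"]))
    }
  }
  writeLines(lines, path)
}

write_manifest <- function(config) {
  inputs <- purrr::compact(list(
    alignment = config$alignment, tree = config$tree,
    states = config$states, edits = config$edits))
  manifest <- list(
    package = "cctrace",
    version = as.character(utils::packageVersion("cctrace")),
    seed = config$seed,
    window = config$window,
    expected_intronless_length = config$expected_intronless_length,
    mode = if (is.null(config$simulation)) "files" else "simulation",
    inputs = inputs,
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list()
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
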