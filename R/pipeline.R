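# End-to-end orchestration: survey -> filter -> assign -> inventory ->
# Dollo reconstruction, as one reproducible, seeded run.

#' Run configuration
#'
#' Two entry modes: `"synthetic"` simulates clone libraries for a set of
#' taxa with known true inventories (the six surveyed lineages by default)
#' and runs the full chain against them; `"inventory"` skips sequence-level
#' work and runs the parsimony analyses on a supplied presence matrix.
#'
#' @param mode `"synthetic"` or `"inventory"`
#' @param taxa named list of true inventories (synthetic mode); defaults to
#'   the six comprehensively surveyed lineages with their reported gene sets
#' @param presence presence matrix or TSV path (inventory mode); defaults to
#'   the packaged lineage matrix
#' @param tree rooted `phylo` or Newick path; defaults to the accepted
#'   sarcopterygian topology (pruned to the available taxa)
#' @param hypotheses named list of alternative topologies to score with
#'   [compare_topologies()]; default the four turtle hypotheses
#' @param hypothesis_gene character state column scored across `hypotheses`
#' @param min_support,n_bootstrap,d_max assignment thresholds (bootstrap
#'   default follows the survey's 1,000 replicates; tests use smaller,
#'   documented sizes)
#' @param max_mismatch primer mismatch tolerance
#' @param sim a [sim_config()] (synthetic mode)
#' @param seed master seed
#' @param out_dir optional output directory for TSV/Newick reports
#' @return list of class `"hox_run_config"`
#' @export
hox_run_config <- function(mode = c("synthetic", "inventory"),
                           taxa = NULL, presence = NULL, tree = NULL,
                           hypotheses = turtle_hypotheses(),
                           hypothesis_gene = "C3",
                           min_support = 70, n_bootstrap = 1000,
                           d_max = 5, max_mismatch = 0,
                           sim = NULL, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(sim)) sim <- sim_config(seed = seed,
                                      max_mismatch = max_mismatch)
  if (is.null(taxa) && mode == "synthetic") taxa <- surveyed_taxa()
  if (is.character(presence)) {
    if (!file.exists(presence)) stop("presence matrix path does not exist: ",
                                     presence)
    presence <- read_presence_tsv(presence)
  }
  if (is.character(tree)) {
    if (!file.exists(tree)) stop("tree path does not exist: ", tree)
    tree <- ape::read.tree(tree)
  }
  structure(list(mode = mode, taxa = taxa, presence = presence, tree = tree,
                 hypotheses = hypotheses, hypothesis_gene = hypothesis_gene,
                 min_support = min_support, n_bootstrap = n_bootstrap,
                 d_max = d_max, max_mismatch = max_mismatch, sim = sim,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "hox_run_config")
}

#' True inventories of the six comprehensively surveyed lineages
#'
#' @return named list of gene-label vectors
#' @export
surveyed_taxa <- function() {
  d <- hox_lineage_deltas()
  keep <- c("lungfish", "caecilian", "salamander", "snake", "turtle",
            "crocodile")
  out <- lapply(keep, function(tx) {
    i <- match(tx, d$taxon)
    build_inventory(.split_genes(d$gains[i]), .split_genes(d$losses[i]))
  })
  stats::setNames(out, keep)
}

# collapse + filter every library of one taxon; returns validated locus
# representatives with frames, plus the exclusion/merge log
.filter_taxon <- function(clones, libraries) {
  frames <- stats::setNames(libraries$frame, libraries$library_id)
  loci <- list(); log <- list()
  for (lib in unique(clones$library_id)) {
    cl <- clones[clones$library_id == lib, , drop = FALSE]
    fr <- collapse_clones(cl)
    fr$frame <- unname(frames[lib])
    flt <- filter_library(fr)
    reps <- flt[flt$status == "distinct", , drop = FALSE]
    loci[[lib]] <- reps
    log[[lib]] <- flt[flt$status != "distinct", , drop = FALSE]
  }
  list(loci = do.call(rbind, loci), events = do.call(rbind, log))
}

#' Run the full survey pipeline
#'
#' Synthetic mode: evolves a reference panel, simulates the tiered
#' degenerate-PCR survey and clone libraries for every taxon, collapses and
#' filters each library with the allelic-variant/error rules, assigns every
#' validated locus to a Hox gene member, builds the presence matrix, scores
#' it against the ground truth, and reconstructs inventory evolution by
#' Dollo parsimony (plus the topology-hypothesis table). Inventory mode
#' runs only the parsimony stage on a supplied matrix. Reruns with the same
#' configuration and seed are identical.
#'
#' @param config a [hox_run_config()]
#' @return list with (mode-dependent) elements `panel`, `clones`, `loci`,
#'   `assignments`, `presence`, `recovery`, `reconstruction`,
#'   `hypothesis_table`, `log`
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "hox_run_config"))
  set.seed(config$seed)
  out <- list(config = config)
  if (config$mode == "inventory") {
    m <- config$presence %||% hox_presence_matrix()
    tree <- config$tree %||% sarcopterygian_tree()
    tree <- ape::keep.tip(tree, intersect(tree$tip.label, rownames(m)))
    m <- m[tree$tip.label, , drop = FALSE]
    out$presence <- m
    out$reconstruction <- reconstruct_ancestral(tree, m, "present")
    out$hypothesis_table <- .score_hypotheses(config)
  } else {
    primers <- hox_primer_table()
    roots <- hox_root_homeoboxes(primers)
    panel <- evolve_panel(default_guide_tree(), roots, config$sim, primers)
    out$panel <- panel
    acfg <- assign_config(min_support = config$min_support,
                          n_bootstrap = config$n_bootstrap,
                          d_max = config$d_max)
    inv <- list(); clones <- list(); loci <- list(); asg <- list()
    logs <- list()
    attach <- rep_len(default_guide_tree()$tip.label,
                      length(config$taxa))
    for (tx in names(config$taxa)) {
      tmpl <- make_templates(config$taxa[[tx]], roots, config$sim, primers,
                             seed = NULL, panel = panel,
                             attach_species =
                               attach[match(tx, names(config$taxa))])
      sim <- simulate_library(tmpl, primers, config$sim, taxon = tx,
                              seed = NULL)
      flt <- .filter_taxon(sim$clones, sim$libraries)
      ass <- assign_fragments(
        data.frame(sequence = flt$loci$sequence, frame = flt$loci$frame,
                   fragment_id = paste0(tx, ".", flt$loci$locus_id, ".",
                                        flt$loci$library_id)),
        panel, acfg, seed = config$seed + match(tx, names(config$taxa)))
      inv[[tx]] <- sort_genes(unique(stats::na.omit(ass$gene)))
      clones[[tx]] <- sim$clones
      loci[[tx]] <- flt$loci
      asg[[tx]] <- ass
      logs[[tx]] <- list(survey = attr(sim$survey, "log"),
                         filter = flt$events, truth = sim$truth)
    }
    out$clones <- clones
    out$loci <- loci
    out$assignments <- asg
    out$presence <- presence_matrix(inv)
    out$recovery <- recovery_report(out$presence, config$taxa)
    tree <- config$tree %||% sarcopterygian_tree()
    common <- intersect(tree$tip.label, names(inv))
    if (length(common) >= 2L) {
      tree <- ape::keep.tip(tree, common)
      out$reconstruction <- reconstruct_ancestral(
        tree, out$presence[tree$tip.label, , drop = FALSE], "present")
    }
    out$hypothesis_table <- .score_hypotheses(config)
    out$log <- logs
  }
  if (!is.null(config$out_dir)) .write_reports(out, config$out_dir)
  out
}

.score_hypotheses <- function(config) {
  if (is.null(config$hypotheses)) return(NULL)
  states <- hoxc3_amniote_states()
  compare_topologies(states, config$hypotheses, "present")
}

.write_reports <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  if (!is.null(out$presence)) write_presence_tsv(out$presence,
                                                 file.path(dir,
                                                           "presence.tsv"))
  if (!is.null(out$assignments))
    w(do.call(rbind, out$assignments), "assignments.tsv")
  if (!is.null(out$loci)) w(do.call(rbind, out$loci), "loci.tsv")
  if (!is.null(out$hypothesis_table)) w(out$hypothesis_table,
                                        "hypothesis_losses.tsv")
  if (!is.null(out$reconstruction)) {
    w(out$reconstruction$losses, "loss_events.tsv")
    ape::write.tree(out$reconstruction$tree, file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}
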