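# Synthetic-data generator: canonical root homeoboxes carrying the survey's
# primer motifs at fixed homeodomain coordinates, reference panels evolved on
# a guide tree, genomic templates for a chosen true inventory, and clone
# libraries with allelic variants and PCR errors drawn with known truth.

# ---- canonical root homeoboxes -------------------------------------------

# Homeodomain scaffold (60 aa). The recognition-helix WFQNRR block sits at
# residues 48-53 as in real homeodomains; anterior/posterior motif regions
# are laid out per paralogue group so that each designated primer matches its
# root with zero mismatches.
.HD_SCAFFOLD <- c(
  strsplit("RKRGR", "")[[1]],               # 1-5
  strsplit("GSNVAFSA", "")[[1]],            # 6-13
  strsplit("LELEKEFH", "")[[1]],            # 14-21
  strsplit("FNRYLTRRRRIEIAHSLCLSERQIKI", "")[[1]],  # 22-47
  strsplit("WFQNRRMK", "")[[1]],            # 48-55
  strsplit("WKKEN", "")[[1]]                # 56-60
)

# per-cluster residues at free positions, giving paralogous genes of one
# group distinct proteins (omitted for PG6, whose members are deliberately
# protein-identical and separable only at the nucleotide level)
.CLUSTER_POS <- c(26L, 32L, 38L, 44L, 57L, 59L)
.CLUSTER_RES <- list(
  A = c("S", "T", "V", "I", "N", "T"),
  B = c("A", "K", "D", "L", "E", "S"),
  C = c("G", "R", "Q", "F", "Y", "A"),
  D = c("P", "H", "E", "M", "Q", "G")
)

# paralogue-group-diagnostic residues inside the recognition-helix region,
# as in real homeodomains, so that amplicons confined to the conserved
# 14-55 window (e.g. HoxF1 products) still separate paralogue groups at the
# protein level; positions overlapping a group's own motif layout are
# simply overwritten by it
.PGVAR_POS <- c(24L, 27L, 34L, 37L, 40L, 43L, 46L)
.PGVAR_ALPHA <- strsplit("ADEFGHIKLMNPQRSTVY", "")[[1]]
.pgvar_residues <- function(pg) {
  .PGVAR_ALPHA[1L + (pg * 5L + seq_along(.PGVAR_POS) * 7L) %%
                 length(.PGVAR_ALPHA)]
}

# motif layouts: aa substitutions (position = residue index) and primer
# anchors (primer name, 0-based nt offset of its binding site start within
# the 180-nt homeobox)
.pg_layout <- function() {
  sub <- function(at, what) stats::setNames(strsplit(what, "")[[1]],
                                            seq(at, length.out = nchar(what)))
  list(
    PG1 = list(genes = c("A1", "B1", "C1", "D1"),
               mods = c(sub(4, "NFTTKQLT"), sub(12, "QTLELEKEFH")),
               anchors = list(c("HoxF1S", 9), c("HoxF1N1", 33),
                              c("HoxF1", 40), c("HoxR1", 141))),
    PG2 = list(genes = c("A2", "B2"),
               mods = c(sub(5, "RTAYTNTQ"), sub(13, "TLELEKEFH")),
               anchors = list(c("HoxF2S", 12), c("HoxF1N1", 33),
                              c("HoxF1", 40), c("HoxR1", 141))),
    PG3 = list(genes = c("A3", "B3", "C3", "D3"),
               mods = c(sub(6, "AYTSAQLV"), sub(14, "LELEKEFH"),
                        sub(29, "RPRRVEMA")),
               anchors = list(c("HoxF3S", 15), c("HoxF3S1", 84),
                              c("HoxF1", 40), c("HoxR1", 141)),
               skip_cluster_pos = 32L),
    PG4 = list(genes = c("A4", "B4", "C4", "D4"),
               mods = c(sub(5, "TAYTRQQV"), sub(13, "TLELEKEFH")),
               anchors = list(c("HoxF4S", 12), c("HoxF1", 40),
                              c("HoxR1", 141))),
    PG5ab = list(genes = c("A5", "B5"),
                 mods = c(sub(1, "GKRARTA"), sub(14, "LELEKEFH")),
                 anchors = list(c("HoxF5S", 0), c("HoxF1", 40),
                                c("HoxR1", 141))),
    PG5c = list(genes = "C5",
                mods = c(sub(2, "KRSRTSYT"), sub(14, "LDLEKEFH")),
                anchors = list(c("HoxFC5", 3), c("HoxR1", 141))),
    PG6 = list(genes = c("A6", "B6", "C6"),
               mods = c(sub(6, "QTYTRYQT"), sub(14, "LELEKEFH")),
               anchors = list(c("HoxF7S", 15), c("HoxF1N1", 33),
                              c("HoxF1", 40), c("HoxR1", 141)),
               protein_identical = TRUE),
    PG7 = list(genes = c("A7", "B7"),
               mods = c(sub(6, "QTYTRYQT"), sub(14, "LELEKEFH")),
               anchors = list(c("HoxF7S", 15), c("HoxF1N1", 33),
                              c("HoxF1", 40), c("HoxR1", 141))),
    PG8 = list(genes = c("B8", "C8", "D8"),
               mods = sub(14, "LELEKEFLFNP"),
               anchors = list(c("HoxF8N", 40), c("HoxF8", 46),
                              c("HoxF8S", 48), c("HoxR1", 141))),
    PG9 = list(genes = c("A9", "B9", "C9", "D9"),
               mods = c(sub(1, "TRKKRCPY"), sub(14, "LELEKEFLFNM")),
               anchors = list(c("HoxF9", 0), c("HoxF8N", 40),
                              c("HoxF8", 46), c("HoxF9S", 48),
                              c("HoxR1", 141))),
    PG10 = list(genes = c("A10", "B10", "C10", "D10"),
                mods = c(sub(1, "TRKKRCPYTKH"), sub(14, "LELEKEFLFNS")),
                anchors = list(c("HoxF9", 0), c("HoxF10S", 9),
                               c("HoxF8N", 40), c("HoxF8", 46),
                               c("HoxR1", 141))),
    PG11 = list(genes = c("A11", "C11", "D11"),
                mods = c(sub(1, "TRKKRCPY"), sub(15, "ELEREFFF")),
                anchors = list(c("HoxF9", 0), c("HoxF11", 42),
                               c("HoxR1", 141))),
    PG12c = list(genes = "C12",
                 mods = c(sub(1, "SRKKRKPY"), sub(9, "SKLQM"),
                          sub(14, "LELEKEAH")),
                 anchors = list(c("HoxF12", 0), c("HoxF12C", 15),
                                c("HoxR1", 141))),
    PG12d = list(genes = "D12",
                 mods = c(sub(1, "SRKKRKPY"), sub(9, "TKQQI"),
                          sub(14, "LELEKEAH")),
                 anchors = list(c("HoxF12", 0), c("HoxF12D", 15),
                                c("HoxR1", 141))),
    PG13a = list(genes = "A13",
                 mods = c(sub(1, "GRKKRVPY"), sub(13, "QLKELEREY"),
                          sub(48, "WFQNRRVK")),
                 anchors = list(c("HoxF13A", 0), c("HoxF13A1", 36),
                                c("HoxR13", 141))),
    PG13b = list(genes = "B13",
                 mods = c(sub(1, "GRKKRIPY"), sub(13, "QLKELENEY"),
                          sub(48, "WFQNRRVK")),
                 anchors = list(c("HoxF13B", 0), c("HoxF13B1", 36),
                                c("HoxR13", 141))),
    PG13cd = list(genes = c("C13", "D13"),
                  mods = c(sub(1, "GRKKRVPY"), sub(13, "QLKELENEY"),
                           sub(48, "WFQNRRVK")),
                  anchors = list(c("HoxF13A", 0), c("HoxF13B1", 36),
                                 c("HoxR13", 141))),
    PG14 = list(genes = "A14",
                mods = c(sub(1, "GRKKRVPY"), sub(14, "TSPGQNVA"),
                         sub(23, "ENRFLTPE"), sub(48, "WFQNRRVK")),
                anchors = list(c("HoxF13A", 0), c("HoxR14", 66),
                               c("HoxR13", 141)))
  )
}

# per-nt allowed base sets implied by a gene's primer anchors
.anchor_allowed <- function(anchors, primers) {
  allowed <- rep(list(c("A", "C", "G", "T")), 180L)
  for (a in anchors) {
    row <- primers[primers$name == a[[1]], ]
    if (nrow(row) != 1L) stop("unknown anchor primer: ", a[[1]])
    pat <- if (row$direction == "reverse") reverse_complement(row$sequence)
           else row$sequence
    off <- as.integer(a[[2]])
    pch <- strsplit(pat, "")[[1]]
    for (i in seq_along(pch)) {
      p <- off + i
      allowed[[p]] <- intersect(allowed[[p]], IUPAC_DNA[[pch[i]]])
      if (length(allowed[[p]]) == 0L)
        stop("conflicting primer anchors at homeobox position ", p)
    }
  }
  allowed
}

#' Canonical root homeobox sequences
#'
#' Builds one 180-nt homeobox (and its 60-residue homeodomain) per gene of
#' the 43-gene universe. Each root is a homeodomain scaffold carrying the
#' survey primers' protein motifs at fixed coordinates (the WFQNRR
#' recognition-helix block at residues 48-53), with codons chosen inside the
#' expansion sets of the primers designated to detect that gene, so every
#' designated primer matches its root exactly. Codon choices rotate with the
#' gene index, so paralogous genes differ at synonymous sites even where
#' their proteins agree (all of PG6, deliberately). HoxC5 is built divergent
#' from the general-tier primers and detectable only by its member-specific
#' primer, mirroring the survey's escalation case.
#'
#' These are synthetic stand-ins for real homeobox sequences: no GenBank
#' material is shipped, and a user-supplied real panel in the same format is
#' accepted everywhere a panel is taken.
#'
#' @param primers primer table (default packaged)
#' @return data.frame with columns `gene`, `aa` (60 residues), `nt` (180 nt)
#'   and attribute `"anchors"` (named list of anchor tables per gene)
#' @export
hox_root_homeoboxes <- function(primers = hox_primer_table()) {
  layouts <- .pg_layout()
  genes <- character(); aas <- character(); nts <- character()
  anchor_list <- list()
  gidx <- 0L
  for (ly in layouts) {
    aa0 <- .HD_SCAFFOLD
    aa0[.PGVAR_POS] <- .pgvar_residues(gene_pg(ly$genes[1]))
    for (p in names(ly$mods)) aa0[as.integer(p)] <- ly$mods[[p]]
    allowed <- .anchor_allowed(ly$anchors, primers)
    for (g in ly$genes) {
      gidx <- gidx + 1L
      aa <- aa0
      if (!isTRUE(ly$protein_identical) && length(ly$genes) > 1L) {
        keep <- setdiff(.CLUSTER_POS, ly$skip_cluster_pos %||% integer())
        cl <- gene_cluster(g)
        aa[keep] <- .CLUSTER_RES[[cl]][match(keep, .CLUSTER_POS)]
      }
      nt <- character(180L)
      for (i in seq_len(60L)) {
        cods <- codons_for(aa[i])
        ok <- vapply(cods, function(cd) {
          b <- strsplit(cd, "")[[1]]
          all(b[1] %in% allowed[[3 * i - 2]], b[2] %in% allowed[[3 * i - 1]],
              b[3] %in% allowed[[3 * i]])
        }, logical(1))
        valid <- cods[ok]
        if (length(valid) == 0L)
          stop("no codon for residue ", aa[i], " at position ", i,
               " satisfies the primer anchors of ", g)
        pick <- valid[1L + (gidx * 7L + i) %% length(valid)]
        nt[(3 * i - 2):(3 * i)] <- strsplit(pick, "")[[1]]
      }
      genes <- c(genes, g)
      aas <- c(aas, paste(aa, collapse = ""))
      nts <- c(nts, paste(nt, collapse = ""))
      anchor_list[[g]] <- ly$anchors
    }
  }
  ord <- order(match(genes, hox_universe()))
  out <- data.frame(gene = genes[ord], aa = aas[ord], nt = nts[ord],
                    stringsAsFactors = FALSE)
  attr(out, "anchors") <- anchor_list
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- simulation configuration --------------------------------------------

#' Simulation configuration for the synthetic survey
#'
#' @param seed integer seed controlling every random draw
#' @param rate substitution-rate multiplier applied to guide-tree branch
#'   lengths (expected substitutions per site at `rate = 1`)
#' @param kappa transition/transversion rate ratio of the K2P process
#' @param clone_mean mean of the zero-truncated Poisson clone count drawn
#'   per amplicon library
#' @param allele_prob probability that a locus carries a second allele
#'   (1-3 synonymous substitutions, at least two clones each)
#' @param error_prob per-clone probability of a PCR/sequencing error
#'   (1-2 non-synonymous substitutions, singleton)
#' @param allele_frac expected fraction of clones carrying the minor allele
#' @param taxon_divergence branch length separating a surveyed taxon's
#'   genome from the canonical roots
#' @param flank random genomic flank length (nt) on each side of the
#'   homeobox in a template
#' @param max_mismatch primer mismatch tolerance used by the in-silico PCR
#' @return list of class `"hox_sim_config"`
#' @export
sim_config <- function(seed = 1L, rate = 1, kappa = 2, clone_mean = 8,
                       allele_prob = 0.15, error_prob = 0.03,
                       allele_frac = 0.4, taxon_divergence = 0.05,
                       flank = 60L, max_mismatch = 0L) {
  stopifnot(allele_prob >= 0, allele_prob <= 1, error_prob >= 0,
            error_prob <= 1, kappa > 0, clone_mean > 0)
  structure(list(seed = as.integer(seed), rate = rate, kappa = kappa,
                 clone_mean = clone_mean, allele_prob = allele_prob,
                 error_prob = error_prob, allele_frac = allele_frac,
                 taxon_divergence = taxon_divergence, flank = as.integer(flank),
                 max_mismatch = as.integer(max_mismatch)),
            class = "hox_sim_config")
}

# zero-truncated Poisson draw
.rztpois <- function(n, lambda) {
  out <- stats::rpois(n, lambda)
  while (any(out == 0L)) out[out == 0L] <- stats::rpois(sum(out == 0L), lambda)
  out
}

# evolve one concrete sequence along a branch under K2P, restricted to the
# per-position allowed sets (primer-anchored positions stay compatible) and
# refusing in-frame stop codons
.evolve_k2p <- function(seq, t, kappa, allowed = NULL, frame_checked = TRUE) {
  if (t <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * t)   # per transversion target
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  tv_of <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
                T = c("A", "G"))
  u <- stats::runif(n)
  new <- ch
  hit_ts <- u < p_ts
  hit_tv1 <- !hit_ts & u < p_ts + p_tv
  hit_tv2 <- !hit_ts & !hit_tv1 & u < p_ts + 2 * p_tv
  new[hit_ts] <- ts_of[ch[hit_ts]]
  new[hit_tv1] <- vapply(ch[hit_tv1], function(b) tv_of[[b]][1], character(1))
  new[hit_tv2] <- vapply(ch[hit_tv2], function(b) tv_of[[b]][2], character(1))
  if (!is.null(allowed)) {
    viol <- which(new != ch & !mapply(function(b, s) b %in% s, new, allowed))
    new[viol] <- ch[viol]
  }
  if (frame_checked && n %% 3L == 0L) {
    code <- genetic_code()
    for (i in seq_len(n %/% 3L)) {
      idx <- (3 * i - 2):(3 * i)
      if (code[paste(new[idx], collapse = "")] == "*") new[idx] <- ch[idx]
    }
  }
  paste(new, collapse = "")
}

#' Default guide tree for panel evolution
#'
#' Four well-separated panel species spanning sarcopterygian depth at
#' desk-scale divergences.
#'
#' @return an ape `phylo`
#' @export
default_guide_tree <- function() {
  ape::read.tree(text =
    "(coelacanth:0.05,(frog:0.04,(chicken:0.03,human:0.03):0.015):0.015);")
}

#' Evolve a reference panel from the canonical roots
#'
#' Simulates each gene's homeobox independently along the guide tree under a
#' K2P substitution process (`cfg$rate` times the branch lengths,
#' transition/transversion ratio `cfg$kappa`). Positions under a primer
#' anchor only accept substitutions compatible with the primer, and in-frame
#' stop codons are refused, so every panel entry remains a valid, primed
#' homeobox. Fully reproducible from `cfg$seed`.
#'
#' @param guide_tree ape `phylo` with branch lengths; leaves are the panel
#'   species
#' @param roots root homeoboxes (default [hox_root_homeoboxes()])
#' @param cfg a [sim_config()]
#' @param primers primer table used for the anchor constraints
#' @return data.frame (`gene`, `species`, `label`, `nt`, `aa`) of class
#'   `"hox_panel"`
#' @export
evolve_panel <- function(guide_tree = default_guide_tree(),
                         roots = hox_root_homeoboxes(),
                         cfg = sim_config(),
                         primers = hox_primer_table()) {
  set.seed(cfg$seed)
  anchors <- attr(roots, "anchors")
  tr <- ape::reorder.phylo(guide_tree, "cladewise")
  ntip <- length(tr$tip.label)
  rootn <- ntip + 1L
  out <- list()
  for (gi in seq_len(nrow(roots))) {
    g <- roots$gene[gi]
    allowed <- .anchor_allowed(anchors[[g]], primers)
    node_seq <- character(ntip + tr$Nnode)
    node_seq[rootn] <- roots$nt[gi]
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
      node_seq[chd] <- .evolve_k2p(node_seq[par],
                                   tr$edge.length[e] * cfg$rate,
                                   cfg$kappa, allowed)
    }
    for (k in seq_len(ntip)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = g, species = tr$tip.label[k],
        label = paste(g, tr$tip.label[k], sep = "_"),
        nt = node_seq[k], stringsAsFactors = FALSE)
    }
  }
  pan <- do.call(rbind, out)
  pan$aa <- vapply(pan$nt, translate_dna, character(1), frame = 0)
  class(pan) <- c("hox_panel", "data.frame")
  pan
}

#' Write/read a reference panel as FASTA
#'
#' Headers carry `gene=<label> species=<tag>` tokens.
#'
#' @param panel a panel data.frame
#' @param path file path
#' @export
write_panel_fasta <- function(panel, path) {
  write_fasta(stats::setNames(panel$nt,
    paste0(panel$label, " gene=", panel$gene, " species=", panel$species)),
    path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  seqs <- read_fasta(path)
  gene <- sub(".*gene=([^ ]+).*", "\\1", names(seqs))
  species <- sub(".*species=([^ ]+).*", "\\1", names(seqs))
  pan <- data.frame(gene = gene, species = species,
                    label = paste(gene, species, sep = "_"),
                    nt = unname(seqs), stringsAsFactors = FALSE)
  if (any(nchar(pan$nt) != 180L))
    stop("panel entries must be 180-nt homeoboxes")
  pan$aa <- vapply(pan$nt, translate_dna, character(1), frame = 0)
  class(pan) <- c("hox_panel", "data.frame")
  pan
}

#' Genomic templates for a taxon with a chosen true inventory
#'
#' One template per present gene: the taxon's homeobox embedded in random
#' genomic flanks, so primers must locate it. Absent genes contribute
#' nothing. The homeobox is evolved by `cfg$taxon_divergence` under the
#' anchored K2P process from the panel entry of `attach_species` when a
#' panel is given (a surveyed taxon is a relative of the reference species,
#' as in the real survey), and from the canonical root otherwise.
#'
#' @param inventory character vector of present genes (subset of the
#'   universe)
#' @param roots,cfg,primers see [evolve_panel()]
#' @param seed optional; defaults to `cfg$seed` (pass `NULL` to keep the
#'   current RNG state when composing generators)
#' @param panel optional reference panel supplying the starting homeoboxes
#' @param attach_species panel species the taxon is related to
#' @return named character vector of templates (names = gene labels) with
#'   attribute `"homeobox_start"` (0-based offset of the homeobox)
#' @export
make_templates <- function(inventory, roots = hox_root_homeoboxes(),
                           cfg = sim_config(), primers = hox_primer_table(),
                           seed = cfg$seed, panel = NULL,
                           attach_species = "frog") {
  if (!is.null(seed)) set.seed(seed)
  if (length(bad <- setdiff(inventory, hox_universe())))
    stop("inventory outside the gene universe: ", paste(bad, collapse = ", "))
  anchors <- attr(roots, "anchors")
  inventory <- sort_genes(unique(inventory))
  out <- character(0); starts <- integer(0)
  for (g in inventory) {
    ri <- match(g, roots$gene)
    allowed <- .anchor_allowed(anchors[[g]], primers)
    start_nt <- if (!is.null(panel) &&
                    any(panel$gene == g & panel$species == attach_species))
      panel$nt[panel$gene == g & panel$species == attach_species][1]
    else roots$nt[ri]
    hb <- .evolve_k2p(start_nt, cfg$taxon_divergence, cfg$kappa, allowed)
    fl <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    out <- c(out, paste0(fl(cfg$flank), hb, fl(cfg$flank)))
    starts <- c(starts, cfg$flank)
    names(out)[length(out)] <- g
  }
  attr(out, "homeobox_start") <- starts
  out
}

# apply k synonymous single-nt changes to an amplicon (complete codons in
# `frame`, restricted to [lo, hi) 0-based) -- returns NULL if impossible
.synonymous_variant <- function(seq, frame, k, lo, hi) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  code <- genetic_code()
  cand <- list()
  st <- frame
  while (st + 3L <= n) {
    if (st >= lo && st + 3L <= hi) {
      cod <- paste(ch[(st + 1):(st + 3)], collapse = "")
      syn <- setdiff(codons_for(code[cod]), cod)
      syn <- syn[vapply(syn, function(s)
        sum(strsplit(s, "")[[1]] != ch[(st + 1):(st + 3)]) == 1L, logical(1))]
      if (length(syn)) cand[[length(cand) + 1L]] <- list(st = st, syn = syn)
    }
    st <- st + 3L
  }
  if (length(cand) < k) return(NULL)
  pick <- sample(seq_along(cand), k)
  for (p in pick) {
    st <- cand[[p]]$st
    new <- sample(cand[[p]]$syn, 1L)
    ch[(st + 1):(st + 3)] <- strsplit(new, "")[[1]]
  }
  paste(ch, collapse = "")
}

# apply k non-synonymous single-nt changes within [lo, hi)
.nonsyn_variant <- function(seq, frame, k, lo, hi) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  code <- genetic_code()
  done <- 0L; guard <- 0L
  while (done < k && guard < 200L) {
    guard <- guard + 1L
    pos <- sample(seq.int(lo + 1L, hi), 1L)           # 1-based position
    ci <- (pos - 1L - frame) %/% 3L
    st <- frame + 3L * ci
    if (st < lo || st + 3L > hi || st < 0L || st + 3L > n) next
    old <- ch[pos]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    cod <- ch[(st + 1):(st + 3)]
    cod[pos - st] <- new
    if (code[paste(cod, collapse = "")] ==
        code[paste(ch[(st + 1):(st + 3)], collapse = "")]) next
    ch[pos] <- new
    done <- done + 1L
  }
  if (done < k) return(NULL)
  paste(ch, collapse = "")
}

#' Simulate a degenerate-PCR clone library for one taxon
#'
#' Runs the tiered in-silico survey on the taxon's templates, then for every
#' amplicon (gene x primer pair) draws a zero-truncated Poisson number of
#' clones. With probability `allele_prob` the locus carries a second
#' haplotype differing by 1-3 synonymous substitutions and represented by at
#' least two clones; each clone is independently hit by a PCR/sequencing
#' error (1-2 non-synonymous substitutions, necessarily a singleton) with
#' probability `error_prob`. Substitutions are placed between the primer
#' footprints, where real amplicons can vary.
#'
#' @param templates named templates from [make_templates()]
#' @param primers primer table
#' @param cfg a [sim_config()]
#' @param taxon label stamped into clone ids
#' @param seed optional; defaults to `cfg$seed` (use `NULL` when composing)
#' @return list with `clones` (data.frame `clone_id`, `library_id`,
#'   `sequence`), `truth` (per-clone provenance and true gene), `survey`
#'   (the tiered survey report) and `libraries` (per-amplicon metadata
#'   including the forward-primer frame offset)
#' @export
simulate_library <- function(templates, primers = hox_primer_table(),
                             cfg = sim_config(), taxon = "taxon",
                             seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  hb <- primers[primers$region == "homeobox", ]
  fw <- hb[hb$direction == "forward", ]
  rv <- hb[hb$direction == "reverse", ]
  fw_t <- lapply(fw$targets, parse_targets)
  rv_t <- lapply(rv$targets, parse_targets)
  survey <- tiered_survey(templates, primers, max_mismatch = cfg$max_mismatch)
  libs <- list(); clones <- list(); truth <- list()
  for (g in names(templates)) {
    det <- survey[survey$gene == g & survey$detected, , drop = FALSE]
    if (nrow(det) == 0L) next
    tier <- det$tier[1]
    fsel <- which(fw$tier == tier &
                    vapply(fw_t, function(t) g %in% t, logical(1)))
    rsel <- which(vapply(rv_t, function(t) g %in% t, logical(1)))
    for (fi in fsel) for (ri in rsel) {
      amp <- in_silico_pcr(fw$sequence[fi], rv$sequence[ri], templates[[g]],
                           max_mismatch = cfg$max_mismatch, template_id = g)
      if (nrow(amp) == 0L) next
      frame <- validate_primer_motif(fw$sequence[fi], fw$aa_motif[fi],
                                     "forward")$frame
      lib_id <- paste(taxon, fw$name[fi], rv$name[ri], sep = ".")
      for (ai in seq_len(nrow(amp))) {
        s <- amp$sequence[ai]
        lf <- nchar(fw$sequence[fi]); lr <- nchar(rv$sequence[ri])
        lo <- lf; hi <- nchar(s) - lr
        n <- .rztpois(1L, cfg$clone_mean)
        hap <- rep(1L, n); prov <- rep("faithful", n)
        seqs <- rep(s, n)
        if (stats::runif(1) < cfg$allele_prob) {
          if (n < 4L) n <- 4L
          k <- sample(1:3, 1L)
          s2 <- .synonymous_variant(s, frame, k, lo, hi)
          if (!is.null(s2)) {
            n2 <- max(2L, stats::rbinom(1L, n, cfg$allele_frac))
            n2 <- min(n2, n - 2L)
            hap <- c(rep(1L, n - n2), rep(2L, n2))
            prov <- ifelse(hap == 2L, "allelic", "faithful")
            seqs <- ifelse(hap == 2L, s2, s)
          }
        }
        err <- stats::runif(length(seqs)) < cfg$error_prob
        for (ei in which(err)) {
          es <- .nonsyn_variant(seqs[ei], frame, sample(1:2, 1L), lo, hi)
          if (!is.null(es)) { seqs[ei] <- es; prov[ei] <- "error" }
        }
        ids <- sprintf("%s|%s|%s|c%02d", taxon, g, lib_id, seq_along(seqs))
        libs[[length(libs) + 1L]] <- data.frame(
          library_id = lib_id, gene = g, fwd = fw$name[fi],
          rev = rv$name[ri], frame = frame, amplicon = s,
          length = nchar(s), stringsAsFactors = FALSE)
        clones[[length(clones) + 1L]] <- data.frame(
          clone_id = ids, library_id = lib_id, sequence = seqs,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          clone_id = ids, library_id = lib_id, gene = g,
          provenance = prov, sequence = seqs, stringsAsFactors = FALSE)
      }
    }
  }
  list(clones = do.call(rbind, clones), truth = do.call(rbind, truth),
       survey = survey, libraries = do.call(rbind, libs))
}

#' Precision and recall of artifact exclusion against the generating truth
#'
#' A unique fragment is a true artifact when every clone carrying its
#' sequence in its library is an error clone. Precision is the fraction of
#' excluded fragments that are true artifacts; recall the fraction of true
#' artifacts excluded.
#'
#' @param filter_events data.frame of non-distinct fragments from the
#'   filter stage (with `library_id`, `sequence`, `status`)
#' @param truth per-clone ground truth (with `library_id`, `sequence`,
#'   `provenance`)
#' @return list with `precision`, `recall`, `n_excluded`, `n_true`
#' @export
artifact_metrics <- function(filter_events, truth) {
  key <- function(df) paste(df$library_id, df$sequence, sep = "\r")
  exc <- unique(key(filter_events[filter_events$status ==
                                    "artifact_excluded", , drop = FALSE]))
  by_key <- split(truth$provenance, key(truth))
  true_art <- names(by_key)[vapply(by_key, function(p) all(p == "error"),
                                   logical(1))]
  list(precision = if (length(exc)) mean(exc %in% true_art) else NA_real_,
       recall = if (length(true_art)) mean(true_art %in% exc) else NA_real_,
       n_excluded = length(exc), n_true = length(true_art))
}

#' Compare an inferred presence matrix with the generating truth
#'
#' @param inferred presence matrix (taxa x genes, 1/0/NA)
#' @param truth named list of true inventories (gene-label vectors)
#' @return list with `per_taxon` data.frame (accuracy, false absences,
#'   false presences), overall `accuracy`, `false_absent`, `false_present`
#' @export
recovery_report <- function(inferred, truth) {
  uni <- colnames(inferred)
  taxa <- intersect(rownames(inferred), names(truth))
  if (length(taxa) == 0L) stop("no shared taxa between matrix and truth")
  rows <- lapply(taxa, function(tx) {
    tv <- as.integer(uni %in% truth[[tx]])
    iv <- inferred[tx, ]
    known <- !is.na(iv)
    data.frame(taxon = tx,
               accuracy = mean(iv[known] == tv[known]),
               false_absent = sum(iv[known] == 0L & tv[known] == 1L),
               false_present = sum(iv[known] == 1L & tv[known] == 0L))
  })
  per <- do.call(rbind, rows)
  list(per_taxon = per,
       accuracy = sum(per$accuracy * length(uni)) / (length(taxa) * length(uni)),
       false_absent = sum(per$false_absent),
       false_present = sum(per$false_present))
}
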