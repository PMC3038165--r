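# Two-level ortholog assignment of homeobox fragments: ungapped anchoring to
# a reference panel, NJ trees on JTT (protein) then K2P (nucleotide)
# distances, and bootstrap support of the defining clade.

#' Anchor a fragment against the reference panel
#'
#' Homeoboxes are a fixed-length, indel-free 180-nt region, so gapped
#' alignment is replaced by ungapped positional anchoring: the fragment is
#' translated and slid along the panel's majority-consensus homeodomain in
#' both orientations (and all frames when none is supplied), keeping the
#' placement with the highest protein identity. Fragments covering fewer
#' than `min_codons` aligned codons, or falling below `min_identity`, are
#' rejected as unalignable (the in-silico analogue of a non-Hox screening
#' hit).
#'
#' @param sequence concrete fragment sequence
#' @param panel reference panel (data.frame with `aa`, `nt`)
#' @param frame known frame offset of the forward orientation (from the
#'   library's forward primer), or `NA` to try all three
#' @param min_codons minimum aligned codons (default 20)
#' @param min_identity minimum protein identity to the consensus
#' @return list: `orientation` (`"+"`/`"-"`), `frame`, `codon_start`,
#'   `codon_end` (1-based homeodomain columns), `aa`, `nt` (the aligned
#'   complete-codon part, reoriented), `identity`
#' @export
anchor_fragment <- function(sequence, panel, frame = NA,
                            min_codons = 20L, min_identity = 0.4) {
  cons <- panel_consensus(panel)
  best <- NULL
  for (orient in c("+", "-")) {
    s <- if (orient == "+") toupper(sequence) else
      reverse_complement(sequence)
    frames <- if (!is.na(frame) && orient == "+") as.integer(frame) else 0:2
    for (fr in frames) {
      n_cod <- (nchar(s) - fr) %/% 3L
      if (n_cod < 1L) next
      aa <- tryCatch(translate_dna(substr(s, fr + 1L, fr + 3L * n_cod)),
                     error = function(e) NULL)
      if (is.null(aa)) next
      av <- strsplit(aa, "")[[1]]
      if (n_cod > length(cons)) next
      for (off in 0:(length(cons) - n_cod)) {
        cmp <- cons[(off + 1):(off + n_cod)]
        informative <- av != "X" & av != "*"
        if (!any(informative)) next
        ident <- mean(av[informative] == cmp[informative])
        if (is.null(best) || ident > best$identity +
            1e-9 || (abs(ident - best$identity) <= 1e-9 &&
                     n_cod > best$codon_end - best$codon_start + 1L)) {
          best <- list(orientation = orient, frame = fr,
                       codon_start = off + 1L, codon_end = off + n_cod,
                       aa = aa,
                       nt = substr(s, fr + 1L, fr + 3L * n_cod),
                       identity = ident)
        }
      }
    }
  }
  if (is.null(best) ||
      best$codon_end - best$codon_start + 1L < min_codons ||
      best$identity < min_identity)
    stop("fragment could not be anchored to the homeobox panel ",
         "(screening failure)")
  best
}

#' Majority-consensus homeodomain of a panel
#'
#' @param panel reference panel
#' @return character vector of 60 residues
#' @export
panel_consensus <- function(panel) {
  m <- do.call(rbind, strsplit(panel$aa, ""))
  apply(m, 2, function(col) names(sort(table(col), decreasing = TRUE))[1])
}

#' Assignment configuration
#'
#' @param min_support minimum bootstrap percentage for an unambiguous call
#'   (the survey reports do not state a threshold; 70 is the package's
#'   explicit stand-in)
#' @param n_bootstrap bootstrap replicates per fragment and level
#' @param n_neighbor_genes panel genes retained (by proximity) for the
#'   fragment's NJ tree
#' @param boot_genes panel genes retained for the bootstrap subset
#' @param d_max distance saturation ceiling
#' @param min_codons,min_identity anchoring thresholds
#' @return list of class `"hox_assign_config"`
#' @export
assign_config <- function(min_support = 70, n_bootstrap = 100,
                          n_neighbor_genes = 8L, boot_genes = 4L,
                          d_max = 5, min_codons = 20L, min_identity = 0.4) {
  structure(list(min_support = min_support, n_bootstrap = n_bootstrap,
                 n_neighbor_genes = n_neighbor_genes,
                 boot_genes = boot_genes, d_max = d_max,
                 min_codons = min_codons, min_identity = min_identity),
            class = "hox_assign_config")
}

# fast grid-only JTT distance matrix over a character matrix (taxa x cols);
# `coarse` thins the grid (used inside bootstrap replicates, where only the
# induced topology matters)
.aa_dist_chars <- function(m, d_max = 5, coarse = FALSE) {
  n <- nrow(m)
  codes <- lapply(seq_len(n), function(i) match(m[i, ], .JTT_ORDER))
  gr <- .jtt_grid(d_max)
  sel <- which(gr$d <= d_max)
  if (coarse) sel <- sel[unique(c(seq(1L, length(sel), by = 4L),
                                  length(sel)))]
  Msel <- gr$M[sel, , drop = FALSE]
  dsel <- gr$d[sel]
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- !is.na(codes[[i]]) & !is.na(codes[[j]])
    if (!any(keep)) { D[i, j] <- D[j, i] <- d_max; next }
    if (all(codes[[i]][keep] == codes[[j]][keep])) next
    counts <- tabulate((codes[[i]][keep] - 1L) * 20L + codes[[j]][keep],
                       nbins = 400L)
    ll <- as.vector(Msel %*% counts)
    D[i, j] <- D[j, i] <- dsel[which.max(ll)]
  }
  D
}

# K2P distance matrix over a character matrix
.nt_dist_chars <- function(m, d_max = 5) {
  n <- nrow(m)
  conc <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    keep <- a %in% conc & b %in% conc
    if (!any(keep)) { D[i, j] <- D[j, i] <- d_max; next }
    a <- a[keep]; b <- b[keep]
    diff <- a != b
    ts <- diff & (a %in% purine) == (b %in% purine)
    P <- mean(ts); Q <- mean(diff & !ts)
    arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
    d <- if (arg1 <= 0 || arg2 <= 0) d_max else
      min(-0.5 * log(arg1 * sqrt(arg2)), d_max)
    D[i, j] <- D[j, i] <- d
  }
  D
}

# smallest split containing `frag` whose other members share one gene label
.defining_clade <- function(tree, frag, gene_of) {
  tips <- tree$tip.label
  ntip <- length(tips)
  sides <- list()
  for (cl in .clade_tip_sets(tree)) {
    sides[[length(sides) + 1L]] <- cl
    sides[[length(sides) + 1L]] <- setdiff(tips, cl)
  }
  # pendant-edge complements give the (n-1)-sized sides; also allow the
  # 2-tip side {frag, sister leaf} via cherries already included above
  sides <- Filter(function(s) frag %in% s && length(s) >= 2L &&
                    length(s) < ntip, sides)
  if (length(sides) == 0L) return(NULL)
  sides <- sides[order(vapply(sides, length, integer(1)))]
  for (s in sides) {
    others <- setdiff(s, frag)
    g <- unique(gene_of[others])
    if (length(g) == 1L) return(list(gene = g, side = s))
  }
  NULL
}

# distances from row 1 to all other rows of a character matrix
.dist_to_all <- function(m, level, d_max) {
  n <- nrow(m)
  out <- numeric(n - 1L)
  if (level == "protein") {
    codes <- match(m, .JTT_ORDER)
    dim(codes) <- dim(m)
    gr <- .jtt_grid(d_max)
    sel <- which(gr$d <= d_max)
    Msel <- gr$M[sel, , drop = FALSE]
    a <- codes[1L, ]
    for (j in 2L:n) {
      b <- codes[j, ]
      keep <- !is.na(a) & !is.na(b)
      if (!any(keep)) { out[j - 1L] <- d_max; next }
      if (all(a[keep] == b[keep])) next
      counts <- tabulate((a[keep] - 1L) * 20L + b[keep], nbins = 400L)
      out[j - 1L] <- gr$d[sel][which.max(Msel %*% counts)]
    }
  } else {
    conc <- c("A", "C", "G", "T"); purine <- c("A", "G")
    a <- m[1L, ]
    a_conc <- a %in% conc
    a_pur <- a %in% purine
    for (j in 2L:n) {
      b <- m[j, ]
      keep <- a_conc & b %in% conc
      if (!any(keep)) { out[j - 1L] <- d_max; next }
      diff <- a[keep] != b[keep]
      ts <- diff & a_pur[keep] == (b[keep] %in% purine)
      P <- mean(ts); Q <- mean(diff & !ts)
      arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
      out[j - 1L] <- if (arg1 <= 0 || arg2 <= 0) d_max else
        min(-0.5 * log(arg1 * sqrt(arg2)), d_max)
    }
  }
  stats::setNames(out, rownames(m)[-1L])
}

# one assignment level (protein or nucleotide) for an anchored fragment
.assign_level <- function(frag_seq, panel_seqs, gene_of, cfg, level,
                          seed = NULL) {
  m_all <- do.call(rbind, strsplit(c("__frag__" = frag_seq, panel_seqs), ""))
  distfun <- if (level == "protein") .aa_dist_chars else .nt_dist_chars
  # rank genes by proximity to the fragment
  dfrag <- .dist_to_all(m_all, level, cfg$d_max)
  bygene <- tapply(dfrag, gene_of[names(dfrag)], min)
  near <- names(sort(bygene))[seq_len(min(cfg$n_neighbor_genes,
                                          length(bygene)))]
  keep <- c("__frag__", names(panel_seqs)[gene_of[names(panel_seqs)] %in%
                                            near])
  tree <- nj_tree(distfun(m_all[keep, , drop = FALSE], cfg$d_max))
  cand <- .defining_clade(tree, "__frag__", gene_of)
  if (is.null(cand)) return(NULL)
  # bootstrap on the candidate gene plus its nearest competitors
  bg <- unique(c(cand$gene,
                 names(sort(bygene))[seq_len(min(cfg$boot_genes,
                                                 length(bygene)))]))
  bkeep <- c("__frag__", names(panel_seqs)[gene_of[names(panel_seqs)] %in%
                                             bg])
  bfun <- if (level == "protein")
    function(m) nj_tree(.aa_dist_chars(m, cfg$d_max, coarse = TRUE))
  else function(m) nj_tree(.nt_dist_chars(m, cfg$d_max))
  # support = fraction of column-resampled replicates in which the
  # fragment's defining clade points to the same gene
  if (!is.null(seed)) set.seed(seed)
  mb <- m_all[bkeep, , drop = FALSE]
  hits <- 0L
  for (b in seq_len(cfg$n_bootstrap)) {
    idx <- sample.int(ncol(mb), replace = TRUE)
    dc <- .defining_clade(bfun(mb[, idx, drop = FALSE]), "__frag__",
                          gene_of)
    if (!is.null(dc) && dc$gene == cand$gene) hits <- hits + 1L
  }
  list(gene = cand$gene, support = 100 * hits / cfg$n_bootstrap,
       level = level)
}

#' Assign a fragment to an exact Hox gene member
#'
#' Two-level procedure: the fragment is anchored to the panel, an NJ tree of
#' fragment plus panel neighborhood is built on JTT protein distances, and
#' the fragment's smallest containing clade whose other leaves share one
#' gene label is read off. If that clade's bootstrap support reaches
#' `min_support` the fragment is assigned at the protein level; otherwise
#' the same procedure is repeated with K2P distances on the nucleotide
#' columns (which separates paralogue groups whose homeodomain proteins are
#' nearly identical, e.g. PG6); failing both, the fragment is `ambiguous`.
#'
#' @param sequence fragment sequence
#' @param panel reference panel
#' @param cfg an [assign_config()]
#' @param frame forward-orientation frame offset (or `NA`)
#' @param fragment_id label for the report
#' @param seed seed for the bootstrap resampling (`NULL`: current RNG state)
#' @return one-row data.frame: `fragment_id`, `gene`, `level`, `support`,
#'   `identity`, `codons`
#' @export
assign_fragment <- function(sequence, panel, cfg = assign_config(),
                            frame = NA, fragment_id = "fragment",
                            seed = NULL) {
  anc <- anchor_fragment(sequence, panel, frame,
                         cfg$min_codons, cfg$min_identity)
  cs <- anc$codon_start; ce <- anc$codon_end
  gene_of <- stats::setNames(panel$gene, panel$label)
  paa <- stats::setNames(substr(panel$aa, cs, ce), panel$label)
  pnt <- stats::setNames(substr(panel$nt, 3 * cs - 2L, 3 * ce), panel$label)
  res <- .assign_level(anc$aa, paa, gene_of, cfg, "protein", seed = seed)
  if (is.null(res) || res$support < cfg$min_support) {
    res_nt <- .assign_level(anc$nt, pnt, gene_of, cfg, "nucleotide",
                            seed = seed)
    if (!is.null(res_nt) && res_nt$support >= cfg$min_support) res <- res_nt
    else res <- NULL
  }
  if (is.null(res))
    return(data.frame(fragment_id = fragment_id, gene = NA_character_,
                      level = "ambiguous", support = NA_real_,
                      identity = anc$identity, codons = ce - cs + 1L,
                      stringsAsFactors = FALSE))
  data.frame(fragment_id = fragment_id, gene = res$gene, level = res$level,
             support = res$support, identity = anc$identity,
             codons = ce - cs + 1L, stringsAsFactors = FALSE)
}

#' Assign a set of validated fragments
#'
#' @param fragments data.frame with `sequence`, optional `frame` and
#'   `fragment_id` columns
#' @param panel,cfg see [assign_fragment()]
#' @param seed integer; each fragment gets a derived sub-seed so the whole
#'   table is reproducible
#' @return data.frame, one row per fragment (unanchorable fragments are
#'   reported with level `"rejected"`)
#' @export
assign_fragments <- function(fragments, panel, cfg = assign_config(),
                             seed = 1L) {
  ids <- fragments$fragment_id %||% paste0("frag", seq_len(nrow(fragments)))
  frames <- fragments$frame %||% rep(NA, nrow(fragments))
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    tryCatch(
      assign_fragment(fragments$sequence[i], panel, cfg, frames[i], ids[i],
                      seed = (seed + i) %% .Machine$integer.max),
      error = function(e)
        data.frame(fragment_id = ids[i], gene = NA_character_,
                   level = "rejected", support = NA_real_,
                   identity = NA_real_, codons = NA_integer_,
                   stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
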