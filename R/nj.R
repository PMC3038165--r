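# Neighbor-joining (Saitou-Nei agglomeration) with deterministic tie-breaks,
# and nonparametric bootstrap support by bipartition counting.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with the Q criterion and canonical
#' branch-length formulas. On an additive matrix the generating topology and
#' branch lengths are recovered exactly (to float tolerance). Ties in Q are
#' broken deterministically towards the lexicographically smallest pair of
#' cluster labels (each cluster labelled by its smallest leaf). Negative
#' branch lengths are clamped to zero with the remainder moved to the sister
#' edge.
#'
#' @param D symmetric distance matrix with zero diagonal and row/column
#'   labels (2 or more taxa; 2 gives the degenerate one-edge tree)
#' @return unrooted ape `phylo`
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs) || any(labs != colnames(D)))
    stop("distance matrix must carry matching row/column labels")
  if (nrow(D) < 2L) stop("need at least 2 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) || any(diag(D) != 0))
    stop("matrix must be symmetric with zero diagonal")
  if (any(!is.finite(D))) stop("distances must be finite")
  nwk <- labs                 # newick fragment per active cluster
  minleaf <- labs             # smallest leaf label per cluster (tie-break)
  act <- seq_along(labs)      # active cluster indices into D
  while (length(act) > 3L) {
    n <- length(act)
    Da <- D[act, act, drop = FALSE]
    r <- rowSums(Da)
    Q <- (n - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9 * (1 + abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      keys <- vapply(seq_len(nrow(cand)), function(k) {
        p <- sort(c(minleaf[act[cand[k, 1]]], minleaf[act[cand[k, 2]]]))
        paste(p, collapse = "\r")
      }, character(1))
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- Da[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- Da[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newd <- (Da[i, ] + Da[j, ] - Da[i, j]) / 2
    ii <- act[i]; jj <- act[j]
    # reuse slot ii for the merged cluster
    D[act, ii] <- D[ii, act] <- newd
    D[ii, ii] <- 0
    nwk[ii] <- sprintf("(%s:%.10g,%s:%.10g)", nwk[ii], vi, nwk[jj], vj)
    minleaf[ii] <- min(minleaf[ii], minleaf[jj])
    act <- act[act != jj]
  }
  if (length(act) == 3L) {
    Da <- D[act, act]
    v <- pmax(c((Da[1, 2] + Da[1, 3] - Da[2, 3]) / 2,
                (Da[1, 2] + Da[2, 3] - Da[1, 3]) / 2,
                (Da[1, 3] + Da[2, 3] - Da[1, 2]) / 2), 0)
    txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   nwk[act[1]], v[1], nwk[act[2]], v[2], nwk[act[3]], v[3])
  } else {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", nwk[act[1]], D[act[1], act[2]] / 2,
                   nwk[act[2]], D[act[1], act[2]] / 2)
  }
  ape::read.tree(text = txt)
}

#' Canonical bipartition keys of an unrooted tree
#'
#' Each non-trivial bipartition is encoded as the sorted tip set of the side
#' not containing the reference tip; `split_key()` canonicalises an
#' arbitrary tip set on a given full leaf set the same way, so supports can
#' be looked up by clade.
#'
#' @param tree ape `phylo`
#' @param ref reference tip (default: alphabetically first)
#' @return character vector of canonical keys
#' @export
tree_splits <- function(tree, ref = NULL) {
  tips <- tree$tip.label
  if (is.null(ref)) ref <- min(tips)
  ntip <- length(tips)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- tips[cl]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

# tip-label sets of every internal node (rooted representation)
.clade_tip_sets <- function(tree) {
  lapply(ape::prop.part(tree), function(cl) tree$tip.label[cl])
}

#' @rdname tree_splits
#' @param side tip set to canonicalise
#' @param tips full leaf set
#' @export
split_key <- function(side, tips, ref = min(tips)) {
  if (ref %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "\r")
}

#' Nonparametric bootstrap support for a tree builder
#'
#' Resamples alignment columns with replacement, rebuilds the tree with
#' `builder` on every replicate, and reports for each internal edge of the
#' full-data tree the percentage of replicates containing the same
#' bipartition. Reproducible for a fixed seed.
#'
#' @param alignment character matrix (taxa x columns) of single characters,
#'   with rownames
#' @param builder function taking such a matrix and returning an ape `phylo`
#' @param n_replicates number of bootstrap replicates
#' @param seed integer seed (`NULL` keeps the current RNG state)
#' @return list: `tree` (full-data tree), `splits` (canonical bipartition
#'   keys), `support` (named percentage vector over `splits`)
#' @export
bootstrap_support <- function(alignment, builder, n_replicates = 100,
                              seed = NULL) {
  stopifnot(is.matrix(alignment), n_replicates >= 1)
  if (ncol(alignment) < 2L) stop("alignment must have at least 2 columns")
  if (!is.null(seed)) set.seed(seed)
  full <- builder(alignment)
  sp <- tree_splits(full)
  hits <- stats::setNames(numeric(length(sp)), sp)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(ncol(alignment), replace = TRUE)
    rep_tree <- builder(alignment[, idx, drop = FALSE])
    rsp <- tree_splits(rep_tree, ref = min(full$tip.label))
    hits[sp %in% rsp] <- hits[sp %in% rsp] + 1
  }
  list(tree = full, splits = sp, support = 100 * hits / n_replicates)
}
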