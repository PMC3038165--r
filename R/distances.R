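# Pairwise evolutionary distances: Kimura two-parameter (nucleotide) and
# maximum-likelihood JTT (protein).

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion proportions over shared columns. Columns in
#' which either sequence carries an ambiguity code (or gap) are dropped
#' (pairwise deletion). When the log argument is non-positive the distance
#' is saturated: the configured ceiling `d_max` is returned with attribute
#' `saturated = TRUE`, keeping distance matrices complete for
#' neighbor-joining.
#'
#' @param a,b aligned nucleotide sequences of equal length
#' @param d_max saturation ceiling (default 5 substitutions/site)
#' @return non-negative distance; 0 for identical sequences
#' @export
k2p_distance <- function(a, b, d_max = 5) {
  ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences must be aligned (equal length)")
  conc <- c("A", "C", "G", "T")
  keep <- ca %in% conc & cb %in% conc
  if (!any(keep)) stop("no shared concrete columns")
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  diff <- ca != cb
  purine <- c("A", "G")
  ts <- diff & (ca %in% purine) == (cb %in% purine)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(structure(d_max, saturated = TRUE))
  d <- -0.5 * log(arg1 * sqrt(arg2))
  if (d > d_max) structure(d_max, saturated = TRUE) else d
}

# ---- JTT model ------------------------------------------------------------

# Published Jones-Taylor-Thornton (1992) amino-acid exchangeabilities
# (lower triangle, column-major, residue order ARNDCQEGHILKMFPSTWYV) and
# equilibrium frequencies, as distributed with PAML (jones.dat).
.JTT_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
.JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)
.JTT_FREQ <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

# eigendecomposition of the normalised JTT rate matrix, built once
.jtt_eigen <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    S <- matrix(0, 20, 20, dimnames = list(.JTT_ORDER, .JTT_ORDER))
    S[lower.tri(S)] <- .JTT_EXCH
    S <- S + t(S)
    pi <- .JTT_FREQ / sum(.JTT_FREQ)
    Q <- S %*% diag(pi)
    diag(Q) <- -rowSums(Q)
    Q <- Q / sum(-diag(Q) * pi)          # one expected substitution per unit
    # symmetrise for a stable eigendecomposition: B = D^(1/2) Q D^(-1/2)
    d12 <- sqrt(pi)
    B <- diag(d12) %*% Q %*% diag(1 / d12)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    cache <<- list(pi = pi, lambda = e$values,
                   V = diag(1 / d12) %*% e$vectors,
                   Vinv = t(e$vectors) %*% diag(d12))
    cache
  }
})

# log(pi_a * P(b | a, d)) as a 400-vector (column-major over a, b)
.jtt_logM <- function(d) {
  eg <- .jtt_eigen()
  P <- eg$V %*% (exp(eg$lambda * d) * eg$Vinv)
  P[P < 1e-12] <- 1e-12
  as.vector(log(eg$pi * P))   # recycles pi down columns: pi_a * P[a,b]
}

# integer-coded residues (1..20, NA for X/gap/stop)
.aa_code <- function(s) {
  m <- match(strsplit(toupper(s), "")[[1]], .JTT_ORDER)
  m
}

# 400-cell pair pattern counts for two coded sequences
.aa_pair_counts <- function(ca, cb) {
  keep <- !is.na(ca) & !is.na(cb)
  tabulate((ca[keep] - 1L) * 20L + cb[keep], nbins = 400L)
}

# shared log-likelihood grid over candidate distances
.jtt_grid <- local({
  cache <- NULL
  function(d_max) {
    if (!is.null(cache) && cache$d_max >= d_max) return(cache)
    dg <- exp(seq(log(1e-4), log(max(d_max, 5)), length.out = 240L))
    M <- t(vapply(dg, .jtt_logM, numeric(400L)))
    cache <<- list(d = dg, M = M, d_max = max(d_max, 5))
    cache
  }
})

.jtt_loglik <- function(counts, d) {
  sum(counts * .jtt_logM(d))
}

#' Maximum-likelihood JTT protein distance
#'
#' The distance maximising the likelihood of the site patterns under the
#' reversible JTT substitution process (published JTT exchangeabilities and
#' equilibrium frequencies, not alignment-empirical ones). Columns
#' containing `X`, gaps or stops are dropped pairwise. The optimum is
#' bracketed on a log-spaced grid and refined by Brent's method; an optimum
#' at the ceiling `d_max` is reported as saturated.
#'
#' @param a,b aligned protein sequences of equal length
#' @param d_max saturation ceiling
#' @return non-negative distance; 0 for identical sequences; symmetric in
#'   its arguments by reversibility
#' @export
jtt_distance <- function(a, b, d_max = 5) {
  ca <- .aa_code(a); cb <- .aa_code(b)
  if (length(ca) != length(cb)) stop("sequences must be aligned (equal length)")
  counts <- .aa_pair_counts(ca, cb)
  if (sum(counts) == 0L) stop("no shared unambiguous columns")
  keep <- !is.na(ca) & !is.na(cb)
  if (all(ca[keep] == cb[keep])) return(0)
  gr <- .jtt_grid(d_max)
  ll <- as.vector(gr$M %*% counts)
  sel <- gr$d <= d_max
  i <- which.max(ll[sel])
  lo <- gr$d[max(i - 1L, 1L)]
  hi <- min(gr$d[min(i + 1L, sum(sel))], d_max)
  opt <- stats::optimize(function(d) .jtt_loglik(counts, d),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-7)
  d <- opt$maximum
  if (d >= d_max * 0.999) structure(d_max, saturated = TRUE) else d
}

#' Pairwise distance matrices for aligned sequence sets
#'
#' Vectorised over all pairs (the JTT grid is shared across pairs, which
#' makes bootstrap replicates cheap).
#'
#' @param seqs named character vector of aligned sequences
#' @param d_max saturation ceiling
#' @return symmetric matrix with zero diagonal, labelled by `names(seqs)`
#' @export
jtt_dist_matrix <- function(seqs, d_max = 5) {
  n <- length(seqs)
  codes <- lapply(seqs, .aa_code)
  gr <- .jtt_grid(d_max)
  sel <- gr$d <= d_max
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    counts <- .aa_pair_counts(codes[[i]], codes[[j]])
    keep <- !is.na(codes[[i]]) & !is.na(codes[[j]])
    if (sum(keep) == 0L) { D[i, j] <- D[j, i] <- d_max; next }
    if (all(codes[[i]][keep] == codes[[j]][keep])) next
    ll <- as.vector(gr$M[sel, , drop = FALSE] %*% counts)
    k <- which.max(ll)
    lo <- gr$d[max(k - 1L, 1L)]
    hi <- min(gr$d[min(k + 1L, sum(sel))], d_max)
    opt <- stats::optimize(function(d) .jtt_loglik(counts, d),
                           lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
    D[i, j] <- D[j, i] <- min(opt$maximum, d_max)
  }
  D
}

#' @rdname jtt_dist_matrix
#' @export
k2p_dist_matrix <- function(seqs, d_max = 5) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- as.numeric(k2p_distance(seqs[[i]], seqs[[j]],
                                                  d_max))
  D
}

#' Simulate protein evolution under the JTT process
#'
#' Draws ancestral residues from the JTT equilibrium frequencies and evolves
#' them for a given distance; used for parameter-recovery checks of
#' [jtt_distance()].
#'
#' @param n_sites number of sites
#' @param d evolutionary distance (expected substitutions per site)
#' @return list with `a` and `b`, two aligned protein sequences
#' @export
simulate_jtt_pair <- function(n_sites, d) {
  eg <- .jtt_eigen()
  P <- eg$V %*% (exp(eg$lambda * d) * eg$Vinv)
  P[P < 0] <- 0
  anc <- sample.int(20L, n_sites, replace = TRUE, prob = eg$pi)
  der <- vapply(anc, function(a)
    sample.int(20L, 1L, prob = P[a, ]), integer(1))
  list(a = paste(.JTT_ORDER[anc], collapse = ""),
       b = paste(.JTT_ORDER[der], collapse = ""))
}
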