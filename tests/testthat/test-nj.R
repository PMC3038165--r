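# least-squares fit of branch lengths for a fixed unrooted topology;
# total tree length is the minimum-evolution score
.ols_tree_length <- function(tree, D) {
  tips <- tree$tip.label
  n <- length(tips)
  tree$edge.length <- rep(1, nrow(tree$edge))
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(tree$edge))
  pp <- ape::prop.part(tree)
  sides <- lapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= n) ch else which(tips %in% tips[pp[[ch - n]]])
  })
  for (k in seq_len(nrow(pairs))) for (e in seq_along(sides)) {
    in1 <- pairs[k, 1] %in% sides[[e]]
    in2 <- pairs[k, 2] %in% sides[[e]]
    if (xor(in1, in2)) A[k, e] <- 1
  }
  d <- D[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  fit <- stats::lm.fit(A, d)
  sum(fit$coefficients)
}

test_that("NJ is exact on additive matrices, including branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(tr)
  est <- nj_tree(D)
  expect_true(ape::dist.topo(ape::unroot(tr), ape::unroot(est)) == 0)
  expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] -
                      D)), 1e-9)
})

test_that("NJ equals exhaustive minimum evolution on 5-taxon additive
           matrices", {
  set.seed(17)
  topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = LETTERS[1:5])
  for (rep in 1:20) {
    tr <- ape::rtree(5, tip.label = LETTERS[1:5],
                     br = function(k) stats::runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    scores <- vapply(topos, .ols_tree_length, numeric(1), D = D)
    best <- topos[[which.min(scores)]]
    est <- nj_tree(D)
    expect_true(ape::dist.topo(best, ape::unroot(est)) == 0)
  }
})

test_that("NJ agrees with an independent implementation on random additive
           matrices", {
  set.seed(19)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_true(ape::dist.topo(ape::unroot(tr), ape::unroot(est)) == 0)
    expect_true(ape::dist.topo(ape::unroot(ape::nj(D)),
                              ape::unroot(est)) == 0)
  }
})

test_that("degenerate and tied inputs give deterministic valid trees", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_identical(sort(t3$tip.label), c("a", "b", "c"))
  expect_true(all(t3$edge.length >= 0))

  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(length(nj_tree(D2)$tip.label), 2L)

  De <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(De) <- 0
  expect_identical(ape::write.tree(nj_tree(De)),
                   ape::write.tree(nj_tree(De)))
  expect_error(nj_tree(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")
  Dbad <- De; Dbad[1, 2] <- Inf; Dbad[2, 1] <- Inf
  expect_error(nj_tree(Dbad), "finite")
})

test_that("bootstrap supports separate clear clades and are reproducible", {
  set.seed(23)
  ncol <- 60
  base1 <- sample(c("A", "C", "G", "T"), ncol, TRUE)
  base2 <- sample(c("A", "C", "G", "T"), ncol, TRUE)
  jitter <- function(x, k) {
    pos <- sample(ncol, k)
    x[pos] <- vapply(x[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    x
  }
  al <- rbind(A1 = jitter(base1, 2), A2 = jitter(base1, 2),
              B1 = jitter(base2, 2), B2 = jitter(base2, 2))
  builder <- function(m) {
    seqs <- apply(m, 1, paste, collapse = "")
    nj_tree(k2p_dist_matrix(seqs))
  }
  bs <- bootstrap_support(al, builder, n_replicates = 100, seed = 7)
  key <- split_key(c("A1", "A2"), rownames(al))
  expect_gte(unname(bs$support[key]), 95)
  # a single replicate can only give 0 or 100
  bs1 <- bootstrap_support(al, builder, n_replicates = 1, seed = 9)
  expect_true(all(bs1$support %in% c(0, 100)))
  # determinism under a fixed seed
  bs2 <- bootstrap_support(al, builder, n_replicates = 25, seed = 11)
  bs3 <- bootstrap_support(al, builder, n_replicates = 25, seed = 11)
  expect_identical(bs2$support, bs3$support)
  expect_error(bootstrap_support(al[, 1, drop = FALSE], builder, 10),
               "2 columns")
})
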