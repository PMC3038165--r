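test_that("loss counting handles the boundary character patterns", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  all1 <- c(a = 1L, b = 1L, c = 1L, d = 1L)
  expect_identical(dollo_min_losses(tr, all1, "present")$losses, 0L)
  one0 <- c(a = 1L, b = 1L, c = 0L, d = 1L)
  expect_identical(dollo_min_losses(tr, one0, "present")$losses, 1L)
  clade0 <- c(a = 1L, b = 1L, c = 0L, d = 0L)
  expect_identical(dollo_min_losses(tr, clade0, "present")$losses, 1L)
  # under derive the gain moves to the carriers' MRCA
  single <- c(a = 1L, b = 0L, c = 0L, d = 0L)
  dm <- dollo_min_losses(tr, single, "derive")
  expect_identical(dm$losses, 0L)
  expect_error(dollo_min_losses(tr, c(a = 0L, b = 0L, c = 0L, d = 0L),
                                "derive"), "gain node undefined")
  # unknown leaves are ignored, not imputed
  unk <- c(a = 1L, b = NA, c = 0L, d = NA)
  expect_identical(dollo_min_losses(tr, unk, "present")$losses, 1L)
  expect_error(dollo_min_losses(tr, c(a = 1L, b = 0L, c = 0L), "present"),
               "every leaf")
})

test_that("loss counting equals the exhaustive single-gain oracle on random
           trees", {
  set.seed(29)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = NULL)
    states <- stats::setNames(sample(c(0L, 1L), n, TRUE), tr$tip.label)
    if (stats::runif(1) < 0.3)
      states[sample(n, 1)] <- NA
    for (rs in c("derive", "present")) {
      if (rs == "derive" && !any(states == 1L, na.rm = TRUE)) next
      mine <- dollo_min_losses(tr, states, rs)$losses
      oracle <- dollo_oracle(tr, states, rs)
      expect_identical(mine, as.integer(oracle),
                       label = paste("n =", n, "rs =", rs))
    }
  }
})

test_that("pruning an absent leaf never increases the loss count", {
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, br = NULL)
    states <- stats::setNames(sample(c(0L, 1L), n, TRUE), tr$tip.label)
    if (sum(states == 0L) == 0L || sum(states == 1L) == 0L) next
    full <- dollo_min_losses(tr, states, "present")$losses
    drop <- sample(names(states)[states == 0L], 1)
    tr2 <- ape::drop.tip(tr, drop)
    pruned <- dollo_min_losses(tr2, states[tr2$tip.label], "present")$losses
    expect_lte(pruned, full)
  }
})

test_that("the turtle hypotheses give the reported HoxC3 step counts", {
  cmp <- compare_topologies(hoxc3_amniote_states(), turtle_hypotheses(),
                            "present")
  expect_identical(stats::setNames(cmp$losses, cmp$hypothesis),
                   c(A = 3L, B = 3L, C = 2L, D = 2L))
  expect_setequal(attr(cmp, "argmin"), c("C", "D"))
  # identical trees score identically
  same <- compare_topologies(hoxc3_amniote_states(),
                             turtle_hypotheses()[c("A", "A")], "present")
  expect_identical(same$losses[1], same$losses[2])
  bad <- turtle_hypotheses()
  bad$B <- ape::read.tree(text = "(mammal,(turtle,(squamate,bird)));")
  expect_error(compare_topologies(hoxc3_amniote_states(), bad, "present"),
               "share one leaf set")
})

test_that("HoxC1 in caecilians requires fewer losses under Batrachia", {
  states <- c(caecilian = 1L, frog = 0L, salamander = 0L, amniote = 0L)
  batrachia <- ape::read.tree(text = "(amniote,(caecilian,(frog,salamander)));")
  alternative <- ape::read.tree(text = "(amniote,(frog,(caecilian,salamander)));")
  expect_lt(dollo_min_losses(batrachia, states, "present")$losses,
            dollo_min_losses(alternative, states, "present")$losses)
})

test_that("ancestral reconstruction reproduces leaves and the reported loss
           events", {
  m <- hox_presence_matrix()
  tr <- sarcopterygian_tree()
  m <- m[tr$tip.label, ]
  rec <- reconstruct_ancestral(tr, m, "present")
  ntip <- length(tr$tip.label)
  # root carries the full universe
  expect_length(rec$node_sets[[ntip + 1L]], 43L)
  expect_true(all(c("A14", "B10", "C1", "C3", "D12", "D13", "B13") %in%
                    rec$node_sets[[ntip + 1L]]))
  # per-gene loss counts match the lineage survey reading
  expected <- c(A14 = 1L, B10 = 1L, C1 = 2L, C3 = 2L, D12 = 3L, D13 = 1L,
                B13 = 2L)
  expect_identical(rec$loss_counts[names(expected)], expected)
  expect_identical(sum(rec$loss_counts), 12L)
  # leaf states are conserved exactly
  for (i in seq_len(ntip)) {
    tx <- tr$tip.label[i]
    known <- !is.na(m[tx, ])
    expect_identical(as.integer(colnames(m)[known] %in% rec$node_sets[[i]]),
                     unname(m[tx, known]))
  }
  # a single-taxon tree reflects that taxon's set
  one <- ape::read.tree(text = "(lungfish:1);")
  rec1 <- reconstruct_ancestral(one, m["lungfish", , drop = FALSE],
                                "derive")
  expect_setequal(rec1$node_sets[[1]],
                  colnames(m)[m["lungfish", ] == 1])
  expect_error(reconstruct_ancestral(tr, m[1:3, ]), "differ")
})
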