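# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from the packaged primer table; no sequence data is
# shipped.

.fixture_env <- new.env()

fixture_primers <- function() {
  if (is.null(.fixture_env$primers)) .fixture_env$primers <- hox_primer_table()
  .fixture_env$primers
}

fixture_roots <- function() {
  if (is.null(.fixture_env$roots))
    .fixture_env$roots <- hox_root_homeoboxes(fixture_primers())
  .fixture_env$roots
}

fixture_panel <- function() {
  if (is.null(.fixture_env$panel))
    .fixture_env$panel <- evolve_panel(default_guide_tree(), fixture_roots(),
                                       sim_config(seed = 42),
                                       fixture_primers())
  .fixture_env$panel
}

primer_seq <- function(name) {
  p <- fixture_primers()
  p$sequence[p$name == name]
}

# random concrete nucleotide string
random_nuc <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# random rooted tree with ape, binary, n leaves labelled t1..tn
random_tree <- function(n) ape::rtree(n, br = NULL)

# exhaustive Dollo oracle: minimise losses over all internal 0/1 state
# assignments obeying single gain and irreversible loss
dollo_oracle <- function(tree, states, root_state = "derive") {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  st <- states[tree$tip.label]
  free_leaves <- which(is.na(st))
  n_free <- tree$Nnode + length(free_leaves)
  parent <- integer(nnode)
  for (e in seq_len(nrow(tree$edge))) parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  root <- ntip + 1L
  best <- Inf
  for (mask in 0:(2^n_free - 1L)) {
    s <- integer(nnode)
    s[seq_len(ntip)] <- ifelse(is.na(st), 0L, st)
    bits <- as.integer(intToBits(mask))[seq_len(n_free)]
    s[ntip + seq_len(tree$Nnode)] <- bits[seq_len(tree$Nnode)]
    if (length(free_leaves))
      s[free_leaves] <- bits[tree$Nnode + seq_along(free_leaves)]
    if (root_state == "present" && s[root] != 1L) next
    ones <- which(s == 1L)
    if (length(ones) == 0L) {
      if (any(st == 1L, na.rm = TRUE)) next
      cand <- 0L
      best <- min(best, cand)
      next
    }
    # single gain: nodes with state 1 form a connected subtree, i.e. every
    # 1-node except the topmost has a 1-parent
    tops <- sum(vapply(ones, function(nd)
      nd == root || s[parent[nd]] == 0L, logical(1)))
    if (tops != 1L) next
    losses <- sum(vapply(seq_len(nnode)[-root], function(nd)
      s[nd] == 0L && s[parent[nd]] == 1L, logical(1)))
    best <- min(best, losses)
  }
  best
}
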