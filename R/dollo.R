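# Dollo parsimony over gene presence/absence characters: a gene is gained
# exactly once and can only be lost, so the minimal history places the gain
# at (or above) the MRCA of the carriers and counts one loss per maximal
# absent subtree below it.

# category of each node's subtree: "P" (some known presence), "A" (all known
# leaves absent, at least one), "U" (no known leaves)
.subtree_categories <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cat <- character(nnode)
  st <- states[tree$tip.label]
  cat[seq_len(ntip)] <- ifelse(is.na(st), "U", ifelse(st == 1L, "P", "A"))
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chd <- ord$edge[k, 2]
    if (cat[par] == "") cat[par] <- cat[chd]
    else if (cat[par] == "P" || cat[chd] == "P") cat[par] <- "P"
    else if (cat[par] == "A" || cat[chd] == "A") cat[par] <- "A"
    else cat[par] <- "U"
  }
  cat
}

#' Minimum Dollo losses of one presence/absence character
#'
#' The gain node is the root when `root_state = "present"` (used when
#' outgroups establish ancestral presence) and otherwise the MRCA of the
#' presence leaves. The loss count is the number of maximal subtrees below
#' the gain node whose known leaves are all absent; leaves with unknown
#' state are ignored. This equals the minimum number of losses over all
#' single-gain, irreversible-loss histories reproducing the leaf states.
#'
#' @param tree rooted ape `phylo`
#' @param states named vector of leaf states (1 present, 0 absent, `NA`
#'   unknown), names matching the tip labels
#' @param root_state `"derive"` (gain at the carriers' MRCA) or `"present"`
#'   (gain forced at the root)
#' @return list: `losses` (count), `loss_nodes` (node ids of the maximal
#'   absent subtrees, whose parent edges carry the loss events), `gain_node`
#' @export
dollo_min_losses <- function(tree, states,
                             root_state = c("derive", "present")) {
  root_state <- match.arg(root_state)
  if (!all(tree$tip.label %in% names(states)))
    stop("every leaf needs a state")
  st <- states[tree$tip.label]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  pres <- which(!is.na(st) & st == 1L)
  if (root_state == "derive" && length(pres) == 0L)
    stop("all-absent character: gain node undefined under root_state='derive'")
  gain <- if (root_state == "present" || length(pres) == 0L) root
  else if (length(pres) == 1L) pres[1L]
  else ape::getMRCA(tree, tree$tip.label[pres])
  cat <- .subtree_categories(tree, states)
  if (gain <= ntip)          # single carrier leaf: gain on its own edge
    return(list(losses = 0L, loss_nodes = integer(0), gain_node = gain))
  if (cat[gain] == "U")   # nothing known anywhere: no event to infer
    return(list(losses = 0L, loss_nodes = integer(0), gain_node = gain))
  children <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
  loss_nodes <- integer(0)
  stack <- gain
  while (length(stack)) {
    nd <- stack[1L]; stack <- stack[-1L]
    for (ch in children(nd)) {
      if (cat[ch] == "A") loss_nodes <- c(loss_nodes, ch)
      else if (cat[ch] == "P") stack <- c(stack, ch)
      # "U" subtrees carry no information and no event
    }
  }
  list(losses = length(loss_nodes), loss_nodes = loss_nodes,
       gain_node = gain)
}

#' Dollo reconstruction of ancestral gene inventories
#'
#' Runs [dollo_min_losses()] per gene of a presence matrix and composes
#' per-node ancestral gene sets: a node carries a gene iff it descends from
#' (or is) the gene's gain node and lies in no lost subtree. Leaf rows of
#' the matrix are reproduced exactly (unknown states are reported as
#' reconstructed).
#'
#' @param tree rooted ape `phylo`; tip labels must equal the matrix rows
#' @param matrix presence matrix (taxa x genes; 1/0/NA)
#' @param root_state per-character root handling, see [dollo_min_losses()];
#'   the default `"present"` encodes ancestral presence established by
#'   outgroups carrying the full universe
#' @return object of class `"dollo_reconstruction"`: list with `tree`,
#'   `node_sets` (gene vector per node id), `losses` (data.frame `gene`,
#'   `node`, `edge_label`), `loss_counts` (named integer vector)
#' @export
reconstruct_ancestral <- function(tree, matrix,
                                  root_state = c("present", "derive")) {
  root_state <- match.arg(root_state)
  if (!setequal(tree$tip.label, rownames(matrix)))
    stop("tree leaves and matrix taxa differ")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  carries <- base::matrix(FALSE, nnode, ncol(matrix),
                          dimnames = list(NULL, colnames(matrix)))
  losses <- list()
  counts <- stats::setNames(integer(ncol(matrix)), colnames(matrix))
  desc_cache <- new.env()
  descendants <- function(nd) {
    key <- as.character(nd)
    if (!is.null(desc_cache[[key]])) return(desc_cache[[key]])
    out <- nd
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    for (k in kids) out <- c(out, descendants(k))
    desc_cache[[key]] <- out
    out
  }
  for (g in colnames(matrix)) {
    states <- stats::setNames(matrix[, g], rownames(matrix))
    if (root_state == "derive" && !any(states == 1L, na.rm = TRUE)) next
    dm <- dollo_min_losses(tree, states, root_state)
    counts[g] <- dm$losses
    present <- descendants(dm$gain_node)
    for (ln in dm$loss_nodes) {
      present <- setdiff(present, descendants(ln))
      losses[[length(losses) + 1L]] <- data.frame(
        gene = g, node = ln,
        edge_label = .node_label(tree, ln), stringsAsFactors = FALSE)
    }
    carries[present, g] <- TRUE
  }
  node_sets <- lapply(seq_len(nnode), function(nd)
    colnames(matrix)[carries[nd, ]])
  structure(list(tree = tree, node_sets = node_sets,
                 losses = if (length(losses)) do.call(rbind, losses)
                          else data.frame(gene = character(),
                                          node = integer(),
                                          edge_label = character()),
                 loss_counts = counts),
            class = "dollo_reconstruction")
}

.node_label <- function(tree, nd) {
  ntip <- length(tree$tip.label)
  if (nd <= ntip) tree$tip.label[nd]
  else paste0("mrca(", paste(sort(ape::extract.clade(tree, nd)$tip.label),
                             collapse = ","), ")")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  root_set <- x$node_sets[[ntip + 1L]]
  cat("Dollo reconstruction over", length(x$loss_counts), "genes\n")
  cat("root inventory:", length(root_set), "genes\n")
  cat("loss events:", sum(x$loss_counts), "\n")
  lost <- x$loss_counts[x$loss_counts > 0]
  if (length(lost)) {
    cat("per-gene losses:\n")
    for (g in names(lost)) cat(sprintf("  %-4s %d\n", g, lost[g]))
  }
  invisible(x)
}

#' Compare Dollo step counts across alternative topologies
#'
#' Evaluates competing phylogenetic hypotheses by the number of independent
#' losses each requires for a character (e.g. HoxC3 across the four
#' hypotheses for the position of turtles).
#'
#' @param states named leaf-state vector (1/0/NA)
#' @param trees named list of rooted `phylo` objects over the same leaves
#' @param root_state see [dollo_min_losses()]
#' @return data.frame `hypothesis`, `losses`, with attribute `"argmin"`
#'   (names of the topologies with the fewest losses)
#' @export
compare_topologies <- function(states, trees,
                               root_state = c("present", "derive")) {
  root_state <- match.arg(root_state)
  leaf_sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(leaf_sets)) != 1L)
    stop("all topologies must share one leaf set")
  losses <- vapply(trees, function(t)
    dollo_min_losses(t, states, root_state)$losses, integer(1))
  out <- data.frame(hypothesis = names(trees), losses = unname(losses),
                    stringsAsFactors = FALSE)
  attr(out, "argmin") <- out$hypothesis[out$losses == min(out$losses)]
  out
}

#' The four turtle-placement hypotheses
#'
#' Amniote topologies over mammals, turtles, squamates, birds and
#' crocodiles: (A) turtles as anapsids, sister to all other reptiles;
#' (B) turtles sister to squamates (Lepidosauria); (C) turtles sister to
#' Archosauria (birds + crocodiles); (D) turtles inside Archosauria as the
#' sister group of crocodiles.
#'
#' @return named list of rooted `phylo` objects
#' @export
turtle_hypotheses <- function() {
  txt <- c(
    A = "(mammal,(turtle,(squamate,(bird,crocodile))));",
    B = "(mammal,((turtle,squamate),(bird,crocodile)));",
    C = "(mammal,(squamate,(turtle,(bird,crocodile))));",
    D = "(mammal,(squamate,(bird,(turtle,crocodile))));")
  lapply(txt, function(s) ape::read.tree(text = s))
}

#' HoxC3 presence calls across amniotes
#'
#' Present in squamates (and in the amphibian and lobe-finned-fish
#' outgroups, which is why ancestral presence is forced); absent in
#' mammals, turtles, crocodiles and birds.
#'
#' @return named 0/1 vector over the amniote leaves
#' @export
hoxc3_amniote_states <- function() {
  c(mammal = 0L, turtle = 0L, squamate = 1L, bird = 0L, crocodile = 0L)
}

#' The accepted sarcopterygian species tree
#'
#' Coelacanth branching first, lungfish sister to tetrapods, Batrachia
#' (frog + salamander) within amphibians, and turtles sister to archosaurs
#' among amniotes.
#'
#' @return rooted ape `phylo`
#' @export
sarcopterygian_tree <- function() {
  ape::read.tree(text = paste0(
    "(coelacanth,(lungfish,((caecilian,(frog,salamander)),",
    "(placental,((lizard,snake),(turtle,(bird,crocodile)))))));"))
}
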