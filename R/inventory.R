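# Hox gene inventories over the 43-gene sarcopterygian universe.

#' The sarcopterygian Hox gene universe and the placental core set
#'
#' Sarcopterygians carry four Hox clusters (A-D) with up to 14 paralogue
#' groups. `hox_universe()` returns the 43 genes observed across the lineage:
#' the 39-gene placental core plus the four genes retained only in basal
#' lineages (HoxA14, HoxB10, HoxC1, HoxC3). `hox_core_placental()` returns
#' the 39-gene core (the mammalian inventory used as reference).
#'
#' @return character vector of gene labels such as `"A1"`, `"C13"`
#' @export
hox_universe <- function() {
  sort_genes(c(hox_core_placental(), c("A14", "B10", "C1", "C3")))
}

#' @rdname hox_universe
#' @export
hox_core_placental <- function() {
  core <- c(paste0("A", c(1:7, 9:11, 13)),
            paste0("B", c(1:9, 13)),
            paste0("C", c(4:6, 8:13)),
            paste0("D", c(1, 3, 4, 8:13)))
  sort_genes(core)
}

#' Sort, parse and validate Hox gene labels
#'
#' A gene label is a cluster letter (A-D) followed by a paralogue-group
#' number (1-14). `gene_cluster()` and `gene_pg()` extract the parts;
#' `sort_genes()` orders labels by cluster then paralogue group.
#'
#' @param genes character vector of labels
#' @return `sort_genes()`: sorted labels; extractors: vectors
#' @export
sort_genes <- function(genes) {
  ok <- grepl("^[ABCD](1[0-4]|[1-9])$", genes)
  if (!all(ok)) stop("malformed Hox gene label(s): ",
                     paste(genes[!ok], collapse = ", "))
  genes[order(gene_cluster(genes), gene_pg(genes))]
}

#' @rdname sort_genes
#' @export
gene_cluster <- function(genes) substr(genes, 1, 1)

#' @rdname sort_genes
#' @export
gene_pg <- function(genes) as.integer(substring(genes, 2))

#' Apply stated gains and losses to a reference inventory
#'
#' Per-lineage inventories are reported as deltas against the 39-gene
#' placental core: genes gained (retained basal genes absent from the core)
#' and genes lost. The count law `|result| = |core| + |gains| - |losses|`
#' always holds for valid deltas.
#'
#' @param gains genes to add; must be disjoint from `core`
#' @param losses genes to remove; must be a subset of `core`
#' @param core reference gene set (default the placental core)
#' @return sorted character vector of gene labels
#' @export
build_inventory <- function(gains = character(), losses = character(),
                            core = hox_core_placental()) {
  gains <- if (length(gains)) sort_genes(gains) else character()
  losses <- if (length(losses)) sort_genes(losses) else character()
  if (length(bad <- intersect(gains, core)))
    stop("gain already in core: ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(losses, core)))
    stop("loss not in core: ", paste(bad, collapse = ", "))
  sort_genes(setdiff(union(core, gains), losses))
}

#' Reported per-lineage inventory deltas
#'
#' The gains and losses, relative to the placental core, reported for the
#' major sarcopterygian lineages by comprehensive PCR survey and published
#' genome data: lungfish and coelacanth keep all four basal genes (lungfish
#' lacks HoxD12, the coelacanth HoxD13); amphibians keep HoxC3 (caecilians
#' also HoxC1) and have lost HoxD12, with HoxB13 additionally lost in frogs
#' and caecilians; squamates keep HoxC3 and snakes have lost HoxD12; turtles,
#' crocodiles, birds and placental mammals share the bare 39-gene core.
#'
#' @return data.frame with columns `taxon`, `gains`, `losses` (comma-joined
#'   label strings) and `total` (the resulting inventory size)
#' @export
hox_lineage_deltas <- function() {
  d <- data.frame(
    taxon = c("lungfish", "coelacanth", "caecilian", "salamander", "frog",
              "snake", "lizard", "turtle", "crocodile", "bird", "placental"),
    gains = c("A14,B10,C1,C3", "A14,B10,C1,C3", "C1,C3", "C3", "C3",
              "C3", "C3", "", "", "", ""),
    losses = c("D12", "D13", "D12,B13", "D12", "D12,B13",
               "D12", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
  d$total <- vapply(seq_len(nrow(d)), function(i) {
    length(build_inventory(.split_genes(d$gains[i]), .split_genes(d$losses[i])))
  }, integer(1))
  d
}

.split_genes <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",")[[1]]
}

#' Presence/absence matrix over the gene universe
#'
#' Builds the taxa x gene binary matrix (with `NA` for unknown states, e.g.
#' HoxC3 in marsupials and monotremes, whose HoxC cluster assemblies lack the
#' flanking sequence) from per-taxon inventories, or loads the packaged
#' matrix transcribing the lineage survey results.
#'
#' @param inventories named list of gene-label vectors (one per taxon)
#' @param unknown named list of gene-label vectors to mark `NA`
#' @return integer matrix, taxa in rows, the 43-gene universe in columns
#' @export
presence_matrix <- function(inventories, unknown = list()) {
  uni <- hox_universe()
  m <- t(vapply(inventories, function(g) as.integer(uni %in% g),
                integer(length(uni))))
  colnames(m) <- uni
  for (tx in names(unknown)) m[tx, unknown[[tx]]] <- NA_integer_
  m
}

#' @rdname presence_matrix
#' @export
hox_presence_matrix <- function() {
  path <- system.file("extdata", "lineage_presence.tsv", package = "hoxsurvey",
                      mustWork = TRUE)
  read_presence_tsv(path)
}

#' Read/write presence matrices as TSV
#'
#' Rows are taxa, columns genes; cells are `1`, `0` or `?` (unknown).
#'
#' @param path file path
#' @param m presence matrix as returned by [presence_matrix()]
#' @export
read_presence_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  taxa <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "?"] <- NA
  storage.mode(m) <- "integer"
  rownames(m) <- taxa
  m
}

#' @rdname read_presence_tsv
#' @export
write_presence_tsv <- function(m, path) {
  out <- m
  mode(out) <- "character"
  out[is.na(out)] <- "?"
  df <- data.frame(taxon = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
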