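# Collapse sequenced clones to unique fragments and separate allelic
# variants from PCR/sequencing errors.
#
# The survey's rule set: sequences differing by 1-3 nucleotides that are all
# synonymous, each seen in more than one clone, are allelic variants of one
# locus; a non-synonymous difference of 1-2 nucleotides carried by a single
# clone is a PCR or sequencing error and is excluded.

#' Collapse a clone library to unique fragments
#'
#' @param clones data.frame with columns `clone_id`, `library_id`,
#'   `sequence`; all records must share one `library_id`
#' @return data.frame of unique fragments (`sequence`, `clone_count`,
#'   `library_id`), ordered by count (desc) then sequence; clone counts sum
#'   to the library size
#' @export
collapse_clones <- function(clones) {
  if (nrow(clones) == 0L)
    return(data.frame(sequence = character(), clone_count = integer(),
                      library_id = character()))
  if (length(unique(clones$library_id)) != 1L)
    stop("collapse_clones() expects a single library")
  tab <- table(clones$sequence)
  out <- data.frame(sequence = names(tab), clone_count = as.integer(tab),
                    library_id = clones$library_id[1],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$clone_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# positions (1-based) where two equal-length sequences differ
.diff_positions <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# are all differences between a and b synonymous under `frame`?
# differences outside complete codons cannot be verified and count as
# non-synonymous
.all_synonymous <- function(a, b, frame) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  n <- length(ca)
  code <- genetic_code()
  for (p in pos) {
    ci <- (p - 1L - frame) %/% 3L
    st <- frame + 3L * ci
    if (st < 0L || st + 3L > n || p <= frame) return(FALSE)
    k1 <- paste(ca[(st + 1):(st + 3)], collapse = "")
    k2 <- paste(cb[(st + 1):(st + 3)], collapse = "")
    if (grepl("[^ACGT]", k1) || grepl("[^ACGT]", k2)) return(FALSE)
    if (code[k1] != code[k2]) return(FALSE)
  }
  TRUE
}

#' Classify a pair of unique fragments
#'
#' Implements the allelic-variant versus artifact rules. With `k` differing
#' positions: `"allelic_variants"` iff `1 <= k <= 3`, all differences
#' synonymous in the shared frame, and both fragments are seen in more than
#' one clone; `"artifact"` iff `1 <= k <= 2`, not all synonymous, and the
#' rarer fragment is a singleton (the singleton is the artifact); otherwise
#' `"distinct"`. Pairs of unequal length are `"distinct"` by construction.
#'
#' @param seq_a,seq_b fragment sequences
#' @param count_a,count_b clone counts
#' @param frame shared frame offset (0..2) of the first complete codon
#' @return one of `"allelic_variants"`, `"artifact"`, `"distinct"`
#' @export
classify_pair <- function(seq_a, count_a, seq_b, count_b, frame = 0) {
  if (nchar(seq_a) != nchar(seq_b)) return("distinct")
  pos <- .diff_positions(seq_a, seq_b)
  k <- length(pos)
  if (k == 0L) stop("identical sequences should have been collapsed")
  syn <- .all_synonymous(seq_a, seq_b, frame)
  if (k <= 3L && syn && min(count_a, count_b) >= 2L) return("allelic_variants")
  if (k <= 2L && !syn && min(count_a, count_b) == 1L) return("artifact")
  "distinct"
}

#' Filter a collapsed library
#'
#' Walks unique fragments in decreasing clone-count order, comparing each
#' against the accepted locus representatives of the same length within edit
#' distance 3. Artifacts (non-synonymous singletons next to a multi-clone
#' fragment) are excluded; allelic variants are retained and linked to their
#' locus; synonymous singletons, which the survey's rules leave open, are
#' conservatively merged into the majority variant. Non-synonymous variants
#' with two or more clones stay distinct candidate loci, as do 3-nt
#' non-synonymous singletons (flagged, not silently excluded). The operation
#' is idempotent.
#'
#' @param fragments data.frame from [collapse_clones()]; a `frame` column or
#'   the `frame` argument supplies the reading-frame offset
#' @param frame frame offset used when `fragments$frame` is absent
#' @return data.frame with columns `sequence`, `clone_count`, `library_id`,
#'   `status` (`"distinct"`, `"allelic_variant_of:<locus>"`,
#'   `"artifact_excluded"`), `locus_id`, `flagged` (logical; unresolved
#'   3-nt non-synonymous singletons)
#' @export
filter_library <- function(fragments, frame = 0) {
  fr <- fragments
  if (nrow(fr) == 0L) {
    fr$status <- character(); fr$locus_id <- character()
    fr$flagged <- logical()
    return(fr)
  }
  if (is.null(fr$frame)) fr$frame <- frame
  fr <- fr[order(-fr$clone_count, fr$sequence), , drop = FALSE]
  rownames(fr) <- NULL
  # already-filtered input: strip exclusions, keep links (idempotence)
  if (!is.null(fr$status)) fr <- fr[fr$status != "artifact_excluded", ,
                                    drop = FALSE]
  n <- nrow(fr)
  status <- rep(NA_character_, n)
  locus <- rep(NA_character_, n)
  flagged <- rep(FALSE, n)
  retained <- integer(0)   # rows already accepted (representatives and
                           # allelic variants; all sequences are compared
                           # against each other, so errors sitting on a
                           # minor allele are still recognised)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (r in retained) {
      if (nchar(fr$sequence[r]) != nchar(fr$sequence[i])) next
      if (fr$frame[r] != fr$frame[i]) next
      pos <- .diff_positions(fr$sequence[r], fr$sequence[i])
      k <- length(pos)
      if (k == 0L || k > 3L) next
      syn <- .all_synonymous(fr$sequence[r], fr$sequence[i], fr$frame[i])
      if (syn) {
        # multi-clone: allelic variant; singleton: merged into the majority
        status[i] <- paste0("allelic_variant_of:", locus[r])
        locus[i] <- locus[r]
        assigned <- TRUE
      } else if (k <= 2L && fr$clone_count[i] == 1L) {
        status[i] <- "artifact_excluded"
        locus[i] <- NA_character_
        assigned <- TRUE
      } else if (k == 3L && fr$clone_count[i] == 1L) {
        flagged[i] <- TRUE   # outside both rules; kept as distinct
      }
      if (assigned) break
    }
    if (!assigned) {
      status[i] <- "distinct"
      locus[i] <- paste0("L", length(unique(stats::na.omit(locus))) + 1L)
    }
    if (status[i] != "artifact_excluded") retained <- c(retained, i)
  }
  fr$status <- status
  fr$locus_id <- locus
  fr$flagged <- flagged
  fr
}

#' Read clones from FASTA
#'
#' Headers may carry `library=<id>` (and optionally `count=<n>`, expanding
#' to that many identical clone records); otherwise each record is one clone
#' of the given default library.
#'
#' @param path FASTA path
#' @param default_library library id used when headers carry none
#' @return data.frame `clone_id`, `library_id`, `sequence`
#' @export
read_clone_fasta <- function(path, default_library = "lib1") {
  seqs <- read_fasta(path)
  ids <- sub(" .*", "", names(seqs))
  lib <- ifelse(grepl("library=", names(seqs)),
                sub(".*library=([^ ]+).*", "\\1", names(seqs)),
                default_library)
  cnt <- rep(1L, length(seqs))
  has_cnt <- grepl("count=", names(seqs))
  cnt[has_cnt] <- as.integer(sub(".*count=([0-9]+).*", "\\1",
                                 names(seqs)[has_cnt]))
  idx <- rep(seq_along(seqs), cnt)
  data.frame(clone_id = make.unique(ids[idx]), library_id = lib[idx],
             sequence = unname(seqs)[idx], stringsAsFactors = FALSE)
}

#' Write filtered fragments as TSV
#'
#' @param fragments output of [filter_library()]
#' @param path file path
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
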