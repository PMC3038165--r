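# Degenerate primer model and in-silico PCR with the tiered survey strategy
# (general -> paralogue-group-specific -> member-specific primers).

#' The packaged degenerate primer table
#'
#' The survey's primer set transcribed as TSV: IUPAC-coded oligos targeting
#' homeobox or exon1 regions, each annotated with the protein motif it
#' encodes (or a 5'UTR flag), its target paralogue groups or gene members,
#' the expected product length as printed, and its tier in the escalation
#' strategy. The `aa_motif_printed` column is the verbatim transcription;
#' `aa_motif` corrects a single internal inconsistency (HoxF1N2, whose
#' printed oligo encodes QVTELEKEF, not the printed QLTELEKEF) and is the
#' column used for motif validation.
#'
#' @param path TSV path; defaults to the packaged table
#' @return data.frame with columns `name`, `sequence`, `direction`,
#'   `targets`, `aa_motif`, `aa_motif_printed`, `product_len`, `tier`,
#'   `region`, `notes`
#' @export
read_primer_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("name", "sequence", "direction", "targets", "aa_motif",
            "aa_motif_printed", "product_len", "tier", "region", "notes")
  if (!all(need %in% names(df)))
    stop("primer table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicate primer names")
  stopifnot(all(df$direction %in% c("forward", "reverse")),
            all(df$tier %in% c("general", "pg_specific", "member_specific")),
            all(df$region %in% c("homeobox", "exon1")))
  df$sequence <- vapply(df$sequence, as_nuc_seq, character(1))
  df
}

#' @rdname read_primer_table
#' @export
hox_primer_table <- function() {
  read_primer_table(system.file("extdata", "table1_primers.tsv",
                                package = "hoxsurvey", mustWork = TRUE))
}

#' Expand a primer target specification to gene labels
#'
#' Target strings are paralogue-group ranges (`"PG1-PG7"`), single groups
#' (`"PG13"`) or comma-separated gene members (`"A5,B5"`), resolved against
#' the 43-gene universe.
#'
#' @param spec target string
#' @return character vector of gene labels
#' @export
parse_targets <- function(spec) {
  uni <- hox_universe()
  toks <- strsplit(spec, ",")[[1]]
  out <- unlist(lapply(toks, function(tk) {
    tk <- trimws(tk)
    if (grepl("^PG[0-9]+-PG[0-9]+$", tk)) {
      rng <- as.integer(regmatches(tk, gregexpr("[0-9]+", tk))[[1]])
      uni[gene_pg(uni) >= rng[1] & gene_pg(uni) <= rng[2]]
    } else if (grepl("^PG[0-9]+$", tk)) {
      uni[gene_pg(uni) == as.integer(sub("PG", "", tk))]
    } else {
      sort_genes(tk)
    }
  }))
  sort_genes(unique(out))
}

# does a degenerate codon pattern admit at least one codon of residue `aa`?
.codon_can_encode <- function(codon_pattern, aa) {
  pats <- strsplit(codon_pattern, "")[[1]]
  for (cod in codons_for(aa)) {
    bases <- strsplit(cod, "")[[1]]
    if (all(mapply(function(b, p) b %in% IUPAC_DNA[[p]], bases, pats)))
      return(TRUE)
  }
  FALSE
}

#' Validate a primer against its encoded protein motif
#'
#' A degenerate primer written over a conserved motif reads, from some frame
#' offset, as a run of codons each able to encode the corresponding motif
#' residue (reverse primers are read as their reverse complement). Leading
#' and trailing partial codons are not checked. Failure flags a
#' mistranscribed primer or motif.
#'
#' @param sequence primer sequence (5'->3')
#' @param motif amino-acid motif from the primer table
#' @param direction `"forward"` or `"reverse"`
#' @return list with `frame` (offset 0..2 of the first complete codon in the
#'   reading orientation) and `motif_start` (1-based residue of the motif
#'   matched by that codon)
#' @export
validate_primer_motif <- function(sequence, motif, direction = "forward") {
  stopifnot(direction %in% c("forward", "reverse"))
  if (motif %in% c("", "5' UTR", "5'UTR"))
    stop("primer has no protein motif; nothing to validate")
  seq <- if (direction == "reverse") reverse_complement(sequence)
         else as_nuc_seq(sequence)
  res <- strsplit(motif, "")[[1]]
  best <- NULL
  for (off in 0:2) {
    n_cod <- (nchar(seq) - off) %/% 3L
    if (n_cod < 1L) next
    starts <- off + 1L + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    if (n_cod > length(res)) next
    for (ms in seq_len(length(res) - n_cod + 1L)) {
      ok <- all(vapply(seq_len(n_cod), function(j)
        .codon_can_encode(codons[j], res[ms + j - 1L]), logical(1)))
      if (ok && (is.null(best) || n_cod > best$n_codons))
        best <- list(frame = off, motif_start = ms, n_codons = n_cod)
    }
  }
  if (is.null(best))
    stop("motif mismatch: primer cannot encode motif ", motif,
         " at any frame offset")
  best[c("frame", "motif_start")]
}

#' Find degenerate-primer binding sites on a concrete template
#'
#' Scans every window of the plus strand; a forward primer is compared
#' directly, a reverse primer as its reverse complement. A position matches
#' when the template base lies in the expansion set of the primer symbol.
#' By default any mismatch in the primer's 3'-terminal 3 nt disqualifies the
#' window (polymerase extension is most sensitive there).
#'
#' @param primer primer sequence (IUPAC, 5'->3')
#' @param template concrete template sequence (plus strand)
#' @param max_mismatch maximum mismatches tolerated elsewhere
#' @param direction `"forward"` or `"reverse"`
#' @param three_prime_strict disqualify 3'-terminal mismatches
#' @return data.frame of half-open 0-based sites: `start`, `end`, `strand`,
#'   `mismatches`, sorted by `start`
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 0,
                               direction = "forward",
                               three_prime_strict = TRUE) {
  stopifnot(direction %in% c("forward", "reverse"))
  template <- as_nuc_seq(template)
  if (grepl("[^ACGT]", template))
    stop("template must be concrete (A/C/G/T only)")
  pat <- if (direction == "reverse") reverse_complement(primer)
         else as_nuc_seq(primer)
  lp <- nchar(pat)
  nt <- nchar(template)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer())
  if (nt < lp) return(empty)
  tmpl <- strsplit(template, "")[[1]]
  pch <- strsplit(pat, "")[[1]]
  nw <- nt - lp + 1L
  mism <- integer(nw)
  # primer 3' end is at the window's right edge for forward primers and at
  # its left edge for reverse primers (pattern is the reverse complement)
  tp_idx <- if (direction == "forward") (lp - 2L):lp else 1L:3L
  mism3 <- integer(nw)
  for (i in seq_len(lp)) {
    hit <- tmpl[i:(i + nw - 1L)] %in% IUPAC_DNA[[pch[i]]]
    mism <- mism + !hit
    if (i %in% tp_idx) mism3 <- mism3 + !hit
  }
  keep <- mism <= max_mismatch
  if (three_prime_strict) keep <- keep & mism3 == 0L
  st <- which(keep) - 1L
  data.frame(start = st, end = st + lp,
             strand = if (direction == "forward") rep("+", length(st))
                      else rep("-", length(st)),
             mismatches = mism[keep])
}

#' In-silico PCR of a degenerate primer pair against one template
#'
#' Pairs every forward binding site with every downstream reverse site and
#' keeps products whose span falls inside the configured size window (the
#' survey's homeobox products run 80-165 bp). The amplicon sequence is the
#' plus-strand template slice from forward-site start to reverse-site end.
#'
#' @param fwd,rev primer sequences (IUPAC); `fwd` binds the plus strand,
#'   `rev` is matched as its reverse complement
#' @param template concrete template
#' @param min_len,max_len product length bounds in bp
#' @param max_mismatch tolerated mismatches per primer site
#' @param three_prime_strict see [find_binding_sites()]
#' @param template_id optional label copied into the result
#' @return data.frame of amplicons: `template_id`, `start`, `end` (half-open,
#'   plus strand), `length`, `sequence`, ordered by (start, end)
#' @export
in_silico_pcr <- function(fwd, rev, template, min_len = 80, max_len = 165,
                          max_mismatch = 0, three_prime_strict = TRUE,
                          template_id = NA_character_) {
  fs <- find_binding_sites(fwd, template, max_mismatch, "forward",
                           three_prime_strict)
  rs <- find_binding_sites(rev, template, max_mismatch, "reverse",
                           three_prime_strict)
  out <- data.frame(template_id = character(), start = integer(),
                    end = integer(), length = integer(),
                    sequence = character())
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(out)
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    if (rs$start[j] < fs$end[i]) next
    len <- rs$end[j] - fs$start[i]
    if (len < min_len || len > max_len) next
    out <- rbind(out, data.frame(
      template_id = template_id, start = fs$start[i], end = rs$end[j],
      length = len,
      sequence = substr(template, fs$start[i] + 1L, rs$end[j])))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Tiered degenerate-PCR survey of a template pool
#'
#' Reproduces the survey escalation strategy: general primer pairs are run
#' first; any target gene without a product is retried with its
#' paralogue-group-specific primers and finally with member-specific primers
#' (e.g. HoxF5S and then HoxFC5 for a divergent HoxC5). Templates are named
#' by the gene they carry, so the report records at which tier each gene of
#' the universe was detected.
#'
#' @param templates named character vector of concrete templates; names are
#'   gene labels (several templates may share a gene)
#' @param primers primer table (default the packaged table); only homeobox-
#'   region primers take part
#' @param max_mismatch,min_len,max_len,three_prime_strict see
#'   [in_silico_pcr()]
#' @return data.frame per universe gene: `gene`, `pg`, `detected`, `tier`,
#'   `fwd`, `rev`, `template_id`, `start`, `end`, `length`, `sequence`,
#'   `frame` (frame offset of the forward primer's first complete codon
#'   within the amplicon). Attribute `"log"` holds the escalation log.
#' @export
tiered_survey <- function(templates, primers = hox_primer_table(),
                          max_mismatch = 0, min_len = 80, max_len = 165,
                          three_prime_strict = TRUE) {
  if (nrow(primers) == 0L) stop("empty primer table")
  hb <- primers[primers$region == "homeobox", , drop = FALSE]
  fw <- hb[hb$direction == "forward", , drop = FALSE]
  rv <- hb[hb$direction == "reverse", , drop = FALSE]
  fw_targets <- lapply(fw$targets, parse_targets)
  rv_targets <- lapply(rv$targets, parse_targets)
  uni <- hox_universe()
  res <- data.frame(gene = uni, pg = gene_pg(uni), detected = FALSE,
                    tier = NA_character_, fwd = NA_character_,
                    rev = NA_character_, template_id = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    length = NA_integer_, sequence = NA_character_,
                    frame = NA_integer_, stringsAsFactors = FALSE)
  log <- data.frame(gene = character(), tier = character(),
                    fwd = character(), rev = character(),
                    template_id = character(), n_amplicons = integer())
  tiers <- c("general", "pg_specific", "member_specific")
  for (tier in tiers) {
    todo <- res$gene[!res$detected]
    for (g in todo) {
      tmpl_idx <- which(names(templates) == g)
      if (length(tmpl_idx) == 0L) next
      fsel <- which(fw$tier == tier &
                      vapply(fw_targets, function(t) g %in% t, logical(1)))
      rsel <- which(vapply(rv_targets, function(t) g %in% t, logical(1)))
      for (fi in fsel) for (ri in rsel) for (ti in tmpl_idx) {
        amp <- in_silico_pcr(fw$sequence[fi], rv$sequence[ri],
                             templates[[ti]], min_len, max_len,
                             max_mismatch, three_prime_strict,
                             template_id = paste0(g, ".", ti))
        log <- rbind(log, data.frame(
          gene = g, tier = tier, fwd = fw$name[fi], rev = rv$name[ri],
          template_id = paste0(g, ".", ti), n_amplicons = nrow(amp)))
        if (nrow(amp) > 0L && !res$detected[res$gene == g]) {
          k <- which(res$gene == g)
          frame <- validate_primer_motif(fw$sequence[fi], fw$aa_motif[fi],
                                         "forward")$frame
          res[k, c("detected", "tier", "fwd", "rev", "template_id")] <-
            list(TRUE, tier, fw$name[fi], rv$name[ri], amp$template_id[1])
          res[k, c("start", "end", "length")] <-
            amp[1, c("start", "end", "length")]
          res$sequence[k] <- amp$sequence[1]
          res$frame[k] <- frame
        }
      }
    }
  }
  attr(res, "log") <- log
  res
}
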