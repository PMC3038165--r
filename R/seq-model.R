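# Core sequence alphabet: IUPAC ambiguity semantics, genetic code and
# frame-aware translation shared by the whole pipeline.

#' IUPAC nucleotide expansion sets
#'
#' The 15-letter IUPAC DNA alphabet mapped to the concrete bases each symbol
#' stands for. Degenerate PCR primers are written in this alphabet so that a
#' single oligo covers every codon variant encoding a conserved protein motif.
#'
#' @format Named list of character vectors; names are the 15 IUPAC symbols.
#' @export
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# complement of every IUPAC symbol (R<->Y, K<->M, B<->V, D<->H; S,W,N self)
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

# Standard genetic code (NCBI transl_table 1), codons in TCAG order.
.CODE_STRING <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.make_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  stats::setNames(strsplit(.CODE_STRING, "")[[1]], codons)
}

#' Standard genetic code
#'
#' @return Named character vector of 64 entries mapping codons to one-letter
#'   amino acids, with `*` for the three stop codons.
#' @export
genetic_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- .make_genetic_code()
    code
  }
})

#' @rdname genetic_code
#' @param aa single one-letter amino acid code (or `*`)
#' @return `codons_for()`: the codons translating to `aa`.
#' @export
codons_for <- function(aa) {
  code <- genetic_code()
  names(code)[code == aa]
}

.valid_nuc_chars <- strsplit(.IUPAC_FROM, "")[[1]]

#' Validate and normalise a nucleotide sequence
#'
#' Uppercases the input and checks every symbol against the 15-letter IUPAC
#' DNA alphabet. `U` is rejected rather than converted: the surveyed material
#' is genomic DNA, so an RNA letter signals a data error.
#'
#' @param x character scalar
#' @return normalised uppercase sequence
#' @export
as_nuc_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (nchar(x) == 0L) stop("empty nucleotide sequence")
  ch <- strsplit(x, "")[[1]]
  bad <- setdiff(unique(ch), .valid_nuc_chars)
  if (length(bad))
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
  x
}

#' Is a concrete base compatible with an IUPAC symbol?
#'
#' @param symbol IUPAC code (one character)
#' @param base concrete base in `A`, `C`, `G`, `T`
#' @return `TRUE` iff `base` is in the expansion set of `symbol`; reflexive
#'   for concrete bases.
#' @export
iupac_compatible <- function(symbol, base) {
  set <- IUPAC_DNA[[toupper(symbol)]]
  if (is.null(set)) stop("unknown IUPAC symbol: ", symbol)
  if (!base %in% c("A", "C", "G", "T")) stop("base must be concrete A/C/G/T")
  base %in% set
}

# vectorised compatibility of two symbol vectors: do expansion sets intersect?
.iupac_sets_intersect <- function(a, b) {
  mapply(function(x, y) length(intersect(IUPAC_DNA[[x]], IUPAC_DNA[[y]])) > 0L,
         a, b, USE.NAMES = FALSE)
}

#' Degeneracy of an IUPAC-coded sequence
#'
#' Product over positions of the expansion-set sizes; 1 iff the sequence is
#' concrete.
#'
#' @param seq nucleotide sequence (IUPAC alphabet)
#' @return integer (may be large; returned as double for long primers)
#' @export
expansion_count <- function(seq) {
  seq <- as_nuc_seq(seq)
  ch <- strsplit(seq, "")[[1]]
  prod(vapply(ch, function(s) length(IUPAC_DNA[[s]]), integer(1)))
}

#' Reverse complement with ambiguity codes
#'
#' Ambiguity codes map to their complement codes (R-Y, K-M, B-V, D-H; S, W
#' and N are self-complementary), so the expansion set of the result is the
#' reverse complement of the input's expansion set.
#'
#' @param seq nucleotide sequence
#' @return reverse-complemented sequence, same length
#' @export
reverse_complement <- function(seq) {
  seq <- as_nuc_seq(seq)
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# all concrete expansions of a short IUPAC string (codons: <= 64)
.expand_iupac <- function(seq) {
  sets <- IUPAC_DNA[strsplit(seq, "")[[1]]]
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}

# translate one codon that may contain ambiguity codes: single amino acid if
# all expansions agree, otherwise "X"
.translate_codon <- function(codon, code) {
  if (grepl("^[ACGT]{3}$", codon)) return(unname(code[codon]))
  aas <- unique(unname(code[.expand_iupac(codon)]))
  if (length(aas) == 1L) aas else "X"
}

#' Frame-aware translation
#'
#' Translates complete codons starting at `frame` (0, 1 or 2); the trailing
#' partial codon is dropped. Codons containing ambiguity codes yield their
#' unique amino acid when all expansions agree and `X` otherwise, so
#' primer-contributed degenerate ends of amplicons translate conservatively.
#'
#' @param seq nucleotide sequence
#' @param frame integer offset 0..2
#' @return protein sequence (one-letter codes, `*` for stop, `X` ambiguous)
#' @export
translate_dna <- function(seq, frame = 0) {
  seq <- as_nuc_seq(seq)
  stopifnot(frame %in% 0:2)
  n <- nchar(seq)
  if (n - frame < 3) stop("sequence too short to translate in this frame")
  code <- genetic_code()
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- vapply(codons, .translate_codon, character(1), code = code)
  if (all(aa == "X")) stop("no resolvable codon in any expansion")
  paste(aa, collapse = "")
}

#' Are two concrete codons synonymous?
#'
#' @param a,b concrete codons (3 nt, no ambiguity codes)
#' @return `TRUE` iff both map to the same amino acid under the standard code
#' @export
is_synonymous <- function(a, b) {
  code <- genetic_code()
  if (!grepl("^[ACGT]{3}$", a) || !grepl("^[ACGT]{3}$", b))
    stop("synonymy is defined for concrete codons only")
  unname(code[a]) == unname(code[b])
}

#' Read and write FASTA
#'
#' Thin wrappers over seqinr preserving record IDs verbatim. Sequences are
#' returned as a named character vector of uppercase strings.
#'
#' @param path file path
#' @param seqs named character vector of sequences
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  stats::setNames(toupper(vapply(recs, as.character, character(1))),
                  names(recs))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}
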