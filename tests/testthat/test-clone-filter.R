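make_clones <- function(seqs, lib = "libA") {
  data.frame(clone_id = sprintf("c%03d", seq_along(seqs)), library_id = lib,
             sequence = seqs, stringsAsFactors = FALSE)
}

test_that("clone collapsing preserves totals and orders deterministically", {
  cl <- make_clones(c(rep("AAAT", 5)))
  fr <- collapse_clones(cl)
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$clone_count, 5L)

  cl2 <- make_clones(c(rep("AAA", 2), "AAT"))
  fr2 <- collapse_clones(cl2)
  expect_identical(fr2$sequence, c("AAA", "AAT"))
  expect_identical(sum(fr2$clone_count), nrow(cl2))

  empty <- data.frame(clone_id = character(), library_id = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  expect_identical(nrow(collapse_clones(empty)), 0L)
  bad <- rbind(make_clones("AAA", "x"), make_clones("AAA", "y"))
  expect_error(collapse_clones(bad), "single library")
})

test_that("pair classification applies the allelic and error rules", {
  # one synonymous difference (GAA/GAG both Glu), both multi-clone
  expect_identical(classify_pair("GAAGAAGAA", 3, "GAAGAGGAA", 2),
                   "allelic_variants")
  # one non-synonymous difference carried by a singleton
  expect_identical(classify_pair("GAAGAAGAA", 4, "GAAGATGAA", 1),
                   "artifact")
  # too many differences: a distinct locus
  expect_identical(classify_pair("GAAGAAGAAGAAGAA", 3,
                                 "GTGGTGGTGGAAGAA", 3), "distinct")
  # synonymous but singleton fails the allelic rule
  expect_identical(classify_pair("GAAGAAGAA", 5, "GAAGAGGAA", 1),
                   "distinct")
  # non-synonymous with both multi-clone is not an artifact
  expect_identical(classify_pair("GAAGAAGAA", 5, "GAAGATGAA", 2),
                   "distinct")
  # unequal lengths bypass the rules
  expect_identical(classify_pair("GAAGAA", 5, "GAAGAAGAA", 1), "distinct")
  expect_error(classify_pair("GAA", 2, "GAA", 2), "collapsed")
  # frame shifts what counts as synonymous
  expect_identical(classify_pair("TGAAGAAGAA", 3, "TGAAGAGGAA", 2,
                                 frame = 1), "allelic_variants")
})

test_that("library filtering excludes artifacts, links alleles, stays
           idempotent", {
  fr <- data.frame(
    sequence = c("GAAGAAGAAGAA",   # major variant
                 "GAAGAGGAAGAA",   # synonymous, 2 clones: allele
                 "GAAGATGAAGAA",   # non-synonymous singleton: artifact
                 "TTTTTTCCCCCC"),  # far away: own locus
    clone_count = c(5L, 2L, 1L, 4L),
    library_id = "libA", stringsAsFactors = FALSE)
  out <- filter_library(fr)
  expect_identical(out$status[out$sequence == "GAAGATGAAGAA"],
                   "artifact_excluded")
  expect_match(out$status[out$sequence == "GAAGAGGAAGAA"],
               "^allelic_variant_of:")
  expect_identical(out$locus_id[out$sequence == "GAAGAGGAAGAA"],
                   out$locus_id[out$sequence == "GAAGAAGAAGAA"])
  # two loci survive
  expect_identical(length(unique(stats::na.omit(out$locus_id))), 2L)
  # idempotence on the retained set
  again <- filter_library(out)
  expect_identical(again$status, out$status[out$status !=
                                              "artifact_excluded"])
  # a synonymous singleton is merged, not excluded
  fr2 <- data.frame(sequence = c("GAAGAAGAAGAA", "GAAGAGGAAGAA"),
                    clone_count = c(5L, 1L), library_id = "libA",
                    stringsAsFactors = FALSE)
  out2 <- filter_library(fr2)
  expect_match(out2$status[2], "^allelic_variant_of:")
  # an error stacked on the minor allele is still recognised
  fr3 <- data.frame(sequence = c("GAAGAAGAAGAA", "GAAGAGGAAGAA",
                                 "GATGAGGAAGAA"),
                    clone_count = c(5L, 3L, 1L), library_id = "libA",
                    stringsAsFactors = FALSE)
  out3 <- filter_library(fr3)
  expect_identical(out3$status[out3$sequence == "GATGAGGAAGAA"],
                   "artifact_excluded")
  # a 3-nt non-synonymous singleton is kept but flagged
  fr4 <- data.frame(sequence = c("GAAGAAGAAGAA", "GATGATGATGAA"),
                    clone_count = c(5L, 1L), library_id = "libA",
                    stringsAsFactors = FALSE)
  out4 <- filter_library(fr4)
  expect_identical(out4$status[out4$sequence == "GATGATGATGAA"], "distinct")
  expect_true(out4$flagged[out4$sequence == "GATGATGATGAA"])
})

test_that("filtering never drops multi-clone fragments and never increases
           locus count beyond fragment count", {
  set.seed(8)
  base <- random_nuc(30)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(base, "")[[1]]
      k <- sample(0:4, 1)
      if (k > 0) {
        pos <- sample(30, k)
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    fr <- data.frame(sequence = unique(seqs),
                     clone_count = sample(1:6, length(unique(seqs)), TRUE),
                     library_id = "lib", stringsAsFactors = FALSE)
    out <- filter_library(fr)
    multi <- out$clone_count >= 2
    expect_false(any(out$status[multi] == "artifact_excluded"))
    expect_lte(length(unique(stats::na.omit(out$locus_id))), nrow(fr))
  }
})

test_that("clone FASTA headers carry library and count tokens", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">c1 library=libX count=3", "ACGTACGT",
               ">c2 library=libX", "ACGTACGA",
               ">c3", "TTTTTTTT"), tmp)
  cl <- read_clone_fasta(tmp, default_library = "libZ")
  expect_identical(nrow(cl), 5L)                      # count=3 expands
  expect_identical(sum(cl$library_id == "libX"), 4L)
  expect_identical(cl$library_id[5], "libZ")
  fr <- collapse_clones(cl[cl$library_id == "libX", ])
  expect_identical(fr$clone_count, c(3L, 1L))
  out <- tempfile(fileext = ".tsv")
  write_fragments_tsv(filter_library(fr), out)
  expect_true(file.exists(out))
})
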