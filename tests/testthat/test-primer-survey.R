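test_that("motif validation accepts the survey primers and flags mismatches", {
  # forward primer read at offset 0
  r <- validate_primer_motif("GARAARGARTTYYTNTTYAAYCC", "EKEFLFNP", "forward")
  expect_identical(r$frame, 0L)
  expect_identical(r$motif_start, 1L)
  # reverse primer valid on its reverse complement
  expect_silent(validate_primer_motif("TTCATNCKNCKRTTYTGRAACCA",
                                      "WFQNRRMK", "reverse"))
  # an oligo that cannot encode the motif is a transcription error
  expect_error(validate_primer_motif("ATGATG", "KK", "forward"),
               "motif mismatch")
  # HoxF1N2's printed motif contradicts its printed sequence
  expect_error(validate_primer_motif(primer_seq("HoxF1N2"), "QLTELEKEF",
                                     "forward"), "motif mismatch")
  expect_silent(validate_primer_motif(primer_seq("HoxF1N2"), "QVTELEKEF",
                                      "forward"))
})

test_that("every motif-bearing primer in the packaged table validates", {
  tab <- fixture_primers()
  for (i in seq_len(nrow(tab))) {
    if (tab$aa_motif[i] == "5' UTR") next
    expect_silent(validate_primer_motif(tab$sequence[i], tab$aa_motif[i],
                                        tab$direction[i]))
  }
})

test_that("binding-site scan is exhaustive, sorted and strand-aware", {
  tmpl <- paste0(random_nuc(10), "ACGTTTGGCCAAGGTTCCAATTGG", random_nuc(10))
  s <- find_binding_sites("ACGTTTGGCCAAGGTTCCAATTGG", tmpl, 0, "forward")
  expect_identical(s$start, 10L)
  expect_identical(s$end, 34L)

  s2 <- find_binding_sites("AYG", "ACGATG", 0, "forward")
  expect_identical(s2$start, c(0L, 3L))

  expect_identical(nrow(find_binding_sites("ACGACG",
                                           paste(rep("T", 50), collapse = ""),
                                           0, "forward")), 0L)
  # template shorter than primer: empty result, not an error
  expect_identical(nrow(find_binding_sites("ACGTACGT", "ACG", 0, "forward")),
                   0L)
  # reverse primers are matched as their reverse complement on +
  tmpl3 <- paste0("AAAA", reverse_complement("TTGGCCAA"), "AAAA")
  s3 <- find_binding_sites("TTGGCCAA", tmpl3, 0, "reverse")
  expect_identical(s3$start, 4L)
  expect_identical(s3$strand, "-")
  # 3'-terminal mismatches disqualify a site even within max_mismatch
  tmpl4 <- paste0("AAAA", "ACGTACGA", "AAAA")  # last base mismatches ACGTACGT
  expect_identical(nrow(find_binding_sites("ACGTACGT", tmpl4, 1, "forward",
                                           three_prime_strict = TRUE)), 0L)
  expect_identical(nrow(find_binding_sites("ACGTACGT", tmpl4, 1, "forward",
                                           three_prime_strict = FALSE)), 1L)
})

test_that("in-silico PCR pairs sites, windows product length and shifts", {
  roots <- fixture_roots()
  pg1 <- roots$nt[roots$gene == "A1"]
  amp <- in_silico_pcr(primer_seq("HoxF1"), primer_seq("HoxR1"), pg1)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, amp$end - amp$start)
  expect_identical(amp$sequence, substr(pg1, amp$start + 1, amp$end))
  # invariance under template prefixing, modulo coordinate shift
  amp2 <- in_silico_pcr(primer_seq("HoxF1"), primer_seq("HoxR1"),
                        paste0(random_nuc(37), pg1))
  expect_identical(amp2$start, amp$start + 37L)
  expect_identical(amp2$sequence, amp$sequence)
  # size window excludes otherwise valid pairings
  none <- in_silico_pcr(primer_seq("HoxF1"), primer_seq("HoxR1"), pg1,
                        min_len = 150, max_len = 165)
  expect_identical(nrow(none), 0L)
  # no reverse site downstream of a forward site -> empty
  half <- substr(pg1, 1, 100)
  expect_identical(nrow(in_silico_pcr(primer_seq("HoxF1"),
                                      primer_seq("HoxR1"), half)), 0L)
})

test_that("canonical fixtures reproduce printed product lengths where the
           table is internally consistent", {
  roots <- fixture_roots()
  cases <- list(c("HoxF7S", "HoxR1", "A6", 149),
                c("HoxF2S", "HoxR1", "A2", 152),
                c("HoxF8S", "HoxR1", "B8", 116),
                c("HoxF9S", "HoxR1", "A9", 116),
                c("HoxF9", "HoxR1", "A9", 164),
                c("HoxF11", "HoxR1", "A11", 122),
                c("HoxF3S1", "HoxR1", "A3", 80),
                c("HoxF13A1", "HoxR13", "A13", 128),
                c("HoxF13A", "HoxR14", "A14", 89))
  for (cs in cases) {
    amp <- in_silico_pcr(primer_seq(cs[1]), primer_seq(cs[2]),
                         roots$nt[roots$gene == cs[3]])
    expect_identical(amp$length, as.integer(cs[4]),
                     label = paste(cs[1], cs[2], "on", cs[3]))
  }
})

test_that("tiered survey escalates exactly where general primers fail", {
  roots <- fixture_roots()
  templates <- stats::setNames(roots$nt, roots$gene)
  sv <- tiered_survey(templates, fixture_primers())
  expect_true(all(sv$detected))
  # a divergent HoxC5 is recovered only by its member-specific primer
  expect_identical(sv$tier[sv$gene == "C5"], "member_specific")
  expect_identical(sv$fwd[sv$gene == "C5"], "HoxFC5")
  # paralogue groups 1-11 except C5 fall to the general tier
  anterior <- sv$gene[sv$pg <= 11 & sv$gene != "C5"]
  expect_true(all(sv$tier[sv$gene %in% anterior] == "general"))
  # genes without a template stay undetected
  sv2 <- tiered_survey(templates[names(templates) != "D12"],
                       fixture_primers())
  expect_false(sv2$detected[sv2$gene == "D12"])
  # empty pool: nothing detected
  sv3 <- tiered_survey(stats::setNames(character(), character()),
                       fixture_primers())
  expect_false(any(sv3$detected))
  expect_error(tiered_survey(templates, fixture_primers()[0, ]), "empty")
})
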