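test_that("root homeoboxes cover the universe and carry their primer
           anchors exactly", {
  roots <- fixture_roots()
  prim <- fixture_primers()
  expect_setequal(roots$gene, hox_universe())
  expect_true(all(nchar(roots$nt) == 180))
  expect_true(all(nchar(roots$aa) == 60))
  expect_false(any(grepl("*", roots$aa, fixed = TRUE)))
  expect_true(all(vapply(seq_len(nrow(roots)), function(i)
    translate_dna(roots$nt[i]) == roots$aa[i], logical(1))))
  anchors <- attr(roots, "anchors")
  for (g in roots$gene) {
    nt <- roots$nt[roots$gene == g]
    for (a in anchors[[g]]) {
      row <- prim[prim$name == a[[1]], ]
      sites <- find_binding_sites(row$sequence, nt, 0, row$direction)
      expect_true(as.integer(a[[2]]) %in% sites$start,
                  label = paste(g, a[[1]]))
    }
  }
})

test_that("panel evolution is seeded, anchored and rate-consistent", {
  roots <- fixture_roots()
  prim <- fixture_primers()
  # zero rate: panel identical to roots
  p0 <- evolve_panel(default_guide_tree(), roots,
                     sim_config(seed = 5, rate = 0), prim)
  expect_true(all(p0$nt == roots$nt[match(p0$gene, roots$gene)]))
  # same seed, same panel
  p1 <- evolve_panel(default_guide_tree(), roots, sim_config(seed = 6), prim)
  p2 <- evolve_panel(default_guide_tree(), roots, sim_config(seed = 6), prim)
  expect_identical(p1, p2)
  # two-leaf tree of total length t: mean pairwise K2P distance ~ rate * t
  two <- ape::read.tree(text = "(x:0.08,y:0.08);")
  pr <- evolve_panel(two, roots[roots$gene %in%
                                  c("A4", "B9", "C10", "D4"), ],
                     sim_config(seed = 8), prim)
  ds <- vapply(unique(pr$gene), function(g) {
    as.numeric(k2p_distance(pr$nt[pr$gene == g & pr$species == "x"],
                            pr$nt[pr$gene == g & pr$species == "y"]))
  }, numeric(1))
  # anchored positions resist substitution, so the realised rate sits a bit
  # below the nominal 0.16 but well away from 0 or 2x
  expect_gt(mean(ds), 0.06)
  expect_lt(mean(ds), 0.26)
  # panel FASTA round trip
  tmp <- tempfile(fileext = ".fa")
  write_panel_fasta(p1[1:8, ], tmp)
  back <- read_panel_fasta(tmp)
  expect_identical(back$nt, p1$nt[1:8])
  expect_identical(back$gene, p1$gene[1:8])
})

test_that("templates exist exactly for the genes of the true inventory", {
  roots <- fixture_roots()
  prim <- fixture_primers()
  cfg <- sim_config(seed = 3)
  expect_length(make_templates(character(), roots, cfg, prim), 0L)
  t39 <- make_templates(hox_core_placental(), roots, cfg, prim)
  expect_length(t39, 39L)
  lf <- make_templates(build_inventory(c("A14", "B10", "C1", "C3"), "D12"),
                       roots, cfg, prim)
  expect_length(lf, 42L)
  expect_setequal(names(lf), build_inventory(c("A14", "B10", "C1", "C3"),
                                             "D12"))
})

test_that("clone libraries honour the allele and error dials with known
           truth", {
  roots <- fixture_roots()
  prim <- fixture_primers()
  inv <- c("A1", "B2", "A6", "C12")
  # no alleles, no errors: every clone faithful
  cfg0 <- sim_config(seed = 9, allele_prob = 0, error_prob = 0)
  tm <- make_templates(inv, roots, cfg0, prim)
  sim0 <- simulate_library(tm, prim, cfg0, taxon = "t")
  expect_true(all(sim0$truth$provenance == "faithful"))
  expect_identical(nrow(sim0$clones), nrow(sim0$truth))
  # allele probability 1: every locus carries a linked second haplotype
  cfg1 <- sim_config(seed = 9, allele_prob = 1, error_prob = 0)
  sim1 <- simulate_library(make_templates(inv, roots, cfg1, prim),
                           prim, cfg1, taxon = "t")
  for (lib in unique(sim1$truth$library_id)) {
    for (g in unique(sim1$truth$gene[sim1$truth$library_id == lib])) {
      sub <- sim1$truth[sim1$truth$library_id == lib & sim1$truth$gene == g, ]
      counts <- table(sub$sequence)
      expect_identical(length(counts), 2L, label = paste(lib, g))
      expect_true(all(counts >= 2))
    }
  }
  # determinism and the product size window
  cfgd <- sim_config(seed = 12)
  tmd <- make_templates(inv, roots, cfgd, prim)
  sa <- simulate_library(tmd, prim, cfgd, taxon = "t")
  sb <- simulate_library(tmd, prim, cfgd, taxon = "t")
  expect_identical(sa$clones, sb$clones)
  expect_true(all(nchar(sa$clones$sequence) >= 80 &
                    nchar(sa$clones$sequence) <= 165))
})

test_that("recovery reports count false calls exactly", {
  truth <- list(t1 = c("A1", "B2"), t2 = c("A1"))
  perfect <- presence_matrix(truth)
  rep0 <- recovery_report(perfect, truth)
  expect_identical(rep0$accuracy, 1)
  expect_identical(rep0$false_absent, 0L)
  dropped <- perfect
  dropped["t1", "B2"] <- 0L
  rep1 <- recovery_report(dropped, truth)
  expect_identical(rep1$false_absent, 1L)
  expect_identical(rep1$false_present, 0L)
  expect_error(recovery_report(perfect, list(zz = "A1")), "no shared taxa")
})
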