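---
title: "Reconstructing Hox gene inventories from degenerate-PCR surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Hox gene inventories from degenerate-PCR surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxsurvey)
```

## The problem

Sarcopterygians (lobe-finned fishes plus tetrapods) carry four Hox clusters
(A-D) whose gene content varies across lineages within a 43-gene universe:
the 39-gene placental core plus four genes (HoxA14, HoxB10, HoxC1, HoxC3)
retained only in basal lineages. Because whole-genome assemblies are missing
for many key groups (lungfishes, caecilians, salamanders, snakes, turtles,
crocodiles), inventories are established by comprehensive degenerate-PCR
surveys of the 180-bp homeobox, followed by phylogenetic assignment of the
amplified fragments to exact gene members and presence/absence analysis on a
species tree. `hoxsurvey` implements that entire chain as tested, seeded
code, together with a synthetic-data generator that provides ground truth
for every stage.

## The survey model

**Degenerate primers.** A primer written in the 15-letter IUPAC alphabet
covers every codon variant of a conserved protein motif. The packaged primer
table records, for each oligo, its motif, targets and escalation tier.
Motif validation checks that, from some frame offset, every complete codon
of the primer (reverse primers read as their reverse complement) can encode
the corresponding motif residue; a failure flags a transcription error. The
weaker "can encode" (non-empty intersection) criterion is deliberate: real
degenerate primers often cover a superset of the residue's codons (`YTN`
spans Leu and part of Phe) or only its common codons (`CKN` hits `CGN`
arginines but not `AGR`), so neither containment direction holds for
working primer sets.

**In-silico PCR.** Binding sites are all template windows compatible with
the primer within a mismatch budget (default 0); by default any mismatch in
the primer's 3'-terminal 3 nt disqualifies a site, because polymerase
extension is most sensitive there. Products pair a forward site with each
downstream reverse site and are kept when their span lies in the survey's
80-165 bp window. Coordinates are 0-based half-open on the plus strand
throughout.

**Tiered escalation.** General primer pairs are run first; any target gene
without a product is retried with paralogue-group-specific primers and
finally member-specific ones. The synthetic HoxC5 root is built divergent
from the general primers on purpose, so the escalation path (HoxF5S, then
HoxFC5) is exercised and tested, mirroring how a refractory gene is chased
in practice.

**Clone filtering.** Within one library (species x primer pair), unique
sequences differing by 1-3 nucleotides that are all synonymous and each
seen in more than one clone are allelic variants of one locus; a
non-synonymous difference of 1-2 nucleotides carried by a single clone is a
PCR/sequencing error and is excluded. Cases the rules leave open are
resolved conservatively and are documented in the function help: synonymous
singletons are merged into the majority variant; non-synonymous variants
with two or more clones stay distinct candidate loci; 3-nt non-synonymous
singletons are kept but flagged; any amino-acid-changing difference defeats
the allelic rule even when mixed with synonymous ones. All retained
sequences are compared against each other, so an error stacked on a minor
allele is still recognised.

## Ortholog assignment

Fragments are anchored ungapped against the reference panel: homeoboxes are
a fixed-length, indel-free region, so gapped multiple alignment is replaced
by sliding the translated fragment along the panel's consensus homeodomain
in both orientations, keeping the placement with the highest protein
identity. Fragments covering fewer than 20 codons or below 40% consensus
identity are rejected (the analogue of a non-Hox screening hit); random
sequences score far below this threshold, while genuine posterior-group
fragments sit near 45-60% against a consensus dominated by anterior groups,
which is why the threshold is 0.4 rather than 0.5.

Assignment is two-level, as in homeobox surveys: neighbor-joining trees of
the fragment plus its panel neighborhood are built first on maximum-
likelihood JTT protein distances; the fragment's smallest containing clade
whose other leaves share one gene label names the candidate. Support is the
percentage of column-bootstrap replicates in which the recomputed defining
clade points to the same gene; this replicate-level re-reading is more
stable than tracking a single bipartition, because the fragment's exact
sister species legitimately varies across replicates. If protein-level
support stays below `min_support` (default 70; the survey literature does
not state a threshold, so this default is an explicit stand-in), the same
procedure is repeated with Kimura two-parameter distances on the nucleotide
columns - this is what separates paralogue groups whose homeodomain
proteins are nearly identical (all of PG6 in the synthetic panel). Failing
both levels, the fragment is reported `ambiguous`, a value rather than an
error.

Numerical choices: K2P uses pairwise deletion of ambiguous columns and maps
saturated pairs (non-positive log argument) to a ceiling `d_max` (default
5) so NJ always sees a complete matrix. The JTT distance maximises the
site-pattern likelihood under the published Jones-Taylor-Thornton
exchangeabilities and equilibrium frequencies (not alignment-empirical
ones, i.e. JTT rather than JTT+F), bracketing the optimum on a log-spaced
grid and refining with Brent's method; inside bootstrap replicates a
coarser grid is used because only the induced topology matters. The NJ
implementation breaks Q-criterion ties towards the lexicographically
smallest pair of cluster labels for cross-platform determinism, and clamps
negative branch lengths to zero, moving the remainder to the sister edge.

## Inventory evolution by Dollo parsimony

A Hox gene is gained once and can only be lost, so the minimal history
places the gain at the root (when outgroups establish ancestral presence)
or at the carriers' MRCA, and counts one loss per maximal subtree of absent
leaves below the gain node. Unknown states (e.g. HoxC3 in marsupials and
monotremes, whose HoxC assemblies lack the flanking sequence) are excluded
per character, not imputed. Competing topologies are scored by their
required loss counts; for HoxC3 across amniotes the four turtle-placement
hypotheses score A = 3, B = 3, C = 2, D = 2 losses, and for HoxC1 the
Batrachia arrangement of the living amphibians needs strictly fewer losses
than the alternative. The tuatara is absent from the packaged matrix, as it
is from the survey data.

## What the generator emulates - and what it does not

The generator owns every input with known truth:

* **Root homeoboxes** place the primers' protein motifs at fixed
  homeodomain coordinates (the WFQNRR recognition-helix block at residues
  48-53), with codons drawn from the primers' expansion sets so every
  designated primer matches its root exactly. Paralogue groups differ at
  diagnostic helix-region positions and clusters at six further positions,
  as in real homeodomains; PG6 members are protein-identical on purpose.
  The printed product-length column of the primer table is internally
  inconsistent at the few-bp level, so product lengths are asserted only
  where the primer arithmetic reproduces them exactly (HoxF7S 149, HoxF2S
  152, HoxF8S 116, HoxF9 164, HoxF11 122, HoxF13A1 128, HoxR14 89).
* **Panels** evolve each root independently along a guide tree under a K2P
  process (default rate multiplier 1, kappa 2, four species at desk-scale
  divergences of 0.03-0.05 substitutions/site per branch); primer-anchored
  positions only accept compatible substitutions and in-frame stops are
  refused.
* **Templates** for a surveyed taxon evolve from the panel entry of a
  related species (default branch length 0.05) and embed the homeobox in
  random 60-nt flanks, so primers must find it. Evolving templates from the
  universe root instead produces fragments basal to every gene clade - a
  placement NJ resolves poorly, and a geometry the real survey does not
  have, since surveyed species are relatives of the reference species.
* **Libraries** draw zero-truncated Poisson clone counts (mean 8 per
  amplicon) over all tier-matched primer pairs; with probability 0.15 a
  locus carries a second haplotype (1-3 synonymous changes, at least two
  clones), and each clone is hit by an error (1-2 non-synonymous changes,
  singleton) with probability 0.03, a realistic Taq-plus-Sanger figure.
  Six surveyed lineages at these defaults produce roughly 3,500-3,900
  clones, the scale of the real survey.

Not emulated: polymerase error spectra, chimeras, primer-dimers, indels,
chromatogram-level noise, and real sequence divergence patterns
(synonymous-site saturation, codon-usage bias). Passing the end-to-end
checks therefore demonstrates that the pipeline's logic is correct at
realistic signal-to-noise, not that these thresholds are optimal for any
particular real dataset.

## Problem sizes used by the test suite

The packaged checks run the full six-lineage synthetic survey once
(~3,500-3,900 clones, ~450 validated loci, 50 bootstrap replicates per
fragment and level), verify the Dollo and NJ engines against exhaustive
oracles on 1,000 random instances each of up to 8 taxa, and recover a JTT
distance of 0.3 from 10,000 simulated sites. The pipeline default of 1,000
bootstrap replicates follows the survey convention; the smaller replicate
counts in tests are a documented choice of problem size, with support
thresholds unchanged.

## Known limitations

* Assignment support is meaningful only relative to the supplied panel; a
  gene missing from the panel can only yield `ambiguous` or a wrong
  neighbor, never "novel gene".
* The ungapped anchoring assumes indel-free homeoboxes; a panel with
  length-variant entries is rejected on load.
* Dollo parsimony reports equally parsimonious loss placements only through
  the per-character counts; it does not enumerate alternative histories.
* The in-silico PCR has no thermodynamic model; mismatch counting with a
  3'-end rule is a deliberate, documented simplification.
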