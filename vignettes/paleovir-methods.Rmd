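---
title: "Reconstructing and dating endogenous pararetroviruses with paleovir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and dating endogenous pararetroviruses with paleovir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant pararetroviruses (family Caulimoviridae) replicate episomally and
carry no integrase, yet fragments of their circular dsDNA genomes are
captured into host chromosomes during double-strand-break repair and
then inherited vertically.  These endogenous viral elements (EVEs) are
molecular fossils: each insertion is a dated snapshot of a virus that
infected the host's ancestors.  Because selection on the viral sequence
stops at endogenization, mutations accumulate independently in each
copy, and a per-column majority ("modal") consensus over many decayed
copies approximates the ancestral exogenous genome.  Orthologous
insertions shared between related host species further bracket the
insertion's age between the divergence times of the species that share
it and those that do not.

`paleovir` implements this whole analysis at desk scale:

1. **Discovery** — seeded translated (protein-probe) and nucleotide
   (consensus-library) homology search, and chaining of hits into loci.
2. **Reconstruction** — tolerant anchored assembly of the recruited
   fragments into a circular majority consensus, rotated so the
   tRNA-Met primer-binding-site motif marks position 0 (the family's
   convention for the start of the genome).
3. **Annotation** — ORF finding (circular-aware), polyprotein domain
   placement (MP, CP, AP, RT, RH1, plus the second ORF), species
   demarcation at 80% RT–RH1 identity, classification of bipartite
   component A (RT/RH1 retained, CP lost) and component B (MP/CP/AP
   retained, RT lost) genomes, conspecific A/B pairing through the
   shared intergenic region, and replication-competency scanning
   (copy multiplicity, tandem structure, intact ORFs).
4. **Integration landscape** — genome occupancy, distances to genes
   and transposable elements, intron overlap, (TA)n-repeat proximity
   enrichment against a randomized null, flank-redundancy clustering,
   joining of insertions split by younger nested insertions, and
   exact-match small-RNA coverage.
5. **Dating** — flank-based orthology matching into a
   presence/absence/missing matrix and single-gain (Dollo) parsimony
   placement on a calibrated ultrametric species tree, yielding a
   minimum-age bracket per insertion.

A first-class synthetic-data module simulates every layer with exact
ground truth, so the full pipeline is testable without any external
assembly.

## The synthetic generative model

`simulate_ancestral_virus()` draws a circular genome of 7.2–8.5 kbp
(the size range of complete florendovirus-like genomes) with the
canonical layout: origin motif at position 0, a short leader, ORF1
encoding the MP–CP–AP–RT–RH1 polyprotein from random sense codons
(stop-free by construction), ORF2 in a different translational frame,
and a non-coding intergenic region closing the circle.  Domain
lengths are fractions of the ORF1 protein (defaults 0.22, 0.18, 0.08,
0.26, 0.12, the remainder as linkers), sized so the polyprotein comes
out near the observed 1,900 residues.  The origin motif is kept unique
in the genome up to two mismatches so rotation recovery is
well defined.

`simulate_endogenization()` plants decayed fragments into i.i.d.
uniform ACGT host sequences.  Per insertion it samples a contiguous
sub-interval of the circle — the start is uniform *on the circle*, so
fragments may span the origin; this keeps expected coverage flat along
the genome, which matters for consensus recovery — a strand,
independent per-site substitutions (uniform over the three alternative
bases) and geometric-length indels.  With probability `ta_bias` a
(TA)n run is written at the integration site so the insertion is
TA-flanked; with probability `nested_prob` the insertion lands inside
an older one, splitting it into two collinear parts (exercising the
long-join repair); with probability `intron_bias` it is placed inside
a simulated intron.  Divergent reverse-transcriptase-like decoys
(default 35% divergence) are planted to probe masking specificity.
Every inserted base records exact provenance.

What the generator deliberately does **not** model: realistic base
composition, codon-usage evolution, selection on reading frames,
heterogeneous mutation rates, or assembly artifacts.  Green tests
therefore demonstrate algorithmic correctness under a clean
generative model, not robustness to all features of real assemblies.
Survey-scale genome masking (hundreds of megabases)
is out of desk scale by design.

The decay-rate defaults (3% substitutions, 0.1–0.2% indels per site)
are free parameters, not estimates — no quantitative decay rates are
published for these elements; they were chosen once to represent a
moderately decayed family where discovery is non-trivial but
reconstruction is possible, and the recovery studies sweep
substitution rates 0–15% explicitly.

`simulate_ortholog_history()` places one gain per locus on a branch
drawn proportionally to branch duration (including a root stem,
default a quarter of the root age, so unbounded-above brackets occur),
then loses it along descendant lineages as a Poisson process per MY;
tip observations turn "missing" with a configurable probability,
emulating unassembled genomes.  `simulate_ortholog_genomes()` realizes
the history as per-tip sequences: present sites carry
flank–EVE–flank, empty sites retain the pre-insertion (TA)n run
between the same flanks, missing tips omit the region.

## Search parameters

Translated search re-implements a tBLASTN-style scan as exact
amino-acid `k`-mer seeds (default k = 4) gated by ungapped x-drop
extension, followed by affine-gap Smith–Waterman (BLOSUM62, gap open
−11 / extend −1) restricted to candidate windows on both the probe
and the subject.  Subjects up to 20 kb skip seeding entirely, so on
small inputs the search *is* exhaustive six-frame local alignment —
this is the regime in which the test suite proves exact equivalence
to an independent brute-force implementation.  The default reporting
threshold is 25% of the probe self-score; the discovery thresholds of
the original analyses are not published, so this is a package default
meant to be overridden per probe.

Nucleotide masking mirrors a RepeatMasker-style screen: score cutoff
250 (match +2, mismatch −3, gap −5/−2), maximum divergence 20%
(divergence = 100 × (1 − identity) over gap-free aligned columns — a
simplification of masking-tool divergences, which adjust for CpG),
and only hits longer than 200 bp counted.  At these settings the
planted 35%-divergent RT-like decoys are rejected while 10%-decayed
insertions are recovered over ≥90% of their span.

Hit chaining uses strict gap thresholds (`gap < join_distance`), with
the three conventional distances appearing throughout: 20 bp
(enrichment locus definition), 200 bp (feature-distance clustering),
1 kbp (flank-analysis locus definition).  Coordinates are 0-based
half-open everywhere internally; under that convention two abutting
intervals are at distance 0, which resolves the ±1 ambiguity of
"adjacent" without special cases.  GFF3 export converts to 1-based
inclusive.

## Consensus reconstruction

Assembly is iterative anchored extension: the longest fragment seeds
the scaffold; each further fragment is placed by best local alignment
(tried first against an anchor-guided slice, then the whole scaffold)
and accepted while the mismatch-plus-gap budget stays within
`error_clearance` (default 500) and identity ≥ 0.55; fragments that
cannot be aligned but carry a virus-coordinate anchor are placed by
offset when the implied gap is at most `max_gap` (default 200 bp,
bridged with N).  The 500/200 tolerances follow the relaxed
overlap-assembly settings used for this kind of decayed material; the
assembly algorithm itself is this package's own.  Fragments that can
neither be aligned nor anchored are assembled separately and reported
as additional contigs rather than silently merged.

Each placed fragment base votes for its scaffold column.  The final
call is the modal base when depth ≥ `min_depth` (default 2); exactly
tied columns take the alphabetically first base by default
(`tie_rule = "n"` emits N instead) — determinism was preferred over
realism here; depth-1 columns take their single observed base but are
flagged low-confidence; bridged gaps are N.  How the original
consensus handled depth floors and ties is not stated anywhere, so
both are exposed as parameters.

Because the genome is circular and fragments may span the origin, a
linear scaffold can end in a rotated duplicate of its start.  After
voting, the builder aligns the scaffold tail against its head
(windows capped at half the scaffold so they are disjoint) and, when
the tail reproduces the head at ≥85% identity over ≥300 columns, folds
the tail votes onto the matching head columns and truncates.  Votes at
fold columns with no projection target are counted in
`n_fold_dropped`, so depth bookkeeping stays exact.

`rotate_to_origin()` scans all rotations for the best origin-motif
match (≤ `max_mismatches`, leftmost on ties, with a warning) and
rotates the sequence and all per-column statistics together.

Under the study conditions used in the recovery tests — 15 fragments
of 2.5–4 kb at 5% substitutions tiling an ~8.4 kb genome at mean
depth ≈ 5.8 — the reconstruction is ≥99% identical to the true
ancestor across seeds 1–10, and identity is non-increasing in the
substitution rate (checked at 0/5/10/15%).

## Enrichment statistics

`ta_enrichment()` merges the EVE annotations at <20 bp, keeps loci
>500 bp, and counts the fraction lying within 1 kbp of a (TA)n run
(period-2 scanner; `min_units = 13` approximates a
tandem-repeat-finder score cutoff of 50 at match weight 2, i.e. 25
matching bp; interruptions up to 3 bp are bridged).  The null is `R`
seeded replicates (default 999) of an equal number of fixed-length
random loci, uniform over N-free positions with overlaps permitted —
exclusion rules for the randomization are not published, so the
simplest shuffle-style null was chosen.  The primary p-value is the
add-one empirical proportion, `(1 + #{replicates ≥ observed}) /
(R + 1)`, never exactly 0.  A Mann–Whitney test comparing the
per-locus nearest-distance sets (observed vs pooled random) is
reported alongside; which samples the published test ranked is
ambiguous, so both statistics are always available and labeled.

The empirical test is exact only when observed loci are exchangeable
with the replicates.  Real EVE loci are sparse (tens of loci per
hundreds of megabases), so the <20 bp merge step is inert; in dense
artificial configurations where observed loci merge, the merged
observed fraction is under-dispersed relative to the fixed-length
replicates and the test becomes conservative (never anticonservative
— the add-one p-value is super-uniform by construction).  In the
sparse regime with uniformly placed loci the type-I error at nominal
0.05 sits inside [0.03, 0.07] across 400 simulations, and with a 50%
integration bias (100 loci, R = 99, ~0.2% of the genome in TA runs)
the test rejects at p ≤ 0.01 in ≥95% of runs.

## Dating

`parse_dated_tree()` requires an ultrametric tree (tips at age 0
within 1e-6 MY, violations reported with the worst tip) with branch
lengths in MY.  `place_insertion()` is hard-coded single-gain Dollo
parsimony: the gain sits on the branch subtending the MRCA of all
present tips; losses are the maximal subtrees underneath whose
non-missing tips are all absent; missing tips neither support nor
penalize a placement.  No other single-gain placement can need fewer
losses (verified against exhaustive enumeration on small trees).
Precise excision is treated as negligible; for sensitivity the
no-loss multiple-gain cost is also reported
(`n_gains_alternative`).  Because a single locus cannot distinguish
true loss from incomplete lineage sorting, the flag is named
`homoplasy_flag`, with ILS as one interpretation.

`age_bracket()` returns the ages of the nodes bounding the gain
branch; a root-branch gain is unbounded above.  On the bundled
calibrated rice tree (eleven Oryza taxa, root fixed at 15 MY), the
locus shared by all AA-genome species except *O. meridionalis*
brackets to 1.832–2.317 MY, and a locus private to *O. glaberrima*
to 0–0.120 MY — the package's worked example, recomputed by
`scripts/acceptance.R`.

Orthology matching clusters locus flanks (500 bp by convention)
single-linkage per side at a configurable identity threshold (the
published criterion is not quantified; 0.90 is the default); a group
is a left-cluster × right-cluster combination, and loci whose two
flanks disagree are set aside as ambiguous.  Genomes without a member
are probed for an empty site: both flanks found directly adjacent
(gap ≤ 200 bp, room for a residual TA run but not an EVE) record
absent; anything else records missing.

## Numerical choices and limitations

* Alignment identity excludes gap columns; p-distances additionally
  exclude N (pairwise deletion), matching the uncorrected-distance
  convention.
* Species demarcation uses single linkage (the published threshold
  does not state a linkage; complete linkage is available), and
  within-species strain clusters use a second configurable threshold
  (default 0.91) since the strain-level cutoff is never stated.
* Seeded search is exact whenever a seed word survives inside a
  reportable alignment; at 20% divergence, 12-mer nucleotide seeds
  occur every ~14 bp in expectation, so misses are vanishingly rare,
  but the guarantee is probabilistic above the exhaustive-mode size.
* All stochastic operations take an explicit seed and restore the
  caller's RNG state; reruns are bit-identical.
* Problem sizes in the test suite (hosts of 30–600 kb, 8–100
  insertions, trees of 6–11 tips, R = 99–999) were chosen as the
  smallest scales at which each statistical property is
  distinguishable from noise.
* The greedy overlap resolution of translated HSPs (by score, ties to
  the leftmost start, dropping >50% overlaps of the shorter hit) can
  merge-shadow near-duplicate placements in different frames; the
  locus chaining downstream is insensitive to this.
* `map_srnas()` maps against the linear consensus; reads spanning the
  circular origin junction are not wrapped.

## A compact worked run

```r
library(paleovir)

virus <- simulate_ancestral_virus(seed = 1)
truth <- simulate_endogenization(virus, host_size = 60000,
                                 n_insertions = 16, ta_bias = 0.3,
                                 seed = 2)

mask  <- nucleotide_mask(truth$host_sequences,
                         c(virus = virus$sequence))
loci  <- merge_hits(mask, join_distance = 200)
frags <- recruit_and_orient(loci, truth$host_sequences)
cons  <- rotate_to_origin(build_consensus(frags), virus$origin_motif)

doms  <- annotate_domains(cons, domain_probes(virus))
classify_component(doms)$value        # "complete"

tree  <- oryza_dated_tree()
hist  <- simulate_ortholog_history(tree, loss_rate = 0.05,
                                   n_loci = 20, seed = 3)
date_insertions(tree, hist$tip_presence)
```
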