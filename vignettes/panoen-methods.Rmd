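---
title: "Methods: pan-genome inference and its synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome inference and its synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`panoen` implements a comparative pan-genome analysis for small bacterial
strain collections of the kind exemplified by *Oenococcus oeni*: a
streamlined ~1.8 Mb genome, around 1800 protein-coding genes and on the
order of a hundred pseudogenes per strain, extensive strain-to-strain
variation in phage content, cell-wall exopolysaccharide (EPS) cassettes,
sugar transport and amino acid biosynthesis, and a species tree with a
divergent basal pair of strains. This vignette documents the models and
procedures, the tunable parameters, the synthetic benchmark and what it
does and does not establish, and the numerical conventions.

## Orthology model

Orthology is assigned by protein homology arbitrated by genomic synteny.

**Alignment.** All homology rests on one deterministic pairwise aligner:
global alignment with free (unpenalised, unaligned) end gaps — the
"overlap" flavour of Needleman–Wunsch — under BLOSUM62 with affine gap
cost `11 + k` for a gap of `k` residues. Identity is the fraction of
matching residue pairs over aligned columns; terminal overhangs never
enter the denominator, internal gap columns do. Coverage is the aligned
span divided by sequence length, computed for both partners. This is the
closest deterministic analogue of local-alignment identity on full-length
orthologs, with no E-value machinery: identity and coverage thresholds
play the role that E-value cut-offs play in heuristic search tools.
Default thresholds are identity ≥ 40%, coverage ≥ 0.5 on both sequences;
they are declared, configurable, and recorded in pipeline reports.

**Prefilter.** A pair is aligned only if the two proteins share at least
`min_shared` 5-mers (default 2 in the exported search functions). The
prefilter can only skip pairs; it never alters a computed score. In the
all-pairs stage of `infer_pan_genome()` the default is raised to 6:
within a strain collection, ortholog pairs share hundreds of exact
5-mers, while amino-acid composition bias makes the ≥2 criterion admit an
order of magnitude more chance pairs than true ones. Any pair dropped by
`min_shared = 6` lies far below the 40% identity threshold. Passing
`rbh_min_shared = 2` restores the strict behaviour.

**Reciprocal best hits and clustering.** For every ordered strain pair,
each query's best passing hit is the top-scoring subject, ties broken to
the lexicographically smallest id; a pair is an RBH when each member is
the other's unique top hit. Because the aligner is symmetric, each
candidate pair is aligned once, which also makes
`reciprocal_best_hits(A, B)` exactly the transpose of the `(B, A)` call.
Provisional loci are the connected components of the RBH graph over all
strain pairs.

**Synteny refinement.** A component in which some strain contributes two
or more members is *conflicted* — the signature of paralogy, tandem
duplication or split genes. Conflicts are resolved by neighbor-locus
agreement: each feature carries the set of provisional loci of its ≤5
neighbors per side on its replicon (orientation- and order-insensitive,
for robustness to local inversions), and a competing member joins the
locus with which it shares the most neighbor loci. A member whose best
agreement falls below 2 founds a new locus instead — splitting paralogs
is preferred over creating chimeric loci that would inflate the core.
Adjacent co-oriented members from one strain are kept together as a split
gene. Remaining members are peeled iteratively into further loci.
Tie-breaks are deterministic: identity to the locus representative, then
coordinate.

**Numbering and status.** Loci with reference-strain members are numbered
in reference genome order; the rest interleave at the midpoint of their
flanking reference anchors, the anchor chosen by majority vote over
carrier strains with ties toward the earlier anchor. A member is a
pseudogene if its translation contains an internal stop, if its protein
is shorter than 0.8 times the median length of non-stop members of the
locus, or if it is a split-gene fragment; split fragments count once
toward locus membership so that pan counts stay non-degenerate. The 0.8
length fraction is a declared decision: no published criterion pins it,
and the tests exercise it directly.

## Pan-genome statistics

The presence–absence matrix is tri-state (absent / pseudogene / intact).
Rarefaction enumerates, for each subset size `x`, *all* `choose(S, x)`
strain subsets whenever that count is at most `exact_limit`
(default 10 000 — chosen so that a 14-strain collection is exact at every
`x`, the largest stratum being `choose(14, 7) = 3432`); larger strata are
sampled uniformly under a stated seed. Core = loci present in all subset
strains; pan = loci present in at least one. Because full-length genes
and pseudogenes are tabulated separately, the counting convention is
explicit and configurable: the default counts a pseudogene as absent for
the core and present for the pan; both all-present and all-absent
conventions are available, and the two core flavours (intact-in-all
versus present-in-all) are reported side by side by the pipeline. Note
that under the intact-in-all convention a per-strain, per-gene
pseudogenization probability `p` thins the core by `(1 - p)^S`, a factor
of about 0.49 at the defaults — the dominant reason the intact core is
far smaller than the number of universally present loci.

The non-reference inventory partitions loci absent from a supplied
"published" reference annotation into three disjoint, exhaustive classes:
`annotation_difference` (the pipeline finds an intact reference member),
`reference_pseudogene` (a reference member exists but is a pseudogene)
and `strain_specific_insertion` (no reference member). Loci whose best
external-proteome identity exceeds their best within-collection
cross-strain identity are additionally flagged as candidate imports.

## Variation scans

**HGT.** Each locus of a strain receives the identity of its best donor
hit (0 if none passes coverage 0.5). Flagged regions are maximal runs of
at least `min_run = 5` consecutive loci each individually at or above
`min_identity = 90` — the run definition is conjunctive, never based on
window means. The 10-locus window mean is computed for plotting only,
mirroring the separation between a smoothed identity trace and discrete
flagged boxes. The boundary is sharp: a run of five flags, a run of four
does not.

**Prophages.** The attachment-site model drives detection: a temperate
phage integrating at a tRNA duplicates the tRNA 3' end as direct repeats
(attL/attR). For each tRNA, the final 20 bp are matched within 60 kb
downstream at ≥90% identity (≤2 mismatches, satisfying a ≥15 bp repeat
requirement); each inter-repeat segment is an element copy. Genes inside
the span are assigned roles by ≥40% identity to integrase and endolysin
references; *int* plus *lys* makes an element `full`, *int* alone
`fragment`, and spans without *int* are not reported. Copy number is the
maximal run of adjacent segments carrying an integrase, so tandem
duplications merge into one element with `copy_number ≥ 2`. Element
boundaries come from the repeats, not from gene content.

**Cassettes.** A cassette locus is the ordered list of pan ids strictly
between two core anchor loci; identical ordered contents share a variant
label (labels ordered by frequency, then signature). Content is
orientation-normalized so that an inverted but content-identical region
matches the uninverted variant and is flagged `inverted`. Strains missing
an anchor are `unresolved` rather than forced into a variant.

**Completeness and fusions.** Role labels are inputs (user tables or
simulation truth), never inferred — function annotation is out of scope.
A role group (pathway or transporter complex) is complete in a strain
when every role has at least one intact locus; blocks distinguish
pseudogenization from absence. A fusion candidate is a protein covered
≥30% by representatives of two different families with ≤10% mutual
overlap and by no single family at ≥80%, with the breakpoint estimated at
the midpoint between the two spans.

## Phylogeny

Loci enter the concatenated phylogeny only when intact in every strain
with exactly one member each, no member has a within-proteome second hit
scoring ≥0.7 of its self-score (the paralog guard — an alignment-based
stand-in for single-copy cluster filtering), and, when an outgroup
proteome is given, the representative matches some outgroup protein at
≥60% identity. Family alignment is center-star progressive alignment
around the longest member, exact for the substitution-only families the
simulator produces; alignments are concatenated in pan-id order with a
recorded partition map. Distances are p-distances over shared non-gap
columns with optional Jukes–Cantor (nucleotide) or Poisson (amino acid)
correction.

Trees are built by canonical neighbor joining, with Q-criterion ties
broken to the pair containing the lexicographically smallest taxa, so
results are reproducible; on an additive matrix the generating tree and
its branch lengths are recovered exactly (a property the tests verify on
random additive matrices, cross-checked against an independent NJ
implementation). Distance-based NJ with bootstrap deliberately replaces
maximum-likelihood inference: it is deterministic, fast at collection
scale, and sufficient for topology recovery, which is what the benchmark
measures. Bootstrap resamples alignment columns with replacement via
site-pattern compression (multinomial reweighting of unique columns), and
support is the fraction of replicates containing each internal
bipartition.

## The synthetic benchmark

`simulate_collection()` generates the study conditions: an ancestral
chromosome of core genes in fixed random orientation separated by 50–400
bp intergenic spacers, evolved down a random coalescent-shaped tree by
per-branch uniform nucleotide substitutions (no indels inside genes, so
frames are preserved and family members stay length-matched; substitutions
that would create an in-frame stop are redrawn). The two final strains
form a designated basal cherry on a long branch, emulating a divergent
subspecies pair, and also carry a private gene set. Per-strain events add
accessory genes (independent presence per strain), cassette variants
(each variant guaranteed realized at least once so programmed variant
counts are identifiable), premature-stop pseudogenes at a uniform
internal codon, phage insertions at tRNA sites delimited by exact 20 bp
att repeats (full elements = *int* + *lys* + 8 structural genes; fragments
= *int* only; tandem copies repeated with internal att repeats), an HGT
segment whose proteins sit at a configured amino-acid identity to a donor
proteome, and small circular plasmids. Genes are wrapped by stop codons on
both flanks so that start-to-stop ORF calling recovers exact coordinates.

Default sizes were chosen once to match the emulation target — 14 strains
of ~1.8 Mb with ~1800 full-length genes and ~100 pseudogenes each: 1650
core families, 430 accessory families at presence probability 0.5, three
cassette loci with 7/3/3 variants, 25 basal-pair-private genes, six tRNA
sites with eleven phage insertions including one tandem duplication, one
8-gene HGT segment at 95% identity into seven strains, 20 paralog pairs
at 35% divergence, mean gene length 250 codons, substitution rate 0.003
per site per unit branch (branch lengths `0.003 × (0.3 + Exp(1))`, the
floor guaranteeing that every internal branch carries thousands of
substitutions), pseudogene rate 0.05 per gene per strain. Plasmids occur
in ~30% of strains with five genes each. The empirical distribution of
accessory-gene sharing among real strains is not documented, so
independent Bernoulli presence was chosen for testability rather than
realism.

What the simulator does *not* emulate — and therefore what green tests do
not establish about real data: realistic codon usage and composition,
within-gene recombination and indels, assembly gaps and fragmented
contigs, annotation error beyond the modelled classes, gene-tree/species
tree discordance, and donor taxa with genuine phylogenetic structure.
Performance numbers (recall, sensitivity, exact phage classification) are
upper bounds that say the algorithms are implemented correctly, not that
real collections will behave as cleanly.

## Numerical conventions and problem sizes

Coordinates are 0-based half-open internally, converted at the GFF3
boundary (1-based inclusive). Translation uses bacterial code table 11
with ATG/GTG/TTG initiators; internal stops translate to `*` and are
surfaced to the classifier. All randomness flows from a single integer
seed; the pipeline fans it out to per-stage child seeds by stable hashing
of stage names so stages can be rerun in isolation, and reruns are
byte-identical (reports contain digests, never timestamps). Degenerate
inputs are defined: empty donor sets and empty role groups are errors,
tRNAs missing from an annotation are skipped with a warning, collections
of fewer than three strains refuse the tree stage, and `nj_tree` returns
a cherry or star for fewer than three taxa.

The test suite runs the full default-scale study (14 strains, ~26 000
genes) once and reuses it across checks; unit tests use a five-strain
~200-gene-per-strain collection exercising every event type, and oracle
comparisons (exhaustive rarefaction enumeration, reference dynamic
programming for alignment, additive-matrix NJ recovery) run at toy scale
where exhaustive computation is feasible. The acceptance script repeats
the default-scale study end to end, measuring every stage against truth.

## Known limitations

Center-star alignment is exact only for substitution-dominated families;
families with many long indels would need a proper progressive aligner.
The paralog guard is score-based and misses paralogs below ~70% of the
self-score; such loci are still safe for the phylogeny unless they are
also core single-copy, which the other filters make unlikely. The
att-repeat scanner assumes integration duplicates at least 18 of the
final 20 tRNA bases; heavily decayed prophage boundaries fall back to
fragments or are missed. Rarefaction is exact only up to 30 strains
(integer bitmask patterns); beyond that, sampling takes over.
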