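---
title: "Screening cell-free mitochondrial DNA from low-pass sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfmito methods}
  %\VignetteEncoding{UTF-8}
---

## The setting

Whole-genome NIPT sequencing reads maternal plasma cell-free DNA at a
fraction of an x for the nuclear genome, yet the mitochondrial genome —
16,569 bp, circular, present at hundreds of copies per cell — comes out
at mean depths of roughly 1–40x. `cfmito` treats that mitochondrial
by-product as an analysable dataset: it quantifies the mtDNA pool per
sample, calls and filters variants, classifies heteroplasmy, assigns
haplogroups and summarises cohorts. The cf-mtDNA pool is a mixture: the
bulk is maternal mtDNA from apoptotic cells, a small share is foetal
(placental), and a variable share is mtDNA from leukocytes that degrade
in the collection tube before plasma separation. That third component is
the pipeline's central QC concern, because the nuclear DNA leaking along
with it dilutes the foetal fraction on which NIPT accuracy rests.

## The synthetic cohort generator

No patient-level cf-mtDNA data are distributable, so the package ships a
generator with known truth; every claim the test suite makes about the
pipeline is a claim about recovery of that truth.

Per sample the generator draws a geographic region (five categories with
cohort shares 46.9/31.8/8.5/10.2/2.6%), a collection tube and transport
time (remote regions ship longer and predominantly as whole blood), a
haplogroup from region-specific superclade priors (the Yakutia prior is
weighted to the east-Eurasian clades C and D, elsewhere H dominates),
and a maternal haplotype as the root-to-leaf union of defining variants
in the packaged tree. The foetal haplotype equals the maternal one —
mtDNA is maternally inherited — with optional de-novo foetal variants
disabled by default. Private variant sets distinguish the cell-free pool
from the leukocyte pool (Poisson means 4 and 6), so that paired
buffy-coat/plasma simulations reproduce the observation that the two
pools barely overlap unless leakage is high.

Leaked leukocyte mass follows a deterministic tube/time law
(`leakage_weight()`): EDTA tubes are processed to plasma before
shipping, so their leakage stays at the baseline `w0 = 0.05` regardless
of transport time; Streck tubes ship whole blood and stay at `w0` up to
the 72-h threshold (3 days), then grow exponentially at `k = 0.35` per
day. The growth form and rate are the package's own choice — the
phenomenon is qualitative (content rises after 72 h) and a single-rate
exponential is the simplest monotone model. On top of the deterministic
law each sample receives a mean-one lognormal factor
(`leakage_noise_sdlog = 0.6`): cell lysis and handling vary between
samples, which couples mtDNA content to foetal fraction continuously
rather than only at the tube/time change-points. The foetal fraction is
then `ff0 / (1 + leaked)` and the mixture weights of
maternal-cf/foetal-cf/leukocyte fragments follow from `ff0` and the
leaked mass.

Sequencing is modelled as uniform placement of fragments (mean length
170 bp, the nucleosome-protected cfDNA scale; lengths are truncated
normal with 15% CV) on the circular reference, with wrap-around at the
origin. Mean depth is log-uniform over 1–40x, multiplied by the leakage
enrichment and capped at 40x. A fragment carries each truth variant of
its tissue with probability equal to the variant's heteroplasmy; 95% of
private variants are homoplasmic (heteroplasmy 1), the rest draw from
Beta(2, 2). Errors follow the semiconductor profile: substitutions
uniformly at 1e-4 per base, and indel errors placed inside homopolymer
runs with a per-fragment probability that doubles per run base
(0.002 at run length 3, capped below 0.5).

What the generator does **not** emulate: base qualities, strand bias,
PCR duplicates, GC-dependent coverage (the real genome shows coverage
cold spots), NUMT mis-mapping, and a realistic phylogeny (the packaged
tree is ~44 nodes, not PhyloTree). Passing tests therefore demonstrate
the pipeline's logic — filters remove what they are specified to
remove, estimators are unbiased under the stated sampling model — not
performance on real Ion Torrent data.

## The packaged reference and annotation fixtures

The packaged reference is a generated sequence, not a copy of rCRS, with
rCRS geometry: 16,569 bp, circular, D-loop at 16,024–576 (wrapping the
origin), HV1 at 16,024–16,383, HV2 at 57–372. Bases at every position
named in the packaged annotation tables are fixed so the published
variant names (e.g. m.15326A>G, m.9906delG) are expressible, and those
positions are kept clear of homopolymer runs so the filtration cascade
does not remove them by construction. The annotation table is a frozen
miniature in the ClinVar schema (closed significance vocabulary,
`|`-separated diagnoses); the ancestral list holds the six broadly
shared variants used as the default exclusion set when ranking
population-informative variants.

## Variant calling and the cascade

A permissive frequency caller stands in for a full somatic caller:
every non-reference allele with at least 2 supporting reads becomes a
record, and all screening decisions live in the downstream filters,
where the thresholds are visible and testable. Multi-allelic sites emit
one record per alternative allele, and the reference-read count excludes
other alternative alleles, so the heteroplasmy fraction is always a
two-allele quantity.

The cascade flags records on three independent predicates — depth < 5;
homopolymer association; alternative support < 4 — so the kept set is
invariant to filter order, while the staged report (total → depth →
homopolymer → alt-support, split SNV/indel) preserves the bookkeeping
of a sequential protocol. Homopolymer membership is type-dependent: an
SNV must lie inside a run, while an indel inside *or immediately
adjacent to* a run boundary is flagged, because left-alignment places a
run indel at the run edge; the adjacency rule is deliberately positional
(any run, not only runs of the indel's base) and is the package's
reading of "within homopolymers", recorded here as an open choice. The
standard cascade uses run length ≥ 4 for both classes; a stricter ≥ 3
indel mode exists for indel reporting, where 3-runs are the dominant
residual error source. Deletions are represented at the first deleted
base and insertions at their anchor; on VCF output deletions are
left-anchored per VCF 4.2 (a deletion at position 1 of the circular
genome cannot be left-anchored on a linear VCF line and is rejected — a
known limitation).

Heteroplasmy classification offers the strict rule (homoplasmic iff
zero reference reads) and the approximation that also counts reference
support below 4 reads as homoplasmic, symmetric with the
alternative-support error argument; the two differ exactly on sites
with 1–3 reference reads.

## QC models

mtDNA content is a read-count ratio (not base counts). The
coverage–depth expectation 1 − e^(−c) is the standard Poisson
approximation for uniform placement; it is used for QC expectations and
the acceptance checks, never for inference. Content classes default to
cohort tertiles (type-1 quantiles) because no published boundaries
exist; ties fall to the lower class and an all-equal cohort is
"medium". Group comparisons are tie-corrected Kruskal–Wallis tests with
no multiple-testing correction, matching per-figure testing practice.

## Haplogroup scoring

The Kulczynski measure ½(|S∩E|/|E| + |S∩E|/|S|) averages the overlap
relative to the node's cumulative defining set and relative to the
sample set; `S` is restricted to tree-informative positions so private
variants do not dilute confidence. Ties break toward deeper nodes, then
lexicographic names, making calls deterministic. Calls with confidence
≤ 0.5 are discarded (the "score of 0.5" discard rule is read as
inclusive). The packaged confidence is analogous to, but not
numerically comparable with, external haplogroup-quality scores, and
samples with few informative variants land in the discard regime by
construction.

## Numerical and testing choices

All cohort randomness flows from a single seed; reruns are
bit-identical, and every artefact carries the seed and a configuration
hash. The test suite sizes simulations to keep the default run within a
couple of minutes while leaving comfortable statistical margins: 200
samples per depth for coverage convergence (2% absolute tolerance
against 1 − e^(−c)), a 30-sample cohort at 15–40x for cascade
correctness, 1,000 sites at 50x for heteroplasmy bias (2 binomial
standard errors), 200 samples at 5–40x for superclade recovery, a
200-sample cohort for the transport/contamination direction checks, and
100 random toy cohorts against brute-force set algebra. The acceptance
script uses 200 samples per depth for the 2x/4x coverage means and 500
per candidate depth when locating the smallest depth reaching 99.9%
mean coverage.

## Known limitations

Indel error modelling is single-base; the caller has no base-quality or
strand-bias awareness; gene-level annotation of the 37 mitochondrial
genes and NUMT masking are out of scope; the packaged tree cannot
resolve subclades beyond its ~4 levels; and cohort-level published
frequencies (distinct-variant counts, haplogroup percentages, ClinVar
diagnosis shares) depend on the original cohort and are not reproduced
by simulation — the pipeline reproduces the procedures, not the
cohort-specific numbers.
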