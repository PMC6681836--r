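---
title: "Methods behind the terpene synthase family survey"
author: "tpsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the terpene synthase family survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsurvey)
```

## The problem

Plant terpene synthases (TPSs) are defined by two Pfam-style domains: an
N-terminal domain (NTD, PF01397-like, carrying the RRX8W motif) and a
C-terminal domain (CTD, PF03936-like, carrying the DDxxD and NSE/DTE
motifs). A genome-wide family survey asks, per species: which genes carry
which domains (full-length versus single-domain "domain loss" genes), which
subfamily (TPS-a through TPS-h) each member belongs to, how the family
expanded (tandem duplication, segmental duplication, mobile elements),
whether duplicates diverged in expression, how selection acted on them
(Ka/Ks), and whether the family's deep origin connects to isoprenyl
diphosphate synthases (IDS, PF00348-like) through a shared 33-aa partial
C-terminal domain (PPD) motif — including screens for putative horizontal
gene transfer (HGT) between plants and bacteria.

`tpsurvey` implements this whole pipeline so that each stage is an ordinary,
separately testable function, and pairs it with a synthetic-data generator
that emits fully labeled inputs for every stage. Real surveys depend on
external genome and expression accessions; the synthetic route is what makes
the pipeline verifiable on a desk.

## Domain identification

### Profile HMMs

`build_profile()` turns a seed domain alignment into a profile HMM: columns
with at least 50% residue occupancy become match states, the rest insert
states; emissions and transitions get a Laplace pseudocount; the background
is the seed's residue frequency. Scanning uses a Plan-7-like local
architecture: self-looping flank states emit background residues (loop
probability $n/(n+2)$ for a target of length $n$), entry is uniform over
match columns, and exit is uniform from any match column, so a domain can
be found anywhere in a protein and a *partial* domain (fewer than 60% of
match columns spanned, configurable) is still scored — the property the PPD
discovery step depends on. The local entry/exit wrapper is deliberately not
renormalized against the core transitions; scores are log-odds bits and all
significance comes from empirical calibration, which absorbs any constant
normalization. Forward and Viterbi run in log space in compiled code and are
exact for sequences to at least 5,000 residues; the forward recursion is
tested against an explicit path-enumeration oracle on toy profiles.

### E-values

HMMER-style analytic E-values need calibration constants; we fit them
empirically. `calibrate_profile()` scores `n_samples` (default 1000) random
background sequences — lengths resampled from the database that will be
scanned — with the forward algorithm and fits a Gumbel distribution by
maximum likelihood; `E = database_size * P(S >= s)`. Two compositions
matter: the *scoring* background (log-odds denominator) is the seed
alignment's frequencies, but the *calibration null* defaults to uniform
residues, matching an uninformative database. When the two are confounded —
calibrating on the seed-derived frequencies while scanning uniform-ish
proteins — E-values become badly miscalibrated in either direction, which we
observed directly; pass `null_freqs` when scanning a strongly biased
database. Per-sequence (not per-domain) thresholding is used, with
additional envelopes found by masking the first envelope and re-scanning.

A practical consequence of honest E-values: at the survey's standard cutoff
of `E <= 1.0`, about one background sequence per scan is *expected* to pass.
Truth-equality tests therefore assert at the homology-grade cutoff
(`E <= 0.01`); the relaxed cutoff `E <= 100` is reserved for PPD discovery.

### Identification workflow

The census combines the NTD and CTD scans (`scan_proteome()`,
`classify_architecture()`, `census()`) with a supplemental homology search
(`supplemental_homology_search()`): local alignments of confirmed family
members against the proteome at `E <= 0.01` propose candidates that the HMM
scan missed; candidates are only admitted after a domain re-scan at a laxer
presence threshold, and the rest are reported as unverified artifacts rather
than counted. The census identities `n_ntd_only = n_ntd_total - n_full` and
`n_ctd_only = n_ctd_total - n_full` are the domain-loss arithmetic and hold
on every run by construction. Proteins with internal stop codons stay in the
census but are flagged (`has_premature_stop()`) and excluded from phylogeny.

## Alignment and distances

Pairwise optimal alignment is delegated to Biostrings (affine-gap
Smith-Waterman / Needleman-Wunsch, BLOSUM62, gap open 11 / extend 1 — BLASTP
defaults, since no alternative is specified anywhere upstream). Identity is
the fraction of alignment columns with identical residues; coverage is
query-relative, because every rule that consumes it ("at least 30% of its
sequence", "70% of queried protein coding regions") is phrased on the query.
Local-alignment E-values use Karlin-Altschul statistics with $(K, \lambda)$
fitted once per scoring scheme by a Gumbel fit to 10,000 null alignment
scores at a fixed seed.

The multiple aligner is classic progressive alignment: UPGMA guide tree on
pairwise `1 - identity`, profile-profile dynamic programming with
sum-of-pairs column scores and a linear gap penalty (gap-gap pairs score
zero). It is checked against an exhaustive three-sequence dynamic program on
small cases. Linear (not affine) gaps at the profile stage keep the DP
simple; domain-length sequences of a family are similar enough that the
difference does not change the downstream trees in our tests.

JTT distances are maximum-likelihood: the published JTT exchangeability
table (as packaged by phangorn, normalized to one expected substitution per
site) gives $Q$; `jtt_distance()` maximizes
$\sum_{\text{columns}} \log(\pi_a P_{ab}(t))$ by bounded scalar
optimization, capped (default 10 substitutions/site) with a saturation flag.
The estimate is validated by parameter recovery on simulated pairs and by a
1,000-point likelihood grid. We verified our generator equals phangorn's JTT
generator exactly (as transposes, both rate-normalized); phangorn's
`dist.ml` output itself differs from the ML optimum of this likelihood by a
systematic few percent, so the cross-check is pinned at the generator level.

## Phylogeny and subfamily assignment

Trees are neighbor joining (`ape::nj`) on JTT distance matrices, with
negative branch lengths clamped to zero and flagged. NJ replaces
maximum-likelihood and Bayesian tree search deliberately: subfamily
assignment depends on clade membership, not branch-length fine structure,
and NJ is deterministic and exact on additive matrices (tested against
exhaustive minimum-evolution enumeration on 5 taxa). Bootstrap support
resamples alignment columns and counts bipartition recovery.

`classify_query()` aligns the query with a labeled reference panel, builds
the joint NJ tree, and assigns the label of the smallest query-side
bipartition group containing at least one reference; mixed labels at that
group, or equally small groups with different labels, yield `unassigned`.
This is a bipartition formulation of "smallest enclosing monophyletic
reference clade" that is well defined on unrooted trees and invariant to
leaf order and reference duplication. When NTD and CTD trees disagree, the
NTD call stands and the conflict is flagged (`assign_subfamily()`), because
the NTD tree is the survey's designated classification authority.

The synthetic reference panels mutate a common family ancestor (35% per
site) into subfamily consensuses, then members diverge 10% within each
subfamily: the between/within ratio is comfortably above 2 while distances
stay far from saturation. Fully unrelated random consensuses would saturate
the JTT distances (everything at the cap) and randomize the tree — a useful
reminder that the 100%-accuracy property holds for diverged-but-related
panels, not for arbitrary sequence soup.

## Duplication mechanisms

A tandem call (`call_tandem()`) requires all three rules: child coverage at
least 30% in a significant local alignment (`E <= 0.01`), identity at least
70%, and proximity — no more than 10 gene ranks apart *and* within 100 kb
(genomes under 200 Mb) or 350 kb (otherwise), measured midpoint to midpoint.
Rank distance is `|rank_a - rank_b|` (the reading of "no more than ten genes
apart" we fixed, documented here because "ten intervening genes" is also
defensible); genes on different chromosomes fail proximity rather than
erroring. The classifier is property-tested against direct predicate
evaluation on 10,000 randomized pairs.

Segmental blocks (`chain_anchors()`) come from DAGchainer-style collinear
chaining: quadratic dynamic programming over anchor pairs in both
orientations with a linear gap penalty (default 0.05 per unit gap, max gap
10 gene ranks), best chains reported greedily, blocks under 5 anchor pairs
discarded. The chain optimum is tested against exhaustive
increasing-subsequence enumeration on up to 10 anchors. Mobile-element
association (`flank_overlap()`) classifies each gene as contained in,
partially overlapping, flanked by (within 50 kb), or clear of annotated
elements; element discovery itself is out of scope — intervals are inputs.

## Expression

`fpkm()` is the textbook formula
`counts * 1e9 / (gene_length * mapped_total)`; the identity
$\sum_g \mathrm{fpkm}_{gs} \cdot \mathrm{len}_g = 10^9$ (when totals are
the column sums) is asserted numerically. Zeros are masked as "no
expression" by `log2_matrix()` and treated as silence, not as small values.

A gene is tissue-preferred when its top tissue beats *every* other tissue at
least 2-fold (linear scale) with `p < 0.05` in every pairwise t-test; a
duplicate pair is diverged when some tissue shows a 2-fold difference with
`p < 0.05` or one gene is silent where the other is expressed. The t-test is
the classic pooled-variance Student's test by default. We initially used
Welch, but at triplicate depth Welch's degrees of freedom collapse to about
2 and measured power at the reference conditions (8-fold signal, NB
dispersion 0.05, n = 3) is only ~0.88; the pooled test — which is also what
the source methods name — reaches ~0.99 with measured type-I error below
nominal. Welch remains available (`var_equal = FALSE`). No multiple-testing
correction is applied by default, mirroring the surveyed procedure. The fold
gate is applied on the linear scale (a log2 difference of 1); tissues with a
single replicate get fold-only descriptive treatment with a warning.

The synthetic expression generator draws negative-binomial counts
(`variance = mu + dispersion * mu^2`) around tissue means, with planted
preferred genes at `fold * baseline` in their tissue and planted silent
genes at zero. Defaults — 3 tissues, 3 replicates, baseline mean 100,
dispersion 0.05 — are ordinary bulk-RNA-seq scale. Power studies plant
preferred genes as a minority (100 among 1,000): FPKM's per-sample
normalization absorbs the signal if every gene moves together, which is a
real compositional caveat, not an artifact of the generator.

## Ka/Ks and the screens

`ng86_kaks()` is the Nei-Gojobori (1986) estimator: fractional
synonymous-site counts per codon with mutations to stop codons excluded and
the position renormalized (so N + S = 3 per codon exactly), averaged over
the two sequences; observed differences averaged over all minimal
substitution pathways between codons, stop-crossing pathways excluded;
Jukes-Cantor correction, saturation (`p >= 0.75`) capped and flagged. Single
and double-difference codons are checked against hand-enumerated pathway
counts. On simulated pairs evolved with acceptance probability
$\omega = 0.5$ for nonsynonymous proposals, the estimator is unbiased;
single 1,000-codon pairs scatter about 12% (simulation noise), so recovery
is asserted on means over replicate pairs. `back_translate()` threads codons
through a protein alignment to produce the codon-aware nucleotide alignment.

The PPD pipeline scans IDS proteins with the CTD profile at the relaxed
cutoff `E <= 100` (`discover_ppd()`), exact-deduplicates the envelope
subsequences (near-duplicate clustering deliberately not applied), builds a
PPD profile from the aligned unique seeds (`build_ppd_profile()`), and
reports per-set hit counts as exact ratios rounded half-up to one decimal
(`ppd_scan_report()`, `percent_of()`); conserved-column analysis
(`conserved_columns()`) supports row subsets to find positions conserved in
IDSs but variable in TPSs.

The HGT screen is a two-stage rule engine (`screen_hgt()`, with the pure
predicate exposed as `hgt_rules()` for property testing): candidates need
70% query coverage at `E <= 0.01` against the plant panel; a candidate
verdict additionally needs identity above 80%, such hits in at least two
plant species ("multiple" read minimally, configurable), and *no* homolog
above 50% identity in any other bacterial genome.

## Scales, seeds, determinism

Every generator is a pure function of (configuration, seed) and restores the
session RNG. The shipped test-and-acceptance scales — 500-protein proteomes
for recall, 150/180-column seed alignments (domain scale), 1,000 null genes
for error calibration, 1,000-codon pairs for Ka/Ks, 10,000-case predicate
sweeps — were chosen as the smallest sizes at which the stochastic
properties have comfortable margins, and run in a few minutes in total.

## What the synthetic data does not show

The generator emulates domain architecture, genomic layout and count noise
— not real seed alignments (Pfam seeds have phylogenetic correlation
structure; ours are star-shaped around a consensus), not codon/composition
bias, not assembly and annotation error, not isoform inflation (the census
counts one architecture per gene id), and not read-level artifacts
(quantification is consumed, never performed). Passing the planted-truth
suites therefore demonstrates the rules and estimators are implemented
correctly and calibrated under their stated noise models; it does not by
itself validate biological conclusions on any particular genome.
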