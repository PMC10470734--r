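---
title: "Screening for large-RdRp mitoviruses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for large-RdRp mitoviruses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screening problem

Mitoviruses are capsidless +ssRNA viruses that replicate inside
mitochondria and encode a single protein, the RNA-dependent RNA polymerase
(RdRp). Most mitovirus RdRps are 556-1,136 aa (averaging ~761 aa). A
distinct class associated with glomeromycotinian (arbuscular mycorrhizal)
fungi encodes unusually large RdRps of 986-1,134 aa (~1,036 aa on average)
that share a conserved N-terminal block of 53-58 aa, and uses UGA codons
for Trp only rarely (~1.4% of Trp residues on average) even though the
mold-mitochondrial genetic code reads UGA as Trp. `mitoscreen` implements
the resulting screen as a pipeline:

1. call ORFs in all six frames under genetic codes 1 and 4 and select the
   candidate RdRp;
2. scan the RdRp (and, if wanted, all six genome frames) with a log-odds
   profile of the N-terminal motif;
3. compute %UGA-for-Trp;
4. classify: **large duamitovirus iff RdRp >= 900 aa (inclusive) AND the
   N-terminal motif is present**;
5. ordinate the three factors by PCA;
6. at community scale, assign queries to labelled references by local
   alignment, build site-by-group count matrices, run NMDS with
   permutation environment fitting, and test per-library co-occurrence.

Every stage is exercised on synthetic genomes and simulated
metatranscriptome libraries with known ground truth; nothing is
downloaded.

## ORF calling under two genetic codes

Because %UGA-for-Trp spans 0-75% across mitoviruses, neither genetic code
can be assumed: the caller always evaluates table 1 (UGA = stop) and
table 4 (UGA = Trp) and selects the RdRp across both. Within each frame an
ORF opens at the *first AUG* after the frame start or the previous stop --
the standard initiation rule -- and closes at the next in-frame stop.
ORFs that run off the 3' end are kept and flagged `partial_3prime`,
because metatranscriptome contigs are frequently truncated; length
filtering is a pipeline decision, not the caller's. How the original RdRp
ORFs were delimited is not documented for this class of virus; first-AUG
is this package's recorded policy, and removing UGA stops can only
lengthen ORFs, so every table-1 ORF is contained in a same-frame table-4
ORF (a tested invariant). Ties in RdRp selection (equal length) prefer
table 4, then the lower frame, then the lower start: table 4 is the code
these viruses actually use in their hosts' mitochondria.

Coordinates are 0-based half-open on the forward strand; the internal
alphabet is RNA (inputs in DNA are converted on read) because the genomes
are +ssRNA. IUPAC ambiguity codes are rejected by default; with
`ambiguity = "mask"` they become `N` and ORFs that would run through a
masked codon are discarded, since codon statistics are undefined under
ambiguity. Default enumeration floor: `min_len_aa = 100`, low enough that
the caller never hides a genuine RdRp; survey-style 500-aa filters belong
downstream.

## The motif profile

The profile is a position-specific log-odds matrix built from a seed
alignment. Columns with gap fraction >= 0.5 are dropped; remaining column
frequencies are

    f_a = (count_a + pc * bg_a) / (N_eff + pc),   score_a = ln(f_a / bg_a)

with pseudocount `pc = 1` by default. Scanning is ungapped: the motif is a
short well-conserved block, and a full profile HMM would buy little at the
cost of a much larger surface. `X` scores 0 in every column -- the
expectation of a log-odds column under the background -- so unknown
residues neither help nor hurt.

A hit counts as *N-terminal* only if its window starts within the first
100 aa of the RdRp (`n_terminal_window = 100`). The motif is described as
N-terminal without a stated offset bound; 100 aa covers the observed
placements with margin, and the synthetic generator plants motifs within
the same window.

Motif presence in the literature on these viruses is reported without a
stated score cutoff, so the threshold here is this package's own
construction: the (1 - fpr) quantile of maximum window scores over random
background proteins of length 300 (`fpr = 1e-4` by default). The
recommended background is pooled from the user's reference protein set
(`aa_background()`), falling back to uniform 1/20: under a uniform
background and a small seed alignment the null score distribution has
large atoms (many columns share identical count patterns) and a quantile
threshold cannot hold an exact false-positive rate; a realistic pooled
background breaks those ties.

## Classification factors

%UGA uses the Trp denominator only: among codons translated as Trp (UGA
under table 4, plus UGG), the percentage that are UGA. Per-virus values up
to 75% only make sense on that denominator, not over all codons. Genomes
with zero Trp have undefined %UGA (`NA`) and are excluded from the PCA
rather than imputed -- exclusion is transparent, and at realistic Trp
densities (~1.3 per 100 aa) it is vanishingly rare.

The rule *RdRp >= 900 aa AND motif present* has an inclusive boundary at
900. `classify()` is monotone: lengthening the RdRp or gaining the motif
can never flip a genome out of the large class (a tested property).

For the PCA, motif presence enters as 0/1 and all three columns are
centered and scaled to unit variance. Whether the original analysis
z-scored its factors is unstated; scaling is recorded as this package's
decision, without which RdRp length (hundreds of aa) would swamp a binary
factor. Scores come from the SVD of the standardized matrix, with a
deterministic sign convention (the largest-magnitude loading of each
component is positive); explained variances are the eigenvalues of the
correlation matrix, verified against an independent eigendecomposition in
the tests.

## Similarity search

Reference assignment mirrors a Blastp top-hit search at desk scale:
Smith-Waterman local alignment with affine gaps (a gap of length L costs
`gap_open + L * gap_extend`), BLOSUM62, and the Blastp default penalties
11/1. The highest-scoring reference donates its genus and host-taxon
labels; ties break by reference order. Scores below `min_score` yield
"unknown" -- the recommended threshold is the 99.9th percentile of
shuffled-query null scores, since the original retrieval cutoffs are
unstated. "100% identity" clustering is exact full-length string equality,
the plainest reading of that phrase; containment clustering is
deliberately not implied. An optional 4-mer prefilter skips references
sharing no 4-mer with the query and is verified against the unfiltered
search; it is off by default.

## Community statistics

Assignments are counted into a site x (genus x host-taxon) matrix;
all-zero site rows are dropped with a warning. Dissimilarity is
Bray-Curtis on raw counts by default -- the transform used originally is
unstated, so the default is recorded explicitly rather than guessed.

NMDS minimizes Kruskal stress-1,

    stress1 = sqrt( sum (d_ij - dhat_ij)^2 / sum d_ij^2 ),

where `d` are configuration distances and `dhat` their non-decreasing
(pool-adjacent-violators) fit to the dissimilarity ranks, with Kruskal's
primary tie treatment (tied blocks may order freely, realized by
pre-sorting configuration distances within tied blocks). The
configuration update is gradient descent on stress with doubling/halving
step search; convergence is a relative stress change below `tol = 1e-7`.
One start is classical metric scaling, the remaining `n_starts - 1`
(default 20 total) are random Gaussian configurations; the best final
solution is returned centered, rotated to principal axes, and
deterministically reflected, so a fixed seed gives bit-identical output.
The 2-d stress on the default community simulation lands in the same
regime (~0.04-0.13) as real mitovirus community ordinations, and the
implementation is cross-checked against an independent NMDS implementation
on small crafted inputs.

Environment fitting regresses each per-site variable on the ordination
axes: r-squared is the coefficient of determination, the arrow direction
the unit-normalized coefficients, and significance comes from permuting
the variable across sites with the add-one estimator
`p = (1 + #(permuted r2 >= observed)) / (n_perm + 1)`, which can never be
zero. The fitted variables are per-site *category frequencies* of the
metadata factors (the proportion of a site's libraries that are soil,
root, ...): how the original per-site "frequencies" were computed is not
documented, and this proportion interpretation is recorded as an
assumption, not asserted as fact.

The co-occurrence test is the Pearson correlation of per-library counts
of large duamitoviruses versus other mitoviruses, with
`t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom, two-sided.

## What the synthetic data emulates -- and what it does not

`gen_genomes()` plants the study conditions directly: large-class RdRp
lengths from a truncated normal with mean 1,036 aa on 986-1,134;
normal-class mean 761 aa on 556-1,136; per-Trp UGA probability 0.014 for
the large class; an 8-large/6-normal default panel; the motif embedded
within the first 100 aa of large-class RdRps only. Values the source
conditions leave open were fixed once as field-realistic defaults:
normal-class theta 0.30 (UGA-rich, as in most non-glomeromycotinian
mitoviruses), Trp density 1.3 per 100 aa (typical proteome frequency),
UTRs of 60 +/- 15 nt. Non-Trp residues take uniform synonymous codons --
only Trp usage is the statistic of interest. Stops are drawn from
UAA/UAG so table-4 translation closes exactly at the planted end, and
UTRs are kept free of AUG (and reverse-strand AUG) trigrams, which makes
the planted RdRp the unique longest ORF in >99% of genomes (a tested
invariant, with violations observable rather than silent).

`gen_community()` plants a standard-normal site gradient that drives
group abundances through a log link (`gradient_effect = 1`,
`base_abundance = 8` over 9 genus-host groups and 20 sites) and ties the
ecosystem factor to the same gradient, while sample type is pure noise --
so environment fitting has one true positive and one true negative.
Across the default 184 libraries, other-mitovirus counts are negative
binomial (mu 30, size 5) and large-duamitovirus counts Poisson with mean
linear in the other count, the slope solved so the planted correlation is
`rho = 0.6`.

The generators deliberately do **not** simulate phylogenetically
structured sequence evolution, realistic residue composition beyond Trp,
codon-usage bias, sequencing error, chimeric contigs, or segmented
genomes. Passing tests therefore demonstrate that the pipeline recovers
planted parameters under clean, well-specified conditions -- correctness
of the machinery -- not that the screen's error rates transfer to real
metatranscriptomes, where partial contigs, compositional bias and
divergent motifs will all be harsher.

## Numerical choices and degenerate inputs

* RdRp selection tie-break: length, then code 4 over 1, then lower frame,
  then lower start -- fully deterministic.
* Proteins shorter than the profile width get a score of `-Inf` and are
  never "present".
* Zero-variance PCA columns contribute all-zero standardized scores with
  a warning; all-constant input is an error.
* `bray_curtis` on two all-zero vectors is an error (undefined), and
  all-zero site rows are removed before ordination.
* Permutation p-values use the add-one estimator; the minimal reportable
  value is 1/(n_perm + 1).
* A Pearson r of exactly +/-1 reports t = Inf and the smallest
  representable double as its p-value.
* All Monte-Carlo entry points take explicit integer seeds and restore
  the caller's RNG state, so library calls never perturb user
  reproducibility.

## Problem sizes used by the test-suite

The suite works at deliberately modest sizes chosen to give each check
real statistical teeth while keeping the whole run interactive: 200
random genomes for the ORF-caller oracle, 1,000 null proteins for the
false-positive-rate check (target 0.02, +/- 3 binomial SE), 1,000
large-class genomes for the pooled %UGA recovery at theta = 0.014, 100
simulations for the PCA separation and co-occurrence power checks, 1,000
and 2,000 replicates for the envfit and correlation type-I checks, and
exhaustive oracles on inputs of length <= 8 where enumeration is exact.

## Known limitations

* Ungapped motif scanning cannot follow insertions inside the motif; a
  profile HMM would, at a substantial complexity cost.
* The Smith-Waterman search is O(nm) per pair with no E-value model; it
  is meant for hundreds of references, not full-database mining.
* NMDS gradient descent can in principle stop at a local optimum; the
  multi-start design (metric-scaling start plus random starts) makes this
  rare at the problem sizes here, and the returned stress is always the
  best across starts.
* The classifier is a hard rule; genomes just under 900 aa or with
  borderline motif scores carry no uncertainty estimate.
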