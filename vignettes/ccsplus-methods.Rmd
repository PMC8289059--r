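---
title: "Methods: convergence detection with an empirical control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence detection with an empirical control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsplus)
```

## The problem

Genome-wide scans for site convergence — the independent evolution of
the same derived amino acid at the same alignment column in unrelated
lineages — have historically drowned in noise: without a control, the
background level of coincidental convergence is as large as any signal.
`ccsplus` implements a two-step design whose defining feature is that
the noise level is *measured*, twice: first empirically, by running the
identical calling rules on control lineages, and then by simulation, to
quantify how much of that noise survives stricter filtering.

## Step I: the symmetric design

The unit of analysis is a per-gene amino-acid alignment covering, at
minimum, R ≥ 2 focal key species, R control key species (one per focal,
same clade), and one outgroup. The design is symmetric on purpose: every
rule applied to the focal side can be applied verbatim to the control
side by swapping the role labels (`swap_roles()`), so the control count
is an estimate of the noise under exactly the calling rules used for the
signal.

A column is **conservative** when every control key carries the same
non-missing state as the outgroup. At such columns the ancestral state
is taken to be the shared state O directly — no probabilistic ancestral
reconstruction is attempted, because the design restricts calling to
columns where the reconstruction would be trivial anyway. A
**convergent site** is a conservative column where at least two focal
keys share one non-missing derived state ≠ O; all three sharing it is
one call with larger support. Genes with at least `z` convergent sites
(distinct columns; default `z = 2`) become candidate genes. With A
focal and N control candidate genes, `summarize_step1()` reports
S = A − N and P_true = S/A, clamped at 0 (with a flag) if the control
side exceeds the focal side.

**Missing data.** Gap (`-`) and unknown (`X`) are a single "missing"
category everywhere. A missing state at the outgroup or any control key
disqualifies the column as conservative — conservatism is an assertion
about *all* controls, so absence of evidence fails it. A missing state
at a focal key merely removes that species from the support set: in
Step I, focal species neither support nor veto through missing data.
The veto lives in Step II.

## Step II: the full phylogeny and the retention rate q

All remaining species join as `focal_extra` / `control_extra`. A Step-I
call survives iff (i) every added focal species carries the derived
state, (ii) no added control species carries it, and (iii) the gene
retains ≥ z surviving sites. By default a missing state in an added
focal species removes the call (`strict_missing = TRUE`): Step II is
the maximal de-noising step, and a species that cannot be shown to carry
the state does not get the benefit of the doubt. The lenient mode
(ignore missing extras) is available behind a flag and logged in the
output; missing data in an added control never vetoes. A focal-extra
species entirely absent from a gene is treated exactly like a missing
state at the call column.

The surviving focal count A′ is observed. The surviving noise is
N′ = N·q, with q estimated by `estimate_noise_retention()`: sequences
are simulated under a neutral amino-acid model along the full phylogeny
(no selection, hence every call is noise), assembled into genes by
cycling the real dataset's gene-length list in input order (a trailing
partial gene is discarded), and pushed through the identical Step-I and
Step-II code. q = n′/n is the fraction of simulated Step-I noise genes
surviving Step II. The reference protocol simulates 1e8 sites over 5155
gene lengths; the package's own tests use 5e4–1e6 sites on toy trees,
which is enough because q there is only compared against an independent
recount of the same simulated data and against its own sampling error,
both of which scale with the simulated size. The q estimate and a
user-supplied `--q` are interchangeable in `summarize_step2()`:
P′_true = (A′ − N·q)/A′, reported to 3 decimals.

## The simulator

`aa_rate_model()` builds a general time-reversible generator from a
symmetric exchangeability matrix and equilibrium frequencies:
Q_ij = s_ij π_j, zero row sums, scaled so −Σ π_i Q_ii = 1 (one expected
substitution per site per unit branch length). Because the chain is
reversible, the π-symmetrized generator is diagonalized once and every
branch's transition matrix P(t) = exp(Qt) is two matrix products;
transition rows are clipped at 0 and renormalized to guard against
eigendecomposition round-off (deviations are at the 1e-12 level).
The root sequence is drawn from π, sites are independent, and the same
seed reproduces the simulation exactly.

The default model is LG (exchangeabilities and frequencies taken from
the `phangorn` model library; `read_paml_rates()` reads any empirical
matrix in the standard lower-triangular text layout). Two deliberate
defaults, both exposed rather than silently chosen:

* **No among-site rate heterogeneity.** The protocol being emulated
  names only the substitution model and equilibrium frequencies. A
  discrete-gamma option would be the obvious robustness knob but is not
  the default.
* **Model frequencies, not empirical (+F) frequencies.** `lg_model()`
  accepts replacement frequencies for +F-style runs.

Branch lengths always come from the user's tree; tree inference is out
of scope.

## Usage convergence

Compositions are counted over all residues of a proteome FASTA
(non-standard letters skipped and counted). The outlier criteria for
one amino acid, judged on the pooled panel of reference plus focal
genomes (mirroring a 54 + 3 = 57-genome panel):

| criterion | rule | default |
|---|---|---|
| (i) | all focal genomes beyond Q1/Q3 of the pooled values | quartile type 7 |
| (ii) | ≥ 1 focal genome within the extreme ranks | top/bottom 10 %, rank ≤ ceiling(0.10 n) |
| (iii) | each focal more extreme than its relative, 2×2 chi-square | p < 0.01, no Yates correction |

The quartile convention is configurable (`outlier_criteria()`); R's
default type 7 is used because the choice only matters for small panels,
and it is the convention a practitioner would reproduce first. The
chi-square uses the closed-form Pearson statistic so zero-margin tables
degrade to statistic 0 rather than an error; Yates correction is off by
default because proteome counts are in the 1e5–1e7 range where it is
irrelevant.

`resample_significance()` rebuilds, per replicate, pseudo-focal genomes
by drawing each amino acid's value independently from the reference
column and renormalizing (the draws are therefore weakly coupled, which
is why simulation rather than a product of marginals is needed). The
pseudo-genomes *replace* the focal genomes in the pooled ranking panel,
and only criteria (i) and (ii) are applied — criterion (iii) needs a
designated relative, which a pseudo-genome does not have; the emulated
protocol is explicit about checking (i) and (ii) only. Reported are
P(total outliers ≥ k), P(under ≥ k_under), and the conditional
P(over ≥ k_over | under ≥ k_under) that mirrors the published
"overused given underused" construction.

GC-by-site-class uses third positions of 4-fold degenerate codons
(computed from the code table, not hard-coded) and optional introns as
neutral yardsticks. Biosynthetic cost is a frequency-weighted mean over
an editable high-energy-phosphate-bond table shipped as data with its
citation. Enrichment of annotations in gene sets is Fisher's exact
test, with an explicit flag for whether the background counts include
the gene set (both reporting conventions exist in the wild; the
inclusive convention reproduces the published pathway example).

## The Ki spectrum

`enumerate_one_step_pairs()` walks all 61 sense codons × 9 single-base
neighbors, drops stops and synonymous edges, and collapses to unordered
amino-acid pairs — exactly 75 under the standard code. The estimator in
`estimate_ki()` is a counting estimator, chosen over a maximum-likelihood
codon-model fit as a deliberate methodological substitution: it is
self-contained, transparent, and adequate in precisely the regime the
analysis targets (closely related pairs, Ks well below saturation); a
warning fires above Ks ≈ 0.3. Its validity is established by parameter
recovery on simulated codon pairs rather than by matching another
program's output. Mechanics:

* observed counts: codon columns differing at exactly one position
  (2–3-base differences are excluded and tallied);
* opportunity: per pair type, the number of single-base neighbor
  mutations realizing it, summed over the alignment's codons (averaged
  between the two sequences); the opportunities of the 75 types plus the
  synonymous type exactly exhaust the alignment's single-hit neutral
  expectation;
* scaling: each type's rate per opportunity is divided by the
  synonymous rate per opportunity, so neutral types sit at Ki = 1
  ("scaled such that Ka/Ks = 1"); Ks itself is reported per synonymous
  site (opportunities/3), with an optional Jukes–Cantor correction.

Identical sequences leave the spectrum flagged undefined rather than
zero. Ranks K1…K75 break ties by pair name for determinism. The
expected spectrum (`universal_index()`) is a per-pair mean and SD over
user-supplied reference spectra, with n ≥ 3 enforced; expected values
are data, never package constants. `compute_deviations()` scores
z = (observed − expected)/SD, positive meaning accelerated, and the
convergent set requires |z| > threshold (default 2.5 SD) in *every*
focal taxon pair.

## Synthetic data: what it does and does not emulate

The generators exist so every stage is testable with exact ground truth:

* `make_planted_dataset()` simulates neutral background alignments,
  then overwrites randomly chosen conservative columns in signal genes
  with a shared derived state across all focal species (and optional
  homoplasies in added controls). Planting post hoc, rather than
  re-simulating under selection, keeps the truth table exact.
* `make_usage_dataset()` draws per-species compositions from a Dirichlet
  around a plant-like base (LG frequencies), shifts the focal base
  multiplicatively (4 amino acids up, 5 down by default, renormalized),
  and emits i.i.d.-residue proteomes.
* `simulate_codon_pair()` evolves two sequences from a uniform
  sense-codon ancestor under a symmetric codon chain — synonymous
  single-base changes at rate 1, each one-step nonsynonymous type at its
  stated relative rate — so the truth Ki of a type is its stated rate.

What passing these tests shows is that the *inference machinery* is
correct and calibrated under its own assumptions. What it cannot show:
real proteins have among-site rate variation, correlated sites, indels,
alignment error, and non-i.i.d. residue order; real convergence is not
planted at random conservative columns; and the codon generator's
uniform ancestor and symmetric chain are conveniences, not biology.
Conclusions about real genomes still depend on the adequacy of those
assumptions for the data at hand.

A note on an edge the tests made visible: with one pair type's rate set
to zero, the estimator's count for that type is zero only at low
divergence. At moderate Ks, two-step paths through different lineages
(e.g. Val→Ala in one and Val→Ile→Thr in the other) can leave codons one
base apart that look like a forbidden one-step exchange. This is a
property of pairwise counting itself, not a bug, and is the same
multiple-hit regime the Ks warning guards.

## Numerical and design choices

* Alignment columns are indexed 1-based internally and in reports
  (report headers say so); R's native indexing is used throughout
  rather than a 0-based internal convention, to keep every index
  printable without translation.
* Species matching is by exact id string; no fuzzy matching — silent
  mismatches are the dominant real-world failure mode.
* Two derived states at one column are two call rows but one site for
  the per-gene threshold, because the unit being counted is the
  convergent *site*.
* The per-call number of extra species actually evaluated is recorded
  (`n_extras_evaluated`), since genes differ in which extras they cover.
* Degenerate inputs fail loudly: frequencies with zeros, asymmetric
  exchangeabilities, trees with missing or negative branch lengths,
  ragged alignments, duplicate ids, internal stop codons.

## Problem sizes

The test suite and acceptance checks run at deliberately modest sizes:
1e5-site closed-form simulator checks, a 1e6-site noise-retention run on
a 21-tip tree with an exact independent recount, 20 seeds × 5e4 sites
for the nestedness of q, 1e5-codon Ki recovery, 200 null datasets for
the sign-test calibration, and resampling nulls at hundreds of
replicates. These sizes were chosen so each check's Monte-Carlo error is
small relative to the effect it verifies; production runs would scale
the same calls up (1e8 sites, 1e5 replicates) without code changes.

## Known limitations

* Step I's ancestral-state shortcut is only as good as the conservative
  filter; highly divergent outgroups shrink the usable column set.
* q is a single global retention rate; per-gene-length variation in
  retention is averaged over, exactly as in the emulated protocol.
* The counting Ki estimator has no multiple-hit correction per pair
  type; at Ks beyond ~0.3 it biases toward the mean and the package
  says so rather than correcting silently.
* The usage criteria are rank-based over a finite panel; with fewer
  than ~8 reference genomes quartiles are unstable, and the code
  refuses to run rather than degrade.
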