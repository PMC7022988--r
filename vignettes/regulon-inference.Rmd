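---
title: "Methods: from selection reads to a candidate regulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from selection reads to a candidate regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsatk)
```

This vignette documents the models behind each stage of the pipeline, the
parameters that matter, the behaviour of the synthetic-data generators, and
the design decisions taken where several reasonable conventions exist.

## The problem

Iterative in-vitro selection (REPSA and related protection/selection schemes)
enriches, from a randomized double-stranded cassette library, those sequences
a protein binds tightly: bound templates are protected from a type IIS
restriction endonuclease, survive the round, and are amplified. After several
rounds the pool is dominated by binding sequences; sequencing the pool and
eliciting a motif yields the protein's consensus. Scanning the genome with
that motif proposes binding sites; label-free kinetics (biolayer
interferometry) validates them; and comparing expression between wild-type
and factor-deficient strains indicates which proposed targets respond in
vivo. TetR-family repressors bind as homodimers, so their sites are
(pseudo)palindromic — a constraint the motif stage can exploit.

## Cassette extraction

Reads have the layout `left_flank + cassette + right_flank`, possibly reverse
complemented. A read is retained iff in one orientation both flanks match
with at most `max_flank_mismatch` substitutions each (sliding-window Hamming
distance; indel-tolerant matching is deliberately out of scope, as selection
reads are short and substitution-dominated), exactly `cassette_length`
unambiguous bases lie between the flanks, and the mean Phred quality over
the cassette is at least `min_mean_q` (default 20, a mean-quality reading of
the usual "≥ Q20" accounting; a per-base filter would be stricter but
discards more data than the downstream EM needs). Rejections are counted by
the first filter that failed in the orientation that got furthest, which
makes the accounting invariant under read-wise reverse complementation.
Duplicates are kept: round-over-round duplication *is* the selection signal.
Deduplication is available behind a flag for diversity diagnostics.

## Motif discovery

`em_fit` is a standard EM over site placements: each cassette of length `L`
offers `K = 2(L − w + 1)` windows (both strands) for a motif of width `w`.
Under ZOOPS a cassette may also carry no site; the site prior is initialized
at 0.5 and re-estimated each iteration. The M-step adds a pseudocount of
0.25 per base. With `palindromic = TRUE` the expected count matrix is
averaged with its reverse complement before normalization — the
maximum-likelihood M-step under the constraint that the PWM equal its own
reverse complement — so the likelihood ascent property is preserved, and the
returned matrix is exactly strand-symmetric. Restarts (default `n_starts =
10`) are seeded from randomly chosen cassette windows sharpened to 0.7/0.1;
the best final log-likelihood wins. Convergence is declared at an absolute
log-likelihood change below `tol = 1e-6` or 500 iterations. Ten restarts
matter in practice: a planted palindrome has phase-shifted palindromic local
optima that single starts occasionally land in, with a clearly lower
likelihood.

The `significance` field is a likelihood-ratio diagnostic (chi-square tail
scaled by the number of candidate placements). It is emphatically **not**
comparable to MEME E-values, which are computed against a different null on
a different corpus; it is reported only to compare runs on the same pool.

Consensus notation (`consensus_string`) works column by column: a base with
probability ≥ 0.75 is written upper case; a purine or pyrimidine pair is
`R`/`Y` when the top two bases hold ≥ 0.90 together, `r`/`y` at ≥ 0.75; a
mixed pair at ≥ 0.75 becomes `(b1/b2)`, ordered by frequency and upper-cased
at ≥ 0.95; anything weaker is `n`.

`distinct_duplex_kmers(k)` counts reverse-complement equivalence classes of
k-mers — the number of distinct duplexes a randomized cassette presents:
`(4^k + 4^{k/2})/2` for even `k`. For `k = 16` this is 2,147,516,416, the
"about 2.15 billion" sequence space a full-coverage selection library must
oversample.

## Genome scanning and exact p-values

Windows are scored with the log2-odds of PWM versus a 0-order background.
The background defaults to the scanned sequence's own base composition,
symmetrized over strands (the composition of double-stranded DNA); a uniform
background or explicit frequencies are available. Strand symmetrization
makes plus- and minus-strand scores of a palindromic PWM exactly equal, so
both strand records are emitted at such loci (a `collapse_palindromic` flag
keeps one).

Match p-values are exact, not approximated: per-column scores are rounded
onto a grid of `granularity` bins per log2 unit (default 1000, bounding the
score round-trip error by `w/(2g)`), and the null distribution of the total
integer score of a random background sequence is built by column-wise
convolution. The p-value of a hit is the exact tail mass at its integer
score; the minimum achievable score has p = 1, and queries above the maximum
return the point mass of the maximum rather than 0. The test suite checks the
convolution against brute-force enumeration of all `4^w` sequences for every
width up to 8, at 1e-12.

q-values are Benjamini–Hochberg, computed over the emitted (threshold-passed)
hit list, mirroring how per-occurrence FDRs are usually reported alongside
scan hits; the same `bh_adjust` implementation serves the expression stage.

Annotation reports, for each gene within `max_distance` (default 300 bp), the
gene-oriented signed offset of the hit's 5'-most base from the first base of
the start codon, with non-negative offsets shifted by +1 so position 0 does
not exist. This convention was chosen because it makes the two reported
locations of a shared site in a divergent (bidirectional) promoter — one
offset per flanking gene — mutually consistent; a proximal-edge convention is
available behind the `convention` argument for comparison with tools that use
it. `intergenic` flags hits overlapping no annotated coding span.

## Binding kinetics

The 1:1 Langmuir association-then-dissociation model is fitted globally: one
`(kon, koff, Rmax)` triple shared by all concentration traces, minimizing the
summed squared residuals over the concatenated association and dissociation
points, which is also the domain of the single global R². Parameters are
log-transformed (positivity by construction) and optimized by
Levenberg–Marquardt. Starting values come from a linearized analysis: the
apparent rate of each association phase is regressed on concentration
(`kobs = kon·C + koff`), and `koff` is refined from the log-linear decay of
the highest-concentration dissociation. Single-trace fits are allowed with a
warning — `kon` and `Rmax` are only weakly identified by one concentration.
Flat traces return an unconverged diagnostic instead of crashing. No
mass-transport or bivalent extensions are provided: the model is
deliberately the single-state one.

When a trace table has no explicit `t_assoc`, the boundary is taken as the
midpoint between the last association sample and the first dissociation
sample, which is exact whenever the true boundary is not itself a sample
point (e.g. 300 s is not on a 1.6 s grid).

Equilibrium KDs from gel-shift titrations use the isotherm
`θ(C) = C/(C + KD)`. The midpoint method interpolates log-linearly in `C` to
`θ = 0.5` and therefore *requires* the titration to bracket the midpoint —
it errors otherwise; the least-squares method always returns an estimate but
flags it `extrapolated` when no measurement crosses 0.5. Both are reported
by default. Affinity classes default to high < 1 nM ≤ intermediate <
100 nM ≤ weak < 10 µM ≤ nonspecific; only the 1 nM boundary is anchored in
common usage for high-affinity repressor sites, and all thresholds are
configurable.

Published kinetic tables occasionally contain internal inconsistencies. Two
rows of the source data this package's tests draw their identities from
print a KD one order of magnitude away from their own koff/kon ratio
(a consensus point-mutant probe, printed 4.560e-9 vs ratio 4.56e-10, and one
weak promoter site, printed 8.357e-7 vs ratio 8.36e-8 — though the
accompanying text says 836 nM). `compute_kd` computes the ratio; those rows
are excluded from identity checks rather than silently "corrected".

## Differential expression

The two-group stage computes `logFC = mean(perturbed) − mean(reference)`,
pooled variances on `n1 + n2 − 2` degrees of freedom, then empirical-Bayes
moderation: `d0` and `s0²` are estimated by moment matching on `log s²`
(digamma/trigamma matching, with a Newton inversion of the trigamma
function), the posterior variance is `s̃² = (d0 s0² + df s²)/(d0 + df)`, and
the moderated t has `d0 + df` degrees of freedom. When the observed
variances show no excess spread the moment estimate diverges; `d0` is then
infinite and `s0²` is the mean observed variance, so identical sample
variances are a fixed point. Forcing `d0 = 0` disables moderation and
reproduces the ordinary pooled t exactly. The B statistic is the posterior
log-odds of differential expression under the moderated-t model with a
configurable prior DE proportion (default 0.01) and a prior effect variance
estimated from the extreme t statistics. The unit tests cross-check t, p,
d0 and s0² against the independent limma implementation.

## What the generators emulate — and what they do not

Every generator is a pure function of its config, including the seed, and
emits a truth table sufficient to score the stage that consumes its output.

* **Selection rounds** (`gen_repsa_pool`): round 0 is uniform random except
  for a `planted_fraction` (default 2%) of cassettes carrying the exact
  consensus — a finite simulated pool stands in for a real library that
  oversamples the full sequence space, where matching molecules are
  guaranteed. Each later round resamples reads with weight
  `exp(stringency × best-window log2-odds)`, a one-parameter Boltzmann
  surrogate for protection/cleavage chemistry; the default `stringency =
  0.1` gives the gradual round-over-round enrichment characteristic of a
  six-round selection, while 0 gives none and values ≥ 1 saturate in one
  round. Reads are flank + cassette + flank, half reverse-complemented, with
  uniform substitution errors (default 0.002/base) and constant Q30
  qualities (an optional low-quality tail exercises the quality filter).
  PCR bias, indels and platform-specific error profiles are *not* modelled,
  so passing tests say nothing about indel robustness.
* **Genomes** (`gen_genome`): i.i.d. background at a configurable GC
  (default 0.69, thermophile-like), verbatim planted sites, gene spans with
  strand and translation start. No repeats, operonic structure or
  compositional heterogeneity — scan false-positive rates on real genomes
  will differ from the i.i.d. calculation.
* **Sensorgrams** (`gen_sensorgrams`): exact model mean plus homoscedastic
  Gaussian noise; defaults follow the assay design the kinetic stage
  targets — five concentrations 3.7–300 nM, 300 s phases, 1.6 s sampling,
  wild-type-consensus rate constants, 1% noise. Instrument drift and
  reference-channel artefacts are not simulated.
* **Expression** (`gen_expression`): gene baselines N(8, 1.5²) log2 units,
  residual sd 0.25 (chosen to match the implied standard errors of strongly
  significant effects in 3 vs 3 microarray designs), two groups × 3
  replicates, planted logFCs −8.51/+1.95/+1.83 by default among nulls.
  Array normalization and probe effects are upstream of this model.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 500 cassettes × 24 bp for
motif recovery (5 seeds × 10 restarts), 50-kb genomes for scan recall,
50 seeds of five-trace sensorgram sets for kinetic recovery, and 10 seeds of
2000-gene matrices for DE calibration and ranking. These sizes were chosen so
that every stochastic check sits far from its decision boundary while the
whole suite runs in minutes on one core.

## Interfaces

The stages are exposed as plain R functions, orchestrated by
`run_pipeline()` from a YAML or list config; file outputs are FASTQ/FASTA
(via Biostrings), BED/GFF3 (via rtracklayer; BED is 0-based half-open on
disk, GFF3 1-based inclusive — both are normalized on read), MEME minimal
motif format, CSV traces, and TSV/JSON tables and manifests. The package is
aimed at R users, so no shell executable is shipped; any stage is one
`Rscript -e` away.
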