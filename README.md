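# repsatk

**repsatk** implements the inference chain that turns iterative in-vitro
selection (REPSA/SELEX-type) sequencing data into a transcription factor's
DNA-binding consensus and a candidate regulon. It is aimed at groups studying
bacterial transcription factors — typically homodimeric TetR-family
repressors — in organisms where genetic tools are limited, so that binding
specificity must be established biochemically and cross-referenced against
public expression data.

The pipeline has five analysis stages, each usable on its own:

1. **Cassette extraction** (`extract_cassettes`). Selection reads have the
   layout `flank + randomized cassette + flank`, in either orientation.
   Cassettes are recovered by sliding-window Hamming matching of both flanks
   (no indels), with exact-length, unambiguous-base and mean-Phred filters,
   and full rejection accounting (retained + rejected = input, always).

2. **Motif discovery** (`em_fit`). A fixed-width motif is fitted by
   expectation–maximization under the ZOOPS model (zero or one site per
   cassette, both strands). With the palindromic constraint the expected site
   counts are symmetrized with their reverse complement at every M-step — the
   maximum-likelihood update under the constraint that the position-weight
   matrix (PWM) equal its own reverse complement, as expected for a homodimer.
   Outputs: letter-probability matrix `p[i,b]`, per-column information
   content `IC_i = 2 + Σ_b p[i,b] log2 p[i,b]` (bits), and a mixed-case
   consensus notation (upper case for dominant bases, `R/Y` for
   purine/pyrimidine pairs, `(b1/b2)` for mixed pairs).

3. **Genome scanning** (`scan_sequences`). Every window on both strands is
   scored with the log-odds `Σ_i log2(p[i, s_i] / b(s_i))`. Match p-values —
   the probability that a random background sequence scores at least as
   well — are computed **exactly** by dynamic programming over the
   integerized per-column score distributions (1000 bins per log2 unit by
   default), then filtered at a configurable threshold (default
   `p ≤ 5.10e-6`) and given Benjamini–Hochberg q-values. Hits are annotated
   with gene-oriented offsets from the start of translation (no position 0;
   the first base of the start codon is +1) and an intergenic flag.

4. **Binding kinetics** (`fit_global`, `fit_emsa`). Label-free sensorgrams
   (e.g. biolayer interferometry) are fitted globally to the 1:1 Langmuir
   association-then-dissociation model,

   ```
   association:  R(t) = Req (1 − e^{−kobs t}),   kobs = kon·C + koff,
                 Req  = Rmax·C / (C + KD)
   dissociation: R(t) = R(t_assoc) e^{−koff (t − t_assoc)},   KD = koff/kon
   ```

   with one shared `(kon, koff, Rmax)` across all concentrations
   (Levenberg–Marquardt on log-parameters) and a global R² over all points.
   Equilibrium KDs from gel-shift (EMSA) titrations come from the binding
   isotherm `θ(C) = C/(C + KD)` by midpoint interpolation and least squares.
   `classify_affinity` bands KDs into high (< 1 nM), intermediate, weak, and
   nonspecific.

5. **Differential expression** (`de_analyze`). Two-group comparisons of log2
   intensities (wild-type vs factor-deficient, ≥ 2 replicates each) use an
   empirical-Bayes moderated t: per-gene variances are shrunk toward a prior
   estimated by moment matching on `log s²`, `s̃² = (d0·s0² + df·s²)/(d0 +
   df)`, with two-sided p-values on `d0 + df` degrees of freedom, BH-adjusted
   p, and B log-odds of differential expression.

`run_pipeline` orchestrates all stages from one config (YAML or list) and
joins sites, affinities and expression changes into a regulon report;
`regulon_report` flags weak-affinity sites as less likely to be occupied in
vivo and marks genes with a strong site that are derepressed in the knockout
as candidate repressed targets. Synthetic-data generators (`gen_repsa_pool`,
`gen_genome`, `gen_sensorgrams`, `gen_expression`, `gen_emsa_titration`)
produce every input with known ground truth.

## Worked example

```r
library(repsatk)

# six selection rounds, extract final-round cassettes, fit the motif
cfg  <- selection_sim_config(n_reads = 1000, rounds = 6, seed = 7)
sim  <- gen_repsa_pool(cfg, dir = "reads")
pool <- extract_cassettes(sim$fastq_paths[7], cfg$left_flank,
                          cfg$right_flank, cassette_length = 24)
#> cassette_pool: 999/1000 reads retained (length 24)
#> rejections: no_left_flank=1

motif <- em_fit(pool, width = 16, palindromic = TRUE, n_starts = 10, seed = 1)
#> motif_result: width 16, zoops (palindromic), 999 sites, logL -13700.52
#> consensus: CTGACCGATCGGTCAG
```

The extractor lost one read to a flank hit by two sequencing errors; EM on
the remaining 999 cassettes recovers the planted 16-bp palindrome exactly.
Scanning a 50-kb synthetic genome carrying two planted copies:

```r
g <- gen_genome(genome_sim_config(
  length = 50000,
  planted_sites = data.frame(sequence = "CTGACCGATCGGTCAG",
                             position = c(984, 30210), strand = c("+", "-")),
  genes = data.frame(id = c("geneA", "geneB"), strand = c("+", "-"),
                     start = c(1000, 29500), end = c(2200, 30100)),
  seed = 2))
hits <- scan_sequences(motif$pwm, g$sequence, p_threshold = 5.10e-6,
                       collapse_palindromic = TRUE)
annotate_hits(hits, g$annotation)
#>   start   end strand  score         p         q  gene location intergenic
#> 1   984   999      + 31.414 3.349e-10 3.349e-10 geneA      -16       TRUE
#> 2 30210 30225      + 31.414 3.349e-10 3.349e-10 geneB     -125       TRUE
```

Both plants are found with exact match p-values around 3e-10; the first sits
16 bp upstream of geneA's start codon. Kinetics and expression close the
loop:

```r
fit <- fit_global(gen_sensorgrams(sensorgram_sim_config(seed = 3))$traces)
#> 1:1 kinetic fit
#>   kon  = 2.737e+05 1/(M*s)
#>   koff = 0.0005731 1/s
#>   KD   = 2.094e-09 M
#>   R^2  = 0.9990 over 5 trace(s)

e  <- gen_expression(expression_sim_config(seed = 4))
head(de_toptable(de_analyze(e$values, e$groups)), 3)
#>        gene  logFC      t  P.Value adj.P.Val    B
#> 1 gene00001 -8.646 -43.12 1.21e-54  2.41e-51 99.5
#> 2 gene00002  2.158  10.38 3.70e-16  3.70e-13 26.1
#> 3 gene00003  1.673   8.25 4.01e-12  2.67e-09 17.3
```

The fit recovers the simulated kon/koff within a fraction of a percent at 1%
noise, and the three planted expression effects (−8.51, +1.95, +1.83 log2
units) head the moderated-t ranking. `run_pipeline(config, outdir)` performs
the same chain end-to-end and writes TSV/JSON reports plus a manifest.

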