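# ctermbias

Statistics of C-terminal protein sequence composition in bacteria, and of
its consequences for protein expression.

The last residues of a protein sit at the crossroads of translation
termination and protein degradation. Across bacterial proteomes their
composition is strongly non-random — positively charged residues (lysine,
arginine) are over-represented at the last position while threonine and
hydrophobic residues are depleted — and the identity of the last one or two
amino acids measurably shifts protein abundance, largely through the
degradation rate. `ctermbias` is an analysis package for quantifying these
effects, aimed at comparative genomicists and at groups analyzing
C-terminal reporter libraries or degradation assays.

## What it computes

* **Position-specific composition bias.** For symbol *s* (amino acid or
  codon) at position *x* ∈ {−20, …, −1}, the 2×2 table of terminal vs bulk
  counts gives the sample odds ratio
  OR = k(B−K) / ((N−k)K), a two-sided Fisher exact p, and
  Benjamini–Hochberg q-values (one family per table, 5% FDR), plus an
  `underpowered` flag for cells where even a 2-fold depletion could not
  reach significance. Dipeptide bias and stratified variants (stop-codon
  context, functional categories, abundance bins) use the same machinery
  against each stratum's own bulk.
* **Pair epistasis (genomic).** Observed terminal pair frequency vs the
  product of the positional marginals, tested with a two-sided exact
  binomial test.
* **Substitution rates.** From triplets of closely related genomes and
  3-taxon parsimony, q_ij(x) = events(i→j at x) / ancestral-i sites at x,
  pooled into amino-acid groups and compared between positions with
  Fisher tests.
* **ELM-seq DAMratio.** Per variant, the ratio of read proportions between
  DpnI- and MboI-digested samples, normalized to the geometric mean;
  per-slot effects as 10^(mean log10 R); pair cooperativity
  Q = R_pair / (R(aa−2)·R(aa−1)).
* **Degradation kinetics.** Per-replicate OLS of log luminescence on time
  after shut-off; d = −slope, half-life ln2/d; steady-state regression
  X = s/d on 1/d.
* **Synthetic data** with known ground truth for every analysis above
  (proteomes with injected positional/pair biases, triplet alignments with
  position-dependent rates, paired digestion read counts, decay curves).

## Worked example

Inject a known bias into a synthetic proteome and recover it:

```r
library(ctermbias)

mu <- mu_matrix()
mu["K", "-1"] <- 2.32      # 2.32-fold lysine enrichment at the last position
mu["T", "-1"] <- 0.44      # threonine depletion
tab <- gen_proteome(10000, mu = mu, seed = 7)

bias <- position_bias(tab, "aa", positions = -1)
subset(bias, symbol %in% c("K", "T", "A"))
#>  symbol obs_count obs_total bulk_count bulk_total odds_ratio   q_value significant
#>       A       935     10000     215372    2261899      0.980  8.69e-01       FALSE
#>       K       963     10000     100477    2261899      2.292 6.74e-105        TRUE
#>       T       238     10000     122180    2261899      0.427  4.06e-49        TRUE
```

The recovered odds ratios match the injected multipliers (2.29 vs 2.32,
0.43 vs 0.44) because a multiplicative frequency bias maps exactly onto the
odds ratio; the unbiased alanine stays at OR ≈ 1 and is not called.

Decay rates from a simulated shut-off assay (10% multiplicative noise,
3 replicates; the defaults anchor the assay's printed extremes, L = 0.26/h
and D = 0.072/h):

```r
lum <- gen_luminescence(cv = 0.1, seed = 7)
fits <- fit_decay(normalize_series(lum)$decay)
decay_summary(fits)
#>  variant d_mean    d_sd n_replicates half_life
#>        D 0.0800 0.00904            3      8.67
#>        L 0.2609 0.01861            3      2.66
#>        ...
```

The fastest variant (hydrophobic C-terminus, L) has a half-life of about
2.7 h against roughly 9 h for the slowest (acidic, D) — a ~3.6-fold rate
difference that dominates the steady-state expression differences
(`steady_state_fit()` regresses steady state on 1/d).

The `analysis/` directory holds six numbered drivers
(`01_simulate_proteome.R` … `06_degradation.R`) that run the full set of
analyses on synthetic inputs and write their tables under `results/`.

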