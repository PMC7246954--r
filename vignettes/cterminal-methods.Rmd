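---
title: "Methods: C-terminal composition bias and its impact on expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C-terminal composition bias and its impact on expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ctermbias` implements a family of analyses around one question: does the
identity of the last few amino acids of a bacterial protein carry a signal —
in genome composition, in molecular evolution, and in measured protein
levels? The package provides (i) composition-bias statistics of the
C-terminal region of proteomes, (ii) position-resolved amino-acid
substitution rates from three-taxon parsimony, (iii) quantification of
expression effects of randomized C-terminal sequences from paired
methylation-sensitive digestion counts, (iv) protein degradation kinetics
from reporter shut-off time courses, and (v) synthetic-data generators that
carry known ground truth for all of the above. Every statistic here can
therefore be exercised against data whose answer is known by construction.

# Composition bias of the C-terminal region

## Regions and the null

Each protein is split into an N-terminal region (first `n_N = 20` residues),
a C-terminal region (last `n_C = 20` residues), and the bulk in between. The
N-terminal region is discarded so that well-known start-proximal biases do
not contaminate the null; the bulk provides the null composition. Sequences
must leave a non-degenerate bulk of at least two residues (length
`n_N + n_C + 2` = 42 with defaults) — shorter sequences are excluded with a
message. Proteomes are additionally pre-filtered to lengths of at least 50
residues, and redundant paralogs are removed (below), so in practice the
partition excludes nothing.

## The bias statistic

For a symbol $s$ (amino acid or codon) at C-terminal position $x \in
\{-20, \dots, -1\}$ ($-1$ = last residue), the package forms the 2×2 table

$$\begin{pmatrix} k_{s,x} & N - k_{s,x} \\ K_s & B - K_s \end{pmatrix}$$

with $k_{s,x}$ the count of $s$ at $x$ among the $N$ contributing sequences
and $K_s$ its count among the $B$ bulk residues. The association measure is
the unconditional sample odds ratio
$\mathrm{OR} = k(B-K) / ((N-k)K)$, tested with a two-sided Fisher's exact
test. Zero cells produce `Inf`/`0` sentinels rather than a continuity
correction; downstream log transforms must (and do) handle them. Under the
generator's multiplicative position model, a per-position frequency
multiplier $\mu$ maps exactly onto the odds ratio (renormalization cancels),
which is why the recovery tests can compare OR estimates directly against
injected multipliers.

Multiple testing is corrected with Benjamini–Hochberg at a 5% FDR, with one
family per returned table: the whole-proteome table is one family, each
stratum (stop-codon class, functional group, abundance bin) is its own
family. The codon alphabet is the set of sense codons of the genetic code in
force — 61 under the standard bacterial code (table 11), 62 including
TGA-tryptophan under table 4 (Mycoplasma).

## Statistical power flags

Rare symbols in small groups cannot reach significance at any realistic
effect size, and plotting them as "no bias" would mislead. A cell is flagged
`underpowered` when the smallest expected C-terminal count $m^*$ for which a
2-fold depletion (odds ratio 0.5) would reach $p < 0.05$ still exceeds the
cell's actual expected count $N K_s / B$. The search over $m$ uses an
internal hypergeometric-sum p-value that implements the same
minimum-likelihood two-sided rule (and the same $1+10^{-7}$ relative
tolerance) as `stats::fisher.test`; reported table p-values always come from
`fisher.test` itself, and a unit test pins the two implementations together.

## Dipeptides and pair epistasis

The last two residues are analyzed twice. First, the terminal pair is
compared against the frequency of the same dipeptide among all overlapping
two-residue windows of the bulk (overlapping windows maximize counts).
Second, epistasis: the observed terminal pair frequency is compared to the
product of the two positional marginals computed on the same sequence set —
the independence null — with a two-sided exact binomial test
(minimum-likelihood two-sidedness, as implemented by `stats::binom.test`).
A pair observed with zero expected frequency receives a `p = 0` sentinel and
a message. Note that when the generator reshapes the joint distribution of
the last two positions, the marginals move too; the observable
observed/expected ratio is therefore slightly below the injected pair
multiplier, and the recovery tests compute the exact observable target from
the generator configuration rather than assuming the multiplier itself.

## Stratified analyses

`stratified_bias()` recomputes the full bias machinery within groups defined
by any external labeling — functional category, subcellular localization,
taxonomic clade — always against the group's own bulk, so that differences
in bulk composition between groups are corrected for. Abundance bins use
within-species percentiles of mean protein abundance (low 0–20, medium
20–80, high 80–100), excluding species where fewer than 40% of proteins have
an abundance value; several abundance entries for one protein are averaged.

## Stop-codon context and overlapping starts

Codon bias at position $-1$ is computed within each stop-codon class (TAA /
TAG / TGA) against that class's own bulk. A gene is "overlap-flagged" when a
same-strand neighbour starts exactly one nucleotide before its stop codon —
the configuration in which an A as third base of the last codon plus a TGA
stop spells an overlapping ATG start (A-TG-A). Excluding flagged genes from
the TGA class isolates how much of the NNA codon preference is due to
overlapping starts rather than to termination biology; the third-base
contrast (t-tests on log2 odds ratios, NNA vs others and NNA vs NNG)
quantifies the shift before and after exclusion.

# Redundancy removal

Gene duplication puts near-identical C-termini into the counts many times.
The package removes redundancy per genome with a greedy two-step clusterer:
full sequences at 80% identity, then, within multi-member clusters, the last
20 residues at 85% identity; one representative (the longest sequence, ties
broken lexicographically by id) is kept per final cluster. Identity is
defined as matched residues under a global alignment with unit match score
and free gaps, divided by the shorter length — a deterministic, desk-scale
definition that is easy to oracle-test; no attempt is made to reproduce the
word-filter heuristics of production clustering tools. Greedy assignment
compares each sequence (in decreasing length order) to cluster
representatives only, which makes the procedure deterministic and
idempotent.

# Substitution rates from three-taxon parsimony

## Triplet selection

Closely related genome triplets are chosen from a synonymous-distance (dS)
table: an ingroup pair with dS in [0.2, 1.0], preferring values close to 0.2
(enough substitutions, no saturation), and an outgroup at 1.2–2 times the
ingroup distance from both members, preferring 1.5× — far enough to be an
unambiguous outgroup, close enough to stay alignable. One triplet per genome
cluster; ties break lexicographically.

## The counting rule

Alignments whose last three columns contain any gap are excluded (length-
variable C-termini — stop-codon gain/loss, frameshifts — would otherwise
blur end-anchored positions). Positions are column offsets from the final
column; columns beyond $-20$ pool into "bulk"; gapped columns are skipped.
On the tree ((in1, in2), out), a column is countable only when either all
three states agree (one ancestral-state site, no event) or exactly one
ingroup member differs while the outgroup matches the other (one i→j event
on that ingroup branch, ancestral state = the shared residue). Columns where
the outgroup differs from both ingroup members are excluded even though a
full parsimony reconstruction could sometimes resolve them — in particular
`in1 == in2 != out` places the change ambiguously on the stem or outgroup
branch, and three-state columns need two changes. This stricter rule is
exactly checkable: a test sweeps all $20^3$ columns against exhaustive
minimum-change enumeration over both internal nodes.

The substitution rate from $i$ to $j$ at position $x$ is
$q_{ij}(x) = n_{i \to j}(x) / n_i(x)$, events over ancestral-$i$ sites. For
reliable per-position statistics amino acids are pooled into positively
charged (K, R), hydrophobic (A, I, L, M, F, W, Y, V), threonine, and others;
rates between groups at two positions are compared with a two-sided Fisher
test on the event/site table.

# ELM-seq quantification (DAMratio)

Reads are matched exactly (no mismatch tolerance — the filter is a literal
template) against
`CGCGAAAAAA NNNNNN TAA NNNNNN CAGGCCTTGA`, capturing the last two codons and
the six nucleotides after the designed stop. Variants need at least 30 reads
in *each* of the two enzyme-treated samples; variants whose reconstructed
local sequence contains a GATC site anywhere — including junctions with the
constant flanks — are dropped, since extra methylation-sensitive sites
distort the read ratio.

The DAMratio of a variant is the ratio of its read *proportions* in the
DpnI- and MboI-digested samples. The proportion form makes the statistic
invariant to per-sample sequencing depth; this is a deliberate
interpretation (a raw read ratio would carry the depth ratio as a constant
factor, which cancels from all relative effects either way). The normalized
effect $R$ divides by the geometric mean over retained variants, so
$\overline{\log_{10} R} = 0$ exactly.

Effects are aggregated per nucleotide position, codon slot, amino-acid slot
and amino-acid pair by averaging $\log_{10} R$ over the variants carrying
the symbol — log-space averaging is consistent with the multiplicative
model and the reported quantity ($\log_{10}$ DAMratio); an arithmetic-mean
alternative sits behind the `log_space = FALSE` flag for sensitivity
analysis. Slot tables are re-centered to zero mean log-effect per slot. The
codons of the last two positions are translated under table 4 (TGA =
tryptophan in Mycoplasma), with TAA/TAG appearing as internal stop controls.
Pair epistasis is $Q = R_\text{pair} / (R_{-2} R_{-1})$; the log identity
$\log_{10} Q = \log_{10} R_\text{pair} - \log_{10} R(aa_{-2}) - \log_{10}
R(aa_{-1})$ holds exactly by construction.

# Degradation kinetics

Shut-off luminescence tracks are normalized to their time-0 value per
variant and replicate; steady-state expression is the time-0 luminescence
over the constitutive-marker normalization, expressed relative to a
reference variant. Decay rates come from ordinary least squares of
log-luminescence on time over the post-shut-off points (2–8 h), with a free
intercept — the time-0 point is excluded from the regression, so forcing the
line through the origin would discard the Methods' own design; a
fixed-intercept variant is a documented alternative rather than the
default. Fitting is per replicate, then summarized as mean ± SD across
replicates (not a pooled fit of the mean curve). Half-life is $\ln 2 / d$;
$d \le 0$ yields an infinite half-life with a warning rather than an error,
since a flat track is an informative outcome. Note the arithmetic: a printed
rate of 0.072/h gives $\ln 2 / 0.072 = 9.63$ h, so a printed half-life of
9.67 h implies an unrounded rate near 0.0717 — the package reports the
computed value and does not force agreement with rounded inputs.

Under a constant synthesis rate $s$, steady state follows $X = s/d$;
regressing $X$ on $1/d$ (free intercept) and reading the adjusted $R^2$
quantifies how much of the steady-state variance degradation explains.
Group contrasts (charged vs hydrophobic extensions) use two-sided
equal-variance t-tests; Welch's correction is available through
`stats::t.test` directly if wanted, but the equal-variance form is the
package convention.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions for every test:

* **Proteomes** (`gen_proteome`): i.i.d. residues per position — bulk
  positions from an E. coli-like composition, the last 20 positions from
  bulk × a per-position multiplier matrix, optionally a reshaped joint for
  the last two residues. Lengths are log-normal (median 250 residues,
  sdlog 0.35, truncated at 50), codons uniform over synonymous codons, stop
  codons at bacterial-like usage (TAA 0.63 / TGA 0.29 / TAG 0.08 under
  table 11). Verbatim duplications, short genes and stop-overlapping
  neighbour starts are injected at configurable rates with full
  bookkeeping. The model deliberately ignores domain structure,
  autocorrelation and operon architecture: the statistics under test depend
  only on positional composition, which is exactly what the generator
  controls. Passing recovery tests therefore demonstrates correctness of
  the statistics, not realism of bacterial proteomes.
* **Triplets** (`gen_triplets`): a root sequence per orthogroup; each
  ingroup branch mutates each site independently at its position's
  probability, the outgroup at 1.5× that (mirroring the longer branch);
  mutation targets are uniform over the other 19 residues unless a
  directional influx is injected. Alignments are gap-free — the gap filter
  is exercised by dedicated tests instead. Outgroup mutations produce the
  known parsimony misattribution at small rates; it affects both compared
  positions equally and cancels from rate ratios to first order.
* **ELM-seq** (`gen_elmseq`): all 4096 combinations of the last two codons
  crossed with a few downstream 6-mers, uniform abundance; true expression
  is the product of per-slot effects and a pair interaction; methylation
  follows the saturating link $m = E/(E + K_m)$ — the simplest monotone map
  from expression to methylation fraction, a test-harness contract and not
  a claim about enzyme chemistry; reads are multinomial per sample with
  weights ∝ m (DpnI) and 1 − m (MboI). No sequencing errors, adapters or
  quality profiles are simulated.
* **Luminescence** (`gen_luminescence`): $X_0 e^{-dt}$ with multiplicative
  log-normal noise (errors scale with signal, as plate-reader luminescence
  does). The default eight variants anchor the two printed extremes of the
  degradation assay (L 0.26/h, D 0.072/h) and interpolate the remaining
  rates monotonically along the expression ordering; steady states are the
  printed relative levels with P = 1.

All generators are bit-reproducible under a fixed seed and attach a
machine-readable `"truth"` attribute consumed by the tests.

# Numerical choices and problem sizes

* Odds ratios use `Inf`/`0`/`NaN` sentinels for empty cells; no Haldane
  correction anywhere.
* The two-sided Fisher and binomial p-values follow the minimum-likelihood
  rule with the conventional $1+10^{-7}$ relative tolerance.
* Ties break deterministically everywhere (lexicographic ids in clustering
  and triplet selection; first-found cluster in greedy assignment).
* The test suite verifies Fisher p-values against exhaustive hypergeometric
  enumeration over all 2×2 tables with margins up to 30, and the parsimony
  rule over the full $20^3$ column sweep. Parameter-recovery checks run at
  50,000 synthetic sequences (position bias), 30,000 (pair epistasis),
  80,000 triplet alignments (rate contrasts), $10^6$ reads per sample
  (ELM-seq), and 50 simulation seeds (decay) — sizes chosen so that the
  Monte-Carlo error sits well inside each asserted tolerance, with
  tolerances derived from binomial error propagation before the tests were
  run.

# Known limitations

* The greedy identity clusterer is quadratic in genome size and meant for
  desk-scale data; real proteome-scale deduplication should use a dedicated
  clustering tool upstream and feed its representatives in.
* The parsimony rule discards three-state columns that a likelihood or
  full-parsimony reconstruction might resolve; on such sites the package
  deliberately diverges from reconstruction-based pipelines.
* Headline numbers from published proteome-scale analyses (millions of
  sequences over thousands of genomes, or deposited sequencing libraries)
  are not reproducible at desk scale; the package's guarantees are
  oracle-equivalence and parameter recovery on synthetic data of known
  truth.
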