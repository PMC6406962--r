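---
title: "Detecting AID/APOBEC deaminase footprints with nucleotide weight matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting AID/APOBEC deaminase footprints with nucleotide weight matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamfootprint)
library(dplyr)
```

## The problem

AID/APOBEC cytosine deaminases (AID, APOBEC1, APOBEC3A/B/C/G) convert
cytosine to uracil in single-stranded DNA, and their off-target activity is
a major source of somatic mutations in cancer genomes. Each enzyme prefers
a characteristic local sequence context ("mutable motif"): WRC for AID
(W = A/T, R = A/G), TC for APOBEC3A/3B, CCC for APOBEC3G. The conventional
way to look for these footprints in a mutation catalogue is a consensus
sequence match, which throws away the graded, position-specific nature of
the preference. `deamfootprint` instead represents each motif as a
nucleotide **weight matrix** (sequence profile) and asks whether the
mutated sites in a catalogue score higher against that profile than the
non-mutated cytosines in their own immediate DNA neighborhoods.

## The model

**Matrix construction.** Training data are sets of 11-mer windows centered
on mutated cytosines (positions $-5..+5$, 0 = the mutated base,
strand-normalized so the center is always C). From per-position base
frequencies $f(b,j)$ and a background model
$e(b) = \text{mean of } f(b,j) \text{ over } j \in \{-5,-4,+4,+5\}$
(the four outermost, least informative positions — a normalization for
base-composition differences between the training genome and the genome
under study), the weight matrix is

$$W(b,j) = \log_2 \frac{f(b,j)}{e(b)}.$$

A window $b_1 \ldots b_L$ gets the matching score
$S = \sum_j W(b_j, j)$, rescaled to the **percent matching score**
("weight")

$$100 \cdot \frac{S - S_{min}}{S_{max} - S_{min}},
\qquad S_{min} = \sum_j \min_b W(b,j),\quad
S_{max} = \sum_j \max_b W(b,j),$$

over the scoring window $-3..+3$ (matrices are stored over $-5..+5$ but
scored over the seven central positions, where deaminase specificity
resides; $S_{min}/S_{max}$ are computed over the scoring window only).

**The footprint statistic.** For each mutation, the 121-bp sequence
centered on it is extracted (the DNA neighborhood). The *ratio* statistic
is the mean weight of the mutated sites divided by the mean weight of all
eligible non-mutated C/G sites in their neighborhoods; a ratio above 1
indicates that mutagenesis is enriched in the motif. Two tests gate a
call:

* a two-tailed Welch *t*-test of mutated-site weights against the pooled
  background weights, thresholded at a conservative Bonferroni-corrected
  large-sample critical value (e.g. 3.1 for a 24-test family), and
* a one-tailed Monte Carlo test: per iteration, one eligible site is drawn
  uniformly from each mutation's own neighborhood and the mean of these
  draws is compared to the observed mutated-site mean; the p-value uses
  the permutation-corrected estimator $(1 + k)/(N + 1)$.

A footprint is claimed only when **both** tests pass.

**Fraction estimation.** The distribution of mutated-site weights is
decomposed by EM into a mixture of two normal components; the mixing
weight of the higher-mean component estimates the fraction of mutations
attributable to the deaminase. The estimate is reported only when a
chi-squared goodness-of-fit test on the 10-unit weight bins does not
reject the fitted mixture (p >= 0.05) — otherwise the decomposition is
unreliable and the fraction is withheld.

## A worked example

```{r example}
genome <- simulate_genome(50000, seed = 1)

# emulated APOBEC3A training contexts and the resulting matrix
contexts <- simulate_context_set(enzyme_motif_spec("APOBEC3A"), 500, seed = 2)
wm <- build_weight_matrix(count_contexts(contexts, name = "APOBEC3A"))
information_content(count_contexts(contexts))

# a catalogue with 40% of mutations planted in the motif
muts <- simulate_mutation_dataset(genome, enzyme_motif_spec("APOBEC3A"),
                                  pi = 0.4, n = 2000, seed = 3)
res <- footprint(wm, muts, genome, mc_iters = 1000, seed = 4)
res %>% select(n_mutations, ratio, t_statistic, mc_p, significant)

w <- site_weights(wm, muts, genome)
estimate_fraction(w, seed = 5)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 0.5 | added to every base count before frequencies; keeps $W$ finite (the background is additionally floored at $1/(4n)$) |
| `scoring_positions` | $-3..+3$ | window actually scored; matrices store $-5..+5$ |
| `mc_iters` | 1000 | Monte Carlo iterations; the smallest attainable p is $1/(N+1)$ |
| `n_min` | 50 | minimum mutations per group for a significance call |
| `alpha`, `n_tests` | 0.05, scan size | family-wise level and Bonferroni family for the *t* gate |
| `mc_alpha` | 0.05 | Monte Carlo gate level |
| `tol`, `max_iter`, `sigma_floor` | 1e-6, 1000, 0.5 | EM convergence and degeneracy guards (weight units) |
| `at_content_filter` threshold | 0.5 | windows with $\geq$ 50% A+T in the 10 flanks are removed (inclusive) |

## Design choices where the method is underdetermined

Several details of the procedure are not fixed by the statistic itself;
the package makes the following choices, each exposed as an argument.

* **Pseudocounts.** $\log_2 0$ is undefined, so 0.5 is added to each count
  (Jeffreys-style) and the background floored at $1/(4n)$ — negligible at
  realistic training-set sizes, but it makes every matrix finite.
* **Background site set.** "Non-mutated sites" in a neighborhood are all
  C/G positions whose full ±5 context lies inside the 121-mer, center
  excluded, with G sites scored on the reverse complement. The motifs are
  C-centered, so only C-centered windows are meaningfully scored, and this
  treats background sites exactly like mutated ones. Whether A/T-centered
  positions should also count is an open question; they do not here.
* **Monte Carlo resampling unit.** One draw per mutation from its *own*
  neighborhood per iteration (rather than a pooled background), preserving
  each record's local context composition. 1000 iterations make p < 0.001
  representable.
* ***t*-test flavor.** Welch's unequal-variance test: the background pool
  is far larger and differently dispersed than the mutated set.
* **Seed policy.** A single master seed; per-(group, matrix) streams are
  derived by hashing the labels, so scan results do not depend on
  iteration order.
* **Chi-squared matrix comparison.** Computed structurally: per-position
  2×4 contingency tables over the 10 flanking positions summed, df
  $= 10 \times 3 = 30$. A df override is exposed because published
  critical-value conventions for this comparison (e.g. df = 42) are not
  derivable from a ±5 window; the package does not guess their intent.
* **Consensus casing.** Upper case at IC ≥ 1 bit, lower case at
  0.25–1 bit, "." below: thresholds invented for readable text logos.
* **UPGMA.** Euclidean distance on ratio vectors, average linkage
  (`stats::hclust`), rows pre-sorted by label so ties break
  lexicographically; Newick with ultrametric branch lengths.
* **Mixture truncation.** Weights live on [0, 100] but the components are
  untruncated normals, following the simple coding-statistic decomposition
  this estimator descends from. Mass piling against a boundary (a last
  bin holding more than twice its neighbor) triggers an explicit warning
  rather than a silent estimate, since boundary pileup is the known
  failure mode of the approach.
* **GOF degrees of freedom.** Pooled bins − 1 − 5 fitted parameters,
  floored at 1.
* **Fraction gate.** The fraction is reported when the GOF test does
  *not* reject (p ≥ 0.05) and withheld otherwise.

## What the synthetic generator does and does not emulate

`simulate_genome` produces i.i.d. base sequences;
`simulate_context_set` draws 11-mers position-independently from a motif
spec (TC-type, CCC-type and WRC-type presets with conservation 0.9 at
informative positions); `simulate_mutation_dataset` places mutations on
eligible genomic C/G sites, with planted mutations drawn with probability
proportional to $2^S$ — a Boltzmann weighting that, because $S$ is the
log-odds score, reproduces exactly the motif's base distribution at
planted sites without inventing a hard score cutoff. Planted sites are
drawn with replacement (recurrent mutation positions are real in
catalogues, and replacement keeps the planted context distribution equal
to the motif even when high-scoring sites are rare in a small genome);
background sites are drawn without replacement. Ground truth (planted vs
background origin) is retained per record.

Real genomes are not i.i.d.: no repeats, no GC isochores, no kataegis
clusters, no replication- or transcription-strand asymmetry, and no
position-to-position correlation within motifs. Passing tests on this
generator therefore demonstrate the statistical machinery — calibration
under the null, power against planted signal, fraction recovery — not
robustness to genomic structure. The A/T-content filter and the
random-matrix control exist precisely because real compositional bias can
inflate false positives; on i.i.d. genomes they are exercised but not
stressed.

## Numerical and scale choices

Degenerate inputs are handled explicitly: a matrix with $S_{min} =
S_{max}$ is an error (percent score undefined); windows containing N are
rejected upstream; records within 60 bp of a contig end are rejected with
a logged reason; a zero background mean flags the result rather than
dividing by zero; EM component collapse below `sigma_floor` restarts once
from a perturbed initialization and then flags the fit.

The test and example problem sizes — 50 kb genomes, context sets of
300–500 windows, catalogues of 200–2000 mutations, 99–1000 Monte Carlo
iterations — are desk-scale choices that keep the full suite fast while
leaving every statistical property measurable; the shuffle-control
experiment in `scripts/acceptance.R` uses a 100 kb genome, five 500-record
null sets and twenty shuffled matrices (four enzyme sets × five
replicates) at 1000 Monte Carlo iterations.

## Known limitations

* Only mononucleotide (position-independent) matrices; no dinucleotide or
  higher-order terms, and no motif discovery — matrices always come from
  aligned mutation contexts.
* Exactly two mixture components; heavily multimodal weight distributions
  will not decompose meaningfully (the GOF gate withholds the fraction in
  that case).
* The fraction estimator measures membership in the high-scoring
  component. When the background itself frequently contains the motif
  (short, weakly informative motifs), that component includes coincidental
  background matches and the estimate exceeds the true planted fraction.
* The mitochondrial-style negative control and immunoglobulin-style
  positive control are interfaces, not bundled datasets: any mutation TSV
  can be supplied.
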