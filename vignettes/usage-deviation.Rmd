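---
title: "Oligonucleotide usage deviation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligonucleotide usage deviation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tudscan)
```

## The statistic

Every genome leaves a compositional signature in how often it uses each
short word. For a word $W$ of length $k$ with nucleotide counts
$(a, c, g, t)$, the package compares the observed count $N(W)$ against the
count expected if bases were drawn independently from the genome's own
mononucleotide frequencies $(f_A, f_C, f_G, f_T)$ — a zero-order Markov
null:

$$E(W) = f_A^{\,a} f_C^{\,c} f_G^{\,g} f_T^{\,t} \cdot N,$$

where $N$ is the sequence length, and the usage deviation is the ratio

$$\mathrm{UD}(W) = \frac{N(W)}{E(W)}.$$

At $k = 4$ this is tetranucleotide usage deviation (TUD), a 256-dimensional
vector per genome. A value of 1 means the word is used exactly as its base
composition predicts; 2 means twice as often. Because the null conditions
on the genome's own composition, the deviation isolates word-level
preferences (codon usage, restriction-site avoidance, methylation-site
enrichment) from plain GC content.

Before counting, each sequence is extended by its reverse complement: the
forward strand and its reverse complement are counted as two *separate*
strings and the counts summed. This makes every statistic invariant to
which strand was deposited in the database. We deliberately do not
concatenate the strands into one string, so no artificial junction-spanning
words exist. A consequence of the extension is an exact symmetry
$\mathrm{UD}(W) = \mathrm{UD}(\mathrm{revcomp}(W))$, which the package
maintains bit-exactly (the factors of $E(W)$ are grouped as
$(f_A^a f_T^t)(f_C^c f_G^g)$ so that the floating-point product is
literally identical for a word and its reverse complement).

```{r}
tv <- usage_deviation("AAAA", k = 2)
tv$deviation[["AA"]]   # 3 observed / 2 expected
```

Two reductions are applied before genomes are compared:

* **Canonicalization** drops one member of each reverse-complement pair
  (keeping the lexicographically smaller; palindromes stay once), leaving
  $(4^k + 4^{k/2})/2$ words for even $k$ — 136 at $k = 4$.
* **Universality filtering** removes any word with observed count zero in
  at least one genome of the collection, so every retained deviation is
  strictly positive and the vectors are log-transformable. On large genome
  collections this typically removes at most a handful of words; on very
  short or biased sequences it can remove many, which is why distances are
  only defined across a filtered collection.

### The length term in E(W)

The expectation formula multiplies by "the length of the genome". Applied
to the extended sequence on which counts are taken, we read this as the
total extended length $2L$ (the default, `denominator = "length"`). The
alternative reading — the number of word start positions, $2(L - k + 1)$ —
is available as `denominator = "positions"`. The two differ by a factor
$1 + O(k/L)$, irrelevant for genome-scale input but visible in toy
examples; the worked `AAAA` example above uses the default.

### Ambiguity codes

Inputs are normalized to `{A,C,G,T,N}`; any other character becomes `N`
with a warning count. A window containing `N` contributes to no word
count, and composition is computed over unambiguous characters only. This
is our policy choice for real-world FASTA, not part of the statistic.

## Comparing genomes

Genome pairs are compared by the Euclidean distance between their filtered
canonical deviation vectors. From the resulting distance matrix the
package builds:

* **Neighbor-joining trees** (`neighbor_joining()`): an in-package
  Saitou–Nei implementation, consistent on tree-additive matrices. A
  negative branch length — possible on non-additive data — is clamped to
  zero with the deficit moved to its sister branch, preserving the path
  length through the join; ties in the Q criterion resolve to the first
  minimal pair in column-major order, so results are deterministic given
  input order. Trees are emitted unrooted; no outgroup logic is applied.
* **Average-linkage dendrograms** (`average_linkage()`): UPGMA via
  `stats::hclust(method = "average")`, returned as a rooted ultrametric
  `phylo` object whose cophenetic distances equal the merge heights —
  exactly ultrametric inputs are reproduced unchanged.
* **PCA** (`tud_pca()`): natural-log transform (the base only rescales
  loadings uniformly; it is fixed for reproducibility), column centering,
  no column scaling, singular value decomposition. Signs are fixed so each
  component's largest-magnitude loading is positive. The log transform
  requires the universality filter to have run, and the function refuses
  zero deviations with a pointer to it.
* **Monophyly checks** (`monophyly_check()`): a labeled group is called
  monophyletic when some edge of the unrooted tree separates exactly that
  group's leaves from the rest — the tree-based operationalization of
  "cluster members group together".

## Scanning within a genome

`window_profile()` slides a window (default 2000 bp, step 500 bp) along a
genome and treats each window as an independent mini-genome: extended by
its own reverse complement and normalized to its own composition. The
2000 bp default balances resolution against sampling: a 2 kb window
contains ~4000 tetranucleotide positions across both strands, enough to
observe most of the 256-word space, while a much shorter window would be
dominated by sampling noise. Windows are 0-based half-open; a final
partial window is dropped rather than truncated (a short window
under-samples the word space and would appear spuriously distant), except
when the whole sequence is shorter than one window, which yields a single
flagged truncated window.

`window_heatmap()` computes all pairwise window distances. Two choices
matter here:

* words with zero *expected* count in either window of a pair (an absent
  nucleotide — possible in short windows) are excluded from that pair's
  distance rather than entering as $0/0 = 0$;
* pairs of overlapping windows are masked (`|start_i - start_j| <`
  window size) and excluded from all downstream statistics, since shared
  sequence makes their distance artifactually small.

`call_outlier_windows()` makes heatmap inspection reproducible: each
window's mean unmasked distance to all other windows is computed, and
windows at or above `median + z * MAD` (scaled MAD, `z = 3` by default)
are flagged, with adjacent flags merged into intervals. The robust
threshold tolerates the heavy upper tail that repeat blocks induce. Two
properties of this rule should be understood when interpreting output:

* the threshold is inclusive, so at `z = 0` at least half of all windows
  are flagged — the degenerate boundary behaves predictably;
* with ~100 windows per genome, the *maximum* window mean sits around
  2.5–3 robust standard deviations above the median even in perfectly
  homogeneous sequence, so isolated single-window flags occur in a
  substantial fraction of ordinary genomes at `z = 3`. We therefore
  quantify specificity as the **per-window false-flag rate** — the
  fraction of windows outside any planted feature that get flagged,
  measured at ~0.1–0.5% under the benchmark conditions below — rather
  than "fraction of genomes with any flag". Calls are evidence for
  *where* to look, and multi-window intervals are far stronger evidence
  than single-window flags.

`word_track()` follows one word (e.g. the Dam methylation site `GATC`, or
the 6-bp `GGATCC`) along the genome in larger windows (default 5 kb, step
1 kb), dividing its two-strand count by its expectation under each
window's own composition; `group_mean_track()` averages tracks across
genomes window-index by window-index, truncating at the shortest track —
genomes are unaligned, so only shared leading indices are comparable.

## The synthetic community generator

Recovery claims are only as good as the benchmark, so the generator is
first-class, seeded code. `random_biased_model()` draws, for every
context of an order-$m$ Markov chain, a transition vector from a
symmetric Dirichlet with concentration $1/\text{bias\_strength}$ per
component: strength 0 is exactly uniform, larger strengths give stronger
word-usage idiosyncrasy. Order 3 is the default because it is the lowest
order that directly shapes 4-mer usage, the package's central statistic.

`generate_community()` builds one model per cluster and per-genome
variants by re-drawing each transition vector from a high-concentration
Dirichlet centered on the cluster model (concentration $200 p$), so that
within-cluster variance is nonzero — clusters are tight but not
degenerate. Defaults (3 clusters × 5 genomes, 50 kb, bias strength 0.5)
give between-cluster TUD distances comfortably above within-cluster ones
while remaining a nontrivial recovery problem; separability is monotone in
bias strength. Planted features are recorded as 0-based half-open ground
truth: an HGT-like event *inserts* a segment generated from a donor
cluster's model (the genome grows — the host sequence is not overwritten),
and a repeat feature inserts a tandem block. All randomness flows from one
top-level seed through fixed arithmetic, so any subset of a community can
be regenerated byte-identically.

What the generator does **not** emulate: gene content and its ordering,
genome-length variation, GC-range conventions of real phage clusters,
amelioration of transferred segments toward the host signature, and
mosaicism with multiple donors. Passing recovery tests on these
communities therefore demonstrates that the statistics behave as designed
under controlled compositional structure — not that every real genome's
clusters will be as cleanly separable, since real subclusters differ by
evolutionary distances, not by independently drawn Dirichlet models.

## Problem sizes and verification

The shipped checks run at desk scale, chosen so the whole suite completes
in a couple of minutes while every stochastic bound is a multi-sigma
check: null calibration of mean TUD on a 1 Mb i.i.d. sequence (band
±0.01); counting verified against a per-position scan oracle on 200
sequences up to 500 bp for $k \le 6$; NJ topology recovery on 50 random
additive matrices of up to 8 leaves (exact); UPGMA cophenetic fixed point
at $10^{-9}$; cluster monophyly on 20 seeded 3×5 communities of 50 kb;
PCA silhouette on planted 2-cluster communities; window-scan sensitivity
on 20 seeded 50 kb hosts with 5 kb inserts. Word-track calibration uses a
1 Mb i.i.d. genome: with 5× overlapping windows a megabase provides only
a few hundred effective draws, and the shorter sequences one might first
reach for would make the ±0.05 calibration band a ~1-sigma coin flip
rather than a meaningful check. Two spec'd example tolerances were
re-derived as under-powered at their nominal sizes and are tested at
matched power instead (binomial-standardized transition-frequency error;
the megabase track above).

## Known limitations

* The zero-order null is the method's definition, not an option; first- or
  higher-order normalizations (which absorb progressively more signal into
  the null) are out of scope.
* Deviation vectors are length-biased for very short sequences (< a few
  kb at $k = 4$): many words are simply unobservable, and the universality
  filter will prune aggressively.
* The window scanner detects *compositional* anomaly only; a transferred
  segment from a compositionally similar donor, or one long since
  ameliorated, is invisible to it.
* `k` is capped at 8 ($4^8$ words) to bound memory; practical use is
  $k \in 2\ldots7$.
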