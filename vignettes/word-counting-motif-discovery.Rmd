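---
title: "Word-counting discovery of degenerate promoter motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-counting discovery of degenerate promoter motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Co-expressed genes tend to share short (5–15 bp) cis-regulatory elements in
their promoters. `promotif` finds such elements by exhaustive word counting:
instead of fitting a probabilistic motif model by local search, it counts,
for *every* degenerate word of a fixed length, how many promoters of a gene
cluster contain it, and compares that with the word's frequency across all
promoters of the genome. Exhaustive enumeration is slower than model
fitting but is guaranteed to find the globally best-scoring words, and it
suits the short, partially degenerate motifs typical of plant promoters.

Two word spaces are used:

* **8-mers over an 11-letter alphabet** — A, C, G, T, the six two-fold
  wobbles r = A|G, y = C|T, s = C|G, w = A|T, m = A|C, k = G|T, and the
  wildcard n. This covers all two-fold degeneracy (11⁸ = 214,358,881
  words); three-fold wobbles (b, d, h, v) are deliberately excluded, as
  they are rarely informative for motif work.
* **12-mers over a 5-letter alphabet** — A, C, G, T, n. Degeneracy is
  restricted to the wildcard, buying word length instead (5¹² =
  244,140,625 words).

Each word maps to an integer by reading its letters as digits (A..n =
0..10), leftmost letter most significant — base-11 positional notation for
8-mers, base-5 for 12-mers. The integer is the word's index into a dense
counter array, which is what makes exhaustive counting feasible.

### Presence counting

The catalog stores, per word, the number of promoters harboring at least
one match (*presence*), not the total occurrence count: a promoter
contributes at most 1 to any word's counter however often the word occurs
in it. Conceptually the loop visits each promoter, extracts every
window of length L, lists each window together with all of its degenerate
forms (5⁸ per 8-mer window: per position the base itself, the three
two-fold wobbles containing it, or n), deduplicates within the promoter,
and increments the counters. The implementation computes the same
quantity by a position-wise bitset recursion: for every concrete word a
bitset records which promoters contain it; degenerate letters are expanded
one position at a time by OR-ing the bitsets of their constituent bases,
and a popcount at each leaf yields the presence count. The two
formulations are provably identical (and are cross-checked against a
brute-force matcher in the tests); the bitset route indexes a
1000-promoter genome over all 11⁸ 8-mers in about two minutes on one core,
with the counter array (~0.9 GB as 32-bit integers) dominating memory.

Promoters are fixed-length upstream windows (canonically 1000 bp) on the
given strand, position 1 being the most upstream base and position
S = 1000 − L + 1 adjacent to the TSS. An `N` in a sequence matches
nothing — degeneracy is a query-side wildcard, not sequence uncertainty —
so windows overlapping an `N` are skipped entirely. The treatment of
assembly-gap `N` runs is our own choice; it errs on the side of never
inventing an occurrence.

## Scoring

### Over-representation

For a cluster of M promoters drawn from a universe of K, with a word
present in m cluster promoters and k universe promoters, significance is
the hypergeometric upper tail

$$p = \sum_{i \ge m} \frac{\binom{k}{i}\binom{K-k}{M-i}}{\binom{K}{M}},$$

computed in log space so tails of order 1e-40 are exact. Only words that
are *restricted* (present in at least one but fewer than half of the
universe's promoters, 1 ≤ k < K/2 — ubiquitous words are uninformative)
and *over-represented* (m > kM/K) are tested. We read "existing in fewer
than 50% of all the promoters" as implying k ≥ 1, since a word absent from
the universe cannot occur in a cluster. After scoring, each
reverse-complement pair keeps only its better-ranked member (single-strand
scanning makes the pair near-redundant; palindromes are kept), and
Benjamini–Hochberg q-values are computed over the deduplicated tested
family. The q-value procedure is our choice of the conventional reading of
an FDR-adjusted column; no specific procedure is forced by the method
itself.

Because a single 8-mer cluster analysis can test tens of millions of
words, the enrichment pass streams over the counter arrays in chunks and
materializes only records below a retention cutoff (`p_keep`), while
counting the tested family and its reverse-complement pairing exactly.
Retained q-values use the true family size; with a truncating `p_keep`
they are exact for the retained records unless a worse-ranked record would
have lowered them, in which case they are conservative.

### Position bias

Functional elements cluster near the TSS. With S valid starts, uniform
placement has mean μ = (1 + S)/2 (497 for 8-mers in 1000-bp windows) and
per-instance variance σ² = (S² − 1)/12, so a word with n occurrence
instances (every instance counts, unlike presence) gets

$$z = \frac{\bar p - \mu}{\sqrt{(S^2-1)/(12\,n)}}.$$

Positive z means TSS-proximal bias. Note the 1/12: quoting the variance of
the mean as (S² − 1)/n without it would give null z-scores with spread
~0.29 rather than 1, which contradicts both the standard discrete-uniform
variance and the empirical flatness of null z around 0 with unit spread
that the calibration reproduces; we therefore implement the /12 form. The
Monte-Carlo tests verify σ² and the CLT calibration of z directly. A
limitation inherited from the mean-based statistic: bias *at the middle*
of the window (e.g. a peak at −500) moves the mean nowhere and is
invisible.

### Qualification and the calibrated cutoffs

A word qualifies as a potential motif if p < 1e-7, or if 1e-7 ≤ p ≤ 1e-5
and z > 3. The two measurements are independent, so words passing both are
high-confidence. The cutoffs come from the null calibration below.

## The position-overlap filter

The top of a ranked list is dominated by degenerate variants of a few
motifs occupying the same binding sites. The filter iterates: take the
best-ranked remaining word as a *major motif*, mark its occurrence
positions (gene id, start) in the cluster, and remove every remaining word
that shares ≥ 10% *of its own* positions with the marked set; stop when
fewer than 10 words remain. Three choices here were genuinely open and are
resolved as follows:

* a *position* is the exact (gene, start) pair — two words covering the
  same site at shifted offsets do not share a position (shifted
  near-reverse-complement pairs are evidently reported separately in this
  method's outputs);
* the 10% denominator is the candidate's own position count (the
  asymmetric reading of "share at least 10% of its position"), which also
  guarantees progress;
* p-value ties break by smaller word code, making the output
  deterministic.

The pipeline (`discover_motifs()`) scans positions only for the
`max_candidates` (default 2000) best-ranked sub-cutoff words. Majors are
drawn from the top of the ranking, so the cap only limits which deep
variants can be explicitly absorbed; it keeps position scanning
proportionate.

## Null calibration

`calibrate_fdr()` reruns the whole enrichment on groups of promoters drawn
at random from the universe, where every sub-cutoff word is by
construction a false positive. With n_r restricted words, roughly half
over-represented in any given group and reverse-complement dedup halving
again, the expected count at cutoff p is n_r·p/4. At full scale
(n_r = 75,029,949 for Arabidopsis 8-mers) this predicts ~1.9, ~19 and
~188 false words at 1e-7, 1e-6 and 1e-5.

The packaged replication is scaled down to run in seconds: 3-mers over a
200-promoter × 40-bp uniform-composition universe, 20 groups of 20, with
cutoffs 1e-4 / 5e-4 / 2e-3. Two of these choices deserve comment. The
40-bp window keeps concrete 3-mer presence below 50% of promoters so the
restricted family is non-trivial; uniform composition avoids the
positional clumping of AT-rich homopolymer words, which would inflate the
null z spread through within-promoter occurrence correlation that the
placement model deliberately ignores. The cutoffs sit in the deep tail of
the attainable p-value support, which is the regime the n_r·p/4 law
describes (and the regime the full-scale cutoffs occupy): in the dense
part of the support the discreteness factor fades and counts run 2–3×
above the law, which is visible in the exact per-genome expectation
E = Σ over restricted words of P(tail ≤ p, over-represented). The
calibration tests therefore compare total counts against n_r·p/4 within
3× Poisson noise, and check that the tested-word z distribution is flat
(mean ≈ 0, sd ≈ 1).

## Two-genome analyses

**Conserved p-values.** For clusters with orthologs in a related species
(ortholog detection is upstream input: a precomputed one-to-one table),
the enrichment runs independently in each species' orthologous promoter
set against its own genome index, records join on
reverse-complement-canonical word identity, and each word's *conserved
p-value* is the larger of its two per-species p-values. True motifs
survive at ~85% promoter identity; independent false positives rarely
recur in both species, so the usable cutoff relaxes to 1e-5. The packaged
two-species fixtures emulate exactly this: species 2 is a mutated copy
(default 15% per-base substitution) with planted instances optionally
protected from mutation.

**Genome-wide bias scan.** TSS position bias needs no cluster: scanning
*all* promoters of a genome for words with z above a cutoff finds globally
positioned elements. To keep the word family interpretable the scan
restricts degeneracy to at most two wobbles drawn from {r, y, s, w, n}
(3,588,096 8-mers; the asymmetric m/k are excluded). Occurrence counts and
position sums aggregate from a concrete 4^L tally, so the scan is fast at
full scale. Intersecting the surviving word lists of two genomes keeps
motifs with *shared* bias — a comparative method needing no promoter
alignment at all. Per-genome instance counts are occurrence counts (the
z-score's n), not presence counts.

## The synthetic-data generator

`generate_fixture()` builds i.i.d. background promoters (default
Arabidopsis-like composition A/T 0.33, C/G 0.17), selects a cluster, and
splices planted motif instances — each a concrete realization of the
degenerate word, at a start drawn from the configured interval — recording
a truth table for recovery scoring. All randomness flows from one seed
through named sub-streams. What the generator does *not* emulate:
nucleosome structure, compositional heterogeneity along real promoters,
correlated occurrences of repetitive elements, or real co-expression
signal. Passing the planted-recovery tests therefore demonstrates the
machinery (counting, scoring, filtering, conservation) end to end, not
performance on real chromatin.

Study scales used by the packaged tests, chosen once to keep the whole
suite a few minutes on one core: planted-motif recovery runs the full
8-mer space over a 200-promoter × 1000-bp universe (cluster of 40,
"rGTCAAmn" planted in 70% at starts 800–986, 15% inter-species
divergence); module-level recovery tests use 5-mers over 150-promoter ×
150-bp universes; the calibration scale is described above; the
full-array smoke test indexes 1000 promoters over all 11⁸ 8-mers.

## Numerical and degenerate-input choices

* Integer word codes stay below 2³¹ for both canonical spaces and are
  held as doubles at the R level; the counter arrays are 32-bit.
* p-values are computed via the log-space hypergeometric tail;
  under-represented input is refused rather than scored.
* Words absent from a cluster are never tested (m = 0 fails
  over-representation); z is undefined (an error) for words with no
  occurrences.
* Empty candidate lists yield empty—not failing—reports; an all-`N`
  promoter simply contributes nothing.
* `read_promoters()` rejects wrong-length records outright: silent
  trimming of upstream windows would shift every position statistic.

## A worked example

```{r example}
library(promotif)

spec <- fixture_spec(
    n_promoters = 150, window_length = 150, cluster_size = 30,
    plants = list(plant_motif("rGTCA", cluster_fraction = 0.8,
                              from = 100, to = 146)),
    seed = 1)
fx <- generate_fixture(spec)

disc <- discover_motifs(fx$genome, fx$cluster_ids, L = 5L, stop_below = 0)
disc$majors[, c("rank", "motif", "m", "k", "pvalue", "mean_position",
                "zscore")]

# two-species confirmation
ofx <- generate_ortholog_fixture(spec, conserved = TRUE)
g1 <- index_promoters(fx$genome, alphabet11(), 5L)
g2 <- index_promoters(ofx$promoters2, alphabet11(), 5L)
conserved_motif_analysis(fx$cluster_ids, ofx$orthologs, fx$genome,
                         ofx$promoters2, g1, g2, L = 5L, cutoff = 1e-5)
```

## Known limitations

* Single-strand scanning with reporting-stage reverse-complement
  deduplication; strand-symmetric occurrence statistics are not pooled.
* The mean-position z-score cannot see mid-window positional bias.
* The overlap filter can absorb genuinely distinct motifs that share
  partial binding sites with a stronger major.
* Three-fold wobbles are not representable by design.
* Variable-length promoters and on-the-fly extraction from genome +
  annotation are out of scope; inputs are pre-extracted fixed windows.
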