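---
title: "starmsa: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{starmsa: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmsa)
```

## The model

`starmsa` implements the center-star heuristic for multiple alignment of
highly similar nucleotide sequences. The heuristic assumes the inputs
arose from a single ancestral sequence by independent accumulation of
substitutions and short indels, so that (i) one input — the *center* —
is close to all others, and (ii) each pairwise alignment against the
center is near the identity, with few, short gaps. Under these
assumptions aligning everything to the center and merging the gaps loses
little compared to exact multi-way alignment, at a tiny fraction of the
cost. The package deliberately does **not** target divergent sequence
sets; on those, a progressive aligner is the right tool.

## Center selection in O(mn)

The exact center maximizes the all-pairs similarity total
$S_i = \sum_{j \ne i} S_{ij}$, which costs $O(m^2 n^2)$ to compute by
dynamic programming. The bitmap proxy used here cuts each sequence into
disjoint 8-mer segments, packs each segment into a 16-bit integer
(2 bits per residue), counts in a $2^{16}$-slot table `Occ[]` how many
*sequences* contain each code (a sequence contributes at most once per
distinct code), and scores each sequence by
$SS = Occ[d_1] + \dots + Occ[d_p]$ over its full, duplicate-retaining
segment list. The sequence with maximal $SS$ is the center; ties break
to the smallest 0-based index for determinism. Total work is one table
update per distinct code per sequence plus one lookup per segment —
at most $2\sum_i \lfloor \ell_i/8 \rfloor$ table operations, i.e. linear
in input size. The test suite verifies both exact agreement with an
independent dictionary-count oracle and the operation bound via
instrumented counters.

Design points worth calling out:

* **Residue coding.** The default mapping is A=00, T=01, G=10, C=11,
  the one consistent with the worked example `ATCGCGAT` → binary
  `0001111011100001` → 7905. (An alternative description of the same
  scheme assigns A,T,C,G → 00,01,10,11, which would give 7089 for the
  same segment; the two are mutually inconsistent, and we follow the
  worked example.) The mapping is configurable (`mapping = "prose"` or a
  named vector), and any bijection onto {0,…,3} gives the same *SS*
  values, only permuting table slots.
* **Trailing remainder.** A final partial segment (< 8 residues) is
  discarded; partial segments have no defined 16-bit code.
* **Self-counts.** Read literally, $SS$ includes each sequence's own
  contribution to `Occ`. `include_self = FALSE` subtracts one count per
  accumulated term (every term contains exactly one self-count), which
  tracks the self-excluding total $S_i$ more closely. The default keeps
  the literal reading; with it, every sequence with $p$ segments has
  $SS \ge p$.
* **Ambiguity policy.** The 2-bit code has no slot for N or IUPAC
  ambiguity codes. The default policy maps ambiguous characters to `A`
  (counted and logged), keeping the encoding total; `strict` refuses
  them; `skip-segment` keeps them in the residue text and drops any
  segment containing one from the encoding. Which behavior real
  pipelines used historically for rRNA data is undocumented, so all
  three are provided.

## Pairwise alignment

Global Needleman–Wunsch with a linear gap penalty; defaults
match = +1, mismatch = −1, gap = −2 (the underlying method's published
description never states its scheme, so these conventional values are a
package choice, configurable via `scoring_scheme()`). Affine gaps and
local alignment are out of scope. The backtrace resolves ties in the
fixed order diagonal ≻ up (gap in the non-center row) ≻ left (gap in the
center row), making every output bit-reproducible. One consequence of
diagonal-first tie-breaking is that among equally optimal placements of
a gap run, the *leftmost* placement is chosen (e.g. `ACGT` vs `AACGT`
aligns as `-ACGT`/`AACGT`, not `A-CGT`/`AACGT`).

### The k-band variant

For similar sequences the optimal path hugs the main diagonal, so the DP
can be restricted to cells with
$\min(0,\delta) - k \le j - i \le \max(0,\delta) + k$, where
$\delta$ is the length difference. The initial half-width is
$k_0 = \max(|\delta| + 1, 8)$ (no published rule exists; this covers the
length difference and gives a useful minimum). The band is doubled and
the alignment recomputed until either the band covers the table or the
in-band optimum is *certified* globally optimal by two conditions:

1. the backtraced path does not touch the band boundary, and
2. the in-band score strictly exceeds
   $\mathrm{match}\cdot\max(0,\min(l_a,l_b) - (k+1)) +
    \mathrm{gap}\cdot(|\delta| + 2(k+1))$,
   an upper bound on any path leaving the band (leaving requires at
   least $|\delta| + 2(k+1)$ gap columns, hence at most
   $\min(l_a,l_b) - (k+1)$ residue-pair columns each worth at most
   `match`).

The path-interior check alone is *not* sufficient — an in-band optimum
can sit strictly inside the band while a better path exists outside it —
which is why the score certificate is required. Under the certificate
every optimal path lies in the band, banded cell values along it equal
the full-table values, and the banded backtrace reproduces the
full-table backtrace exactly, so `kband_align()` returns rows and score
identical to `nw_align()` (property-tested on simulated similar pairs).

## Merging into the MSA

Each pairwise alignment demands gap runs at insertion points on the
center (0-based residue index before which the run sits; index
`len(center)` for trailing runs). The merged gap profile takes the
**maximum** run length per insertion point. The construction is
described elsewhere as "summing" the inserted spaces; literal addition
would misalign even two identical pairwise alignments, so "summed" is
read as "aggregated", and the pointwise maximum is the standard
center-star construction — it is the narrowest profile dominating every
pair. Within an expanded gap block the pair's own characters are placed
left-justified and padded with `-` (no convention is published; this one
is deterministic and documented). Insertion points are keyed to center
residue indexes, so earlier insertions never shift later ones. The final
width is `len(center) + sum(profile)`, every row degaps to its input,
and row order equals input order.

## Workload partitioning

The original execution model splits the pairwise workload between a CPU
and a GPU; this package generalizes to **two configurable worker pools**
so the ratio logic is testable on any machine (GPU kernels are out of
scope). A pre-computation step aligns the same small sample on both
pools; the elapsed-time ratio $R = t_1/t_2$ assigns pool 1
$n_1 = \mathrm{round}(n/(R+1))$ tasks and pool 2 the rest. Choices:

* **Sample size** (unstated in the source): `min(max(32, 1% of n),
  floor(n/2))`, at least 1.
* **Rounding**: round-half-even (R's `round()`); the bound
  $|n_1 - n/(R+1)| \le 1$ holds regardless.
* **Degenerate pools**: a pool with 0 workers is zero-capacity — all
  tasks go to the other pool ($R = 0$ or $\infty$ rather than a division
  by zero).
* **Determinism**: workers share no mutable state and results are
  collected in dataset order, so the final MSA is byte-identical across
  pool counts, splits and completion orders (property-tested).
  Pre-computation results are discarded and recomputed in the main run,
  keeping the contract simple.
* **Fake clock**: a pool may carry a simulated per-task cost, making
  ratio measurement exact and deterministic under test (e.g. costs 2 and
  1 give $R = 2$ exactly).

## The synthetic-data generator

`generate_sequences()` draws a uniform ancestor over {A,C,G,T} and
derives each sequence independently (star topology — exactly the
regime the center-star model assumes): per site, substitution with
probability `sub_rate` (uniform over the 3 alternatives), and
geometric-length insertion/deletion runs starting with `ins_rate` /
`del_rate`. Defaults — length 252, `sub_rate` 0.02, `ins_rate` =
`del_rate` = 0.005, indel mean length 2 — describe a typical
high-similarity nucleotide dataset of a few percent divergence (252 nt
matches the short-amplicon scale the method was demonstrated on);
they were fixed once, before any test was run. Identical configuration
and seed give byte-identical output.

What the generator does *not* emulate: tree-structured phylogenies
(correlated lineages), secondary-structure-constrained evolution, base
composition bias, sequencing error profiles, and ambiguity codes. A
green property suite on simulated data therefore establishes the
*algorithmic contracts* (round-trips, equivalences, determinism, bounds)
— not alignment accuracy on any real biological dataset.

## Numerical and degenerate-input choices

* Scores are accumulated in double precision; with the default integer
  scheme all comparisons are exact.
* Empty sequences are legal alignment inputs (an all-gap row results);
  empty *records* in FASTA are rejected with the record name.
* Sequences shorter than one segment have $SS = 0$; a dataset of only
  such sequences picks index 0 (tie rule). Center selection requires
  $n \ge 2$.
* Gap–gap columns score 0 in SP; the average SP divides by $n$, not by
  the number of pairs, matching the convention it is compared against.
* Coordinates are 0-based everywhere a position is reported (center
  index, insertion points, error positions); the gap character is `-`.

## Known limitations

* SP values here are self-consistent but not comparable to external
  scoring programs whose schemes differ (notably for published benchmark
  tables, which also depend on datasets not shipped here).
* The center-star result is not refined iteratively; no guide tree.
* Only two worker pools; the measured ratio assumes task costs are
  homogeneous across the dataset.
* The O(mn) selection is a proxy: it optimizes shared exact 8-mers, not
  alignment score, and can pick a different center than the exact
  $S_i$ maximizer (by design — that is the speed/accuracy trade).
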