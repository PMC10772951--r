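---
title: "Motif discovery on de Bruijn and Hamming distance graphs: the method behind cemig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery on de Bruijn and Hamming distance graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemig)
```

## The problem

ATAC-seq delineates accessible chromatin, and footprints within accessible
regions mark candidate transcription-factor binding sites — but without the
antibody of a ChIP experiment there is no direct evidence of *which* factor
binds. `cemig` addresses the resulting de novo problem: given only a set of
footprint or peak sequences, find short recurring patterns (motifs) that are
over-represented relative to the local sequence composition, and report them
as position weight matrices with their genomic sites.

The design premise of the algorithm is that motif signal in accessible
chromatin is diluted — footprints mix many factors and much background — so
single k-mer frequencies are unreliable. The method therefore amplifies
signal twice: first by *clustering* k-mers that are one substitution apart
(mutational neighbours of a binding word), then by *assembling* clusters
that overlap by k − 1 characters into longer words on a de Bruijn graph, so
that a motif longer than k can be recovered from its constituent k-mers even
when no single k-mer is individually dominant.

## Stage 1 — Poisson scoring against a Markov background

The input sequences $S_1,\dots,S_n$ (lengths $l_1,\dots,l_n$) supply both
the foreground counts and the background model. Three matrices are
estimated from forward-strand substring frequencies: $M_1(a)$, the
mononucleotide distribution; $M_2(a_2\mid a_1)$, the first-order transition
matrix; and $M_3(a_3\mid a_1a_2)$, the second-order transition matrix. A
pseudocount (default 0.5 per cell) keeps all entries positive. The expected
count of a k-mer $t = a_1a_2\cdots a_k$ is the stationary chain product

$$\lambda(t) = M_1(a_1)\,M_2(a_2\mid a_1)\prod_{j=3}^{k}
  M_3(a_j\mid a_{j-2}a_{j-1})\;\sum_{i=1}^{n}(l_i - k + 1),$$

and the significance of its observed count $n(t)$ is the Poisson upper
tail $P(t) = 1-\sum_{x=0}^{n(t)-1} e^{-\lambda}\lambda^x/x!$, evaluated
with the survival function for numerical stability and clipped below at
the smallest positive normal double before logs are taken. Lower
background orders are supported by collapsing: order 0 sets every row of
$M_2$ and $M_3$ to $M_1$; order 1 sets $M_3(c\mid ab) = M_2(c\mid b)$.

Counting is double-stranded: windows of each sequence and of its reverse
complement are counted as read, and the position total is doubled to keep
$n(t)$ and $\lambda(t)$ on the same scale. This makes the scoring
consistent with the (explicitly double-stranded) de Bruijn construction
and avoids half-counting non-palindromic motifs.

One property of this scheme is worth knowing when interpreting output: a
heavily planted word inflates its own second-order background transitions,
so at order 2 the forward word can rank below its reverse complement
(whose transitions are not inflated by forward-strand estimation). The
motif is still found — k-mer tiers and the graphs carry both orientations —
but single-k-mer ranks at order 2 should not be over-interpreted.

Ranked by decreasing $-\log_{10}P$ (ties broken lexicographically for
determinism), k-mers are tiered: **K1**, the top $\min(100,|K2|)$ seeds;
**K2**, the top half (ceiling for odd counts); **K3**, the rest.

## Stage 2 — the two graphs

* **Hamming distance graph $G$** — vertices are K2 k-mers; an edge joins
  every pair at Hamming distance exactly 1 (the "distance below two" rule
  with distinct vertices), with the distance stored as its weight. The
  graph is built by enumerating each k-mer's $3k$ substitution neighbours
  rather than scanning all pairs, which keeps construction near-linear in
  $|K2|$.
* **de Bruijn graph $G_{DB}$** — vertices are all observed k-mers
  (K2 ∪ K3); a directed edge $u \to v$ exists when the last $k-1$
  characters of $u$ equal the first $k-1$ of $v$, weighted by the count of
  the spelled $(k{+}1)$-mer over both strands. Weights are pure substring
  frequencies regardless of the flanking k-mers' significance; homopolymer
  self-loops are kept; zero-weight edges are dropped.

## Stage 3 — clustering on the Hamming graph

Cluster seeds are a greedy maximal independent set over K1, scanned in
significance order, so seeds are mutually dissimilar (never one
substitution apart). Each seed $v$ initialises a cluster $C$ together with
the pair of its neighbours maximising

$$f(C) = \frac{-\sum_{\{u,v\}\in E(C)} w(u,v)^{-1}\,
  \log\!\big(p(u)\,p(v)\big)}{|C|\,(|C|-1)}\cdot\log(|C|),$$

where the sum runs over adjacent member pairs, $p(u)$ is the k-mer's
Poisson p-value, and logs are natural (an unspecified base only rescales
$f$ and cannot change any argmax). $f$ of a singleton is defined as 0,
matching the $\log(|C|)$ factor's limit. The cluster then hill-climbs:
each round admits the single boundary neighbour whose addition most
increases $f$, then evicts the single non-seed member whose removal most
increases $f$ while keeping the cluster connected around its seed;
strictly increasing $f$ guarantees termination at a one-move local
optimum. Ties are always broken lexicographically. Clusters may overlap at
this stage; the digraph step resolves shared k-mers.

## Stage 4 — cluster digraph, path extension, refinement

Clusters become vertices of a digraph $G_C$: K3 k-mers and unclustered K2
k-mers are excised, a k-mer claimed by several clusters is assigned to the
one with the higher $f$ (ties by seed), and the edge weight
$c_1 \to c_2$ is the sum of $G_{DB}$ weights between their members.
Within-cluster weights are recorded as self-loops but never traversed.

Paths are assembled greedily: start from the uncovered cluster with the
highest $f$; at each step compare the heaviest usable outgoing edge at the
downstream end with the heaviest usable incoming edge at the upstream end
and take the heavier (downstream on a tie). An edge is unusable when its
weight is zero, its target is already on the path, its direction has
already received 3 vertices, or the total edge count would exceed
$18 - k$ — both caps are enforced, so spelled motifs are between $k$ and
18 nt. When both directions block, the path is emitted and all its
vertices (not only the start) become covered; the loop repeats until every
cluster is covered.

A path's **occurrences** are genomic windows, on either strand, whose
successive k-windows each belong to the corresponding cluster of a path
segment. Two segments are scored per path — $O_1$ from the upstream
sub-path including the start cluster and $O_2$ from the downstream
equivalent (the start belongs to both, so their overlap is generically
non-empty) — and the overlap ratio
$r = |O_1\cap O_2| / \min(|O_1|,|O_2|)$ decides the output: one motif from
the full path when $r > 1/2$; three motifs ($O_1$, $O_2$, intersection)
when $1/4 < r \le 1/2$; two motifs ($O_1$, $O_2$) when $r \le 1/4$, the
boundary values following the strict/non-strict inequalities above. Two
occurrences are considered overlapping when they share sequence and strand
and their intervals intersect; the intersection set is materialised from
the $O_1$ side. An empty side gives $r = 0$, and empty occurrence sets are
dropped rather than emitted as empty motifs.

Each surviving occurrence set becomes a PWM with per-column probabilities
$(\text{count} + q)/(\text{nsites} + 4q)$ (default $q = 0.25$), consensus
by column argmax with ties resolved $A<C<G<T$. Output formats are MEME
minimal (probabilities printed at six decimals, which also makes repeated
runs byte-identical) and BED6 site lists scored by mean per-column
information content scaled to 0–1000.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 6 | word length (nt); graphs and tiers are built at this k |
| `markov_order` | 2 | background order, 0–2, with collapse rules |
| `top_k1` | 100 | cap of the seed tier K1 |
| `max_len` | 18 | maximum spelled motif length (nt) |
| `bg_pseudocount` | 0.5 | per-cell pseudocount of $M_1,M_2,M_3$ |
| `pwm_pseudocount` | 0.25 | per-cell PWM pseudocount |

## The synthetic generator, and what passing tests mean

`generate_planted_dataset()` draws background sequences from a Markov
chain (uniform i.i.d. by default, or any estimated background model) and
implants one mutated consensus copy per selected sequence: selection is
Bernoulli(`instance_rate`), each position mutates independently with
probability `mutation_rate` (uniformly to the three other bases), offset
and strand are uniform, and implantation overwrites background so lengths
stay fixed. The exact implanted intervals are returned, enabling
site-level precision/recall (`score_recovery()`: a site is recovered when
a reported occurrence on the same sequence overlaps it by at least its
length minus a slop, default 2 nt).

The reference conditions used throughout the test-suite are an AP-1-like
consensus `TGACTCAT` planted in 30% of 500 sequences of 100 nt at 10%
per-position mutation, with uniform background. What this emulates is
motif dilution and mutational degeneracy. What it does **not** emulate:
Tn5 insertion bias, footprint shape, GC heterogeneity along real open
chromatin, multiple co-occurring motifs per region, or multi-instance
sequences. Passing the planted-motif tests therefore demonstrates correct
mechanics and detectable-signal recovery, not performance on real ATAC-seq
libraries.

Under these reference conditions site-level recall sits near one half:
occurrence matching requires every k-window of a site to belong to its
cluster, so instances carrying mutations outside the clustered
neighbourhood are invisible by construction — at 10% per-position mutation
roughly half the planted instances retain a fully clustered core. The
recall the suite asserts is the value the method attains, not a tuned
quantity.

## Numerical and design choices

* Poisson tails via the survival function (regularised incomplete gamma),
  never the literal alternating sum; p-values clipped to
  $[\,\texttt{double.xmin},\,1]$ because $\log p$ feeds $f(C)$.
* $p(u)$ in $f(C)$ is the k-mer's Poisson p-value — the only per-vertex
  probability the pipeline defines.
* All Hamming edges have weight 1 under the distance-below-two rule, so
  the $w^{-1}$ factor is currently unity; the weight is stored and
  inverted anyway so that a wider distance cutoff would need no code
  change.
* Seeds are never evicted during cluster refinement, and removals must
  preserve connectivity: "neighbouring vertices" is only well-defined
  around a connected, seed-anchored cluster.
* Every tie anywhere (ranking, greedy choices, consensus) is broken
  lexicographically; combined with sorted data structures this makes whole
  runs deterministic, which the suite verifies byte-for-byte on MEME and
  BED outputs.
* Sequences containing `N` are kept but windows containing `N` contribute
  to no count, graph, or occurrence; sequences shorter than k contribute
  zero positions (never negative terms).
* For sequence-level classification the per-sequence score is the best
  double-stranded log-odds window score of a PWM (entries floored at
  1e-4), and the decision threshold maximises accuracy on a held-out
  calibration split — declared here because no canonical thresholding
  exists for this task. AUPRC uses step-wise, interpolation-free
  summation, appropriate for imbalanced classes.

## Problem sizes in the test-suite

The suite validates against brute-force oracles at sizes chosen to finish
in minutes on one core while still exercising every code path: all-pairs
Hamming verification on 50 random vertex sets of 20–2000 6-mers,
independent-set exhaustive checks on 100 random graphs of up to 25
vertices, null-model calibration on 2000 motif-free sequences of 200 nt,
and the full pipeline on the 500-sequence reference conditions above.

## Limitations

* Clusters capture only single-substitution neighbourhoods; indel variants
  of a motif are not merged.
* The background is estimated from the input itself, so a very strong,
  very frequent motif raises its own expected count (see the order-2 note
  above); motifs remain discoverable but their p-values are conservative.
* Motif length is bounded by 18 nt and below by k; dimeric motifs with
  long variable spacers will appear as two separate motifs.
* Site precision is deliberately not optimised: every path over
  significant clusters reports its occurrences, and weak paths contribute
  background-level sites. Consumers wanting a short list should take the
  top-ranked paths (output order) or filter by information content.
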