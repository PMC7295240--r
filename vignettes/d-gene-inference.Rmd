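---
title: "Inferring immunoglobulin D genes from CDR3 repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring immunoglobulin D genes from CDR3 repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dminer)
library(dplyr)
```

## The problem

Antibody heavy chains are assembled by V(D)J recombination: a diversity (D)
germline gene is joined between a V and a J gene, its ends are chewed back by
exonucleases, and untemplated nucleotides are inserted at both junctions. The
resulting junction region — the CDR3 — is the most variable part of the
antibody, and almost every CDR3 carries a *truncated* fragment of one D gene
buried between random insertions and V/J fragments.

Reconstructing the germline D genes of an individual (or a species) directly
from a set of CDR3 nucleotide sequences is hard precisely because no read
shows a full, clean copy of the gene: the gene must be stitched back together
from its surviving substrings. Alignment against known germline sets does not
help for unknown alleles or poorly annotated species. `dminer` implements a
probabilistic, alignment-free reconstruction: abundant k-mers are treated as
seeds and grown outwards, one nucleotide at a time, for as long as the
flanking nucleotide distribution looks templated rather than random.

## A trimming model with an exact likelihood

The intuition is formalised by a deliberately simple generative model
(`simple_model()`): a seed string $s$ over alphabet $A$ is trimmed by an
integer $k$ drawn uniformly from $[0, |s|]$ and re-extended by $k$ uniform
random symbols. The probability that $s$ generates a modified string $c$
depends only on the length $m$ of their longest shared prefix:

$$
P(c \mid s) \;=\; \frac{1}{|s|+1}\sum_{k=0}^{m}\frac{1}{|A|^{|s|-k}}
\;=\; K(|s|, |A|)\,\bigl(|A|^{m+1}-1\bigr),
\qquad
K = \frac{1}{(|s|+1)\,|A|^{|s|}\,(|A|-1)} .
$$

Both forms are implemented (`prob_modified_given_seed()`, with
`method = "sum"` as an algebra cross-check), and the test suite verifies that
they agree to $10^{-12}$ and that the distribution normalises exactly.
Maximising the likelihood of a set $C$ of modified strings over candidate
seeds is equivalent to maximising the score

$$
\mathrm{score}(C \mid s) = \sum_i w_i \log\bigl(|A|^{m_i+1}-1\bigr),
$$

implemented in `score_set()`. Natural logarithms are used; any base is a
positive rescaling and leaves the argmax unchanged. Two reconstructions of
the seed are provided: a greedy position-by-position majority vote
(`reconstruct_seed_greedy()`, ties broken alphabetically for determinism) and
an exhaustive argmax over all $|A|^{|s|}$ candidates
(`brute_force_reconstruct()`, ties broken lexicographically). The exhaustive
search is intended purely as a small-instance oracle; it refuses search
spaces above $10^7$ candidates. The greedy algorithm is suboptimal by design
— it is the conceptual template for the seed-extension heuristic that scales
to real repertoires.

## Seed extension with a chi-square stopping rule

Real CDR3s come from *many* D genes, trimmed on both sides and embedded in
V/J context, so the package's workhorse is an iterative bidirectional
extension (`extend_kmer()`):

1. Start from one of the `num_seeds` most abundant k-mers (`select_seeds()`,
   default `k = 10`, short enough not to exceed any known D gene).
2. At each state, tally the occurrence abundances $N_A, N_C, N_G, N_T$ of the
   four single-nucleotide extensions on each side. Under the null hypothesis
   that the flanking position is a uniform random insertion, the expected
   counts are equal and
   $S=\sum_i (N_i-E_i)^2/E_i$ is approximately $\chi^2_3$
   (`extension_test()`).
3. If exactly one side rejects, extend it by its most abundant symbol; if
   both reject, extend the side with the smaller p-value; if both accept,
   stop.
4. After every step, test the *remaining three* extensions of the extended
   side against uniformity ($E=$ remaining total$/3$, $\chi^2_2$). Rejection
   means a second D gene shares the current string: an independent branch is
   forked from the runner-up symbol.

The significance threshold `alpha` defaults to $10^{-30}$: the test is meant
to fire only when one extension vastly dominates, i.e. when the flanking
position is genuinely templated. Extreme statistics are handled in log space
(`pchisq(..., log.p = TRUE)`), so thresholds far below double-precision
underflow remain meaningful. `branch_alpha` defaults to `alpha`; there is no
evidence the two tests need different stringencies. Extension is capped at
`max_len = 50` nt (known D genes top out around 42 nt) and at
`max_branches = 8` live branches per seed — when the cap is hit the
higher-support main path is kept and the result is flagged. Occurrences
abutting the CDR3 boundary contribute to no extension on that side, which is
what eventually starves V- and J-derived seeds of one direction.

Inference is entirely deterministic: only the simulator consumes a random
seed.

## Filtering and consolidation

Extensions are separated into V-, D- and J-derived classes by their mean
relative position (`mean_relative_positions()`): the first-occurrence index
of the extension in each containing CDR3, normalised by the number of
equally long windows, averaged over CDR3s. Since V, D and J fragments appear
in order, the means form three clusters. Clustering is a fixed, deterministic
1-D Lloyd k-means with $k=3$ and initial centroids $0.1/0.5/0.9$
(`classify_by_position()`); the middle cluster is kept as D-like. Empty
clusters retain their centroid, so a repertoire whose surviving extensions
are all central is not artificially split. With fewer than three extensions,
or indistinguishable positions, everything is labelled D and a warning is
raised.

Before classification, extensions that grew in only one direction are
removed (`filter_unidirectional()`): a zero step count on either side is our
operational definition of "unidirectional", and the filter can be disabled
with `keep_unidirectional`. Genuine D genes are flanked by insertions on
both sides and extend both ways; fragments anchored at the CDR3 boundary
cannot.

Redundant reconstructions of one gene are collapsed on a similarity graph
(`similarity_graph()`): the distance between extensions is
$\min(|e_1|,|e_2|) - |\mathrm{LCS}(e_1,e_2)|$ (longest common substring),
with edges at distance $\le$ `max_dist = 2`. Maximal cliques (Bron–Kerbosch,
via igraph) are processed in decreasing size, ties broken by the
lexicographically smallest member, each node consumed at most once; each
clique is replaced by the longest common substring of its members
re-extended under the stopping rule (`merge_cliques()`). A clique whose
common core is shorter than `min_core = 6` nt is left unmerged — a 6 nt
floor keeps unrelated short overlaps from welding distinct genes together.
Candidates from multiple datasets are consolidated by substring removal
followed by the same clique merge without re-extension
(`merge_across_datasets()`).

## Classification against a germline database

`classify_candidate()` labels each candidate `in_db` (equal to a database
sequence, a substring of one, or a substring extended by at most
`extension = 3` nt per end), `novel_variation` (best ungapped-overlap percent
identity above 75%), or `novel_gene`. Identity uses the best ungapped overlap
over all offsets with a min-length denominator: D-gene variants differ by
substitutions and end truncations, not internal indels, and the min-length
denominator penalises neither direction of truncation. Ties between database
entries are resolved by identity, then overlap length, then name.

## Usage, decoys, over-usage, haplotypes

A CDR3 is *traceable* when it contains a unique substring (length $\ge$
`k_min = 8`) of exactly one gene, with no equally long or longer unique
substring of any other gene (`assign_cdr3s()`; the equal-length tie is
deliberately non-traceable, since the defining condition of both genes
fails). Usage is the fraction of traceable CDR3s formed by each gene,
computed over **distinct** CDR3s — multiplicities reflect clonal expansion
and sequencing depth, not recombination frequency. Allele shares apply the
same rule among the alleles of the assigned gene. The multi-pattern
substring scans are delegated to Biostrings (`PDict`/`vwhichPDict`),
processed from the longest unique substring length downwards so each CDR3 is
decided at its longest match.

`add_decoy_alleles()` appends artificial allelic variants (all combinations
of user-given per-site substitutions, minus sequences already present,
labelled `FA*`). Hypermutated reads that would otherwise be forced onto the
few real alleles scatter onto decoys, which is the diagnostic for
SHM-driven allele misassignment; `mutate_sequences()` provides the uniform
substitution noise for such experiments. Somatic hypermutation is treated
throughout as a *confounder*, not a model component — the generative model
itself stays SHM-free.

A gene is *overused* (`detect_overuse()`) when its usage is at least
`factor = 2` times its maximum usage across reference profiles; genes absent
from all references are reported separately rather than given an infinite
ratio. No significance test is attached: with a handful of repertoires per
condition these ratios are descriptive.

`haplotype_v_genes()` phases heterozygous V genes through heterozygous D
genes: V alleles with at least `min_cdr3s = 1000` distinct CDR3s are
retained, each CDR3 is assigned a D gene and allele, and the joint
(V allele × D allele) distinct-CDR3 matrix is row-normalised within each D
gene. Each V allele pairs with its maximum-share D allele; haplotypes follow
by transitivity through the alphabetically first heterozygous D gene, and a
V gene is flagged inconsistent when its alleles collide on the same D allele.

## The simulator and what it does (not) emulate

`simulate_cdr3s()` draws each CDR3 as
`v_l + e_l + trimmed(gene) + e_r + j_r` and keeps full truth labels (gene,
trims, insertion lengths, V/J identity) for recovery experiments. Where the
recombination literature gives no canonical parametric forms, the defaults
were fixed once as plausible study conditions and not revisited:

* trimming `p`, then `q`, from truncated geometric laws $P(t)\propto 0.7^t$
  bounded by the remaining gene length — short chews dominate, long chews
  are rare;
* insertion lengths uniform on 0–6 nt with uniform nucleotides;
* four fixed V suffixes and four J prefixes of 3–8 nt with uniform weights,
  standing in for the conserved CDR3 margins;
* planted genes: uniform random sequences of 12–35 nt
  (`random_d_genes()`), the span of annotated D-gene lengths across
  well-studied species.

The simulator reproduces the structural features the inference relies on —
nested truncated gene fragments, random junctions, shared substrings between
genes when planted — but **not** somatic hypermutation, biased (non-uniform)
insertion composition, sequencing error, clonal lineage structure, or
realistic V/J length and usage distributions. Passing recovery tests on
simulated repertoires therefore demonstrates the correctness of the
machinery under the stated model, not performance on any real repertoire;
conversely the defaults (`alpha = 1e-30`, `k = 10`, `num_seeds = 600`)
were chosen for realistic repertoire scales and carry over to real data
unchanged.

## Numerical and degenerate-input choices

* All hypothesis tests run in log-probability space; `alpha` comparisons use
  `log(alpha)`.
* Zero-count sides are a "no data" outcome: the null is accepted rather than
  producing 0/0.
* Ties are broken deterministically everywhere: alphabetically smallest
  symbol in greedy and extension steps, left side on equal p-values,
  lexicographically smallest string in the exhaustive argmax, clique
  ordering by size then smallest member, consensus ties in favour of the
  group founder.
* Consensus grouping (`build_consensus_cdr3s()`) is greedy and
  founder-centric: sequences in decreasing multiplicity join the first
  group whose founder is equal-length and within Hamming distance
  `max_mismatches`; groups never chain. The consensus is the
  multiplicity-weighted per-position majority.
* Degenerate inputs (empty k-mer tables, empty candidate sets, all-identical
  relative positions, empty databases) return empty results or
  everything-passes defaults with explicit warnings, never errors, so that
  pipelines on unusual repertoires fail soft.

## Problem sizes used in the tests

The recovery experiments in the test suite use repertoires of 15,000–50,000
simulated CDR3s with 1–10 planted genes, 20 replicate seeds for the
end-to-end recovery claim, 10,000 Monte-Carlo draws for the null calibration
of the extension statistic, and 100,000 draws for simulator-law checks —
sizes at which the binomial/chi-square tolerances asserted in the tests are
comfortably above Monte-Carlo noise while a full suite run stays in the
minutes range on a single core.

## Limitations

* The unidirectional-filter definition (zero steps on a side) and the
  re-extension of clique cores are pragmatic interpretations of
  under-specified steps; both are isolated behind flags/arguments.
* The relative-position classifier assumes a tri-modal structure; repertoires
  dominated by a single segment class degrade to "everything is D" (with a
  warning) rather than inventing clusters.
* Percent identity is ungapped; a database variant with an internal indel
  relative to the candidate would be under-scored (a gapped mode is the
  obvious extension).
* `num_seeds` is species-dependent (more genes and alleles need more seeds);
  600 is a human-scale default, 300 suits mouse-scale loci.
* V-allele calls in the haplotyping input are taken as given; this package
  does not call V alleles.
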