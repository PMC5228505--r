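---
title: "Alignment-free transcriptome phylogenetics with usage-deviation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free transcriptome phylogenetics with usage-deviation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oudphylo)
```

## The problem

Inferring phylogenies from de novo assembled transcriptomes by the classical
route — identify orthologs, build and hand-curate multiple sequence
alignments, fit a substitution model — is slow and fragile: assemblies
contain alternative transcripts, fragmented contigs and uneven coverage, and
every added strain forces the alignments to be rebuilt. oudphylo implements
an alignment-free alternative for exactly this setting (its motivating data
are 18 chrysophyte strains spanning phototrophic, mixotrophic and
heterotrophic nutrition): each strain's transcriptome is reduced to a k-mer
composition signature, signatures are compared by Euclidean distance, and a
tree is built by average-linkage clustering. Adding a strain requires only
one new signature and one new row of distances.

## The signature model

For a transcriptome of total length $L$, the observed count $N(z)$ of each
k-mer $z$ (counted in overlapping windows within each transcript, never
across transcript boundaries) is compared with its expectation and
normalized:

$$\mathrm{OUD}(z) = \frac{N(z) - E_1(z)}{E_0(z)},$$

where $E_0(z) = (L-k)/4^k$ is the expectation if all k-mers were equally
frequent, and $E_1(z) = (L-k)\prod_j p(z_j)$ is the expectation under an
i.i.d. mononucleotide model with base frequencies $p(\cdot)$ pooled over the
whole transcriptome. The numerator removes what base composition alone
explains — important for organisms whose GC content correlates with ecology
rather than ancestry — and the denominator puts all $4^k$ components on a
common, length-free scale. The signature is the full vector over the $4^k$
k-mers in lexicographic order ($A<C<G<T$): 256 components at $k=4$, 4,096 at
$k=6$. Two signatures $x, y$ are compared by

$$d(x,y) = \sqrt{\sum_z \left(\mathrm{OUD}_x(z)-\mathrm{OUD}_y(z)\right)^2},$$

and trees are built from the distance matrix by UPGMA, which assumes
clock-like divergence and returns a rooted ultrametric tree.

A first-order Markov null ($E(z) = (L-k)\,p(z_1)\prod_j p(z_j\mid z_{j-1})$,
transitions from pooled dinucleotide counts) is available as
`null = "markov1"`; dinucleotide normalization is known not to improve these
phylogenies, but the variant is kept so the comparison can be reproduced.

Two conventions deserve a note. First, the window factor is the literal
$L-k$ of the formula above, not the true number of countable windows (which
is smaller by $k-1$ per transcript and by N-containing windows); the
discrepancy is $O(\#\text{transcripts}\cdot k/L)$ and the true window count
is recorded in every `kmer_counts` object for diagnostics. Second, counting
is strand-specific by default because assembled mRNA is stranded; a
`canonical` policy (fold each window onto the lexicographically smaller of
itself and its reverse complement) is provided for unstranded inputs.

## Input modes

Signatures can be computed from three reductions of an assembly:

* **all transcripts** — fastest, but genes with many isoforms contribute
  their k-mers once per isoform, over-weighting them;
* **longest ORF per component** (default) — one CDS per Trinity component
  ("gene"), found by a six-frame stop-to-stop scan (the TransDecoder
  long-ORF definition: maximal stop-free codon runs, open at sequence ends,
  terminal stop included; codons containing N break a run; optional
  `require_start` trims to the first ATG). The default minimum of 300 nt
  (100 codons) is the conventional long-ORF threshold;
* **shared-gene ORFs** — as above, restricted to gene/ortholog IDs present
  in every strain of a user-supplied membership table. Ortholog annotation
  itself is out of scope; the IDs come from the user.

Tie-breaks in ORF selection (forward frames before reverse, lower frame
number, leftmost start, then source transcript ID) exist purely to make
output deterministic; the data rarely exercise them.

## Bootstrap support

Support values are obtained by resampling the signature *components*: each
replicate draws $4^k$ column indices with replacement and applies the same
index multiset to every strain's signature, so the resampled columns remain
comparable across strains, then rebuilds distances and the UPGMA tree.
Support of an internal bipartition of the reference tree is the percentage
of replicates containing it (in unrooted canonical form; pendant and root
splits are excluded). The shared-index reading is an interpretation — the
alternative, resampling independently per strain, would compare unrelated
components and make distances meaningless — and is stated here prominently
for that reason. Default 100 replicates; the generator is seeded and the
seed recorded in the run manifest, so supports are bit-reproducible.

UPGMA ties (equal minimal distances) are broken by representing each cluster
by its lexicographically smallest leaf label and choosing the pair whose
(smaller, larger) representative pair sorts first. Reference average-linkage
implementations do not document their tie order; ours is fixed so that
identical inputs give byte-identical Newick on any platform.

## Functional profiling

Three tabular computations accompany the phylogenetics, all driven by a
strain-by-gene membership table:

* **gene-content partition** — a gene is "present in a group" if at least
  one strain of that group carries it (the natural reading when group sizes
  differ; with a single phototrophic strain, requiring *all* strains would
  conflate group-presence with strain-presence); genes in exactly one group
  are group-exclusive, genes in all groups are the core;
* **hypergeometric pathway enrichment** — upper-tail $P(X \ge x)$ for
  drawing $x$ pathway members among $n$ selected genes from a universe of
  $N_u$ genes containing $K$ pathway members; pathway definitions are
  intersected with the detected-gene universe before testing (genes never
  observed in any strain cannot be drawn); Benjamini–Hochberg adjusted
  values are reported alongside. Conventional thresholds differ by use:
  0.001 for gene-content contrasts, 0.1 for expression contrasts;
* **module completeness** — pathway modules are `complete` when at most one
  required enzyme is missing, `partial` when more are missing but the core
  subset is intact, `missing` otherwise; structural complexes are `complete`
  when strictly more than half of their constituent modules are complete,
  `missing` when none is, `partial` otherwise. The exact-half case is
  unassigned by the usual green/blue/red wording ("majority" vs "less than
  half"); we place it in the middle class. "Functional" constituents are
  read as *complete* constituents, the strict reading.

KEGG is never queried: pathway and module definitions are plain TSVs
supplied by the user, keeping the package free of network and licensing
dependencies.

## The simulator

`simulate_transcriptomes()` generates data with known truth so the whole
method can be validated end-to-end: a random coalescent-style ultrametric
tree (leaves at height 0, root at a chosen depth); root genes built as
proper ORFs (ATG, stop-free codons, terminal stop); evolution along each
branch by a Jukes–Cantor-like channel (each site mutates with probability
$1-e^{-\rho\,\ell}$ and takes a uniformly random different base — the
per-edge transition matrix $(1-m)I + \tfrac{m}{3}(J-I)$ composes in closed
form, and `expected_pairwise_divergence()` evaluates the resulting expected
site differences exactly); Trinity-style isoforms as codon-boundary
truncations of the gene, the first isoform always the full gene so the
longest-ORF mode recovers it; optional per-taxon gene loss; optional
per-taxon GC shifts applied at third codon positions only (never creating a
stop), emulating the GC–ecology confounding of the real data.

Defaults are the package's validation conditions, chosen once: 8 taxa, 200
genes of 900 nt, depth 1, substitution rate 0.065 per site per unit height
— which places the mean expected pairwise site difference across random
coalescent topologies at 7.5%, the centre of the moderate 5–10% divergence
band the validation targets — one isoform with probability 0.8 (else 2–3;
real assemblies have mostly single-transcript components), no loss, no GC
shift. Everything is bit-reproducible from one integer seed.

What the simulator does *not* emulate: sequencing error, coverage-dependent
fragmentation, chimeric assembly, indels (an option exists but is off), and
expression-weighted k-mer abundance. Passing the recovery tests therefore
demonstrates correctness of the machinery on clock-like, cleanly assembled
data, not robustness to assembly artefacts.

## What recovery tests can and cannot show

With the validation defaults, the inferred mode-B $k=4$ tree matches the
true topology in roughly three quarters of random seeds, not all of them.
The failures are informative and worth stating plainly:

* coalescent trees regularly contain internal branches shorter than ~1% of
  the tree depth; at the simulated scale (~180 kb of CDS per taxon) the
  Poisson counting noise of the 256 signature components exceeds the
  distance signal such branches generate, so no distance method can resolve
  them reliably. Real transcriptomes are 20–250× larger, which shrinks this
  noise floor accordingly;
* UPGMA additionally assumes the observed distances are clock-like, but
  per-strain sampling noise enters each strain's signature like an unequal
  pendant-edge extension; on a minority of seeds a clock-free method (NJ)
  recovers a topology UPGMA misses. This mirrors the method's known
  sensitivity on real data, where strains can be displaced by composition
  effects rather than ancestry.

The confounding itself can be reproduced: a strong GC shift applied to one
taxon moves it toward GC-similar taxa in the signature tree even when the
true tree places it elsewhere — the same behaviour observed for real
mixotrophic strains whose placement follows GC content. The package treats
this as a documented property of the method, demonstrated in the simulator,
rather than something to be corrected.

## Numerical and format choices

* N50 uses the "smallest length whose ≥-length contigs hold at least half
  the bases" definition with a real-valued, inclusive comparison.
* Retention percentages are half-up rounded to two decimals (base R's
  `round()` is round-half-even and would print 92.395 as 92.39); summary
  mean/median are computed on the rounded per-strain values.
* Sequences are normalized at ingestion: uppercase, U→T, anything else →N;
  N-containing windows are skipped in counting and N bases excluded from
  base frequencies. If a base frequency is zero, the affected expectations
  are zero and so are the corresponding observed counts, so deviations are
  defined (0), never NaN.
* Newick output stores supports as internal node labels and writes branch
  lengths with 10 significant digits so that write/read round-trips preserve
  heights to 1e-9 — the round-trip guarantee was judged worth more than
  compact files.
* Trees are `ape::phylo` objects throughout; distance matrices serialize to
  PHYLIP square format; signatures to two-column TSV with a `#` metadata
  header.
* Validation problem sizes (50 oracle sets of ≤5 kb; 100 random trees of
  4–16 leaves; 20 simulation seeds at the default scale) were chosen as the
  smallest sizes at which each property is convincingly exercised.

## Limitations

The method is a composition heuristic, not a model-based estimator: no
substitution model, no branch-length interpretation beyond signature
distance, no consistency guarantee off the clock. Signatures ignore k-mer
position and expression level. The ORF finder implements only the long-ORF
step — no coding-potential scoring or homology evidence. Hypergeometric
enrichment treats genes as exchangeable and ignores gene length and
detection bias.
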