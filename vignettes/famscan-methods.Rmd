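---
title: "famscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famscan implements a two-track gene-family annotation workflow of the kind
used for the plant MADS-box family: a profile HMM of the defining domain is
searched against both the predicted proteome and the six-frame-translated
genome, candidate loci are extracted in a fixed window, gene models from
the two tracks are merged, and the resulting family is classified and
analysed for duplication patterns against a reference-labeled phylogeny.
This vignette records the models, the parameters that matter, and the
design decisions taken where the workflow leaves choices open.

## The profile HMM

A profile is built from an aligned set of domain exemplars. Columns whose
gap fraction is below `gap_threshold` (default 0.5) become match states;
all other columns are insert columns. For a match column with residue
counts $n_a$ over $n$ observed residues, the emission probability is

$$ e_k(a) = \frac{n_a + w\,q_a}{n + w}, $$

where $q_a$ is the background distribution (the seed's overall residue
frequencies, themselves smoothed with a uniform pseudocount) and $w$ the
`pseudocount_weight` (default 1). Transitions between the match, insert
and delete states of consecutive match positions are estimated from the
seed rows' implied state paths with the analogous rule (uniform prior over
each state's outgoing options). This background-weighted Laplace scheme is
deliberately simpler than Dirichlet-mixture pseudocounts: it is fully
determined by two documented knobs and adequate for a single conserved
domain; both knobs are in the configuration.

Two modelling restrictions are intentional. The architecture is
single-domain local: a path enters at any match state (uniform entry,
$-\log_2 K$ bits), may exit after any match state, and residues outside
the aligned span or in insert states are emitted at background,
contributing 0 bits. The MADS domain occurs once per protein, so a
multi-hit architecture would only add failure modes. There is no
insert-to-delete (or delete-to-insert) edge, the usual simplification of
profile architectures; seed paths that would need one are attributed to
the nearest representable transitions during estimation.

Scoring is in bits. `viterbi_score()` returns the maximum-scoring
alignment and its state path (ties broken Match > Delete > Insert, with
entry considered last, so alignments prefer extension); `forward_score()`
returns the log-sum over the same ensemble and can only exceed the
Viterbi score. Both kernels are written in C++ (Rcpp) because the genome
track scans millions of translated residues; correctness is pinned by an
independent exhaustive path-enumeration oracle over every profile of up to
four match states and every protein of length up to six on a reduced
alphabet, to $10^{-9}$ bits.

## Two thresholds instead of a remote confirmation step

The workflow this package models confirmed candidate domains against an
external conserved-domain database. famscan replaces that with a
two-threshold scheme: a permissive scan threshold (default 10 bits)
recruits candidates, and a stricter confirmation threshold (default 20
bits) must be passed before a model enters the final set. Both are
configuration values. On the bundled synthetic conditions the planted
domains score well above 20 bits and the length-matched decoy ORFs score
far below; 20 random 100-kb contigs produce no confirmed hit.

## Genome track

Each contig is translated in all six frames (exact coordinate maps:
forward frame $f$, peptide position $p$ → $[f+3p, f+3p+3)$; reverse frame
mirrored). Frame peptides are split at stop codons and only stop-free
segments of at least `min_peptide` residues (default 40) are scanned. The
default sits below the 56–60 aa domain so truncated halves remain
detectable, but a domain interrupted by an intron carrying an in-frame
stop can still be missed — the same blind spot as any translated-genome
search; it is kept deliberately, and the external-predictor interface is
the route around it. Same-strand hits from different frames that overlap
are collapsed to the best score (ties to the lowest frame offset, for
determinism).

Around each accepted hit the locus window is 300 bp upstream and
19,700 bp downstream of the domain-box start, measured on the coding
strand; for minus-strand hits the window is mirrored about the
higher-coordinate box end. That convention (rather than measuring on the
plus strand regardless of hit strand) is asserted as this package's
contract and covered by clipping tests. Windows are clipped at contig
boundaries and flagged.

## Gene models and the merge

The built-in caller is intentionally naive: single exon, hit frame
extended 5' to the nearest in-frame ATG after the nearest upstream
in-frame stop and 3' to the first in-frame stop, minimum 60 codons
(roughly the domain length). Anything spliced is out of its scope — the
workflow it mirrors delegated that to trained gene finders, and famscan
does the same through a command-template interface that runs any external
predictor on the extracted locus FASTA and lifts its GFF3 output to
genomic coordinates. A prediction whose protein lacks the domain (below
the confirmation threshold, or with internal stops) is dropped.

Merging treats a genome-track model as redundant when a CDS-track model
on the same contig and strand overlaps it with reciprocal overlap at or
above `min_reciprocal_overlap` (default 0.5, overlap length over each
model's span). The workflow never defined "the same gene" precisely; the
reciprocal-overlap rule is this package's explicit, tested answer. The
manual-inspection checkpoint becomes a machine-readable QC table (track,
partial flag, confirmation score, exon count, protein length).

## Phylogeny without external aligners

Instead of re-aligning hits with an external MSA tool, famscan reads the
alignment off the HMM itself: every hit's Viterbi path places its
match-emitted residues into the K match-state columns (deletions become
gaps, insert residues are dropped). p-distances over shared columns feed
a Saitou–Nei neighbor-joining implementation with two deterministic
refinements: Q-criterion ties are broken by the lexicographically
smallest label pair, and negative branch estimates are clamped to zero
with the deficit moved to the sibling so the pair's summed length is
preserved. NJ was implemented in-package because these two contract
details are load-bearing for reproducibility; `ape::nj` serves as an
independent cross-check in the tests, and NJ on additive matrices
recovers the generating tree exactly (200 random trees, $10^{-9}$).
Externally built trees (e.g. maximum likelihood) can be imported as
Newick and used everywhere a built-in tree can.

Rooting uses `phangorn::midpoint` (an explicit outgroup list overrides
it); the degenerate all-zero-branch-length tree is rooted at the first
tip in label order with a warning.

## Reference-anchored classification

Classification ascends from each unlabeled leaf toward the root and stops
at the first ancestor clade containing reference leaves: a unanimous
label is transferred, disagreement yields "unclassified", and the clade
size and reference count are reported as support. One refinement proved
necessary: the root clade is never accepted as support. The root contains
every leaf, so "the first reference-containing ancestor is the root"
means the query never clustered with any reference — transferring a label
there would, for example, assign Type I to every Type II gene the moment
all Type II references are removed. With the root excluded, that ablation
leaves them unclassified, which is the behaviour a curator would expect.

Types are assigned on a joint tree, then groups on per-type trees
(references classified to their own labels; stage-1 unclassified genes
are excluded from stage 2). A stage with fewer than three leaves cannot
build a tree and falls back to direct transfer when its references agree.

## Duplication statistics

Maximal species-specific clades (monospecific clades whose parent is not
monospecific) partition each species' leaves; their size histogram is
binned as ≥10, 9…5, and "other", the layout expansion tables usually use.
Lineage-specific duplications are counted as monospecific internal nodes,
which for binary trees equals $\sum(\text{size}-1)$ over that species'
maximal clades — both identities are cross-checked against a brute-force
per-node oracle on 200 random labeled trees. Duplicate pairs are cherries
(sibling leaf pairs) within maximal clades, because a cherry corresponds
to one duplication event; an all-pairs mode exists behind a flag for
exploration. A pair is tandem at gene-rank gap 1, proximal at gap 2
through `proximal_max_gap` (default 10, a named knob), distal otherwise
including different chromosomes. Ranks derive from gene start order per
chromosome across the full gene complement supplied.

Multifurcating input trees are resolved deterministically
(`ape::multi2di(random = FALSE)`, with a message) before counting.

## The synthetic generator and what passing tests mean

The generator is first-class, seeded code. Its defaults are the package's
study conditions:

* seed alignment: 12 exemplars × 57 aa at 0.15 divergence, plus 2
  low-occupancy insert columns;
* family: 30 focal genes (8/5/7 in Mα/Mβ/Mγ, 7/3 in MIKC^C/MIKC*,
  mirroring the Type-I-heavy expansions such families show) and 3
  reference genes per group in a second species;
* divergence ladder: type ancestors at 0.20 from the root domain, group
  ancestors at 0.10 from their type, and each gene's domain drawn at 0.05
  around its lineage founder. The draw is anchored to the founder rather
  than compounding along the genealogy: the domain is modelled as under
  purifying selection, which both matches the biology of a "highly
  conserved" domain and keeps every gene detectable by design rather than
  by luck;
* genome: 5 × 400 kb contigs at GC 0.36, 60 decoy ORFs length-matched to
  the family, intergenic gaps of 0.5–3 kb, 30% of family genes withheld
  from the CDS track and annotation;
* duplication classes drawn as tandem/proximal/distal = 0.2/0.2/0.6;
  cherry pairs are laid out so their recorded class is realised in gene
  ranks (tandem adjacent, proximal at rank gap 3 with decoy spacers,
  distal on different contigs when more than one exists).

Everything is byte-reproducible under a fixed seed, and the manifest is
consistent with the emitted FASTA/GFF3 (extracting and translating each
manifest CDS reproduces the emitted protein — a tested invariant).

What the generator does *not* emulate bounds what green tests mean:
single-exon genes only, uniform substitution (no PAM/BLOSUM weighting,
no indels inside the domain), no introns, no repeats or transposons, no
codon-usage structure. Passing tests demonstrate that the pipeline's
mechanics — detection, coordinate arithmetic, merging, classification,
counting — are correct under realistic signal-to-noise; they say nothing
about spliced-gene recovery, which is delegated to external predictors.

## Numerical and determinism notes

Coordinates are 0-based half-open internally; GFF3 emission converts at
the boundary. All probability invariants are enforced at $10^{-9}$;
serialised profiles are renormalised on load because the text format
carries six decimals. DP works in log2 space with a numerically safe
log-sum-exp. Every string ordering uses radix (locale-independent) sort.
Problem sizes in the test suite (2-Mb assembly for the end-to-end check,
200-replicate tree oracles, exhaustive DP enumeration at K ≤ 4, length
≤ 6 over a three-letter alphabet) were chosen so the whole suite runs in
minutes on a single core while still covering every contract at full
study scale.

## Known limitations

* Genome-track search misses domains split by in-frame-stop-carrying
  introns (by construction; see above).
* The naive caller requires an ATG between the upstream stop and the hit;
  loci without one produce no built-in model (the external-predictor
  route still applies).
* Classification quality degrades with reference sparsity: a group
  without references can only come out unclassified.
* E-values are not computed; scores are bits against the seed-derived
  background, and thresholds are calibrated operationally (two-threshold
  scheme), not probabilistically.
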