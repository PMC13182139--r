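---
title: "Polarized quartet support, homoplasy filtering and clade-supertree ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarized quartet support, homoplasy filtering and clade-supertree ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetpol)
```

## Scope and model

`quartetpol` quantifies phylogenetic signal for alternative rooted
relationships among *predefined clades* rather than estimating a global
tree. The unit of inference is the polarized species-quartet: one species
from each of three ingroup clades plus one outgroup species. With the
outgroup state taken as plesiomorphic, the three rooted topologies of a
quartet are distinguishable by strict synapomorphies — site patterns in
which the grouped pair shares a derived state while the remaining ingroup
taxon retains the outgroup state. Exactly 12 of the 256 nucleotide quartet
patterns support each topology, and the three support classes are mutually
exclusive by construction.

The central statistic contrasts observed synapomorphic counts with their
expectation under convergence. For topology x,

- `Na(x)` counts x-supporting columns among the *usable* columns of the
  quartet subalignment (all four characters unambiguous nucleotides; gaps
  and IUPAC ambiguity codes make a column unusable — ambiguity is treated
  as missing, not as partial information, because fabricating fractional
  signal from ambiguity codes has no principled weighting here);
- `Nc(x)` is the expected number of x-supporting columns if x is *false*:
  GTR+Γ+I models are fitted by maximum likelihood to the same subalignment
  under each rival topology y ≠ x, the exact probability of the
  x-supporting pattern class is computed under each fitted rival by
  summing pruning-algorithm pattern probabilities over the class, and the
  two expectations are averaged and scaled by the usable-column count.
  Averaging avoids an arbitrary choice of rival; `risk_mode = "max"`
  substitutes the more pessimistic rival for users who prefer a
  conservative convergence correction.

Raw support is `S(x) = Na(x) − Nc(x)`. Negative values are clamped to zero
before normalization — the signal criterion is that synapomorphies must
*exceed* their convergent expectation, so a deficit carries no directional
information — and the clamped supports are normalized to `s(x)` in [0, 1]
summing to one. A quartet in which no topology attains positive raw
support is *uninformative* and takes no further part.

This design assumes site independence, a homogeneous (if flexibly
parameterized) substitution process within each quartet subalignment, and
meaningful polarization — i.e. the outgroup truly attaches outside the
three ingroup clades. It deliberately does not model within-clade
phylogeny: clade assignments are inputs.

## Model fitting

Each quartet/topology pair is fitted by maximizing the GTR+Γ+I likelihood
over 15 free parameters: five branch lengths of the unrooted quartet tree,
five exchangeabilities (GT fixed at 1), three free base frequencies, the
gamma shape α and the invariable proportion p_inv. Likelihoods are
computed over the 256-pattern space (site patterns are tabulated once per
quartet, so cost is independent of alignment length) with four
discrete-gamma categories plus an invariant class. The gamma
discretization is mean-of-category with rates rescaled by 1/(1 − p_inv),
the convention shared by the standard likelihood implementations; this
choice lets the package's engine be verified *exactly* against an
independent pruning implementation in the test suite. Because the model is
time-reversible, root placement does not affect the likelihood; polarity
enters only through pattern classification.

Numerical choices:

- initialization: α = 1, p_inv = 0.3, empirical base frequencies with a
  one-count prior, equal exchangeabilities, terminal branch lengths from
  observed pairwise differences and a short (0.05) internal branch;
- optimizer: L-BFGS-B on log/logit-transformed parameters bounded to ±9 on
  the transformed scale, with jittered restarts on non-convergence; the
  optimized log-likelihood is always at least the initial one;
- the inner objective is a compiled (Rcpp) mirror of the R-level engine,
  tested to agree to 1e-12; pattern probabilities sum to 1 within 1e-8;
- degenerate inputs: an all-constant subalignment is refused with
  instructions to mark the quartet uninformative; all-zero branch lengths
  give probability mass only to constant patterns and hence zero to every
  support class.

The default fitting control (`maxit = 60`, `factr = 1e10`, one restart)
favors throughput across hundreds of quartets; parameter-recovery tests
use tighter settings (`maxit = 400`, `factr = 1e7`) and recover simulated
α and p_inv within 15 % relative error at 10^5 sites.

## Filtering

Per species-quartet, `SD12 = s(best) − s(second)` measures decisiveness
and `RISK = Nc(best)/Na(best)` measures how much of the best topology's
apparent support is expected convergence. A quartet is retained only if
`SD12 ≥ L_DIST` **and** `RISK ≤ L_RISK` (both bounds inclusive); rejected
quartets are dropped entirely — the second-best topology never substitutes
for the best. Ties for the best topology are broken canonically
(x1 < x2 < x3) and flagged.

Thresholds are optimized per clade-quartet by grid search over the deciles
of the observed SD12 and RISK distributions plus the endpoints 0 and 1.
The objective is the margin between the best and second-best per-topology
medians over the retained set, multiplied by the square root of the
retained fraction — decisiveness discounted by data loss — subject to at
least one retained quartet; ties prefer the larger retained set, then the
smaller thresholds. One reporting convention matters: for an informative
quartet RISK < 1 always holds (the best topology has positive clamped
support, so Na > Nc), which means a RISK threshold that excludes nothing
is not unique. Such thresholds are reported as their canonical
representative 1 — the retained set is unchanged, and clade-quartets whose
signal is convergence-dominated surface visibly as `L_RISK = 1`. The
threshold-optimization objective itself is a documented package choice:
only its behavioral properties (balanced retention; thresholds able to
reach exactly 1; near-tie removal) are pinned by tests, not its exact
functional form.

## Supertree ranking

Retained normalized supports are aggregated per clade-quartet by the
per-topology *median* (robust to outlier quartets; an even count takes the
mean of the middle two). Medians are deliberately not re-normalized —
their sum already encodes how internally conflicted a clade-quartet is,
and re-normalizing would erase that. Every rooted binary tree on the
ingroup clades is then enumerated (recursive leaf insertion, (2n−3)!!
trees, guarded to 2–8 clades), and each candidate is scored by summing,
over non-empty clade-quartet summaries, the median support of the quartet
topology the tree *induces* on that triplet. For complete clade-quartet
coverage of a binary candidate this induced-topology criterion selects
exactly the maximal compatible quartet set, so the simpler formulation is
used and verified against an independent scorer built on subtree
restriction. Clade-quartets with empty retained sets are excluded from
every candidate's sum equally, preserving rank comparability; exact score
ties are broken by canonical newick order and flagged. Externally supplied
trees (e.g. maximum-likelihood or published species trees) can be scored
and placed within the same ranking.

## The simulator

The synthetic-data module generates supermatrices with the statistical
structure the analysis assumes: a rooted clade tree with
internode lengths in *coalescent units* controls incomplete lineage
sorting; per-clade rate scalars on terminal branches control long-branch
pressure independently; sequences evolve under GTR+Γ+I along
multispecies-coalescent gene trees sampled per locus (k lineages coalesce
at rate k(k−1)/2 per unit within each species-tree branch). Coalescent
lengths convert to substitutions via `mu` (default 0.02 subs/site/unit,
chosen so that preset terminal branches span roughly 0.05–0.6
substitutions/site, the range where homoplasy is material but signal
survives). One individual is sampled per species; species within a clade
hang off a shallow caterpillar because within-clade phylogeny is out of
scope. Three presets share the packaged palaeognath clade sizes (E 2, K 4,
R 2, S 1, T 5, outgroup O 1) on the tinamou-first truth tree
`(O,(S,(T,(E,(K,R)))))`:

- `strong_signal`: 2-unit internodes (discordance ≈ 9 % per internode) —
  clean recovery regime;
- `lba`: 0.1-unit internodes plus 5× rate scalars on the O, T and R
  stems — heavy discordance with long-branch attraction pressure;
- `polytomy`: 0.01-unit internodes — near-anomaly-zone, three-way
  conflict.

Gene-tree concordance is validated against the closed form
P(concordant) = 1 − (2/3)·e^(−T). What the simulator does *not* emulate:
indels and alignment error (gaps arise only from missing-taxon padding),
within-locus recombination, introgression, base-composition
heterogeneity across lineages, and among-locus model heterogeneity.
Passing tests therefore demonstrate correctness of the inference machinery
under the stated generative model, not robustness to every artifact of
real genomic alignments.

## Defaults that matter

| parameter | default | rationale |
|---|---|---|
| `min_cols` | 20 | smallest informative-column count at which the three-way normalization is stable; inclusive bound; genome-scale quartets clear it easily |
| `risk_mode` | `"mean"` | symmetric treatment of the two rival topologies |
| gamma categories | 4 | standard discretization granularity |
| α, p_inv init | 1, 0.3 | conventional starting point for deep-divergence nuclear data |
| `mu` | 0.02 | see simulator section |
| threshold grid | deciles + {0, 1} | scale-free, data-adaptive candidate set |

## Problem sizes in the test suite

Unit tests run on matrices up to 20 × 200 (brute-force cross-checks),
quartet fits at 10^4–10^5 sites (parameter recovery), and full pipeline
runs on 6 × 150 bp loci. The acceptance-level tests run the full pipeline
at 100 loci × 500 bp — five replicate seeds for generating-tree recovery
under `strong_signal`, one seed each for the `polytomy` and `lba`
behavioral checks — and validate the convergence-expectation engine by
Monte-Carlo on twenty random models at 2 × 10^4 sites each.

## Known limitations

- Clade assignments are trusted inputs; a mis-assigned species corrupts
  every quartet it joins.
- The Nc estimator is a reconstruction: "patterns supporting x when x is
  false, averaged over rivals" is one defensible operationalization of
  convergent expectation, pinned by Monte-Carlo oracle tests; other
  conventions (rival-max is provided; mixture weighting is not) would
  shift RISK values somewhat.
- Exhaustive tree ranking is limited to 8 ingroup clades by design;
  beyond that the method's non-heuristic guarantee would be lost anyway.
- Quartet model fits assume a single substitution process per quartet;
  strong among-locus heterogeneity is averaged over, which can inflate
  p_inv and α estimates.
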