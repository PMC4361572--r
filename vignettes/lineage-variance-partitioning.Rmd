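---
title: "Partitioning p-distance variance along a taxonomic lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning p-distance variance along a taxonomic lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clanvar)
```

## The question the method answers

Protein families such as the bacterial export chaperone SecB are sampled
across thousands of organisms with a known taxonomic lineage (kingdom →
phylum → class → order → family → genus → organism). Two forces shape
such a family: vertical descent, in which divergence accumulates along
the taxonomy so that sequences are most similar to members of their own
clan, and horizontal transfer, which moves sequences across clan
boundaries and leaves them more similar to distant taxa than the
taxonomy predicts. `clanvar` quantifies the balance between the two at
every *bifurcation* of the lineage — every taxon whose children at the
next rank split the sequences into two or more clans — by decomposing
the variance of pairwise p-distances into an inter-clan and an
intra-clan component.

## The model

### Distances

For two aligned amino-acid sequences the **p-distance** is the
proportion of differing sites among compared sites. Under the default
*pairwise deletion* a column is compared when both symbols are standard
residues; gaps and `X` ambiguity codes are excluded pair by pair.
*Complete deletion* (drop every column that has a gap in any sequence)
is available as a flag for sensitivity analysis. Pairwise deletion is
the default because length variation in a large alignment (internal
indels, trimmed termini) would otherwise discard most columns for all
pairs. Distances are uncorrected by design: no Poisson or matrix-based
correction is applied, so values are bounded in [0, 1] and saturate near
1 − 1/20 for unrelated sequences.

Per-taxon summaries (the per-rank distance report) use one observation
per sequence: its mean distance to the other members of its taxon. The
alternative all-pairs unit is available; every report names the unit
used. The per-sequence unit is the default because group sizes in this
kind of study are reported as sequence counts, and the global average is
defined as the mean over each sequence's mean distance to all others.

### The variance decomposition

At a parent taxon with clans \(i = 1..k\) (children at the next rank),
each member sequence \(j\) contributes the observation

\[ y_{ij} = \text{mean p-distance of } j \text{ to all other members of
the parent taxon} \]

(the *parent-wide* unit; a *within-clan* unit restricted to clan members
is available by flag). Because clans are a random sample of evolutionary
outcomes rather than fixed treatments, the one-way **model II (random
effects) ANOVA** applies. With \(n_i\) observations per clan,
\(N = \sum n_i\):

\[ MS_A = \frac{\sum_i n_i(\bar y_i - \bar y)^2}{k - 1}, \qquad
   MS_W = \frac{\sum_{ij} (y_{ij} - \bar y_i)^2}{N - k}, \qquad
   n_0 = \frac{N - \sum_i n_i^2 / N}{k - 1} \]

\[ \hat\sigma^2_A = \max\!\left(0, \frac{MS_A - MS_W}{n_0}\right),
   \qquad \hat\sigma^2_W = MS_W \]

and the reported quantities are
\(\mathrm{pct_{inter}} = 100\,\hat\sigma^2_A / (\hat\sigma^2_A +
\hat\sigma^2_W)\) and \(\mathrm{pct_{intra}} = 100 - \mathrm{pct_{inter}}\),
which always sum to 100. \(n_0\) is the effective group size for
unbalanced designs; for balanced designs it equals the common \(n_i\)
exactly. Negative among-clan estimates are truncated at zero and flagged
`truncated`, so a reported 0% inter-clan variance is distinguishable
from a genuinely homogeneous parent; zero total variance is flagged
`degenerate`. Parents with a single child clan, or with no within-group
degrees of freedom, are retained in the output with a reason — they are
data, not errors, because in real lineages many taxa have a single
sampled child.

```{r}
model2Anova(list(A = c(0.1, 0.2), B = c(0.5, 0.6, 0.7)))
```

A large inter-clan share means divergence is structured by the taxonomy
(vertical descent); a large intra-clan share at a bifurcation where
clans should differ is the statistical signature expected from
horizontal transfer.

### What the decomposition can and cannot see

An identifiability limit that users should understand: with the
parent-wide unit, the observation of every member of a clan of size
\(n_i\) has expectation \(\big((n_i - 1)\,\bar w + (N - n_i)\,\bar
b\big)/(N - 1)\), where \(\bar w\) and \(\bar b\) are the expected
within- and between-clan distances. If all clans have the **same size**,
that expectation is identical across clans no matter how divergent they
are, and the expected inter-clan variance component is zero. The
between-clan signal enters only through the product of clan-size
asymmetry and divergence contrast \((\bar b - \bar w)\). Real taxonomic
samples are strongly unbalanced (thousands of sequences in one phylum,
dozens in another), which is why the method is informative in practice —
but a balanced design is a blind spot, and simulations confirm that
balanced clans yield essentially random partitions. Consequently the
package's own tests assert *directional* properties (raising clan-level
divergence raises `pct_inter`; injecting cross-clan transfer lowers it;
near-zero within-clan divergence drives it above 95%) rather than a
universal "inter-clan dominates everywhere" claim, which is not a
theorem of this design even under pure vertical descent.

A second limit is estimator precision: the among-clan variance estimate
carries a relative sampling error of about \(\sqrt{2/(k-1)}\). With
\(k = 20\) clans that is ±32%, so `pct_inter` near 50% has a standard
error of roughly 8 points, while values near 0% or 100% — the regime
reported for strongly transferred or strongly vertical genera — are
pinned down tightly. The parameter-recovery check in the test suite
therefore uses the worked example's components
(\(\sigma^2_A = 0.0978\), \(\sigma^2_W = 0.0083\), true share 92.1%),
where ±5-point recovery is achievable; mid-range truths cannot be
recovered to ±5 points at \(k = 20\) by any estimator of this family.

## Trees

The distance matrix also feeds a classic **neighbor-joining** tree:
iteratively join the pair minimising
\(Q(i,j) = (r-2)\,d(i,j) - R_i - R_j\), with pendant branches
\(d(i,j)/2 \pm (R_i - R_j)/(2(r-2))\) and reduced distances
\((d(i,k) + d(j,k) - d(i,j))/2\). Ties are broken by the
lexicographically smallest pair in current label order, making trees
bit-reproducible across platforms. Negative branch estimates are clamped
to zero by default (raw values available via `negativeBranchPolicy =
"keep"`). On additive matrices the implementation recovers the
generating topology exactly and path lengths to machine precision; the
test suite verifies this on random trees and cross-checks topologies
against `ape::nj`.

Bootstrap clade support resamples alignment columns with replacement;
replicate *r* draws from a substream derived from `(seed, r)`, so
partial re-runs agree and supports are reproducible. Support is the
percentage of replicates containing the same bipartition as each
internal edge of the point-estimate tree.

`countBifurcations()` reports the number of internal nodes on the
root-to-leaf path — a proxy for evolutionary steps that depends entirely
on the display rooting, which is therefore an explicit parameter
(midpoint by default, or the tree's own basal node). Counts from
differently rooted renderings of the same tree are not comparable, which
is why the package always reports the rooting policy alongside the
count.

## The synthetic generator

Because study-scale datasets cannot be redistributed, every stage is
validated against `simulateDataset()`: a rank-structured guide tree
(configurable, ragged fan-outs at each rank), a uniform random root
sequence of `L` columns, and on each branch at rank transition *r* an
independent per-site substitution with probability `m[r]`, uniformly to
one of the 19 other residues. This symmetric 20-state model is chosen
because it admits an exact closed form for the expected p-distance along
a path with branch probabilities \(m_1..m_B\):

\[ \mathbb{E}[p] = 1 - \left[\tfrac{1}{20} + \tfrac{19}{20}
   \prod_b \left(1 - \tfrac{20\,m_b}{19}\right)\right] \]

which the package exposes as `expectedPDistance()` and the tests use as
the analytic oracle tying the simulator to the distance machinery
(single-branch sanity: \(\mathbb{E}[p] = m\)).

Defaults are chosen once to emulate the study conditions: alignment
width `L = 170` (the scale of a chaperone-family alignment), ragged
fan-outs (phylum 2–4, lower ranks 1–3, 1–3 sequences per organism)
giving unequal clan sizes as in real samples, and per-rank substitution
probabilities decreasing toward the leaves (0.15 at phylum down to 0.01
on the terminal branch) — a vertical-descent regime in which close
relatives are much more similar than distant ones. Sequences are
generated aligned and gap-free: indels are deliberately outside the
statistical model because p-distance under pairwise deletion ignores
them, and excluding them keeps the analytic oracle exact. Uniform
residue frequencies and a symmetric substitution matrix are likewise
what make the closed form available; empirical amino-acid models are
out of scope. What passing tests therefore show is that the estimator
and pipeline behave correctly under a clean substitution process — they
do not certify behaviour under alignment error, compositional bias or
rate heterogeneity, which real data have.

Randomness flows from one master seed through named substreams (tree
topology, root sequence, one stream per branch, transfer events), so
enabling transfer events does not perturb the base sequences and any
component can be re-drawn independently.

`injectHgt()` emulates horizontal transfer: each leaf, with probability
`hgtRate`, has its sequence replaced by a copy of a donor from a
different clan at the crossing rank, re-mutated along one terminal
branch. Lineage labels are never changed — the sequence moves, the
taxonomy does not, which is precisely the signature the variance
partition detects: at `hgtRate = 0.5` crossing at genus level the median
genus `pct_inter` collapses from roughly 70 to 0 in the packaged tests.

Two further synthetic stand-ins support study-scale validation without
external data. `simulateStudyTable()` builds a 5162-record dataset with
the bookkeeping structure of the published sample (21 fragments, 1
archaeal + 3 eukaryotic records, 1324 incomplete lineages, and 3813
complete bacterial records covering exactly 4 phyla, 11 classes, 41
orders, 82 families, 269 genera and 3744 organisms, Zipf-skewed clan
sizes, ungapped lengths around 157 ± 27), so the filter → bind →
summarize chain can be exercised end to end; the counts are recomputed
by the pipeline, not read back from the configuration.
`workedPairAlignment()` is a synthetic 169-column pairwise alignment of
two sequences of 155 and 161 ungapped residues with 82 identical
columns, exercising the percent-identity convention (identical columns
over *total alignment columns*, gap columns counting in the denominator
only) on a pair with a realistic internal-indel structure; it is not
real protein data.

## Numerical and policy choices

* **Full-path taxon keys.** A genus name reused under two families is
  counted and grouped separately; all distinct-taxon counts and clan
  groupings use the full path from kingdom down, preventing silent
  merging.
* **`X` ambiguity codes** are excluded from compared sites, like gaps:
  p-distance counts confident differences only. The `strict` alphabet
  policy rejects them at read time.
* **Undefined distances** (zero comparable sites for a pair) are an
  error by default, or `NA` entries under the permissive flag; they are
  never silently zero.
* **Deterministic output.** Report TSVs format numbers to six decimals,
  Newick branch lengths to six decimals, and the run log carries no
  timestamps, so a given config and seed yields a byte-identical report
  bundle — verified in the tests on a ~200-sequence dataset with 100
  bootstrap replicates.
* **Problem sizes.** The packaged checks run at desk scale by choice:
  distance-oracle sweeps at ≤10 sequences × ≤50 columns, NJ consistency
  at ≤12 taxa, the pipeline determinism audit at ~200 sequences × 170
  columns with 100 bootstrap replicates, Monte-Carlo calibration on
  20 000-column pairs. Study-scale runs (thousands of sequences, 1000
  replicates) use the same code paths through `pipelineConfig()`.

## Known limitations

* The variance partition interprets, but cannot prove, transfer:
  elevated intra-clan variance is consistent with HGT but also with
  rate heterogeneity or misassigned taxonomy. Formal HGT inference
  (quartet mapping, reconciliation) is out of scope.
* The F statistic for the among-clan term is available from the mean
  squares but deliberately not interpreted; with per-sequence means as
  observations the independence assumptions behind its null distribution
  do not hold.
* Bifurcation counts depend on the rooting of a displayed tree and are
  reported only alongside their rooting policy; they are not comparable
  across rooting conventions.
* The lineage table is trusted as ground truth; no validation against
  an external taxonomy service is attempted.
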