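---
title: "Motif-based specificity scoring of phage-display selection pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based specificity scoring of phage-display selection pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemotifs)
```

## The model

A synthetic Fab library diversifies four CDR loops on one fixed
framework. Two of them are nearly binary: H1 carries six and H2 eight
two-codon degenerate positions, for 64 and 256 unique sequences. The
other two carry the library's real diversity: L3 (3–7 codons) and H3
(1–17 codons) draw every position from nine codons encoding nine amino
acids, for theoretical diversities of order 10^9 and 10^16. A *paratope*
is the 4-tuple of CDR amino-acid sequences; a *selection pool* is the
multiset of paratopes observed in one selection arm with read counts.

The central premise: a clone that genuinely binds the target shares
linear sequence information — consensus motifs — with the many related
binders that selection co-enriched in the positive pool, whereas a
non-binder does not. Selectivity is therefore a property of a clone's
*motif neighbourhood*, not of its own read count, which is what lets the
method recover clones at frequencies down to 10^-6 that enrichment
ranking cannot see.

### Scoring procedure

For a candidate paratope, every wildcard pattern of its CDR strings is
enumerated (ascending wildcard count, then lexicographic wildcard
position sets — deterministic order), subject to three constraints:

* at most `floor(0.55 * L)` wildcards in a length-L motif (at L = 1 this
  forbids wildcards entirely);
* at least `min_positive_support` unique positive-pool sequences of the
  same length matching the motif (default 100);
* every wildcard matching more than one distinct residue among those
  positive matches — a wildcard that only ever matches one residue is an
  uninformative relabeling of a fixed position.

Each admissible motif contributes one frequency per pool: matching
unique sequences over total unique sequences (reads do not enter;
the parenthetical definition of frequency in the method is explicit on
this point, and a read-weighted variant would be dominated by the
handful of most abundant clones). Matching is same-length only: the
library realises loop lengths as discrete design choices, and a gapped
match would not correspond to any designed molecule.

The two frequency vectors are pooled, midranked (ties averaged), split
back, and compared with the Welch t statistic and Welch–Satterthwaite
degrees of freedom; the rank transform absorbs the severe non-normality
of motif frequencies while the Welch form tolerates unequal variances.
Cohen's d is computed on the same ranks, since the effect-size formula
reuses the rank-sample symbols. A clone is *specific* when
log10 p < −10 and d > 2; a clone with fewer than two admissible motifs,
or with zero rank variance, is *unscorable* — the statistic is undefined
on such samples and reporting p = 1 would silently blend two different
kinds of negative result.

### Which CDRs feed the profile

The candidate profile pools motifs from L3 and H3 by default
(`motif_constraints(cdrs_used = )` accepts all four). This was a
genuinely open design choice, and the package's simulations decided it:
H1/H2 have so little diversity (64/256 variants) that *every* H1/H2
motif is abundant in *any* pool, so their frequencies track overall pool
composition rather than clone-specific enrichment. Including them (i)
dilutes the separation of true binders — their profile fills up with
near-tied background motifs, capping the achievable effect size well
below the d > 2 decision bound — and (ii) couples the scores of
unrelated clones to pool-level composition shifts, which in simulation
produced sub-10^-10 p values for clones with no planted signal. L3/H3
motifs have neither pathology: their background match rates are tiny
(each defined position costs a factor ~9), so admissible L3/H3 motifs
exist only where a real sequence neighbourhood supports them.

### Tail direction and extreme p values

The upper tail P(T_f ≥ t) is used: positive separation of the positive
pool over the negative yields positive t, and the decision rule demands
that *smaller* p mean *stronger* separation. (Written as a lower-tail
integral the rule would invert; the package treats that as the intended
reading and documents it here.) Published scores reach p ≈ 2e-303, the
edge of double precision, so `t_tail_p()` also returns log10 p computed
via the log-space path of the regularized incomplete beta function;
log10 p is the authoritative thresholding quantity and stays finite and
accurate after p itself underflows. The quadrature oracle in the test
suite integrates the t density directly (log-Gamma normalization) and
agrees to 1e-10 where p > 1e-300.

## The chimera filter

PCR template switching at the fixed framework produces amalgams pairing
the L3 of one clone with the H3 cassette of another; they surface as
plausible-looking novel clones and, at a 10% chimera rate, multiply the
apparent unique-clone count more than twentyfold. Because valid L3/H3
pairs are overrepresented relative to artifacts, the filter conditions
on each H3 and examines the counts of its L3 partners: the sorted counts
are split into two contiguous classes at the boundary maximizing
between-class inertia (by the Koenig–Huygens decomposition this
minimizes within-class inertia; the identity is verified to 1e-9 in the
tests), and every pair strictly below the arithmetic midpoint of the
adjacent values across the split is removed.

Numerical conventions, chosen for determinism and safety:

* ties in the criterion resolve to the lowest split point;
* fewer than two partners, or all counts equal, yields no cutoff — no
  evidence of chimerism, keep everything;
* removal is strict (<), so a pair at its H3's maximum count is never
  removed (monotone safety, a tested invariant);
* partner counts are read-weighted by default (artifacts are read-level
  events); `weight = "unique"` counts paratopes instead;
* only the H3-conditioned pass runs by default, matching the described
  procedure; `symmetric = TRUE` adds the mirrored L3-conditioned pass.

The filter is deliberately not model-based: it has one implicit
parameter (the split criterion) and is idempotent on its own output.
Its known failure mode is a *rare* valid clone (one or two reads) whose
H3 attracts a chimeric partner with more reads than the clone itself;
the split then removes the valid pair. In the reference simulation this
affects at most ~1 clone in 5,000 and usually none, but on real pools it
contributes to the large fraction of removed singleton clones.

## The simulator

`simulation_config()` defaults define the reference conditions:
7e6 reads per pool; four specific families of 200 close homologs; a
log-uniform background abundance law over 1e-7..0.3 shared between pools
with log-normal noise (SD 0.5) — reproducing both enrichment-scatter
tails (specific clones upper-right, abundant-in-both lower-right); a
1e4-fold positive enrichment of specific clones, so nearly all family
members have zero negative-pool observations (the "INF" clones of
published tables); one family pinned at an immunodominant 0.3 frequency;
one member per family pinned at 1e-6 (about 7 expected reads at this
depth); and a 10% chimera rate.

Family structure is the load-bearing choice. Each family is a head clone
plus members that share its L3, H1, H2 and the seven fixed (planted)
positions of a 14-residue H3, differ at 1–2 of the seven free H3
positions (each member's H3 distinct), and mutate one L3 position with
probability 0.3. Consequences, each aimed at a property of real
selections:

* every member lies within 3 edits of the head over the 19-residue L3+H3
  string, i.e. above 80% identity — a family is one single-linkage
  cluster, as homolog families are in real data;
* family motifs (patterns fixing the planted positions) are matched by
  100+ members, clearing the support floor the way a real binder's
  sequence neighbourhood does;
* distinct member H3s give every valid H3 a single dominant L3 partner,
  the regime in which the pair filter can remove artifacts without
  touching true clones. Real pools do contain distinct clones sharing an
  H3, and there the filter's removal of rare valid pairs is part of its
  documented behaviour.

Chimera injection converts a binomial fraction of reads into
recombinants (L3 from one abundance-sampled clone, H1/H2/H3 cassette
from another), conserving total reads; a recombinant that reconstitutes
an existing paratope merges into it. Read emission lays the amplicon out
over three reads with the design's framework anchors, barcodes, Phred
labels, per-base substitution errors, and deliberate double-coverage
overhangs at the junctions so that assembly can detect inconsistent
overlaps. All randomness flows from one seed through named substreams,
so each stage is independently reproducible.

What the generator does *not* emulate: selection-round dynamics, display
or amplification bias, position-dependent error profiles, indels, and —
importantly — the selection-shaped skew of real positive-pool
composition, in which even background unique sequences are biased toward
binder-like features. Passing tests therefore demonstrate correct
recovery under an idealized pool structure, not performance on any real
selection.

## Null calibration

The type-I error check simulates both pools from one clone-frequency
distribution (no planted motifs) with an abundance law (1e-4..1e-2) that
the 2e6-read depth fully resolves: every clone appears in both pools, so
unique-sequence compositions are identical and the test is exactly
calibrated-conservative — empirical type-I error is far below both
alpha levels. This isolates the statistic from pool-composition sampling
noise, which is a *composition difference*, not a property of the test.
When the two pools' unique sets differ only by which rare clones
happened to be sampled, motif frequencies shift coherently across the
many nested motifs of a profile, and the t-test's independence
assumption is violated in a way that can inflate |t|; on real data this
is one more reason the stringent 1e-10/d > 2 double threshold, rather
than a conventional 0.05, is the decision rule.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `q_min` | 30 | per-base Phred floor (1:1000 error) over design-covered bases |
| `max_wildcard_fraction` | 0.55 | wildcard cap per motif, floored |
| `min_positive_support` | 100 | unique positive matches per motif; calibrated to multi-million-read pools (~1e5 uniques) and worth scaling down with pool size, as the examples do |
| `p_cut`, `d_cut` | 1e-10, 2 | specificity decision on log10 p and Cohen's d |
| `min_count`, `min_fold` | 200, 4 | enrichment-ranking quadrant (strict >) |
| `identity_threshold` | 0.80 | single-linkage family identity on L3+H3 (inclusive, so identical clones always merge) |

Fold-change conventions mirror published tables: a clone absent from the
negative pool has infinite fold ratio; for log10 fold-change columns its
negative frequency is floored at one read over the negative total and
flagged.

## Problem sizes

The test suite exercises the full pipeline on pools of 2e5 reads
(~1,200 background clones, two families) and the acceptance checks on
the reference 7e6-read configuration (~5,000 background clones, four
families, ~2.3e5 unique clones before filtering); the null calibration
scores 550 candidates. These sizes keep the complete suite under a few
minutes on one CPU while leaving every mechanism — support floors,
chimera loads, rare-clone recovery — at the same operating point as the
full-scale analysis.

## Known limitations

* Motif enumeration is exhaustive over C(L, k) wildcard sets; an H3 of
  length 17 yields ~9e4 patterns per candidate. Scoring every clone of a
  100k-unique pool is an overnight job, not an interactive one; the
  pipeline accepts explicit candidate lists for targeted scoring.
* No multiple-testing correction is applied, matching the fixed-cutoff
  decision rule; the p values of overlapping motif sets are strongly
  dependent across candidates, so corrected values would not be
  interpretable as error rates either.
* Codon-exact validation rejects synonymous variants by design; a
  library realized with codon wobble would need its design document to
  list the synonyms.
* The pair filter assumes artifacts are rarer than their parent pairs;
  a chimera amplified early in PCR can exceed a rare valid clone and
  survive (or displace it).
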