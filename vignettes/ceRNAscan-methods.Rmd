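---
title: "ceRNAscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNAscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAscan)
```

# The problem

Competing endogenous RNA (ceRNA) regulation rests on a titration argument:
transcripts carrying binding sites for the same miRNAs — miRNA response
elements, MREs — draw on a shared, limited miRNA pool, so raising the level
of one transcript de-represses the others. A lncRNA is a plausible sponge
for an mRNA when (i) the two share targeting miRNAs, (ii) a substantial part
of the lncRNA's MRE repertoire belongs to those shared miRNAs, (iii) the
overlap is larger than chance, and (iv) the two RNAs — and the shared
miRNAs — are actually co-expressed at comparable levels somewhere.
ceRNAscan operationalises each of these as a separate, testable stage.

# Target-site discovery

## Seed classes

Site classes follow the TargetScan conventions. With 1-based miRNA
coordinates, the target-side patterns are reverse complements of miRNA
positions 2–7 (6mer), 2–8 (7mer-m8), with the A1 variants (7mer-A1, 8mer)
additionally requiring an `A` on the target opposite miRNA position 1. The
`A` is an identity anchor on the target, required regardless of the miRNA's
own first base — it is recognised by Argonaute, not paired. Seed pairing is
Watson–Crick only: a G:U wobble in the seed is treated as a mismatch. All
comparisons run in a canonical RNA alphabet (`T` = `U`), so DNA- and
RNA-space inputs mix freely; `N` never pairs with anything.

Scanning finds every (possibly overlapping) occurrence of the 6mer core and
then classifies each locus by its two flanking bases, which simultaneously
implements the collapse rule: a locus satisfying both the m8 and the A1
condition is reported once, as an 8mer, never additionally as its contained
6mer/7mer variants. Distinct loci are never merged.

## One-mismatch compensatory sites

Seed matches with exactly one mismatched position in 2–7 (extended to 2–8
when the m8 base also pairs) are reported as class `mismatch-compensatory`,
but only when the target perfectly Watson–Crick pairs miRNA positions 13–18
in the upstream (target 5') part of the alignment window — the classical 3'
compensatory configuration. The check is implemented as an exact substring
search for the reverse complement of positions 13–18 within the upstream
window segment; wobble is deliberately not accepted in the compensatory
block. By default this site class is searched on lncRNAs only
(`mismatch_mode = "lncRNA"`); `"all"` and `"none"` are available.

## Windowed alignment

Each seed match is extended by a local alignment of the full miRNA against
a 25-nt target window, in the spirit of miRanda's modified Smith–Waterman.
The window ends one base downstream (target 3') of the seed core — the base
opposite miRNA position 1 — and extends up to 25 nt upstream, truncating at
transcript ends. Placing the window upstream reflects the antiparallel
geometry: the miRNA 3' half pairs target sequence 5' of the seed site. We
include the position-1 base in the window so that a perfect 22-nt duplex
aligns end to end (22 matches with default scores = 110); a window clipped
at the seed would leave the position-1 column unscorable.

Scoring parameters (`alignment_params()`), miRanda-like magnitudes:

| parameter | default | meaning |
|---|---|---|
| `match_score` | +5 | Watson–Crick pair |
| `wobble_score` | +2 | G:U, outside the seed only |
| `mismatch_penalty` | −3 | any non-pair, and any non-WC seed column |
| `gap_open` / `gap_extend` | −8 / −2 | affine gaps in the 3' extension |
| `min_report_score` | 0 | reporting threshold |

The seed columns are anchored — scored but never realigned — and the miRNA
3' segment is aligned to the reversed upstream window by Smith–Waterman
with affine gaps; the position-1 column contributes only when it pairs.
Because anchored perfect seeds already score positive, the default
`min_report_score = 0` means the alignment score *annotates* perfect-seed
sites rather than filtering them: a seed match is sufficient evidence for a
site, which is also why no thermodynamic or accessibility filtering is
attempted. Extending Watson–Crick pairing in the 3' window can only raise
the score (a property the test suite checks explicitly).

# Annotation

Genomic intervals (conserved elements, AGO CLIP clusters) are projected
into spliced transcript coordinates through exon models: each interval is
intersected with each exon and shifted by cumulative exon offsets;
junction-spanning intervals stay split into per-exon pieces, and on minus
strands coordinates are reversed so position 0 is the transcript 5' end.
All internal coordinates are 0-based half-open (BED convention).

Two flags with deliberately different stringency:

* **conserved** — TRUE iff the seed region is *entirely contained* in one
  conserved block, after discarding blocks shorter than 8 nt. Containment of
  the functional seed is the stringent reading; the 8-nt floor discards
  alignment crumbs shorter than a seed.
* **ago_supported** — TRUE iff the seed overlaps an AGO interval by ≥ 1
  base. CLIP cluster boundaries are fuzzy, so permissive overlap avoids
  false negatives.

Both flags are tri-state: sites on transcripts absent from the annotation
data remain `NA` ("unknown"), serialised as `NA` in TSVs. Annotation never
adds or removes sites. Conserved-only / AGO-only scoring modes re-filter
the site table *before* MRE aggregation, so both the shared-MRE numerator
and the total-MRE denominator reflect the restriction.

# ceRNA scoring

`aggregate_mres()` counts collapsed, deduplicated sites per (transcript,
miRNA). For each candidate pair the ceRNA score is

$$\mathrm{score}(l, m) = \frac{\#\{\text{MREs on } l \text{ for miRNAs shared with } m\}}{\#\{\text{all MREs on } l\}} \in (0, 1],$$

with the lncRNA as the scored candidate: the score asks how much of the
lncRNA's sponge capacity is relevant to this particular mRNA. It reaches 1
exactly when every MRE on the lncRNA belongs to a shared miRNA. Because the
score is MRE-based rather than miRNA-based, a lncRNA with 100 MREs for one
shared miRNA outranks one with 2 MREs for two shared miRNAs — by design.

The overlap of the two miRNA sets is tested with the inclusive upper-tail
hypergeometric probability

$$p = \sum_{i=m_c}^{\min(m_p, m_n)} \frac{\binom{m_p}{i}\binom{M_T - m_p}{m_n - i}}{\binom{M_T}{m_n}},$$

computed in log space (`lchoose` + log-sum-exp) so large universes do not
overflow; $m_c = 0$ returns exactly 1. `M_T` defaults to the number of
distinct miRNAs observed in the loaded data — the universe must match what
was actually scanned, not a fixed genome-wide constant — and is overridable
for users who prefer, e.g., the full miRBase count. Benjamini–Hochberg
q-values (`stats::p.adjust`) are attached across the reported table. Pair
tables sort by shared-miRNA count (descending), then p-value, then ids;
ties are therefore stable and two runs on the same inputs are
byte-identical.

# Expression profiling

Expression is gene-level; abundances are whatever unit the user supplies
(FPKM in the bundled generator). Per tissue and pair the report flags:

* `both_expressed` — both abundances ≥ `expr_threshold` (default 1.0, a
  conventional detectability floor);
* `near_equimolar` — both positive and within `fold_window` (default 2.0)
  fold of each other, the regime where ceRNA cross-regulation is strongest;
* `coexpressed_shared_mirnas` — shared miRNAs with abundance ≥
  `mirna_threshold` (default 1.0) in that tissue.

Missing expression is treated as *unknown*, never as zero: flags are FALSE
when either value is missing, and a missing abundance stays `NA` in the
report. No cross-tissue correlation enters any core contract; a Spearman
rank correlation is available separately (`pair_coexpression()`) as a
clearly-labelled descriptive extra.

# The synthetic-data generator

The generator exists so that every stage can be tested against known truth
with no external dataset.

**miRNA panels** are random 22-nt sequences with pairwise-distinct 6-mer
seeds, subject to two feasibility constraints: seeds must be aperiodic (a
seed like `GGGGGG` overlaps itself, so a single planted site would
unavoidably read as two), and no member's seed core may occur inside
another member's 8mer construct or 3' compensatory block (such a collision
would make every plant of one miRNA a spurious site of another). Both are
rejection-sampled at panel generation.

**Planted transcripts** splice exact site constructs — pattern plus guard
bases that pin the intended class, and for compensatory sites the 13–18
block 11 nt upstream of the core — into a random background. The background
(and the free choices inside the constructs) are redrawn until the
assembled sequence contains *exactly* the planted loci, verified by an
independent character-level scan, so truth lists are exhaustive rather than
lower bounds. This is rejection sampling, not masking: absence of spurious
sites is guaranteed, not patched.

**ceRNA universes** emulate the statistical structure the score and the
test assume: each transcript draws a miRNA subset from a universe of
`n_mirnas`, each targeting miRNA gets `1 + Poisson(mre_lambda)` MREs, and
designated lncRNA–mRNA pairs draw membership jointly with probability
`p_both` per miRNA (with `p_both = p_target^2` the two sets are
independent — the calibration null; `p_both > p_target^2` plants real
overlap; `p_both = p_target` nests the lncRNA's set inside the mRNA's,
forcing score 1). The generator records the realised `m_p`, `m_n`, `m_c`,
MRE counts, score and p-value for every designated pair, so pipeline output
can be compared to truth exactly. With `sequences = TRUE` every transcript
is additionally realised as an actual sequence with planted sites, making
full FASTA-to-pair-table runs checkable; this is feasible for small panels
(tens of miRNAs), while membership-only universes scale to thousands of
pairs. Expression matrices are i.i.d. log-normal with a per-tissue miRNA
detectability probability.

What the generator does **not** emulate: real genome base composition and
repeat structure, realistic conservation patterns, correlated expression
across tissues, or shared targeting structure among panel miRNAs (no seed
families). Passing tests therefore demonstrate algorithmic correctness on
the model's own terms — exact site arithmetic, exact score and tail
computations, calibrated null behaviour — not predictive accuracy on real
transcriptomes.

# Numerical and calibration choices

* Hypergeometric tails are validated against exhaustive enumeration of all
  draws for every configuration with $M_T \le 12$ (tolerance $10^{-10}$),
  plus normalisation and monotonicity sweeps over 1000 random
  configurations.
* The null-calibration check uses 2200 disjoint pairs from an
  independent-overlap universe with $M_T = 1000$ and a per-miRNA targeting
  probability of 0.2 (margins around 200). These sizes were fixed at design
  time: an exact discrete test is conservative, and with small margins the
  achievable tail just below any α sits well under α; margins of this order
  make the discrete null near-continuous so the p < 0.05 fraction is
  expected within 3 binomial standard deviations of 0.05. Observed
  fractions across seeds (0.033–0.050) show the residual, expected
  conservatism.
* Finder/oracle agreement runs on 100 random transcript–miRNA pairs
  (transcripts up to 2000 nt, half of them enriched with spliced-in
  patterns and 3' blocks to stress overlaps and compensatory
  configurations) against a naive every-offset scanner; planted-site
  recovery runs on 100 planted fixtures (1–5 sites, all five classes) and
  100 pattern-free backgrounds.
* Degenerate inputs: empty FASTA yields empty tables; transcripts shorter
  than the seed yield no sites; windows truncate at transcript ends (a
  compensatory candidate whose upstream window cannot hold the 13–18 block
  is simply not reported); zero-MRE transcripts form no pairs (the score's
  denominator is never 0); `m_c = 0` pairs are excluded by the default
  `min_shared = 1`.
* Tie-breaks are all lexicographic or positional and therefore
  deterministic; the only RNG in the package lives in the generator and is
  seeded explicitly, with global RNG state saved and restored.

# Limitations

No thermodynamic (ΔG), accessibility or context scoring — the site model is
seed matching plus complementarity, so specificity rests on seed classes
and optional conservation/AGO restriction. The expression module displays
and flags; it does not model titration dynamics or fit expression-based
ceRNA networks (conditional mutual information approaches are out of
scope). Scores across lncRNAs with very different MRE totals are ratios,
not calibrated probabilities; the hypergeometric p-value assumes
exchangeable miRNAs, which real seed families violate.
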