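---
title: "Designing and analysing molecular inversion probe panels with mipkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing molecular inversion probe panels with mipkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipkit)
```

## The capture model

A molecular inversion probe (MIP) is a single-stranded oligo whose two
termini — a 16–20 nt *extension arm* and a 20–24 nt *ligation arm* — hybridise
immediately on either side of a genomic region of interest, the *gap fill*.
Polymerase extension and ligation circularise the probe around the gap fill,
and the circle is amplified with universal primers sitting in the 30 nt
linker that joins the arms. A 5 nt degenerate unique molecular identifier
(UMI) in the linker tags every captured molecule, so PCR duplicates can be
collapsed and coverage counted in *unique molecules* rather than raw reads.

`mipkit` implements this assay end to end on the computational side: panel
design (`design_panel()`), capture-read simulation (`simulate_reads()`), the
read-processing core (`run_sample()`), unique-molecule variant calling
(`call_sample()`, `cohort_filter()`), and the panel evaluation statistics
(`capture_efficiency()`, `sensitivity()`, `cross_compare()`,
`gene_report()`, `per_sample_cost()`).

## Panel design

Targets are exons padded by ±20 bp of flanking intron (`load_targets()`;
untranslated regions are never added). Overlapping padded exons merge, with
comma-joined gene labels. Each merged region is tiled with gap-fill windows
of 220–230 nt overlapping by at least 20 bp (`tile_region()`): for a region
of length $L$, maximum gap fill $g$ and overlap $v$, the window count is the
closed-form minimum $\lceil (L-v)/(g-v) \rceil$ (one window when $L \le g$),
and windows are spread evenly so the first and last pin the region's ends.
Regions shorter than 220 bp get one window centred on the region, extending
into flanking sequence — every target base must sit under at least one gap
fill, which `validate_panel()` verifies.

Arms are chosen per window from the 5 × 5 grid of admissible length pairs
(`pick_arms()`). A pair is excluded when either arm has more than 5 exact
genomic occurrences (both strands; palindromic self-matches counted once) or
overlaps a common SNP with population minor allele frequency above 1%. Among
surviving pairs the designer minimises
$|\mathrm{GC}(\text{ext})-0.5| + |\mathrm{GC}(\text{lig})-0.5|$, breaking
ties by longer total arm length and then longer extension arm. This
GC-balance objective is our own deterministic stand-in for a
melting-temperature model: it has the same intent (arms annealing at
comparable, moderate temperatures), is reproducible bit-for-bit, and needs
no trained scoring function. When *every* admissible pair overlaps a common
SNP, the panel carries two probes for that window — one matching the
reference allele, one the alternate — so both haplotypes capture.

One accounting subtlety: with a 30 nt linker, a 5 nt UMI and arms of 36–44 nt
total, assembled oligos span 71–79 nt. We therefore treat the nominal
77–80-mer range as an advisory band: `assemble_oligo()` records the length
and flags totals outside the band (`oligo_in_range`) instead of rejecting
them, since rejecting would contradict the stated arm and linker geometry.

Coordinates are 0-based half-open (BED convention) in every file and table
the package reads or writes; conversion to R's 1-based intervals happens
inside the interval operations, and to VCF's 1-based convention only in the
VCF writer.

## What the simulator emulates — and what it does not

`simulate_reads()` draws, per probe, a number of captured molecules from
$\mathrm{Poisson}(\lambda \cdot \text{dosage} \cdot m)$, where $\lambda$ is
the mean unique-molecule yield (`mean_molecules`, default 100 — a realistic
per-probe yield for a rebalanced panel sequenced to >30x unique coverage),
dosage is the probe's pool concentration multiplier, and $m$ is a
capture-efficiency multiplier applied to probes whose gap-fill GC fraction
exceeds 0.5 (default 1; setting it to 0 reproduces the complete dropout of
GC-rich first exons seen in real panels). Each molecule receives a uniform
random 5-mer UMI — collisions are possible and deliberately not prevented,
because the pipeline's dedup semantics must tolerate them — its own draw of
every heterozygous variant (probability 0.5; homozygous variants always),
and $1+\mathrm{Geometric}(d)$ PCR copies (`pcr_dup_mean`, default 1).
Reads are 2 × 150 bp: read 1 is `UMI + extension arm + gap-fill prefix`,
read 2 the reverse complement of `gap-fill suffix + ligation arm`; with a
220–230 nt gap fill the mates overlap in the middle by construction.
Substitution errors hit every base independently at `error_rate`
(default 0.002, a typical post-filter short-read error rate; the model
enforces < 0.01).

The simulator does **not** model: indels longer than 3 bp, sequencing
quality scores (a constant is written), strand-specific capture biases
beyond the GC rule, chimeric circles, or polymerase slippage. Passing tests
on simulated cohorts therefore demonstrate the pipeline's correctness under
this generative model — UMI accounting, arm trimming, merge arithmetic,
filter logic — not robustness to every artefact of real libraries.

## The read-processing core

Reads are assigned to probes by their arms, not by genome alignment: the
extension arm must match read 1 immediately after the UMI and the ligation
arm must match the start of read 2, each within `max_mismatch`
substitutions (default 1 per arm — enough to rescue a typical single
sequencing error without inviting cross-probe misassignment). Pairs whose
arms match different probes are chimeras and stay unassigned; ties between
probes with identical arms resolve by total mismatch count, then panel
order, making assignment deterministic and order-independent.

After trimming, the mates are merged into one gap-fill fragment. Candidate
insert lengths within ±3 bp of the probe's reference gap fill are tried
nearest-first and accepted on an exact overlap match; if no candidate is
exact (a sequencing error in the overlap), the candidate with the fewest
overlap mismatches wins and disagreeing overlap bases are masked to `N`.
The fallback must compare *all* candidate lengths: accepting the reference
length by default would mis-place the read-2 segment of indel-carrying
molecules by the indel length and paint a trail of spurious substitutions
downstream — this failure mode is exercised directly in the test suite.
No gapped alignment is performed anywhere; substitutions are read off by
offset, and indels of up to 3 bp are recovered from the merged fragment
length.

`dedup()` collapses fragments by `(probe, UMI)` with a strict per-position
majority over non-`N` bases (ties give `N`); reads whose merged length
differs from the family's modal length are counted but do not vote. UMIs
are never error-corrected — two families one UMI-mismatch apart stay
separate, which at a 5 nt UMI and realistic error rates costs little and
avoids inventing a clustering the assay does not define.

Coverage is counted in unique molecules (families), and the headline
coverage metric uses a strictly-greater rule: a base at exactly 30x does
*not* count towards ">30x". Probes with no reads in a pilot batch are
classified `failed` (replace); probes with 1–30 unique reads are `poor` and
boosted by adding a 5-fold concentration to the pool, so their dosage
becomes 6× (the original 1× remains; a `replace` mode yielding 5× is also
exposed). The 1–14 band is not specified by the rebalancing rule we adopt
(which names 15–30); we treat 1–14 as `poor` as well, since those probes
perform strictly worse.

## Variant calling and filters

`call_sample()` builds a per-position pileup of family-consensus bases,
pooling probes that overlap the same position; consensus `N` bases are
excluded from depth. A site is reported when any non-reference allele
reaches 20% of unique molecules; sub-threshold alleles at reportable sites
are emitted flagged `LOW_VAF`, sites under 30 unique molecules are flagged
`LOW_DEPTH`, and `cohort_filter()` flags variants present in more than 90%
of batch samples (`COHORT_ARTIFACT`) — in a disease panel a variant carried
by nearly every sample is a systematic capture or reference artefact, not
biology. In a single-sample batch the rule degenerates to flagging
everything (100% > 90%); that is the documented literal reading, and cohort
filtering is simply not meaningful at $n = 1$.

Zygosity is assigned from the alternate fraction with a 0.80 boundary:
heterozygous in [0.20, 0.80), homozygous at or above 0.80. The boundary is
a free parameter of `filter_config()`; 0.80 leaves roughly 6 binomial
standard deviations between a true heterozygote (0.5) and the boundary at
100x unique coverage.

Indels up to 3 bp are called by exact alternate-fragment matching: a family
fragment whose length differs from the reference gap fill must equal the
reference with a single contiguous insertion or deletion applied (`N`
matching anything); the implied allele is then left-aligned and trimmed to
the parsimonious VCF representation (`normalize_variant()`), so repeat-tract
indels always land on the canonical anchor. Truth tables are normalized
with the same routine, making truth/call comparison representation-stable.

## Numerical and reporting conventions

Percentages are reported to one decimal, rounded half-up. Zero-denominator
percentages are reported as `NA` (not applicable), never 0 or 100.
`gene_report()` totals are exact column sums, with the coverage percentage
weighted by targeted bp. The per-sample cost model amortises probe
synthesis and a fixed setup cost over the cohort and charges sequencing per
run of up to `samples_per_run` samples; its printed-table counterpart is
deliberately not asserted anywhere, because per-run accounting in such
tables is underdetermined — the formula and its parameters are exposed
instead.

## Problem sizes used by the test suite

The simulated-cohort studies run at sizes chosen to give stable statistics
while keeping the suite quick on a laptop: a nine-gene, four-exon synthetic
reference (~54–65 probes, ~15 kb of targets), 20 samples, 100 molecules per
probe, 0.2% error, three variants per sample with a 15% indel fraction.
At these settings every planted variant sits on ≥60 unique molecules, so
recovery failures indicate logic errors rather than sampling noise. The
tiling property suite samples 1000 region lengths in 1–2000 bp; the
arm-count oracle cross-checks a brute-force scan on multi-kilobase
references.

## Known limitations

* Arm matching assumes the first `umi_len` bases of read 1 are the UMI and
  tolerates substitutions only; an indel inside an arm loses the read.
* Indels longer than 3 bp, multi-nucleotide substitutions spanning a merge
  junction, and variants inside the arms themselves are out of scope.
* The designer's GC-balance objective is a proxy, not a trained
  hybridisation model; panels destined for synthesis should still be
  reviewed against a thermodynamic model.
* Coverage attribution assigns each family the full gap fill of its probe;
  sub-fragment dropouts (e.g. hard clips) are not modelled.
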