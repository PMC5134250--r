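---
title: "Merging, stitching and expected-error filtering of paired-end amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging, stitching and expected-error filtering of paired-end amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampmerge)
```

## The model

Paired-end amplicon sequencing reads each PCR product from both ends at a
fixed read length $L$ (here, MiSeq 2×300). For an amplicon of length $T$:

* $T \le 2L - w$ (with $w$ the minimum overlap): the mates overlap by
  $2L - T$ bases and can be merged into a single sequence of length $T$;
* $T > 2L - w$: the mates leave an unsequenced inner gap. Discarding such
  pairs — the default in most pipelines — deletes from the community
  profile exactly those taxa whose hypervariable regions run long.

`ampmerge` merges what overlaps, optionally stitches what does not, and
filters the resulting amplicons on their expected error content.

### Merging

The reverse mate is reverse-complemented; candidate overlaps are every
"inward" alignment of a forward-read suffix against a reverse-read prefix
with length in $[w, \min(L_f, L_r)]$. Each candidate is scored by its
mismatch *rate* (mismatch count / overlap length). The best candidate is
the one with the smallest rate, ties resolved toward the longer overlap,
and it is accepted only if the rate is at most `max_mismatch_frac`.
A rate objective is used rather than the raw mismatch count because a raw
count is trivially minimised by very short overlaps; rate plus
longer-overlap tie-breaking matches standard merger practice. Read-through
layouts (amplicon shorter than one read) are deliberately rejected:
the 16S amplicons this tool targets always exceed one read length, and
treating engulfing alignments as overlaps would let adapter read-through
masquerade as merges.

Within an accepted overlap, agreeing columns take the agreed base at
$\max(q_f, q_r)$ — the two independent observations corroborate each
other, and the merged quality is never below either input. Disagreeing
columns are resolved in two stages:

1. **Quality gap.** If $|q_f - q_r| \ge$ `qdiff_threshold` (default 19,
   i.e. nearly two orders of magnitude in error probability), the
   higher-quality base replaces the lower-quality one. The comparison is
   inclusive at the threshold; the source is silent on equality and an
   inclusive reading keeps the quality rule primary.
2. **k-mer context vote.** Otherwise the decision falls to dataset-wide
   sequence context: for each candidate base, every k-mer of the
   tentatively merged sequence spanning the disputed position (with that
   base substituted) is looked up in a table of canonical k-mer counts
   built in a first pass over the whole sample — all forward reads plus
   all reverse-complemented reverse reads, k-mers containing `N`
   excluded, each k-mer pooled with its reverse complement. The larger
   summed count wins; residual ties go to the higher Phred and then to
   the forward base, so merging is fully deterministic. The winning base
   carries its own Phred score. Other disputed columns in the same
   overlap hold a provisional quality-based call while the vote is
   taken; disputes are rare enough (a few per overlap) that interactions
   between them are negligible. An `N` always loses to a called base
   regardless of quality, since it carries no base information.

The table is built per sample rather than per run: context frequencies
are only meaningful at the scope within which the amplicons share
composition. The pipeline holds the pair list in memory for this first
pass; samples of desk scale (up to a few hundred thousand pairs) fit
comfortably.

### Stitching

A non-overlapping pair can be retained by concatenating the forward read,
`n_spacer` `N` bases (default 15), and the reverse-complemented reverse
read. The spacer is written to FASTQ at Phred 2 — the conventional
"no confidence" score, and what downstream consumers see on disk — but is
*masked* in memory: no quality metric or report statistic ever includes
a spacer position, so a stitched amplicon scores exactly as the
concatenation of its two mates would. The stitched record keeps the
forward read's identifier, giving downstream tools one id per amplicon.
FASTQ cannot encode the mask, so `mask_spacer()` rebuilds it on
re-ingestion from the documented signature (a run of ≥ `n_spacer` `N`s,
all at the spacer Phred); sequencer-called `N`s at other qualities are
never masked and their own Phred contributes to the metrics.

### Filtering

For Phred score $Q$, the base-call error probability is
$P = 10^{-Q/10}$. Per amplicon, over unmasked positions:

$$\mathrm{MEE} = \sum_i P_i, \qquad
  \mathrm{meep} = \frac{100 \cdot \mathrm{MEE}}{\text{unmasked length}}$$

MEE is the expected number of miscalled bases; meep normalises it per 100
bases, so a meep cutoff of 1 permits at most one expected error in a
100-nt read. The alternative policy is the traditional mean-Phred cutoff.
Both comparisons are inclusive at the threshold (a 100-base read with MEE
exactly 1 passes meep ≤ 1). Metrics are computed in double precision and
rounded only at display time (3 decimals in the report files).

The motivating contrast: 90 bases at Q40 plus 10 at Q2 average Q36.2 but
carry $90 \cdot 10^{-4} + 10 \cdot 10^{-0.2} \approx 6.32$ expected
errors; 100 bases at Q25 average only Q25 but carry 0.316. An average-Q
filter at 20 keeps both; a meep filter at 1 keeps only the second.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_overlap` | 10 | bases | smallest acceptable overlap |
| `max_mismatch_frac` | 0.2 | rate | mismatch budget within the overlap |
| `qdiff_threshold` | 19 | Phred | quality gap that decides a mismatch outright |
| `kmer_size` | 17 | bases | context k-mer length (odd) |
| `n_spacer` | 15 | bases | `N` patch joining non-overlapping mates |
| `spacer_phred` | 2 | Phred | on-disk quality of spacer bases |
| `keep_nonoverlap` | FALSE | — | stitch rather than discard non-overlapping pairs |
| filter | meep ≤ 1 | % | default policy; `avgq ≥ 20` selectable |

The merge defaults follow the upstream context-aware merging scheme and
are all exposed. Quality encoding defaults to Phred+33 (modern Illumina);
the offset is a parameter throughout because the decoding of a quality
string cannot be inferred reliably from its bytes alone.

## The simulator

`make_templates()` draws uniform random ACGT templates; pipeline
behaviour depends on template *lengths* and injected errors, not on real
taxonomic sequence, so random templates substitute for reference
amplicons without any download. The defaults mirror a realistic V1–V3
survey: four templates of 471–519 bases (overlapping at 2×300) and two
above 595 (non-overlapping).

`simulate_pairs()` reads each template from both ends and substitutes
bases per cycle $i$ with probability

$$p_i = \min\!\left(\tfrac{a + b\,i^4}{100},\ 0.75\right),
  \qquad a = 3\times10^{-3},\ b = 1.8\times10^{-9},$$

a 4th-degree polynomial Illumina profile: ~0.003% at cycle 1 rising to
~14.6% at cycle 300. The polynomial is interpreted in percent units; read
as a raw probability it would exceed 1 before cycle 300, which is
impossible, so the percent convention is the default and a
probability-unit mode (`rate_unit = "probability"`, clamped at 0.75, the
uniform-substitution ceiling) is provided for completeness. Quality
strings are derived from the same model,
$Q_i = \mathrm{round}(-10\log_{10} p_i)$ capped to $[2, 40]$, so
quality-filter behaviour can be reasoned about analytically: the expected
MEE of a simulated 300-base read is $\sum_i p_i \approx 8.8$. Indels are
not simulated, matching the ungapped merger. Substitutions go to a
uniformly random different base. Everything is deterministic given the
seed.

What the simulator does *not* emulate: indels and chimeras, PCR and GC
bias, correlated error bursts, quality variation between reads at the
same cycle, adapter contamination, and real 16S sequence composition
(conserved flanks, homopolymers). Passing tests therefore demonstrate the
algorithmic contracts — overlap detection, mismatch resolution, mask
bookkeeping, filter arithmetic — not field performance on real libraries.

## Numerical choices and degenerate inputs

* Overlap candidate selection is deterministic: strict rate improvement,
  then longer length; no randomness anywhere in merging.
* A fully masked quality vector is a hard error, not NaN; empty input
  files produce a zeroed report and empty outputs with exit 0.
* HQ averages over an empty HQ set are reported as 0 with an explicit
  `hq_empty` flag rather than NaN, keeping the TSV machine-readable.
* Report counts conserve records on every run:
  HQ + LQ + discarded unmergeable = total input pairs. Low-quality
  amplicons are written (not deleted) so the audit is always possible.
* Phred scores are validated into $[0, 93]$ at both decode and encode;
  an out-of-range decode suggests a wrong offset in the error message.

## Study conditions used by the tests

The end-to-end experiment is run at 600 pairs — 100 from each of six
templates (471, 485, 500, 519, 610, 650 bases), a 1/200 scale of the
full 120,000-pair design — which keeps the whole suite to a few minutes
while leaving every per-template statistic with ~100 observations. The
per-cycle error-calibration check uses 10,000 reads from one template.

One property of these conditions is worth stating precisely. For the
519-base template the overlap is only 81 bases and falls entirely in
cycles 220–300 of *both* mates, where the error model averages ~8% per
base; the expected per-column mismatch rate there is
$p_f + p_r - \tfrac{4}{3} p_f p_r \approx 0.16$, within two standard
errors of the 0.2 acceptance cutoff. A computable minority of such pairs
(≈18% for that template, ≈7% across the four short templates) therefore
legitimately fails to merge and, when `keep_nonoverlap` is set, is
stitched instead. The tests assert the analytically supported merge
rates (overall > 88%, every short template a clear majority), not an
idealised 100%. For the same reason nearly all simulated amplicons fail
meep ≤ 1 — a 300-cycle read under this error model carries ~8.8 expected
errors — which is precisely the stringency argument for expected-error
filtering; the structural claims (overlap separation by template length,
retention only under `keep_nonoverlap`, record conservation) are
independent of the filter's pass rate.

## Known limitations

* Ungapped overlap search: an indel in either mate shifts the overlap
  frame and the pair will usually fail to merge rather than merge
  wrongly.
* The k-mer vote assumes the sample is deep enough for true context to
  dominate; in very shallow samples the vote degenerates to the quality
  and forward-base tie-breaks.
* Positional mate pairing assumes order-synchronised input files (the
  instrument's native output); pre-filtered, desynchronised files fail
  fast with an identifier mismatch rather than being re-paired.
* Amplicons shorter than one read length (read-through) are not merged;
  trim adapters upstream if such products are expected.
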