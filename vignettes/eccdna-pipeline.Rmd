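---
title: "Circulome analysis from rolling-circle amplification reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circulome analysis from rolling-circle amplification reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccpipe)
```

# The problem

Extrachromosomal circular DNAs (eccDNAs) are circular molecules excised from
chromosomes. They can carry genes, amplify independently of their source
locus, and act as a fast, reversible vehicle of adaptation — for example in
production cell lines such as Chinese hamster ovary (CHO) under metabolic
stress. A standard experimental route to the circulome is rolling-circle
amplification (RCA): Phi-29 polymerase turns each circle into a long tandem
concatemer, which long-read sequencing then observes as the monomer repeated
1.5–8 times. Analysis therefore runs:

1. **deconcatenation** — collapse each concatemer read to its monomer and
   confirm circularity (a full junction must be observed);
2. **clustering** — collapse near-identical circles within a condition at a
   90 % sequence-identity threshold;
3. **placement and hotspot detection** — assign each circle to its best
   genomic origin, bin origins into consecutive 500-kbp windows, and call
   windows with a count Z-score ≥ 2 "biogenesis hotspots";
4. **structural composition** — annotate gene/tRNA content by feature
   transfer, rDNA and replication-origin (ORI) content by a ≥ 95 %-identity
   homology rule, repeat content per class, and GC;
5. **expression integration** — correlate per-condition eccDNA gene presence
   with TMM-normalized transcript abundance (a 1.2-fold exclusivity rule with
   a TMM < 2 floor) and apply |log2FC| ≥ 2 thresholds including the
   endpoint-versus-baseline "net change" view.

Every stage is exercised end-to-end on a synthetic-data generator, so the
package needs no external downloads and every statistical property is testable
against planted ground truth.

# The synthetic-data generator

`sim_genome()` draws random chromosome sequences at a target GC of 0.405 and
annotates non-overlapping genes, tRNAs, rDNA genes and ORIs plus
possibly-overlapping repeat intervals whose union covers 38 % of bases — the
GC and repeat content observed in hamster-derived circulome data. Repeat
classes (SINE, LINE, LTR, DNA elements, satellites, simple repeats, low
complexity, small RNA, unclassified) are drawn with the base-pair weights of
a typical rodent repeat landscape.

`sim_ecc_population()` draws circle source midpoints from a mixture: with
probability `p_hotspot` (default 0.5) from weighted planted hotspot windows,
otherwise uniformly along the genome. Lengths are truncated normal
(mean 4905/4976/5515 bp per condition — the observed per-condition averages
— SD 1500 bp, floor 200 bp). The published tables report only means and
maxima, so the distribution family is a modelling choice; truncated normal is
the simplest two-parameter family consistent with them. Circles are
contiguous single-locus excisions on a uniformly chosen strand; chimeric
multi-locus circles are out of scope because the downstream structural
statistics do not resolve chimeras.

`sim_concatemer_reads()` repeats each monomer `c` ~ U[1.5, 8] times from a
uniform random rotation and applies iid errors at 1 % with an 8:1:1
substitution:insertion:deletion mix — enough indel content to exercise the
indel tolerance of deconcatenation without dominating it. No attempt is made
to model platform-specific error profiles or adapters; the pipeline consumes
generic long reads.

`sim_expression_table()` plants the correlation structure the integration
rules detect: a configurable fraction of genes carried on eccDNA in exactly
one condition get a ≥ 1.2-fold (default 1.5) abundance boost in that
condition, log-normal noise is applied at CV 0.05, and ~10 % of genes are
held below TMM 2 in all conditions to exercise the low-expression filter.
Optionally it also plants differentially expressed genes (|log2FC| ≥ 2) in
the middle condition with a smaller subset persisting to the endpoint,
emulating the broad transient expression shifts seen under adaptation so the
DE-threshold and net-change operations have end-to-end signal.

What the generator deliberately does **not** emulate: chimeric circles,
sequence-dependent biogenesis preferences, realistic read-quality profiles,
count-level RNA-seq (expression is simulated at the TMM-table level, which is
where the integration rules operate), and genome-scale window counts. Tests
passing on this generator therefore validate the algorithms and their
calibration, not performance on any particular sequencing platform.

# Deconcatenation

`find_monomer_period()` detects the monomer length as the dominant spacing
between recurrences of shared k-mers (k = 15) along the read: consecutive
occurrence gaps are pooled, clustered within a ±2 % tolerance (minimum 3 bp,
so indel jitter never splits short periods), and the best-supported cluster
must carry ≥ 80 % of all votes (`min_period_score`). Non-repetitive reads
produce almost no recurrent 15-mers (two random 10-kb reads share < 0.05
expected 15-mer pairs), so the false-positive rate is controlled by a minimum
of 5 votes rather than by a significance test.

`deconcat_read()` extracts the full copies at offsets 0, p, 2p, … and builds
a consensus on the first copy as backbone. Because 1 % error includes
indels, copies drift by a few bases relative to each other; per-column voting
is therefore anchor-guided: unique shared 12-mers between the backbone and
each other copy form a monotone anchor chain, giving each copy a position
offset track. With three or more copies, backbone indels are repaired where a
strict majority of the other copies' offset tracks jump in unison (−1: an
inserted base in the backbone, +1: a deleted one). Ties in the column vote
keep the backbone base, so with exactly two full copies the consensus equals
the backbone — full multiple alignment is intentionally out of scope at
default settings.

Circularity requires three things: copy number ≥ 1.5 (`min_copies`, so at
least one full junction was observed), the period-support score above 0.8,
and junction consistency. The junction criterion is that a k-mer from the
monomer's first bases re-occurs in the ± 50 bp read window at each copy
boundary, with a majority of boundaries (`junction_frac = 0.5`) required.
We probe start-recurrence rather than the monomer's own wrap sequence
because the consensus length is only accurate to a few bases, which is
enough to corrupt the doubled-monomer junction but irrelevant to
start-recurrence; empirically true tandems score 1.0 at 1 % error and
non-tandem reads score ~0.

Circle identity is rotation- and strand-free, so downstream comparisons use
`canonical_rotation()`: the lexicographically smallest rotation of the
sequence or its reverse complement (computed by candidate filtering on the
doubled string; fully periodic strings resolve to any of their equivalent
survivors).

# Clustering

`greedy_cluster()` follows the classical greedy incremental contract:
sequences sorted by length (descending, ties by id so output is
deterministic and input-order invariant), each joining the first existing
cluster whose representative passes the criterion, else founding a new
cluster. Identity is estimated by k-mer containment: under iid substitutions
at identity *i*, a 12-mer survives in both sequences with probability
~*i*¹², so the 0.90 identity threshold maps to a containment cutoff of
0.90¹² ≈ 0.28. The calibration is verified in the test suite, where greedy
clustering under the containment estimator and under an exact edit-distance
identity oracle produce identical partitions for planted families (≥ 95 %
within, ≤ 50 % between). Because containment is asymmetric, a
representative/member length-ratio guard of 1.25 prevents a long circle from
absorbing short unrelated circles it happens to contain. A second guard
addresses a failure mode specific to circle populations: two circles excised
from overlapping loci share their overlap *verbatim*, so containment alone
scores a 30 % overlap like 90 % uniform divergence. The missing k-mers of a
genuinely 90 %-identical pair are scattered along the member, while those of
a partial overlap form one circularly contiguous block; a member is
therefore rejected when a block longer than `1 − identity` of its length is
absent from the representative. This makes the criterion behave like
identity over the shorter sequence. Candidate
representatives are prefiltered through a bottom-64 min-hash sketch of the
k-mer sets, so unrelated pairs are never compared in full; at the 0.28
containment cutoff the probability that a true candidate is missed by the
sketch is below 10⁻⁴. The threshold is exposed as a flag; we treat the
criterion as ≥ 0.90. Whether the published 90 % referred to global identity
or shorter-sequence coverage is not determinable, and the containment
estimator sits between the two readings.

# Placement, windows, hotspots

`locate_circles()` is a seed-and-vote aligner: 32 evenly spaced 15-mers per
circle and strand are matched exactly against the genome (one `PDict` batch
for the whole circle set), and the locus collecting the most seed hits
within one circle length wins, ties broken toward the lowest chromosome and
start. A placement needs ≥ 5 agreeing seeds (`min_votes`); this acceptance
plays the role that a stringent alignment e-value cutoff plays for a
full aligner, which does not translate to exact seed counting. Placement is
strand-agnostic and tolerant of the arbitrary rotation of a deconcatenated
monomer (seeds from both "halves" of a rotated circle vote for the same
locus span).

`make_windows()` tiles each chromosome with consecutive 500-kbp windows, the
final window truncated at the chromosome end. `bin_and_score()` assigns each
placed circle to the window containing its hit midpoint — a unique
assignment, so window counts always sum to the number of placed circles —
and computes per-window `z = (count − mean)/sd` with the mean and the
*population* standard deviation taken over all windows, zeros included.
Population SD makes the printed worked examples self-consistent and matches
the "mean ± SD" framing of window-count reports; it is a documented choice,
not a flag. Reported Z-scores are rounded half-away-from-zero to 2 decimals
and percentages to 1 decimal, matching printed-table precision; raw values
are kept in the objects so the normalization invariants (mean z = 0,
population SD of z = 1) hold exactly. `call_hotspots()` takes windows with
z ≥ 2, ranked by count (ties by chromosome, start), and formats a top-15
report. When the window SD is zero every z is undefined and the hotspot set
is empty by definition.

# Composition

`annotate_circles()` transfers reference annotations through the genomic
hit: genes and tRNAs count only when *fully contained* in the hit interval —
the containment rule is a deliberate choice where partial capture is
ambiguous, and is configurable in spirit by adjusting the hit interval.
Repeat intervals are intersected with the hit; per-class element counts and
base pairs may overlap between classes, while the per-circle
`repeat_masked_bp` is the union across classes. rDNA and ORI status use
`homology_call()`: a local alignment at ≥ 95 % identity covering ≥ 80 % of
the database entry. The coverage floor is a module decision — published
practice fixes only the identity threshold and an e-value, which has no
direct analogue in exact local alignment — and entries sharing fewer than
`min_coverage/2` of their k-mers with the circle are skipped without
aligning, which cannot discard a true match above the thresholds.
`summarize_condition()` assembles the per-condition table: counts before and
after clustering, max/mean length, pooled GC, repeat accounting per class,
gene-/tRNA-bearing percentages over clustered sequences, and the
interspersed-repeat total defined as SINE + LINE + LTR + DNA + unclassified.

# Expression integration

`correlate_ecc_expression()` implements the fold-change correlation rule: a
gene passes when it sits on eccDNA in exactly one condition, its TMM there is
≥ 1.2× its TMM in the *other* conditions (strict AND by default; a flag
relaxes to ANY), and it is not lowly expressed (TMM < 2 everywhere). For
genes exclusive to the baseline condition the same ratio reads as a
reduction in the later conditions; since published practice examined the
immediately following condition there, `baseline_compare = "next"` restricts
the comparison accordingly (default compares against all). Folds are
compared with a 10⁻⁹ tolerance so an exactly-1.2-fold gene passes. No
multiple-testing control is applied — the rule is a fold threshold, not a
test. `fold_difference()` is symmetric (max/min, 2 decimals), so an increase
and a decrease of the same size report the same fold. `de_classify()` and
`net_change()` threshold log2 fold-change tables at ±2; TMM normalization
and DE model fitting themselves are out of scope — the module consumes TMM
matrices and log2FC tables.

# Orchestration and problem sizes

`run_pipeline()` executes simulate → deconcatenate → cluster → place/bin →
compose → integrate per condition, writes every intermediate (FASTA, BED6,
GFF3, TSV, JSON report), and isolates per-condition failures. The default
configuration runs three conditions of 1000 circles on a 15-Mb
three-chromosome genome with three shared planted hotspot windows — sizes
chosen so a complete run, including the acceptance analysis, finishes in a
few minutes on one CPU while leaving every window statistic well-populated
(30 windows at the 500-kbp width, so a planted hotspot can clear the Z ≥ 2
threshold rather than dominating the distribution it is scored against).
The test suite uses smaller genomes
(0.5–5 Mb) and populations (40–1000 circles) per property; the acceptance
analysis reports exact problem sizes next to every number it emits.
Determinism is end-to-end: one master seed derives per-stage seeds, and
identical configurations produce byte-identical outputs.

# Known limitations

* Deconcatenation assumes a single tandem unit per read; chimeric reads or
  nested repeats longer than 200 bp inside a monomer can confuse the period
  vote (the period-score threshold then rejects the read rather than
  miscalling it).
* Two-copy reads get backbone-quality consensus (~1 % residual error at the
  default error rate); three or more copies get error-corrected consensus
  (< 0.3 % observed).
* The k-mer containment estimator saturates for identities below ~70 %
  (nearly all k-mers destroyed), which is irrelevant at a 90 % threshold but
  makes the estimator unsuitable for distant-homology clustering.
* The seed-and-vote aligner targets near-identical placement (the relevant
  regime for circles excised from the same genome); it is not a general
  read aligner and reports at most one locus.
* Window statistics assume one placement per clustered circle; if a circle
  family spans a window boundary its count lands in the midpoint window
  only.
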