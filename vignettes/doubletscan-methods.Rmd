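---
title: "Methods: enhancer profiling, G4 scanning and synthetic exon doublets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer profiling, G4 scanning and synthetic exon doublets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doubletscan)
```

doubletscan analyses exon sequences for three signals that jointly
characterise the expanded first exons of Olduvai exon doublets: dense
exonic splicing enhancer content, an internal direct duplication, and a
purine-rich segment with G-quadruplex propensity that nonetheless escapes
the canonical G4 motif. This vignette records the models, the parameters
that matter, the numerical choices, and what the synthetic generator does
and does not emulate.

## Per-nucleotide ESE/ESSseq profiles

A hexamer score table assigns one dimensionless ESE/ESSseq score to each of
the 4096 DNA hexamers; positive values are enhancer-like, negative
silencer-like. Real tables derive from minigene splicing screens and are
supplied by the user as two-column TSV; the package never bundles one.
Lookup is case-insensitive and reads `U` as `T`, so RNA and DNA input share
one table.

The profile score at position $i$ of a sequence of length $L$ is the
arithmetic mean of the scores of all in-bounds hexamers covering $i$, i.e.
hexamer starts in $[\max(0, i-5), \min(i, L-6)]$. This overlap-average is
the only symmetric, window-free assignment rule, and it reproduces the
smooth per-nucleotide tracks the field plots. Two consequences worth
keeping in mind:

* edge positions average fewer than six hexamers (coverage 1–5); no
  flanking sequence is invented by padding. When an exon is profiled in
  its genomic context, `exon_profile()` takes real flanking context
  (`flank`, default 0 nt) and reports exon-relative coordinates, negative
  in the 5′ flank;
* a hexamer containing an ambiguity code (`N`) is unscorable and simply
  drops out of the averages. A position covered by no scorable hexamer
  carries `NA` and a coverage of 0 — downstream statistics skip it rather
  than mistake it for a neutral score.

Peak calling (`find_peaks()`) smooths the profile with a centered moving
average (default window 7 nt; edges shrink to the in-bounds half-window),
takes maximal runs where the smoothed track strictly exceeds a baseline,
and reports one peak per run at the run maximum. Region statistics use the
raw profile (smoothing window 1) so that test results never silently depend
on a smoothing choice. The baseline is a user-supplied control-exon mean;
no default value is hard-coded because any value would be an invented
constant.

## Region-versus-background statistics

`compare_region_to_background()` treats the per-nucleotide scores of a
region (a union of intervals) as one sample and either the whole profile
(default, the "transcript average" reading) or its complement as the
other, and applies an unpaired $t$-test — pooled Student by default, Welch
as an option. The two-sided p-value is computed through the regularized
incomplete beta function, $p = I_{\nu/(\nu+t^2)}(\nu/2, 1/2)$.

Treating positions as independent observations is optimistic: overlapping
hexamers correlate scores up to 5 nt apart. The package reproduces this
convention because it is the field's reporting style, and provides
`block_permutation_test()` (blocks of 6 nt, the hexamer span, permuted
whole) as the conservative alternative; the block length preserves the
short-range autocorrelation inside blocks. The tests validate the t-test
against numerical integration of the $t$ density, against a label
permutation oracle, and against a 1000-replicate null for the type-I error
rate.

## G4 propensity

Two formula-based scorers are implemented from their defining rules, so
the pipeline has no external prediction dependency:

* **G4Hunter-style score**: per-base +$\min(k,4)$ in a G-run of length
  $k$, −$\min(k,4)$ in a C-run, 0 otherwise; the window score is the mean.
  The sign convention makes the score antisymmetric under reverse
  complement, which the tests verify on random sequences.
* **cGcC**: $cG/cC$, where a run of $k$ consecutive G (or C) contributes
  $10\,k^2$ (each base weighted $10k$). The run-weight table is passed as
  data (`cgcc_run_weights()`), so an alternative weighting is a data swap,
  not a code change; runs beyond the table extend by the last tabulated
  per-base slope. When a sequence holds no C, the denominator becomes the
  pseudocount 1 and the score equals $cG$ exactly.

`N` scores 0 in G4Hunter, breaks runs in both scorers, and counts as an
arbitrary nucleotide in the canonical motif
$G_{\ge3}N_{1-7}G_{\ge3}N_{1-7}G_{\ge3}N_{1-7}G_{\ge3}$, which is matched
leftmost-shortest and non-overlapping.

Scanning uses 60-nt windows at 10-nt steps, and calls are strict
(`cGcC > 4.5`, `G4H > 0.9`). Two boundary rules are deliberate: a sequence
shorter than the window yields one whole-sequence window; and when
$L - 60$ is not a multiple of the step, one extra *full-length* window is
anchored at $L-60$ rather than truncating the tail, so every base is
scored by at least one full window. Scanning is sense-strand by default
(pre-mRNA semantics) with a `both_strands` flag. The neural-network score
some screeners add (threshold 0.5) is a trained model rather than a
formula and is out of scope here; its config slot exists only in
documentation.

## Intra-exon duplication detection

For each offset $d$, the sequence is compared against itself shifted by
$d$, and maximal windows with at most `max_mismatch` Hamming mismatches
are extracted. Window length is capped at $d$ — otherwise the two copies
would overlap — and a window is maximal when no one-base extension of both
intervals stays within bounds, budget and cap. Windows contained in a
longer window at the same offset are suppressed; different offsets are
independent repeat structures and all reported. Output is deterministic,
sorted by length (desc) then position.

Hamming extension (no gaps) is the right model for near-identical recent
duplications such as the 33-nt block in expanded first exons; `min_len`
defaults to 20 so that a 33-nt duplication is found while random ~100-nt
sequences rarely produce hits. One sharp edge documented here: if the
mismatch budget exceeds the true divergence of the two copies, maximal
windows necessarily absorb flanking bases (extension only stops when the
budget is spent), so *exact* coordinate recovery is expected at a budget
equal to the planted divergence — the setting the self-checks and
acceptance tests use. The exhaustive all-pairs oracle in the test suite
applies the same maximality predicate by direct enumeration.

## The synthetic generator

`generate_doublet_gene()` builds a pre-mRNA with the reference doublet
architecture: 50-nt intronic flanks, first exon, 300-nt intron, 150-nt
second exon. The unexpanded first exon is 52 nt; the expanded one is
109 nt, i.e. the 52-nt ancestral exon with a 57-nt insertion placed after
a 33-nt block A:

```
[head 10][block A 33][separator 7][block A' 33][pad 17][tail 9]
```

where `[separator][A'][pad]` is the insertion and `A..pad` forms a 90-nt
purine region. Block A′ is block A with exactly `dup_mismatches`
(default 1) purine↔purine substitutions, so the copies' purine composition
matches. The pG4-like segment is a 68-nt window inside the purine region,
centered by default; its offset is exposed because the true overlap
geometry between pG4, duplication and insertion is a free choice, and a
large offset lets it straddle the exon 3′ boundary into the intron.

Composition is sampled exactly, not i.i.d.: the insertion receives
$\mathrm{round}(0.95 \times 57) = 54$ purines, so its purine fraction is
exact up to rounding and tests can assert it without tolerance windows. A
single cytosine is planted mid-pad, mimicking the lone pyrimidine observed
inside real pG4 segments; the remaining pyrimidine budget goes to block A
(hence also A′). Purine stretches are built from G-run tokens capped at
`g_run_max = 2` separated by A spacers — G-dense enough that 60-nt windows
over the region exceed the G4Hunter threshold, yet with no run of 3, so
the canonical G4 motif can never match. This reproduces the defining
tension of pG4: strongly G4-prone by run-based scores while failing the
most stringent motif requirement. Specs that break this tension
(`g_run_max` 0 or ≥ 3) are rejected as unsatisfiable.

Two boundary bases are pinned so that the planted duplication is *exactly*
maximal: the base before block A is a pyrimidine (mismatching the
separator's last base at offset 40) and the separator's first base differs
from the pad's first base. After assembly, the model is self-checked
against its own invariants — exact insertion composition, planted Hamming
distance, exact duplication recovery, zero canonical matches in the
pG4-like segment, at least one G4Hunter window call over it — and a
violated check triggers regeneration from a derived attempt seed (bounded
at 50; across seeds 1–20 the first or second attempt suffices). All
randomness flows through a splitmix-style seed derivation, generation
leaves the caller's RNG state untouched, and cohort members
(`generate_cohort()`, alternating expanded/unexpanded) can be regenerated
individually from their derived seeds.

`generate_score_table()` pairs the gene models with a matched score table:
background scores i.i.d. normal (sd 0.05, truncated to $[-1,1]$), the
purine-only hexamers — the insertion's vocabulary — planted at 0.5, and
AGAAGA at 1.034, the published maximum of the real table, which keeps
synthetic tables on the real scale. Planted values outside $[-1.05, 1.05]$
are rejected.

What the generator does *not* emulate: real exons are protein-coding and
far from uniform in base composition; real backgrounds contain repeats,
GC skew and autocorrelation; real doublets differ between paralogs; and
the recombination history that created the expansion is not modelled.
Passing tests therefore demonstrate correctness of the algorithms under
controlled architecture, not performance claims on genomic data — real
analyses require a real hexamer table and real sequences via the FASTA/BED
interfaces.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to exercise every code
path while keeping the full suite in minutes: 200 random sequences
(6–80 nt) for the profile oracle, 100 sequences (≤ 60 nt) for the
exhaustive duplication oracle, 20 generator seeds for end-to-end planted
recovery, 1000 null replicates for the type-I error, 500 sequences for
G4Hunter antisymmetry. Profile agreement with the oracle is required to
1e−12 (the two computations may sum in different orders); the t-test
p-value agrees with numerical integration to 1e−6. Ties in peak calling
resolve leftmost; `find_peaks` on an all-`NA` stretch calls nothing rather
than erroring. Coordinates are 0-based half-open everywhere internally and
on disk (BED convention); only human-readable summaries print 1-based
views.
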