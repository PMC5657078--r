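---
title: "Three-letter bisulfite alignment with chemistry validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-letter bisulfite alignment with chemistry validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bisulfitr)
library(dplyr)
```

## The problem

Bisulfite treatment converts unmethylated cytosine to uracil, which PCR
reads out as thymine; methylated cytosine is untouched. A sequenced
bisulfite read therefore differs from the reference at every unmethylated C,
and aligning it naively fails. The standard remedy — the three-letter
strategy — collapses the distinction before alignment: the reference is
copied twice, once with every C replaced by T and once with every G replaced
by A (the Crick-strand mirror of the same collapse), reads are converted the
same two ways, and alignment happens in the reduced alphabet.

The collapse is lossy, and that is the crux this package is built around.
Once C and T are identical, a read can land on loci it never came from: the
read `AGACCCATG` aligns cleanly onto a reference window `AGATTTATG` in
converted space, although the chemistry forbids it — conversion turns C into
T, never T into C, so a read C sitting over a reference T is impossible.
`bisulfitr` implements the full pipeline around that observation:

1. **conversion** — C→T / G→A copies of reads and reference, with a strand
   task table that fixes which converted read copy is searched against
   which reference copy;
2. **alignment** — two-tier k-mer seed-and-extend in converted space,
   strict first, permissive (gapped) only for reads the strict tier leaves
   unmapped;
3. **validation** — every candidate is re-scored on the *original*
   sequences, each column classified under the chemistry, impossible
   columns rejected (with SNP tolerance), duplicates merged, and one
   verdict emitted per read;
4. **calling** — per-cytosine methylation counts in CpG/CHG/CHH context;
5. **rendering** — color-coded alignment views for terminal and HTML;
6. **simulation** — a bisulfite read simulator with conversion failure and
   per-cycle error, plus mappability scoring, so the whole pipeline is
   testable without external data.

## The strand model

A bisulfite library presents four distinct strands: the converted Watson
strand (OT), the converted Crick strand (OB), and the PCR reverse
complements of each (CTOT, CTOB). Each maps to exactly one combination of
(read conversion, reference space, orientation):

```{r}
strand_tasks()
```

The low-level aligner never searches reverse complements on its own — a
converted read is only ever compared against a converted reference copy of
the same strand, and orientation is applied explicitly from this table.
This matters: with C collapsed into T the reverse complement of a converted
read is *not* the conversion of the reverse complement, so an aligner that
silently tries both orientations in one space produces strand-impossible
hits. The consistency of the table rests on the identity
`c2t(revcomp(s)) == revcomp(g2a(s))`, which the test suite checks on
random strings.

By default all four tasks are searched (`mode = "non-directional"`), since
the conversion step produces both copies for every read; `"directional"`
restricts to OT/OB for the common directional protocol.

## Two-tier alignment

Tier 1 emulates a conservative end-to-end mapper: seeds of `k = 20` placed
non-overlapping at stride `k` plus one seed flush with the read end, no
gaps, at most 2 converted-space mismatches. The flush seed guarantees a
clean seed exists whenever the mismatch count is below
`floor(read_length / k)`. Tier 2, run *only* for reads tier 1 leaves
without a single candidate, emulates a high-recall mapper: `k = 12`, up to
5 mismatches, gapped end-to-end extension of the read against a reference
window widened by `band = 8` bases on each side (the dynamic programming is
done by `Biostrings::pairwiseAlignment`, read-global/reference-local, with
the same scores). A read's candidate list never mixes tiers, and a tier-1
verdict can never be changed by enabling tier 2 — the strict tier's output
is final for the reads it maps.

Converted-space scoring is match +1, mismatch −2, gap `−(5 + 3·len)`.
These values are a documented implementation choice (the two tiers only
need a consistent ranking); every numeric expectation in the tests is
stated against them. A candidate is kept when its score reaches the floor
implied by the mismatch budget, `L − 3·max_mismatches` for a read of length
`L`. `N` never seeds (k-mers containing N are not indexed and not looked
up) and scores as a mismatch during extension, including N-over-N.

Candidates are deduplicated per locus, sorted by (score desc, contig,
start) and capped at `max_candidates = 10` per read and task. Ambiguity is
judged later, after validation, so the cap only needs to retain the
plausible loci.

## Chemistry validation and filtering

Every candidate is re-walked over the original read and original reference
(reverse-orientation tasks are reverse-complemented into reference
orientation first; code strings are stored in that orientation,
column-aligned with the SAM `SEQ` field and the `XM:Z` tag). Columns are
classified:

| code | meaning                              | CT-space rule          |
|------|--------------------------------------|------------------------|
| `.`  | non-cytosine match                   | ref == read, not C     |
| `M`  | methylated call                      | ref C, read C          |
| `U`  | unmethylated (converted) call        | ref C, read T          |
| `x`  | ordinary mismatch (also insertions)  | anything else          |
| `X`  | bisulfite-invalid match              | ref T, read C          |
| `S`  | mismatch excused by a known variant  | alt allele == read base|

The GA space mirrors the rules (`M` = ref G/read G, `U` = ref G/read A,
`X` = ref A/read G). The validated score is +1 per `.`/`M`/`U`/`S`, −2 per
`x`, −8 per `X`, minus gap penalties. The −8 is deliberately heavier than
an ordinary mismatch: even when the user raises `max_invalid` above its
default 0, a chemistry-violating placement should lose every tie against a
clean one. The default `max_invalid = 0` is the strict reading of the
chemistry; it is exposed as a parameter because a sequencing error can turn
a genuine base into a spurious C (at a typical 0.1–0.6% per-cycle error
rate roughly 2–3% of 75 bp reads acquire one such artifact and are dropped
— visible in the audit log as `bisulfite-invalid`, and the price of a
near-zero false-mapping rate).

SNP tolerance requires the variant's alt allele to *explain* the observed
read base at that exact position — matching (contig, position, reference
allele, observed base) — not merely any known variant nearby. Enlarging
the SNP set can therefore only raise scores and never flips a kept
alignment to rejected (a property test asserts this).

Duplicates — the same (contig, start, original strand) reached through
different tiers or through task pairs that collapse to the same original
strand — keep the best-scoring copy. A read is `unique` iff exactly one
candidate attains the maximal validated score (an optional
`min_score_gap` margin is available, default 0, matching the plain
"uniquely mapped" definition), `ambiguous` on ties (all equal-best loci are
retained and rendered), `unmapped` otherwise. Ambiguous reads are written
to SAM at their first equal-best locus with MAPQ 0 (unique gets 42) so the
output round-trips; they contribute nothing to methylation calls.

## The simulator as study condition

The simulator defines the conditions the package is validated under:
i.i.d. random genomes (default 50 kb, GC 0.42 — a mammalian-like figure),
uniform read loci, Illumina-like 75 bp reads, per-context methylation
planted independently per cytosine (defaults CpG 0.70, CHG 0.02, CHH 0.02
— configurable stand-ins for typical mammalian somatic levels), conversion
failure 1% (an unmethylated C escaping conversion is recorded as
*unmethylated* in the truth — it is a chemistry artifact, not biology), and
per-cycle substitution error interpolated linearly from 0.1% to 0.6%
across the read. Paired mode draws template lengths from a truncated
normal (defaults 250 ± 25) and places the forward-oriented task leftmost
with its opposite-strand partner (OT↔OB, CTOT↔CTOB) rightmost; the
simulator and `pair_mates()` share that one table, which makes the pairing
contract testable by round trip.

What the simulator deliberately does not emulate: repeat structure and
low-complexity regions of real genomes (uniqueness is easier on i.i.d.
sequence, so simulated mappability is an optimistic bound), empirical
quality-score profiles, indel sequencing errors, PCR duplicates, M-bias,
and RRBS fragment selection. Passing tests demonstrate the *logic* —
chemistry filtering, strand bookkeeping, tier interaction, recovery of
planted methylation — not performance on any real genome.

Evaluation uses the two standard summary metrics: **mappability**, the
percentage of reads uniquely mapped over all reads, and **correct
mappability**, the percentage of reads whose unique mapping is at the true
locus (exact start by default; a `tolerance` is available for gapped runs,
since an indel can shift the reported leftmost base).

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; SAM POS and VCF
  POS are converted exactly once at I/O, which keeps off-by-one errors out
  of the core.
* Qualities are carried through to output but ignored in scoring; scores
  are integer throughout.
* The permissive tier extends end-to-end (CIGAR over `M`/`I`/`D` only, no
  soft clips): chemistry classification needs every read base accounted
  for, and a soft-clipped tail would silently hide invalid columns.
* Gap placement within a run of identical bases is score-degenerate; the
  DP engine's choice is deterministic, and tests assert score and span
  rather than one canonical CIGAR.
* Ties between equal-best loci are broken by (tier, contig, start, task) so
  results are independent of candidate arrival order.
* Methylation context at a contig edge (no base beyond the cytosine)
  defaults to CHH.
* Run sizes in the test suite — 2,000 × 75 bp reads on 50 kb genomes for
  the mapping checks, 20× coverage on 50 kb for methylation recovery
  (≈13,300 reads, ≈4,400 CpG sites) — are chosen so that planted-parameter
  recovery bands are several binomial standard deviations wide at the
  realized site counts.
* With methylation planted per site as a Bernoulli draw, the *realized*
  mean CpG level on one genome differs from the nominal level with SD
  ≈ `sqrt(p(1-p)/n_sites)`; recovery checks must either compare against the
  realized level or use enough sites that the band dominates this noise
  (the suite does the latter). The observed level is also inflated by
  conversion failure: expected observed = `level + (1 − level)·failure`.

## A worked run

```{r}
cfg <- sim_config(genome_length = 10000, n_reads = 400,
                  conversion_failure = 0.01,
                  error_rate_start = 0.001, error_rate_end = 0.006,
                  directional = TRUE, seed = 42)
d <- simulate_dataset(cfg)
fit <- bs_align(d$reads, d$genome, mode = "directional")
glance(fit)
```

```{r}
evaluate_mapping(fit, d$truth) |> glance()
```

```{r}
rep <- methylation_report(fit)
rep |> filter(context == "CpG") |>
  summarise(sites = n(),
            level = sum(n_methylated) / sum(n_methylated + n_unmethylated))
```

The worked false-mapping example, straight through the classifier:

```{r}
cand <- tibble::tibble(read_id = "r", mate = NA_integer_, task = "OT",
                       contig = "ref", start = 0L, cigar = "9M",
                       conv_score = NA_integer_, tier = 1L)
cl <- classify_alignments(cand, tibble::tibble(read_id = "r", seq = "AGACCCATG"),
                          c(ref = "AGATTTATG"))
cl$codes
filter_alignments(cl)$reason
```

And a rendered view (the `text` style wraps styled bases as
`[class:base]`; `ansi` and `html` styles color them):

```{r}
uid <- with(fit$verdicts, read_id[status == "unique"][1])
cat(render_read_report(fit, uid, width = 60, style = "text")[1:4], sep = "\n")
```

## Limitations

The aligner is a desk-scale reference implementation: a hash k-mer index
over plain R strings, practical for genomes of megabase scale and below,
not an FM-index able to hold a mammalian genome. External aligners could be
slotted in behind the same candidate-list contract, but no adapter ships
here. RRBS-specific handling, base-quality-aware scoring, PCR-duplicate
marking and differential-methylation statistics are out of scope.
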