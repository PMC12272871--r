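---
title: "Profiling transcript termini from adaptor-ligated reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling transcript termini from adaptor-ligated reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtseq)
```

## The problem

Run-off in vitro transcription with single-subunit phage RNA polymerases
(T7 and its relatives) should, ideally, produce one RNA species: initiation
at the +1 base of the promoter and termination exactly at the physical end
of the linear DNA template. Real products are heterogeneous at both ends:
initiation can slip a few bases around +1, the enzyme can prepend
non-templated Gs, termination can occur early (notably inside hairpin
structures), the 3' end can acquire one or more non-templated nucleotides
(NTA), and the polymerase can re-initiate from the transcript's own 3' end
after it folds back on itself, appending the reverse complement of an
upstream region ("self-templating"). Degradation during the reaction and
library preparation adds fragments unrelated to either terminus.

`ivtseq` implements the deep-sequencing readout of this heterogeneity. Both
transcript ends are interrogated through ligated adaptor oligos: reads
containing the 5' adaptor anchor `ATGGCAGTCACA` contribute the following
20 nt as the 5'-terminal window; reads containing the internal tag
`ACTATTGCTTTCACG` (placed 50 nt before the template 3' terminus) followed by
the 3' adaptor anchor `CACGAGCGTTTT` contribute the bases between tag and
adaptor as the 3'-terminal segment. A correct run-off product therefore
yields a 50-nt segment equal to the template suffix.

The headline statistic is the **run-off fidelity**

$$f = \Pr(\text{size} = s_0) \times \Pr(\text{correct sequence} \mid \text{size} = s_0),$$

with $s_0$ the expected segment size (50 nt here). This product is an exact
factorization of the joint fraction of reads that have both the right size
and the right sequence; `direct_runoff_fraction()` computes the joint form
and the test suite asserts the identity on every record set.

## Pipeline stages

1. **Extraction** — `extract_five_prime()` / `extract_three_prime()`:
   exact, leftmost anchor matching (the underlying protocol scripts use
   exact containment; no mismatch tolerance is applied). The 3' adaptor is
   searched only downstream of the tag so adaptor-like sequence elsewhere in
   the read cannot truncate the segment. Reads failing a filter are counted,
   and `run_pipeline()` reports the per-filter accounting, mirroring how
   analyzed read numbers are reported alongside the tables.
2. **Tabulation** — `five_prime_table()`, `size_distribution()`,
   `top_sequences_at_size()`: exact counts, frequencies normalized by the
   number of analyzed records (the per-size top tables renormalize within
   their size class). Ordering is count-descending with lexicographic
   tie-breaks, so reports are deterministic.
3. **Classification** — `classify_five_prime()` applies a fixed precedence:
   templated +1 start, then shifted start (|offset| ≤ `search_span`, default
   10), then non-templated identical leading bases before a +1 start, then
   unrelated. Requiring the stripped leading bases to be a homopolymer run
   matches the extra-G phenomenon and avoids double explanations of mixed
   prefixes. `classify_three_prime()` distinguishes correct run-off,
   templated truncation, self-templated extension, non-templated addition
   and unrelated; the self-templated call requires the observed extension to
   be a prefix of the fold-back prediction and at least `min_match = 3` nt
   long, which keeps 1–2-nt NTA tails from being misattributed to
   fold-back.
4. **Fidelity** — `fidelity_report()` bundles modal size, frequency at the
   expected size, correct-sequence ratio at that size and their product.

## The fold-back model

`fold_back_extend()` models self-templating mechanistically: the longest 3'
suffix (≥ `min_duplex = 3` nt) that is the exact reverse complement of an
internal window ending strictly before the suffix is taken as the annealing
duplex; ties between windows go to the 3'-most window, mirroring the
physical proximity of the fold-back loop. The predicted extension is the
reverse complement of everything 5' of the annealing window, appended in
synthesis order; an optional cap keeps the first-synthesized bases, encoding
agnostically whether extension stops by polymerase drop-off or read length.

`find_hairpins()` deliberately replaces thermodynamic folding with an
exact-stem search (maximal exact reverse-complement arms, loop 3–8 nt, stem
≥ 4 bp, no G·U wobble by default): the analysis only needs the existence and
register of a duplex, not its free energy, and the exact-stem rule keeps the
detector free of parameter fitting. Both functions are verified against
brute-force enumeration oracles on thousands of random sequences.

## The synthetic read generator

No raw sequencing data accompany the published measurements, so the
generator is a first-class part of the package: it draws transcripts from an
explicit mixture over terminal error modes, records per-read truth labels,
and ligates the adaptor oligos in silico. Sampling order is start offset →
extra 5' Gs → end mode → degradation → substitution errors, from a single
seeded RNG stream; the same seed gives byte-identical FASTQ output within
this implementation (seeds are portable across implementations only at the
statistical level).

Two modeling choices deserve justification:

* **Extra Gs are conditioned on a +1 start.** The 5' classifier can only
  attribute non-templated leading bases to a +1 initiation (stripping them
  must leave a +1 match), so the generator adds extra Gs only to +1 starts.
  Consequently the T7 preset sets the probability of *initiating at +1* to
  0.37 = 0.28 (clean +1) + 0.09 (extra-G), so that the measured +1-window
  frequency and extra-G fraction recover the published 28% and 9%.
* **Degraded reads are strictly internal fragments** (≥ 20 nt, touching
  neither terminus). A fragment retaining an intact terminus is
  observationally identical to a standard (possibly truncated) product, so
  allowing it would make truth labels ambiguous and silently inflate the
  correct-terminus counts.

### Presets

`preset()` encodes one configuration per enzyme whose true parameters equal
the published measurements: +1-start fractions 28/22/46/60% (T7, KpnP,
Ro45Iw, CD23823), T7 extra-G 9%, correct-run-off fractions
0.93/5.2/2.6/29%, correct-ratio-at-50-nt 22.5/88.2/83.3/97.4%, and modal
segment sizes 52/51/40/50 nt produced by the mechanistically appropriate
dominant mode: T7 by a −10 hairpin stop followed by fold-back extension
capped at 12 nt (40 + 12 = 52 nt), KpnP by single-nucleotide NTA (51 nt),
Ro45Iw by premature termination at the −10 hairpin (40 nt), CD23823 by
correct run-off (50 nt). The incorrect-sequence mass at exactly 50 nt that
the correct-ratio values imply is realized as fold-back products capped at
10 nt (40 + 10 = 50).

Mass not pinned by a printed value is a modeling choice, not a published
number: minor shifted starts decay away from +1; residual 3' mass is spread
uniformly over premature stops at offsets −1…−35 (small enough per site
never to compete with the modal peak); NTA tails default to uniform base
composition; and a nominal 0.2% of reads are degradation fragments.
Published data show unquantified degradation-derived "unrelated" sequences;
the pipeline measures every statistic relative to all analyzed reads, so a
large degradation fraction would bias every recovered parameter downward —
the presets therefore keep this channel small and attribute interruption
mass to premature stops, which the data do motivate. Preset error rate is
zero: the published percentages are post-sequencing measurements, so the
mixture parameters absorb them directly (the substitution channel exists
for sensitivity studies).

### The packaged template

`default_template()` returns a fixed synthetic 250-nt template (it is *not*
the luciferase-derived fragment of the original protocol; only its designed
features matter). The frozen body was searched under verified constraints:
unique tag site ending 50 nt before the terminus; a hairpin whose 6-bp stem
ends at terminus offset −10 (loop 4 nt) so that a −10-truncated transcript
folds back with a unique 12-nt extension whose first base does not continue
the template; no off-target occurrence of tag or adaptor anchors on either
strand; and 5'-terminal windows distinct across all start offsets used by
the presets. The +1 base is `G` (T7/KpnP/Ro45Iw-style promoters) or `A`
(CD23823-style), selected by `plus_one`; the upstream sense context is the
class-III T7 promoter sequence, used here as a generic placeholder for all
four enzymes.

## Promoter-candidate filtering

`select_candidates()` implements the downstream filter applied to motif
predictions: keep motifs occurring at least `min_hits = 2` times in the
genome ("multiple times") with at least one same-strand occurrence whose 3'
end lies within `upstream_window = 100` nt of an ORF start, and rank by
ORF-upstream count, then total count, then sequence. The source procedure
states neither threshold; both defaults are explicit, configurable
arguments, and the gap convention (0 = motif immediately abutting the
start) is documented in the function help. Candidate generation itself
(e.g. PhagePromoter) is out of scope — the filter consumes any motif list.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open throughout; the single signed
  convention for 3' ends is the terminus offset (−10 = ends 10 nt early).
* All sequences are held in the DNA alphabet in transcript sense; `U` is
  normalized to `T` on ingest; non-IUPAC characters are errors, not
  warnings.
* Frequencies are plain ratios of integer counts; tables must sum to 1
  within 1e-12 and the fidelity product identity holds to double precision.
* Empty inputs error with the stage name (`run_pipeline()` on an empty
  FASTQ names the extraction stage); absent sizes have frequency 0; an
  empty per-size table is returned empty rather than erroring.
* `percent_identity()` uses matches / columns with both-gap columns
  excluded and gap-vs-base counted as mismatch. Published inter-enzyme
  identity values depend on a specific aligner and an unstated formula and
  are not reproducible from sequences alone; the function documents its own
  rule instead.
* Ties: modal size → smallest size; frequency tables → lexicographic;
  fold-back windows → 3'-most.

## Problem sizes and what the tests show

The bundled verification runs use depth 1e5 per enzyme (binomial 3-SD bands
for recovered fractions), 1,000 reads for structural checks, and ≥ 1,000
random sequences for the oracle-equivalence suites; all complete in a few
minutes on one CPU. Passing them shows that the pipeline inverts the
generator's mixture exactly in the error-free case and within sampling
error at the published parameter values. It does not show robustness to
features the generator does not emulate: sequencing indels and quality-
dependent errors, ligation and PCR bias, RT artifacts, templates whose
terminal windows are not unique, or fold-back sites that only form under
thermodynamic (wobble-containing, imperfect) pairing. On real data the
exact-matching defaults will under-collect reads with errors in the anchors
and classify error-bearing windows as unrelated — conservative behavior
consistent with the exact-containment protocol the pipeline reproduces.
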