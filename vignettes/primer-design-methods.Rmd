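---
title: "Methods: thermodynamics and scoring behind stitchkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamics and scoring behind stitchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitchkit)
```

## The problem

Overlapping (fusion) PCR stitches DNA fragments together by amplifying each
piece with primers that carry a shared 5' tail: the tail on one amplicon is
complementary to the end of the other, so a second PCR round fuses them.
Typical applications are promoter::fluorophore reporter fusions and adding
sequencing adapters. Designing these primers means juggling the usual
single-primer constraints (length, GC%, melting temperature, repeats,
hairpins, self-annealing) plus constraints introduced by the tail itself
(overhang complementarity, cross-dimers between fusion oligos).

`stitchkit` takes one DNA sequence, enumerates forward primer candidates in
a 5' search area and reverse candidates in a 3' search area, annotates each
with thermodynamic and sequence-composition metrics, flags rule violations,
attaches overlap tails, and enumerates compatible forward/reverse pairs.
Everything is a tibble, so results compose with ordinary dplyr/ggplot2
workflows.

## Melting temperature

Primer Tm uses nearest-neighbor thermodynamics: enthalpy and entropy are
summed over the primer's dinucleotide stacks plus per-terminal duplex
initiation terms, and

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15
        + 16.6 \log_{10}[\mathrm{Na}^+]$$

with $R = 1.987$ cal mol⁻¹ K⁻¹, total strand concentration $C_T$ (default
250 nM; $C_T/4$ becomes $C_T$ for self-complementary primers, which also
receive the symmetry entropy correction), and the Schildkraut–Lifson
monovalent-salt shift. The default parameter table is the unified set of
SantaLucia (1998); the Breslauer (1986) table is selectable
(`thermo_model(set = "breslauer1986")`). Both ship as plain-text TSVs under
`inst/extdata/` so the numbers are auditable and swappable.

Two conventions worth knowing:

* **Salt.** The form-level choice is 50 mM (default) or 10 mM;
  programmatically any positive concentration is accepted. The Schildkraut
  shift at 50 mM places Tm about 21.6 °C below the 1 M reference value, so
  this scale runs several degrees lower than tools that use the
  entropy-based salt adjustment. The default acceptance window
  `tm_min = 45, tm_max = 55` °C was chosen to be coherent with this scale:
  it corresponds to the conventional 55–62 °C band on an entropy-corrected
  scale. If you change the salt correction convention in your head, change
  the window too.
* **Concordance, not identity.** Different published NN conventions agree
  up to a nearly affine transformation; the test suite and
  `scripts/acceptance.R` verify $R^2 \ge 0.98$ against an independently
  coded reference implementation over 544 random primers, which is the
  meaningful sense in which any two NN Tm engines "agree".

Duplex ΔG° is evaluated at 37 °C as $\sum_i (\Delta H_i - T\Delta S_i/1000)$
over the stacks of a contiguous complementary run. Initiation terms are
excluded by default because the runs being scored are internal segments of a
longer alignment, not free duplexes; `include_initiation = TRUE` restores
them. Divalent cations, dNTP corrections and dangling ends are out of scope.

## Complementarity scoring

`complementarity_scan(a, b)` slides `a` (5'→3') against `b` (3'→5') through
every ungapped offset — equivalently, slides `a` along
`reverse_complement(b)` counting equal characters. Gapless scanning is the
standard primer-screening simplification and is what makes an exhaustive
oracle feasible, so every offset is checked, deterministically: ties between
offsets go to the longer contiguous run, then to the smaller offset. The
report carries the total matches, the longest run and its ΔG°, and the
number of matches within `three_prime_window` (default 5) bases of either 3'
end — those are the extension-competent positions a polymerase can act on.

The weighted score combines the triad the screen cares about — match count,
3' emphasis, duplex stability:

$$W = \text{matches} + (w_3 - 1)\,\text{matches}_{3'} +
      \mathbf{1}[\Delta G^\circ_{run} < -6\ \text{kcal/mol}]$$

with $w_3 = 2$ by default. It is zero exactly when there are no matches and
weighting can only add. Self-complementarity is the scan of a primer against
itself; overhang scoring scans the 5' tail against the primer core, the
partner primer and itself and keeps the worst case; pair (dimer) scoring
scans the two full fusion oligos, tails included, because tails participate
in real dimers.

Cutoff defaults (`score_cutoffs()`: self 12, 3' 4, overhang 10, dimer 12)
are screening maxima, not hard chemistry; they are deliberately permissive
and all exposed. Per-candidate metrics (self, 3', hairpin) are computed on
the gene-specific core, and the per-candidate overhang gate tests the
tail-vs-core scan only: a fixed absolute cutoff cannot sensibly gate a
tail's *intrinsic* self-annealing, which grows with tail length (the
shipped 24–61 nt tails score 6–33 on their own) and which the user fixed
by choosing the tail. Tail-vs-partner and tail-vs-self annealing are
instead screened where they act — in the pair-stage dimer scan, which
always runs over the full fusion oligos. The standalone `overhang_score()`
report still returns the worst of tail-vs-core/partner/self for diagnostic
use. `hairpin_max` (default stem length 6) backs the hairpin
fail reason: stems longer than ~6 bp with a ≥3 nt loop are the conventional
nuisance range for 18–25-mers, shorter stems are ubiquitous in random
sequence and rarely matter at annealing temperature.

Hairpins are found by an exhaustive gapless fold search: every way to pair a
prefix-side arm with a suffix-side arm, requiring a loop of at least 3 nt
(the sterically minimal loop). The score is the longest stem; its ΔG° is
reported alongside. The test suite pins this to a brute-force enumeration
over all substring pairs.

## Candidate enumeration and filters

Forward candidates start at position 1 and step inward by `increment_fwd`
(default 2 bp) while the core stays inside the first `search_area_5p` bases;
reverse candidates are reverse complements of windows stepped inward from
the 3' end within `search_area_3p`. Before filtering the count is exactly
`floor((area - size)/increment) + 1`. Primer sizes constrain the
gene-specific core only — an attached overlap tail never counts toward
`fwd_size`/`rev_size`.

Filters annotate, never drop: each candidate accumulates one fail reason per
violated rule (`gc_range`, `tm_range`, `gc_clamp`, `repetitive`,
`self_complementarity`, `three_prime`, `hairpin`, `overhang`, `contains_n`)
and `pass` is true exactly when the list is empty, so near-misses stay
visible in the output tables. Specific rules:

* **GC clamp** (off by default): the 3'-terminal base must be G or C — the
  simplest standard definition.
* **Repeats** (on by default): a homopolymer run of ≥ 4 bases (`TTTT`) or
  ≥ 4 consecutive identical dinucleotide units (`CGCGCGCG`); three units
  (`CGCGCG`) pass.
* **N handling**: with `remove_n = TRUE` undesignated bases are excised and
  their original positions recorded; otherwise candidates containing N are
  annotated (`contains_n`, Tm undefined) but kept.

A pair is *compatible* when both primers pass individually, the reverse
primer lies 3' of the forward one, the Tm difference is ≤ `max_tm_diff`
(default 5 °C, the conventional pairing tolerance), and the cross-dimer
weighted score is ≤ `dimer_max`. All combinations are reported flagged,
sorted by ascending dimer score then descending product length.

Mutagenesis mode takes the forward mutant oligo, emits its reverse
complement, and picks a single flanking pair: the passing candidate in each
search area with the lowest weighted self score, ties broken by Tm closest
to the window midpoint, then by proximity to the sequence end — a
deterministic ranking favouring clean, well-centred, outermost primers.

## Synthetic inputs and what tests show

`generate_fixture()` draws i.i.d. bases at a target GC fraction, optionally
planting N's and a repeat motif at recorded positions, behind a single seed.
The default test input is 1 kb at 50% GC with 200 bp search areas — a
realistic promoter-fragment scale at which the default parameter set should
and does return non-empty primer and pair tables. An i.i.d. sequence has no
long-range structure, isochores, or genuine repeat families beyond what is
planted, so passing tests demonstrate the algorithmic contracts (counts,
coordinates, scores, filters, file formats), not wet-lab primer performance
on genomic templates.

All scoring primitives are pinned to independent oracles in the test suite:
Tm to a separately coded ΔH/ΔS summation (< 0.01 °C on random primers, and
$R^2 \ge 0.98$ against a reference using the other salt convention),
the scan to exhaustive offset enumeration, the hairpin search to an
exhaustive substring-pair enumeration (complete through length 6, sampled
at lengths 7–12), candidate counts to the closed form, and pair sets to a
cutoff-monotonicity property.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in R and in the TSV reports
  (bench convention); only the BED primer map is 0-based half-open, per the
  format.
* TSVs are UTF-8, tab-separated, `.` decimal; the JSON bundle mirrors the
  tables bit-identically for programmatic round-trips.
* All tie-breaks (scan offsets, mutant ranking) are specified and
  deterministic; the only randomness in the package is the fixture
  generator, behind an explicit seed.
* Degenerate inputs: empty scans are contract errors; sequences too short to
  fold score 0 hairpins; an empty passing set yields an explicitly empty
  summary rather than zeros; a design with zero passing primers still writes
  headered tables and warns.

## Limitations

No Mg²⁺/dNTP salt corrections, dangling-end terms or partition-function
secondary structure; gapless (no-indel) complementarity only; single-locus
designs (no multiplex/LAMP set construction); no sequence retrieval from
accession numbers. The weighted-score formula and cutoff magnitudes are this
package's own calibration of a match-count/3'-emphasis/ΔG° screen; treat
them as screening heuristics to tune per application, not as binding-energy
predictions.
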