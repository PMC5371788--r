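# stitchkit

Primer design for overlapping (fusion) PCR, as a tidyverse-native R package
with a command-line interface.

Overlapping PCR stitches DNA fragments together — promoter::GFP reporter
fusions, adapter-tagged amplicons, site-directed mutagenesis by overlap
extension — using primers that carry a fixed 5′ overlap tail complementary
to the partner fragment. `stitchkit` automates the design: it enumerates
forward and reverse primer candidates inside user-defined 5′ and 3′ search
areas of a single input sequence, annotates each with nearest-neighbor
thermodynamics and composition metrics, flags rule violations, attaches
predefined or user-supplied overlap tails, and enumerates compatible
forward/reverse pairs.

At its core:

* **Melting temperature** from nearest-neighbor ΔH/ΔS sums (SantaLucia 1998
  unified parameters by default, Breslauer 1986 selectable) with the
  Schildkraut monovalent-salt correction:
  `Tm = 1000·ΔH / (ΔS + R·ln(C_T/4)) − 273.15 + 16.6·log10[Na+]`,
  at 50 mM salt by default (10 mM option) and C_T = 250 nM.
* **Complementarity screening**: every ungapped antiparallel offset of one
  primer against another is scored; the report carries total matches, the
  longest run and its duplex ΔG° at 37 °C, matches near the 3′ ends, and a
  weighted score `W = matches + (w₃−1)·matches₃′ + 1[ΔG°run < −6]`. The same
  scan drives self-complementarity, hairpin, overhang (tail) and
  cross-dimer checks.
* **Filters that annotate, never drop**: GC%/Tm windows, optional GC clamp,
  homopolymer (≥ 4 nt) and dinucleotide (≥ 4 units) repeat exclusion, score
  cutoffs — each violation is a named fail reason, so near-misses stay
  visible in the output tables.

## Worked example

Design fusion primers that attach the *C. elegans* GFP overlap tail to the
reverse primers of a 1 kb fragment (here a seeded synthetic fixture; any
single-record FASTA works):

```r
library(stitchkit)

rec <- generate_fixture(seed = 7, length = 1000)
params <- design_parameters(overlap_selection = "named",
                            overlap_name = "GFP_Celegans")
des <- design_primers(rec, params)
des
#> <stitch_design> synthetic_fixture (1000 bp)
#>   forward candidates: 91 (16 passing)
#>   reverse candidates: 91 (12 passing)
#>   compatible pairs:   111 of 8281 combinations
```

91 candidates per strand is the closed-form count
`floor((200 − 20)/2) + 1` for a 200 bp search area, 20 bp cores and a 2 bp
increment. The candidate table is a tibble:

```r
dplyr::filter(tidy(des), pass, strand == "forward") |> head(2)
#>   name  strand  start   end core_seq             gc_percent tm_celsius self_weighted
#> 1 4F    forward     7    26 GACGCCACGCTCAGTGAAAC         60       51.8            12
#> 2 9F    forward    17    36 TCAGTGAAACTGAGTGCCGA         50       49.3            10
```

`gc_percent` and `tm_celsius` are computed on the gene-specific core (tails
never count toward the size or Tm); `self_weighted` is the weighted
self-complementarity score. Compatible pairs come sorted by cross-dimer
score, then product length:

```r
dplyr::filter(des$pairs, compatible) |> head(3)
#>   fwd_name rev_name product_len tm_diff dimer_weighted
#> 1 4F       24R              948    1.49              8
#> 2 13F      25R              928    1.72              8
#> 3 83F      78R              682    4.75              8
```

`product_len 948` means the fused amplicon spans positions 7–954 of the
input; `tm_diff ≤ 5 °C` and `dimer_weighted ≤ 12` are the pairing defaults.
The reverse primers already carry the tail; compare the printed fusion
oligo layout:

```r
build_fusion_primer(get_overlap("GFP_Celegans"), "GTGGTCGTGGGTTTGATG")
#> [1] "AGTCGACCTGCAGGCATGCAAGCTGTGGTCGTGGGTTTGATG"
```

`autoplot(des)` draws the primer map, `autoplot(des$composition)` the
sliding-window GC%/AT% profile, `plot_design_summary(des)` the min/average/
max bars of the designed-primer features, and `glance(des)` a one-row
overview. `run_design()` writes everything to disk (TSV tables, BED primer
map, JSON bundle, parameter log).

The same run from a shell:

```sh
Rscript exec/stitchkit design input.fa --overlap GFP_Celegans --outputs all --out results/
```

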