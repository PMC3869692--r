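---
title: "Uncovering cryptic symbiont strain and haplotype diversity from cloned MLST amplicons"
author: "symbiopoly authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncovering cryptic symbiont strain and haplotype diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiopoly)
```

## The problem

*Wolbachia* and similar maternally inherited endosymbionts are routinely
characterized by multilocus sequence typing (MLST): PCR amplification of a
fixed panel of housekeeping gene fragments (here *gatB* 404 bp, *coxA*
444 bp, *ftsZ* 478 bp, plus the *wsp* typing marker), cloning of the
amplicons, and Sanger sequencing of individual clones. When a symbiont is
transferred into a new host species by embryonic microinjection, the founding
symbiont sample is tiny, so any haplotype diversity present in the donor
passes through a severe bottleneck and drifts across host generations.
Clone libraries sequenced from such lines show two confounded signals:

1. genuine low-frequency symbiont haplotypes (including cryptic co-infecting
   strains at titers below standard detection), and
2. substitutions introduced by the non-proof-reading polymerase during PCR
   and cloning.

`symbiopoly` implements the complete analysis that separates these signals,
plus a forward simulator of the entire sampling process so that every
estimator can be validated against a known ground truth.

## Model and procedure

### Variant calling and recurrence

Each clone read is compared base-by-base against an explicit strain
consensus (a published reference haplotype — never a majority vote of the
reads, which would absorb exactly the diversity under study). Coordinates
are 1-based within the fragment. Any position where the read (or consensus)
carries an IUPAC ambiguity code is excluded from calling; this is the
automated analogue of discarding SNPs that fail visual chromatogram
inspection.

A variant identity is a (position, alternate base) pair. An identity
observed in two or more *independent clones* — whether from one line, from
several lines, or across host systems — is **recurrent**; an identity seen
in exactly one clone is a **singleton**. Recurrent variants are the
fingerprint of real haplotypes (independent clones do not share polymerase
accidents), while singletons are a mixture of rare haplotypes and error.

### Error baseline

The polymerase/cloning error rate is estimated by re-PCR and re-sequencing
of known control fragments and pooling counts:

$$\hat e = 1000 \cdot \frac{\sum_i x_i}{\sum_i n_i L_i} \;\text{SNPs/kb},$$

with an exact (Clopper–Pearson) binomial interval. On the packaged control
counts (0 errors in 4.44 kb + 2.90 kb, 2 errors in 6.00 kb) this gives
0.15 SNPs/kb. A second constant, 0.28 SNPs/kb, is the baseline the source
frequency table subtracts in its corrected columns; the two are never
reconciled in the source, so `corrected_frequency()` takes its baseline as
an explicit argument defaulting to 0.28 and both constants are exposed
(`pooled_error_rate()`, `table2_baseline()`, `published_taq_baseline()`).
Corrected rates are deliberately unclamped: a clean library reads
$0.00 - 0.28 = -0.28$.

### Frequencies and contingency tests

Group SNP frequency is $1000\,n/L$ per kb, displayed with half-up rounding
to 2 decimals while all arithmetic uses raw values. Two groups are compared
on the base-count table

$$\begin{pmatrix} n_A & L_A - n_A \\ n_B & L_B - n_B \end{pmatrix}$$

with the Yates-corrected chi-squared statistic
$\sum (\lvert O-E\rvert - 0.5)^2/E$ (continuity term floored at zero) on
1 df, or with the exact two-tailed Fisher test (full hypergeometric
enumeration, summing tables no more probable than the observed one with a
$10^{-7}$ relative tie slack). This base-count construction is the only one
that reproduces the published P values (e.g. 0.3346 for the donor strain
comparison at *gatB*). Where a published table prints a rounded rate but
not the count, `infer_count_from_rate()` inverts the rounding and errors
out rather than guess when no unique integer exists. No multiple-testing
correction is applied, mirroring the source analysis.

### Codon effects and NG86 dN/dS

All three MLST fragments are read at frame offset 0; this was validated
against the paired nucleotide/amino-acid variant rows of the source table
(nt 11 A→G with aa 4 E→G, nt 3 T→C synonymous at codon 1, and the nonsense
rows at nt 226 and 253 falling on first codon positions of CAA codons). The
fragment-level anchors quoted for the full-locus coordinates are internally
inconsistent and were not used for frame inference. A substitution is
nonsense iff the mutated codon is a stop (ochre TAA, amber TAG, opal TGA —
identical in the standard and bacterial codes) and the consensus codon is
not.

dN/dS follows Nei–Gojobori (1986) path counting with equal path weights:
each codon position contributes a fractional synonymous site equal to the
fraction of its three possible changes that are synonymous (changes to stop
codons count as nonsynonymous); sites are averaged between the two
sequences, so $S + N = 3 \times$ codons compared. Multi-hit codons average
their synonymous/nonsynonymous step counts over all orderings of the
differing positions, excluding paths through premature stop codons unless
no stop-free path exists (then all paths are used, with a warning) — so
$S_d + N_d$ always equals the nucleotide difference count. Proportions are
Jukes–Cantor corrected, $d = -\tfrac34\ln(1 - \tfrac43 p)$, and the ratio
is flagged undefined when $d_S = 0$ rather than forced. Clone-library
aggregation (the mean of defined pairwise clone-vs-consensus ratios) is a
package choice, stated and configurable, because the source aggregation is
unspecified.

### Strain typing, switches, detection power

Diagnostic typing scores a read per strain as the fraction of diagnostic
sites matching that strain's base; the argmax is called when unique and at
least 0.9, otherwise `unknown` (ties are never resolved probabilistically).
Because the true diagnostic haplotypes are not published, packaged profiles
are seeded synthetic stand-ins (`make_wsp_profile()`) and real profiles are
an input. Length-polymorphic (VNTR-style) markers type by amplicon length
within ±2 bp, approximating gel resolution. A line is co-infected when two
strains each reach the support threshold; a prevalence switch is localized
as (last generation the outgoing strain was detected, first later
generation the incoming strain appears alone). `detection_power()`
quantifies, by Monte-Carlo, the probability that a minor strain at a given
titer appears in an n-clone library — with error-free typing and a
single-read detection rule this must equal $1-(1-\text{titer})^n$, which
the tests verify.

### In-silico RFLP

`digest_genome()` cuts at each occurrence of a recognition site (default
HindIII `AAGCTT`, cut after base 1 to mirror A^AGCTT), on a linear or
circular topology; fragment lengths always sum to the genome length.
`probe_fragment_count()` counts fragments overlapping a probe locus by at
least 20 bp — a detectability stand-in that is configurable and explicitly
not an experimentally derived constant. All tests run on synthetic genomes
with planted sites; a real annotated genome is an optional input.

### Fecundity classes

Ovaries are classified by mature (stage-14) egg counts: class I = 0,
II = 1–2, III = 3–9, IV = ≥ 10. Distributions are compared either on the
2×2 class-IV-vs-rest table or on the full 2×4 table by exhaustive exact
enumeration; both constructions are reported because the source figure
does not state which produced its printed significances (its P = 0.004 for
the most affected line is not reproducible from the printed percentages at
n = 40 under either construction, and is therefore not an acceptance
value). Records are per ovary; `per_individual = TRUE` scores each
individual by its better ovary, covering the source's ovary/individual
ambiguity.

## The simulator: a stated world

`simulate_study()` generates the complete data-generating process:

* **Donor pool** (`make_pool()`): a canonical haplotype plus rare
  haplotypes differing at drawn sites, at stated frequencies (default: 5
  haplotypes, canonical at 0.92, four rare at 0.02 each — a "rare haplotype
  coexisting with the canonical one" world at the frequency scale the
  recurrence analysis presumes).
* **Bottleneck** (`bottleneck_and_drift()`): a multinomial founding sample
  of size $N_b$ (default 100) from the donor frequencies, then neutral
  Wright–Fisher multinomial resampling at effective size $N_e$ (default
  1000) per host generation. Drift and selection are invoked only verbally
  in the source; resampling is neutral by default with an optional
  per-haplotype fitness vector. $N_e$ has no published value and is an
  explicit free parameter.
* **Transmission**: maternal transmission is a per-generation Bernoulli —
  0.65 for the first 5 generations and 0.95 after, the two published
  prevalence anchors (65% shortly after transfer, 95% later). Lines are
  conditioned on retention by default, mirroring the source's selection
  regime in which only PCR-positive females found the next generation;
  failures are counted in the ledger.
* **Clone re-sequencing** (`sequence_clones()`): each clone draws a
  haplotype from the current frequencies and receives i.i.d. per-base
  errors at $1.5\times10^{-4}$ (0.15 SNPs/kb, the estimated baseline),
  uniform over the three alternate bases; PCR and cloning are lumped into
  one process because only the lumped rate is published. Default 12 clones
  per sample, the per-line clone depth of the *gatB* panel.
* **Planted switch**: on request, an observation series over seven
  non-consecutive generations in which the major strain is last seen at the
  window start and the minor strain first appears alone at the window end;
  the transition period itself is unobserved, as in the published time
  course, so `locate_switch()` must recover exactly the planted window.

Every output carries a ledger (true haplotype per clone, injected error
positions, frequency trajectories) that fully determines the expected
pipeline results; identical seeds give bitwise-identical outputs.

What the generator does **not** emulate: chimeric PCR products,
recombination between strains, PCR-cycle-dependent error accumulation,
within-host spatial structure, and chromatogram-level noise. A green test
therefore establishes that the estimators are correct for the stated
sampling model, not that the model captures every artifact of real clone
libraries.

## Packaged fixtures and their known inconsistencies

Full amplicon sequences are not printed in the source tables, so fixture
sequences apply the published variant positions and consensus bases to a
seeded synthetic background constrained to (i) contain the anchor codons
above, (ii) contain no spurious in-frame stop in the consensus, and (iii)
create no stop via any non-nonsense variant. Every downstream statistic
depends only on positions and counts, not on the background.

The published tables disagree with each other in four places, and the
fixtures carry the disagreements rather than resolve them
(`table2_discrepancies()` flags them at run time): one line shows a variant
but prints a 0.00/kb rate; another line's printed rate implies one
occurrence fewer than its recurrence annotation requires; the donor row
shows 8 occurrences where the text says 9 (the frequency itself, 1.01/kb,
is reproduced from the printed 9-in-8,888 counts); and the pooled
recipient row's printed rate matches no integer count on its printed base
total.

## Numerical choices

* Display rounding is half-up (away from zero) to 2 decimals; tests and
  arithmetic use raw values.
* Fisher ties use a $10^{-7}$ relative slack; the r×c exact test compares
  log-probabilities with the same slack.
* Yates flooring: the continuity term is clamped at zero when
  $\lvert O-E\rvert < 0.5$; a zero margin returns p = 1 with a warning
  instead of NaN.
* The Jukes–Cantor transform is undefined at $p \ge 0.75$ and returns NA.
* The fixture seed and all simulator seeds are fixed integers below
  $2^{31}$; user-facing functions take `seed` arguments and never reseed
  implicitly unless one is supplied.

## A worked example

```{r example}
amp <- load_fixtures("gatB_table1")
calls <- call_snps(amp)
summ <- summarize_recurrence(classify_recurrence(calls))
unlist(summ)

pooled_error_rate(load_fixtures("taq_controls"))

a <- snp_frequency(infer_count_from_rate(0.52, 9696), 9696, "wCer1 donor")
b <- snp_frequency(9, 8888, "wCer2 donor")
compare_groups(a, b)$p_two_tailed

scan_premature_stops(load_fixtures("ftsZ_table3"))
```

## Limitations

Indels, alignment gaps and quality-aware calling are out of scope
(amplicons are fixed-length by design, and length-mismatched reads are a
hard error naming the clones). The exact r×c Fisher enumeration is feasible
only for small tables (tens of observations per row). dN/dS is the NG86
counting estimator, not a codon-model maximum-likelihood estimate, and on
clone-vs-consensus pairs with one or two differences individual ratios are
extremely noisy — they are meaningful only in aggregate. Printed source
values whose underlying counts are not published (two line-level P values,
one fecundity P value, and the expected probe fragment counts) are
documented as non-reproducible and are not asserted anywhere in the test
suite.
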