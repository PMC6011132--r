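---
title: "Microsatellite marker discovery and evaluation with ssrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite marker discovery and evaluation with ssrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
library(dplyr)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem repeats of 1-6 bp
motifs. Because replication slippage makes their copy number hypervariable,
they are the classic codominant marker for population genetics in
non-model organisms. When no genome is available, markers are developed from
an assembled transcriptome: perfect repeats are mined from the unigenes,
primers are designed in the flanking sequence, and the loci that amplify
cleanly and vary are then genotyped in population samples and summarised
per locus. `ssrkit` implements this whole chain in R, from FASTA to the
per-locus marker statistics table, for data sets such as a survey of the
nipa palm hispid beetle (*Octodonta nipae*), an invasive pest of palms in
southern China, where 1,274 SSR loci mined from ~50,000 unigenes funnelled
down to a nine-marker panel genotyped in two populations of 12 beetles.

## Mining model

`find_perfect_ssrs()` reports every **maximal perfect run** of a
**primitive** motif (a motif that is not itself a repetition of a shorter
word). Each run is reported exactly once, under its shortest primitive
period: a poly-A stretch is one mononucleotide locus, never additionally an
AA or AAAA locus. Partial trailing copies are truncated — `(AC)6A` is six
repeats ending at the last full copy — so reported repeat counts are whole
numbers, matching how published frequency tables bin them. Any character
outside A/C/G/T (including N, which assemblies do contain) breaks a run;
the fragments on either side are scored independently. Only the given
strand is scanned: transcripts are single-stranded, and strand symmetry is
handled later at classification.

The default reporting thresholds are minimum full-copy counts of
12, 6, 5, 5, 4, 4 for motif lengths 1-6 — the settings under which the
reference beetle survey was mined — and are adjustable through
`ssr_thresholds()`. The miner is validated two ways: exact equivalence
with an independent brute-force enumeration oracle on random repeat-rich
sequences (up to 200 bp; 1,000 sequences in the acceptance suite), and
100% recall / 100% precision on simulated transcript sets whose implants
are the only repeats present by construction.

## Canonical motif classes

A repeat observed as `CTT` on a transcript is the same genomic feature as
`TTC`, `TCT` (phase) or `AAG` (opposite strand). `canonical_motif_class()`
therefore groups motifs by rotation **and** reverse complement; the class
key is the lexicographically smallest rotation over both strands, and the
display label is the conventional pair form, e.g. `AAG/CTT` or `ACG/CGT`.
For self-reverse-complement classes, where both sides would read the same,
the label uses the second-smallest rotation on the right — producing the
familiar `AT/TA` — so the printed inventory of 4 dinucleotide and 10
trinucleotide classes is reproduced verbatim. Classification happens at
tabulation time; detection stays strand-literal.

`tabulate_frequencies()` builds the two standard survey matrices (by
repeat type and by motif class), with repeat-count bins 4-11 and >= 12 and
percentages of the grand total rounded **half-up** to 2 decimals — base
R's round-half-even would disagree with published tables on exact halves.
`count_high_repeat_loci()` sums the upper bins, e.g. the dinucleotide and
trinucleotide loci with >= 8 units (103 and 11 in the reference survey),
the length range where polymorphism is expected to be highest.

## Primer screening

`screen_primer_pairs()` enumerates primer placements in the flanks such
that the amplicon contains the full repeat, then applies hard constraints:
product 100-400 bp, primer 18-28 bp (optimum 23 bp), GC within 30-70%,
Tm within 50-65 °C, pair Tm difference <= 5 °C, and no perfectly
complementary run of 8+ bases within or between primers. Mononucleotide
loci are excluded by default — single-base runs genotype poorly and are
conventionally dropped before design. Melting temperatures come from the
unified nearest-neighbor thermodynamic parameters (SantaLucia & Hicks
2004) at fixed, recorded conditions (50 mM Na+, 25 nM per strand,
entropic salt correction), pinned in tests against an independent
implementation of the same table.

Commercial design suites rank candidates with undocumented scores. Rather
than imitate one, `ssrkit` uses an explicit penalty,

    |len_f - 23| + |len_r - 23| + w_tm |Tm_f - Tm_r| + w_gc * gc_dist,

with `w_tm` = 1 per °C, `w_gc` = 10 per GC fraction unit outside the
preferred band [0.45, 0.55], both recorded in `primer_constraints()`.
Ties break deterministically by leftmost forward start, then smallest
product. The weights are a design choice favouring balanced pairs near the
length optimum; the reproducibility of the ranking, not fidelity to any
particular commercial tool, is the goal.

## Marker statistics

For each locus and population, `summarize_locus()` reports the allele
count NA, observed heterozygosity Ho, Nei's **unbiased** expected
heterozygosity

    He = (2n / (2n - 1)) (1 - sum p_i^2),

and Botstein's polymorphic information content

    PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2.

The unbiased form of He is not optional here: only it reproduces the
printed 3-decimal values of the reference panel from integer genotype
configurations (e.g. He = 0.083 for 11 homozygotes + 1 heterozygote in 12
individuals; the plug-in estimator gives 0.080). This was verified with
`reconstruct_genotype_configuration()`, an exhaustive enumeration oracle
that recovers all genotype-count configurations consistent with a
published (n, NA, Ho, He) row — for the reference panel's On1 and On4 rows
the configuration is unique, and its implied PIC matches the printed
0.077 and 0.141. The oracle fixes the heterozygote count at
`round(Ho * n)` to keep enumeration tractable within its documented
bounds (n <= 50, NA <= 4); configurations equivalent under allele
relabeling are collapsed to one canonical representative.

Values are kept at full precision internally and rounded half-up to 3
decimals only in reports. A monomorphic sample forces Ho = He = PIC = 0;
where a published table prints a placeholder such as 0.001 for such cells,
the package reports the arithmetically forced 0. Missing calls are
dropped locus-wise (pairwise deletion), so each locus uses every
individual typed there.

## Hardy-Weinberg and linkage-disequilibrium testing

`hwe_exact_test()` implements the exact test conditional on allele counts
(Levene's distribution). A configuration with heterozygote count h has

    P = n! * prod_i m_i! * 2^h / ((2n)! * prod_{i<=j} n_ij!),

and the probability-test p-value sums P over all configurations no more
probable than the observed one; configurations tied with the observed
probability within a relative 1e-12 are included (the standard exact-test
convention). One-sided deficit and excess p-values sum the tails ordered
by heterozygote count, the follow-up used to ask whether a departure
reflects too few or too many heterozygotes. The full conditional
distribution is enumerated when it has at most 1e5 configurations — at
marker-panel scale (n = 12, 2-3 alleles) it always is, with the
enumeration memoised per allele-count vector — and otherwise a seeded
Monte-Carlo sample (default 1e6 random pairings of the observed allele
copies) is drawn and its standard error reported. Enumerated
probabilities summing to 1 for every allele-count vector at n <= 12,
NA <= 3 is asserted in the acceptance suite, alongside a hand-enumerated
two-configuration example (p = 1/9) and an empirical type-I error check
(<= 0.05 at nominal 0.05 over 2,000 HWE-simulated loci; exact tests are
conservative).

`genotypic_ld_test()` tests pairwise independence of loci on the joint
genotype x genotype table — genotypes, not haplotypes, because phase is
unknown in diploid SSR data. The statistic is the log-likelihood-ratio G;
the null distribution comes from permuting one locus's genotype column,
and the p-value uses the add-one estimator
`(1 + #{G_perm >= G_obs}) / (1 + B)`, which is valid (never
anti-conservative) at any permutation count. `multiple_test_adjust()`
exposes Bonferroni, Holm and Benjamini-Hochberg corrections for batched
tests; none is hard-wired, since reports differ in which they apply.

Published HWE p-values of the reference panel are deliberately **not**
used as validation targets: the raw genotypes behind them are unprinted,
and the source's table and text disagree for at least one locus (a locus
described as deviating through homozygote excess carries a dash and
He = Ho in the table). Validation is instead oracle- and property-based,
as above.

## Synthetic data: what it emulates, what it does not

`simulate_transcripts_with_ssrs()` emulates the input side of a
transcriptome survey at desk scale: background composition mildly A/T-rich
(30/20/20/30), as insect transcriptomes typically are; lengths a few
hundred bp; implanted perfect repeats with recorded coordinates. The
background is rejection-sampled against the miner itself so that the truth
table is exact by construction — self-consistency was chosen over
construction-time guarantees because it is provably aligned with the
detector. `simulate_genotypes()` emulates the genotyping side — the
2 populations x 12 individuals x 9 loci design of the reference panel,
with 2-3 alleles per locus — as a mixture model: with probability F an
individual is autozygous, otherwise alleles are drawn independently, so
expected heterozygosity is `(1 - F)(1 - sum p_i^2)`, verified at
n = 1e4 for F in {0, 0.5, 1}. Allele codes are assigned 1..k in
descending frequency order for stable, readable fixtures.

Passing tests on these simulations show that the algorithms are correct
under the stated models. They do not show robustness to features of real
data the generators omit: mutation processes (stepwise or otherwise),
null alleles and allelic dropout, stutter and binning errors in fragment
calling, linkage between physically close loci, or assembly artefacts
such as chimeric unigenes. Allele codes are abstract labels throughout —
fragment-size binning happens upstream of this package.

## Numerical and interface choices

* Coordinates are 1-based inclusive, the common SSR-table convention.
* GENEPOP files are parsed with 2- or 3-digit allele-code width
  auto-detected per file; allele 0 marks a missing call, and a call with
  any 0 allele is treated as wholly missing. Populations are named by the
  id of their last individual (the de-facto GENEPOP convention),
  overridable via `pop_names`. Written files always use 3-digit codes.
* Empty sequences, N-only sequences and empty locus sets are valid inputs
  yielding empty results; all-missing loci and malformed files are errors
  that name the offending id, position or line.
* Every pipeline report file begins with a comment carrying a hash of the
  scientific configuration (output location excluded) and the seed, so a
  bundle is traceable to its settings; rerunning with the same
  configuration and seed reproduces files byte-for-byte.
* Test problem sizes — 1,000 random sequences for the miner oracle, 2,000
  simulated loci for the type-I error check, 1e4 individuals for
  calibration checks, a few hundred permutations per LD test — were
  chosen as the smallest sizes at which the corresponding statistical
  assertions are sharp (binomial or KS error well below the tested
  margins).

## Known limitations

Compound and interrupted repeats are out of scope: adjacent repeats are
reported as separate loci, and imperfect-repeat merging is not performed.
The primer scorer is a transparent stand-in, not a thermodynamic
simulator — no hairpin folding energies, no multiplex compatibility.
F-statistics, null-allele inference and bottleneck tests are outside the
package's remit, as are haplotype-based LD measures, which would require
phase. The HWE Monte-Carlo fallback matters only beyond panel scale;
its defaults (1e6 draws) are sized for that use.
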