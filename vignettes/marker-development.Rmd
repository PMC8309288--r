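---
title: "Developing flesh-color PCR markers from a single-gene allele panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing flesh-color PCR markers from a single-gene allele panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleshmark)
```

## The problem

Red-fleshed radish (*Raphanus sativus*) accumulates anthocyanins in the
taproot, a trait that cannot be scored at the seedling stage and segregates
awkwardly in breeding programs. The bHLH transcription factor gene *RsTT8*,
part of the MYB–bHLH–WD40 complex that switches on the late anthocyanin
biosynthesis genes, carries a dense set of polymorphisms that separate
red-fleshed (Rf) from white-fleshed (Wf) haplotypes: SNPs, insertion/deletions
(InDels), and a dinucleotide (TC) microsatellite (SSR) whose repeat count
differs drastically between groups. `fleshmark` implements the complete
marker-development analysis over such a panel: variant identification and
classification, distance-based phylogeny, PCR marker design, in-silico
genotyping, and genotype–phenotype concordance reporting — plus a synthetic
allele-panel generator so that every stage is testable without sequence
downloads.

## The allele panel model

A panel is a set of cloned allele sequences of one gene, each attached to a
diploid accession. Accessions carry a skin/flesh subtype — GsRf and RsRf
(red-fleshed, group Rf), WsWf and RsWf (white-fleshed, group Wf) — or are
heterozygous Rf/Wf. All sequences are stored in gene orientation; coordinates
are 1-based on a chosen reference allele (the first Rf allele by sorted id).
Anchor-relative positions (ATG by default, TSS by option) skip zero: the
anchor base is +1 and the base 5' of it is −1, so "−35" means the 35th
nucleotide upstream of the start codon. The gene model is a promoter followed
by 7 exons and 6 introns that tile the transcribed span exactly.

The ATG anchor is the reporting default because the published marker window
(−979 to −818) is stated against the ATG in the marker figure while the text
gives the TSS; the anchor is a flag (`anchor = "tss"`), not a hard-coded
resolution of that ambiguity.

## What the generator emulates — and what it does not

`simulate_panel()` builds a reference allele (1-kb promoter; exon lengths
240/150/120/110/160/280/220 nt and intron lengths 150/350/150/150/200/150 nt,
choices sized so that all mandatory features are placeable; background GC
0.40, typical of Brassicaceae noncoding sequence) and implants polymorphisms
at the published per-region counts: 28/3/3 Rf-vs-Wf SNPs/InDels/SSRs, 6/7/3
WsWf-specific, 9/1/1 RsWf-specific, with the promoter row at 16/2/1 for the
diagnostic class. Dashes in the published table are read as zeros.

Mandatory features reproduce the marker targets:

* a 14-nt insertion carried by all Wf alleles at ATG-relative −35 (the ID-P
  target);
* a (TC) microsatellite at the start of intron 2 with 13 repeats in Rf and 68
  in Wf alleles (the SSR-P target);
* a 3-nt CAT InDel in intron 5 plus the diagnostic exon SNPs (the WD/AD-P
  anchors). The published marker figure mentions three exon-6 SNPs, but the
  published polymorphism table allows only two diagnostic exonic SNPs; the
  generator follows the table and places both in exon 6, which is sufficient
  to anchor the reverse primer;
* four diagnostic promoter SNPs inside the −979..−818 window (the PS-P
  anchors). The number of window SNPs is not stated in the source report; four
  is a package choice consistent with the 16 diagnostic promoter SNPs.

Each line contributes two clone alleles that differ only at three private
nondiagnostic SNPs (the study deposited two clones per inbred line and the
lines are inbred, not doubled-haploid); the second red line additionally
carries two private nondiagnostic SNPs so the two Rf lines are
distinguishable in the tree. White-fleshed line privacy is already encoded by
the WsWf-/RsWf-specific classes, so no extra line-private variants are added
there (they would inflate those classes).

Placement rules keep the truth set exactly recoverable: variant footprints
never collide (6-nt guard), InDels are placed non-shiftable (their flanks do
not allow left/right normalization moves), SNPs and InDels avoid tandem-repeat
runs already present in the background, and microsatellite runs are written
with boundary breakers so their repeat count is unambiguous. Marker targets
sit inside variant-free protection zones (±80 nt) so conserved flanking
primers exist, and anchor SNPs are placed only where a primer window
satisfying the default constraints exists on both haplotypes — the generator
prefers GC-preserving substitutions (A↔T, C↔G) at anchor sites for that
reason, and resamples the promoter marker window background (deterministically
under the seed) if its designable positions would not span a primer pair.
Exonic variants default to protein-conserving placements: SNPs at synonymous
third codon positions where available, InDel lengths in multiples of 3,
mirroring the observation that the encoded proteins are conserved across
haplotype groups.

The generator does **not** model realistic mutation processes, recombination,
sequencing error, paralogy, or within-group haplotype structure beyond the
clone pairs. Passing tests on generated panels therefore demonstrate that the
pipeline's logic is correct under the published polymorphism structure, not
that it is robust to noisy or structurally surprising real data.

## Variant identification

Each allele is aligned to the reference with global affine-gap alignment
(match 2, mismatch −3, gap open −8, gap extend −1; a gap of length L costs
open + L·extend). Gap runs are merged into single InDel events and
left-aligned (VCF-style normalization). Microsatellite loci are detected on
the reference as maximal tandem runs (unit 1–6 nt, ≥4 full repeats, ≥8 nt;
the smallest published locus has 13 repeats, so the threshold sits safely
below it); any length variation falling inside a locus (±1 nt) is reported as
SSR repeat-count variation, never as an InDel, because the published
accounting counts SSRs separately. An InDel that only partially overlaps a
locus is flagged ambiguous rather than silently dropped. `N` bases are
treated as missing states, excluded from variant support.

Specificity classification is by voting: a site is `Rf_vs_Wf` when all Rf
alleles share one state and all Wf alleles share a different one;
`WsWf_specific` (`RsWf_specific`) when that subtype's alleles share a state
different from the single state shared by all other alleles; otherwise
`nondiagnostic`. Alleles with missing states are excluded from the vote.
Adjacent substitution columns are counted as separate SNPs (per-site
accounting, matching the published totals). Coding effects come from the
reading frame anchored at the ATG: synonymous/nonsynonymous for exonic SNPs
via the standard genetic code, frameshift vs in-frame by length modulo 3 for
exonic InDels, noncoding elsewhere.

`summarize_matrix()` emits the counts in the published three-region ×
three-kind × three-class layout with a Total row that must equal the column
sums.

## Phylogeny

Pairwise p-distances (mismatches over compared columns, gap and N columns
excluded pairwise; insertions relative to the reference are not columns) feed
standard neighbor joining. p-distance is used because no substitution
model is reported for the original tree and the tree only supports one claim: that some
internal edge bipartitions the alleles exactly into the Rf and Wf sets,
which `check_group_split()` tests explicitly. Negative NJ branch lengths are
clamped to zero with a warning. Trees are unrooted; output is newick.

## Marker design

Four marker types are attempted, mirroring the published set:

* **ID-P** and **SSR-P** are codominant length markers: a conserved primer
  pair flanking the target InDel/SSR such that the primers bind identically
  in every allele, the amplicon contains no other length-varying site, and
  the Rf/Wf product sizes differ by exactly the target's length difference
  (14 nt for the promoter insertion; 110 nt for (TC)13 vs (TC)68).
* **PS-P** and **WD/AD-P** are dominant allele-specific pairs: one primer
  pair per group, each taken verbatim from its own group's haplotype with the
  3' terminus anchored on a diagnostic site — a SNP base, or the InDel
  junction (for deletion/insertion targets the 3' end may sit up to 3 nt past
  the junction so the discriminating bases fall within the 3'-anchor window
  of the annealing model). PS-P anchors both primers on diagnostic promoter
  SNPs in the −979..−818 window; WD/AD-P anchors the forward primer on the
  intron-5 CAT InDel and the reverse primer on a diagnostic exon-6 SNP.
  Designs are validated by in-silico PCR: each pair must amplify every
  own-group allele exactly once and no other-group allele.

Constraints default to length 18–24 nt, Wallace Tm 55–65 °C (targeting the
62 °C validation annealing), GC 40–60 %, amplicon 100–1200 bp (length
markers; allele-specific products may be shorter, down to 60 bp), and
mononucleotide runs ≤4. Candidates are ranked by |Tm − 60|, then GC proximity
to 50 %, then leftmost position, making designs deterministic. The Wallace
rule (2·(A+T) + 4·(G+C)) is the default because only the PCR program
(not a Tm model) is reported for the validated primers; a unified nearest-neighbor thermodynamic model (SantaLucia
increments, monovalent-salt entropy correction) is available with
`compute_tm(method = "nn")` and agrees with an independent implementation to
well under 0.01 °C. Primer uniqueness is checked only within the supplied
alleles (single-gene scope), not genome-wide. Design failures are reported
per marker with diagnostics, never raised from the suite.

## In-silico genotyping

Annealing is modelled as an exact match over the 3'-terminal 3 bases plus at
most 2 mismatches elsewhere — an explicit, configurable stand-in for
annealing at 62 °C. Virtual PCR reports a product for every convergent
forward/reverse site pair within the size range, sized between the outer 5'
ends. An accession's band set is the union of its two alleles' band sets.
Codominant markers call Rf/Wf/Het/fail by matching band sizes to the expected
class sizes within ±2 nt (an agarose-resolution stand-in; the published
validation scored gel bands); allele-specific markers call by which pair
amplified. Two class sizes within tolerance of each other make the marker
non-discriminating (flagged, call `fail`).

Concordance compares marker-predicted flesh color with observed phenotype.
The default rule predicts red when at least one Rf allele is detected,
because heterozygous commercial cultivars in the published validation panels
are red-fleshed; the alternative recessive rule (red only for Rf/Rf) is a
flag, since breeders have speculated the trait is recessive and the package
does not adjudicate. Pink or still-segregating phenotypes count in a separate
`segregating` bucket, neither concordant nor discordant; unknown phenotypes
and failed calls are `uncallable`. The published failure mode — a
white-fleshed accession carrying an Rf-type SSR repeat count — is available
as the `chengwoo` plan and breaks only the SSR marker's concordance.

## Anthocyanin quantification

`compute_rac()` implements RAC = (A530 − A620) − 0.1·(A650 − A620) and
`compute_tac()` implements TAC = RAC × MW × DF × 1000 × path **verbatim**,
with MW defaulting to cyanidin-3-glucoside (449.2 g/mol). The source formula
multiplies by the optical path length and contains no molar extinction
coefficient, which is dimensionally unconventional; it is implemented as
printed, and `convention = "standard"` additionally offers the textbook form
RAC × MW × DF × 1000 / (ε × path) with a user-supplied ε.

## Numerical choices and degenerate inputs

* Coordinate conversion has no position 0 and is a checked bijection.
* SSR detection requires primitive units (a (TCTC) run is one (TC) locus),
  reports the lexicographically smallest unit rotation, and resolves
  overlapping runs by total length.
* Identical panels yield an empty variant table; empty variant tables yield
  an all-zero matrix; an empty FASTA yields an empty panel with a warning.
* Ties in marker candidate ranking are broken by position, so repeated runs
  of the same inputs give identical primers.
* All randomness flows from a single integer seed; the same seed gives
  byte-identical panel FASTA, truth sets, and downstream TSVs.

## Problem sizes used in the tests

The bundled tests run the full pipeline on the default four-line,
eight-allele panel (gene span ≈ 3.5 kb) across 20 generator seeds for
truth-set recovery and marker concordance, 100 random 5-kb sequences for the
microsatellite oracle equivalence (split between the unit and end-to-end
suites), and enumerated 3- and 4-taxon matrices for neighbor joining. These
sizes were chosen to exercise every code path at the published panel's scale
while keeping the suite comfortably fast on a laptop.

## Known limitations

* The alignment step is pairwise-to-reference; a true multiple alignment
  could resolve placement ambiguity near complex nested variants.
* SSR repeat counts are derived from aligned locus span lengths; interrupted
  repeats with internal SNPs are counted by length, not by perfect-repeat
  parsing.
* The annealing model is a binary site filter, not a thermodynamic
  simulation; primer-dimer and secondary-structure effects are out of scope.
* Genome-wide primer uniqueness is not checked (single-gene scope).
* The recessive/dominant inheritance question for red flesh is surfaced as a
  configuration flag, not resolved.
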