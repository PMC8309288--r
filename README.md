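# fleshmark

Marker-development analysis for predicting radish (*Raphanus sativus*)
taproot flesh color from polymorphisms in the anthocyanin-regulatory bHLH
gene *RsTT8*.

Red flesh cannot be scored at the seedling stage, so breeders need DNA
markers. Cloned *RsTT8* alleles from red-fleshed (Rf: GsRf, RsRf) and
white-fleshed (Wf: WsWf, RsWf) lines differ at a dense set of SNPs, InDels
and a (TC) microsatellite (SSR). From a phenotype-labelled panel of such
alleles, `fleshmark`:

1. **calls and classifies variants** — global affine-gap alignment to a
   reference allele, left-aligned InDel events, SSR repeat-count variation
   (detected tandem loci take precedence over InDel calls), specificity
   classes by state voting (`Rf_vs_Wf`, `WsWf_specific`, `RsWf_specific`,
   `nondiagnostic`), coding effects from the reading frame, and a
   region × kind × class summary matrix with a checked Total row;
2. **builds an allele phylogeny** — neighbor joining on p-distances, with an
   explicit test that an internal edge bipartitions the leaves into the Rf
   and Wf sets;
3. **designs four PCR markers** —
   `PS-P` (dominant allele-specific pair over diagnostic promoter SNPs in
   the −979..−818 window upstream of the ATG), `ID-P` (codominant length
   marker over the 14-nt Wf promoter insertion at −35), `SSR-P` (codominant
   length marker over the (TC)₁₃/(TC)₆₈ microsatellite), and `WD/AD-P`
   (dominant pair anchored on the intron-5 CAT InDel and a diagnostic exon-6
   SNP). Allele-specific primers place a diagnostic difference at their 3'
   terminus; candidates are ranked by |Tm − 60 °C|, GC proximity to 50 %,
   then position (Wallace Tm by default, nearest-neighbor by flag);
4. **genotypes accessions by in-silico PCR** — annealing modelled as exact
   3'-terminal match (3 nt) plus ≤2 mismatches elsewhere, band-size calls
   within ±2 nt, `Rf`/`Wf`/`Het`/`fail` per accession, and
   genotype–phenotype concordance under a dominant (default) or recessive
   red-flesh rule;
5. **quantifies anthocyanin readings** — RAC = (A530 − A620) − 0.1·(A650 −
   A620) and TAC = RAC × MW × DF × 1000 × path (cyanidin-3-glucoside
   reference, implemented verbatim);
6. **generates synthetic panels** — a seeded generator implants the full
   published polymorphism table (28/3/3 diagnostic SNPs/InDels/SSRs, 6/7/3
   WsWf-specific, 9/1/1 RsWf-specific, promoter row 16/2/1) plus the four
   marker targets, and emits a machine-readable truth set, so every stage is
   testable end to end without downloads.

See the methods vignette (`vignettes/marker-development.Rmd`) for the models,
assumptions and design choices.

## Worked example

Markers are discovered and designed on the four-inbred-line panel, then
validated on a wider panel that includes heterozygous cultivars and an
SSR-homoplasy accession:

```r
library(fleshmark)

disc <- simulate_panel(seed = 1)                 # four inbred lines, 8 alleles
model <- attr(disc, "model")

variants <- call_variants(disc, model)
summarize_matrix(variants)[, c("Rf_vs_Wf_SNP", "Rf_vs_Wf_InDel", "Rf_vs_Wf_SSR")]
#>          Rf_vs_Wf_SNP Rf_vs_Wf_InDel Rf_vs_Wf_SSR
#> Promoter           16              2            1
#> Exon                2              0            0
#> Intron             10              1            2
#> Total              28              3            3

suite <- design_marker_suite(disc, variants, model)
names(suite$markers)
#> [1] "PS-P"    "ID-P"    "SSR-P"   "WD/AD-P"
suite$markers[["ID-P"]]$expected_sizes
#>  Rf  Wf
#> 194 208          # Wf product 14 nt larger: the promoter insertion

val <- simulate_panel(seed = 1, plan = validation_plan(chengwoo = TRUE))
report <- genotype_panel(suite, val)
report$concordance[, c("marker", "concordant", "discordant", "fraction")]
#>    marker concordant discordant fraction
#>      PS-P         10          0      1.0
#>      ID-P         10          0      1.0
#>     SSR-P          9          1      0.9
#>  WD/AD-P         10          0      1.0
report$discordant[["SSR-P"]]
#> [1] "Chengwoo"   # white-fleshed accession carrying an Rf-type SSR allele
```

The diagnostic-SNP/InDel/SSR matrix reproduces the implanted counts (the
Total row is 28/3/3 for the Rf-vs-Wf class). The three heterozygous
cultivars call `Het` (both bands / both pairs) and are scored red under the
dominant rule. The SSR marker alone fails on the homoplasy accession — the
reason length-homoplasic microsatellites make poor diagnostic markers even
when flanked perfectly.

The same stages run from the shell via the thin CLI
(`inst/scripts/fleshmark`):

```sh
Rscript inst/scripts/fleshmark all --seed 7 --out out/ --plan chengwoo
```

which writes `panel.fasta`, `panel_meta.tsv`, `gene_model.gff3`, `truth.tsv`,
`variants.tsv`, `matrix.tsv`, `markers.tsv`, `calls.tsv`, `concordance.tsv`,
`tree.nwk` and `distances.tsv`, each TSV carrying a provenance header
(version, seed, config hash).

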