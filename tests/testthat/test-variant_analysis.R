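test_that("pairwise alignment matches an independent affine-gap DP oracle", {
  ## identity
  pa <- align_pair("ACGT", "ACGT")
  expect_equal(Biostrings::score(pa), 8)           # 4 matches x 2
  ## single substitution column
  pa <- align_pair("ACGTACGT", "ACGAACGT")
  expect_equal(Biostrings::score(pa), 7 * 2 - 3)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  expect_equal(sum(strsplit(ap, "")[[1]] != strsplit(as_, "")[[1]]), 1L)
  ## random windows with an implanted insertion: score equals Gotoh DP
  for (seed in 1:4) {
    ref <- random_dna(300, seed = seed)
    ins <- random_dna(14, seed = seed + 100)
    cut <- 120 + seed * 10
    qry <- paste0(substr(ref, 1, cut), ins, substr(ref, cut + 1, 300))
    pa <- align_pair(ref, qry)
    expect_equal(Biostrings::score(pa), gotoh_score(ref, qry))
  }
})

test_that("SSR detector handles constructed runs and thresholds", {
  s <- paste0("AA", strrep("TC", 13), "GG")
  loci <- detect_ssr_loci(s)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$unit, "CT")         # canonical (smallest) rotation of TC
  expect_equal(loci$repeats, 13L)
  expect_equal(loci$start, 3L)
  ## below min_repeats: no locus
  expect_equal(nrow(detect_ssr_loci("GGATCTCTCAA")), 0L)
  ## homopolymer of 8 qualifies at defaults, 7 does not
  expect_equal(nrow(detect_ssr_loci(paste0("CG", strrep("A", 8), "CG"))), 1L)
  expect_equal(nrow(detect_ssr_loci(paste0("CG", strrep("A", 7), "CG"))), 0L)
})

test_that("SSR detector equals the brute-force period scan on random sequence", {
  for (seed in 1:8) {
    s <- random_dna(5000, seed = seed, gc = 0.45)
    got <- detect_ssr_loci(s)
    want <- brute_force_ssr(s)
    expect_equal(got[c("unit", "unit_length", "start", "end", "repeats")],
                 want[c("unit", "unit_length", "start", "end", "repeats")],
                 info = paste("seed", seed))
  }
})

test_that("an identical panel yields no variants", {
  s <- random_dna(600, seed = 2)
  panel <- tiny_panel(c(s, s), c(s, s))
  kind <- c("promoter", rep(c("exon", "intron"), 6), "exon")
  index <- c(1L, as.vector(rbind(1:6, 1:6)), 7L)
  lens <- c(100L, rep(c(50L, 20L), 6), 80L)[1:14]
  start <- cumsum(c(1L, lens[-14]))
  model <- gene_model(data.frame(kind = kind, index = index, start = start,
                                 end = start + lens - 1L),
                      tss_pos = 101L, atg_pos = 121L)
  vt <- call_variants(panel, model)
  expect_equal(nrow(vt), 0L)
})

test_that("a 14-nt Wf insertion 35 nt upstream of the ATG is called as one promoter InDel", {
  set.seed(7)
  s <- random_dna(600, gc = 0.45)
  atg <- 121L
  p_ins <- atg - 35L                      # ATG-relative -35
  ins <- "GATTACCAGGTTCA"
  repeat {                                # non-shiftable placement
    if (substr(ins, 1, 1) != substr(s, p_ins, p_ins) &&
        substr(ins, 14, 14) != substr(s, p_ins - 1, p_ins - 1)) break
    ins <- random_dna(14)
  }
  wf <- paste0(substr(s, 1, p_ins - 1), ins, substr(s, p_ins, 600))
  kind <- c("promoter", rep(c("exon", "intron"), 6), "exon")
  index <- c(1L, as.vector(rbind(1:6, 1:6)), 7L)
  lens <- c(100L, rep(c(50L, 20L), 6), 80L)[1:14]
  start <- cumsum(c(1L, lens[-14]))
  model <- gene_model(data.frame(kind = kind, index = index, start = start,
                                 end = start + lens - 1L),
                      tss_pos = 101L, atg_pos = atg)
  panel <- tiny_panel(c(s, s), c(wf, wf))
  vt <- call_variants(panel, model)
  ind <- vt[vt$kind == "InDel", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$length, 14L)
  expect_equal(ind$region, "promoter")
  expect_equal(ind$pos_atg, -35L)
  expect_equal(ind$specificity, "Rf_vs_Wf")
})

test_that("length variation inside an SSR locus is reported as repeat counts, not InDels", {
  set.seed(9)
  flank1 <- random_dna(200, gc = 0.45); flank2 <- random_dna(300, gc = 0.45)
  mk <- function(reps) paste0(flank1, "GG", strrep("TC", reps), "GA", flank2)
  kind <- c("promoter", rep(c("exon", "intron"), 6), "exon")
  index <- c(1L, as.vector(rbind(1:6, 1:6)), 7L)
  lens <- c(100L, rep(c(40L, 20L), 6), 60L)[1:14]
  start <- cumsum(c(1L, lens[-14]))
  model <- gene_model(data.frame(kind = kind, index = index, start = start,
                                 end = start + lens - 1L),
                      tss_pos = 101L, atg_pos = 121L)
  panel <- tiny_panel(c(mk(13), mk(13)), c(mk(68), mk(68)))
  vt <- call_variants(panel, model)
  expect_equal(nrow(vt[vt$kind == "InDel", ]), 0L)
  ssr <- vt[vt$kind == "SSR", ]
  expect_equal(nrow(ssr), 1L)
  st <- allele_states(ssr)
  expect_equal(unname(st[c("Rf1", "Rf2")]), c("13", "13"))
  expect_equal(unname(st[c("Wf1", "Wf2")]), c("68", "68"))
  expect_equal(ssr$specificity, "Rf_vs_Wf")
})

test_that("specificity classification follows the voting definition", {
  info <- data.frame(
    allele_id = c("r1", "r2", "r3", "r4", "w1", "w2", "w3", "w4"),
    group = rep(c("Rf", "Wf"), each = 4),
    subtype = c("GsRf", "GsRf", "RsRf", "RsRf", "WsWf", "WsWf", "RsWf", "RsWf"),
    stringsAsFactors = FALSE)
  st <- function(...) setNames(c(...), info$allele_id)
  expect_equal(classify_specificity(st("A","A","A","A","G","G","G","G"), info),
               "Rf_vs_Wf")
  expect_equal(classify_specificity(st("A","G","A","A","G","G","G","G"), info),
               "nondiagnostic")
  expect_equal(classify_specificity(st("C","C","C","C","T","T","C","C"), info),
               "WsWf_specific")
  expect_equal(classify_specificity(st("C","C","C","C","C","C","T","T"), info),
               "RsWf_specific")
  ## missing states are excluded from the vote
  expect_equal(classify_specificity(st("A","A",NA,"A","G","G","G",NA), info),
               "Rf_vs_Wf")
})

test_that("coding effects come from the reading frame and genetic code", {
  panel <- fixture_panel(1)
  vt <- fixture_variants(1)
  ## all intronic/promoter variants are noncoding
  expect_true(all(vt$coding_effect[vt$region_class != "Exon"] == "noncoding"))
  ## exonic InDel lengths set frame consequences
  exi <- vt[vt$kind == "InDel" & vt$region_class == "Exon", ]
  expect_true(all(exi$coding_effect ==
                  ifelse(exi$length %% 3L == 0L, "in_frame_indel", "frameshift")))
  ## generator prefers synonymous exonic SNPs (protein-conserving default);
  ## designability constraints may force an occasional nonsynonymous pick
  exs <- vt[vt$kind == "SNP" & vt$region_class == "Exon", ]
  expect_true(all(exs$coding_effect %in% c("synonymous", "nonsynonymous")))
  expect_gte(mean(exs$coding_effect == "synonymous"), 0.5)
  ## direct genetic-code check: GAA -> GAG is synonymous (Glu)
  m <- attr(panel, "model")
  refseq <- as.character(panel$alleles[[reference_allele_id(panel)]])
  v <- strsplit(refseq, "")[[1]]
  cd <- fleshmark:::codon_at(m$atg_pos + 3L, v, m)
  expect_equal(cd$frame, 0L)
})

test_that("left-alignment normalizes InDel positions in homopolymers", {
  ## deleting any one A of an A-run must normalize to the run start
  base <- paste0(random_dna(120, seed = 3), "CC", strrep("A", 6), "GG",
                 random_dna(120, seed = 4))
  run_start <- 123L               # first A of the run (120 nt + "CC")
  refv <- strsplit(base, "")[[1]]
  for (cut in 0:5) {
    del_at <- run_start + cut
    norm <- fleshmark:::left_align_indel(del_at, -1L, "A", refv)
    expect_equal(norm$pos, run_start)
  }
  ## same for an insertion of one more A anywhere in the run
  for (cut in 0:5) {
    norm <- fleshmark:::left_align_indel(run_start + cut, 1L, "A", refv)
    expect_equal(norm$pos, run_start)
  }
})

test_that("variant recovery matches the generator truth set across seeds", {
  for (seed in 1:20) {
    panel <- fixture_panel(seed)
    truth <- attr(panel, "truth")
    vt <- fixture_variants(seed)
    a <- truth[order(truth$genomic_pos),
               c("kind", "pos_atg", "region", "specificity")]
    b <- as.data.frame(vt)[order(vt$genomic_pos),
                           c("kind", "pos_atg", "region", "specificity")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a, info = paste("seed", seed))
  }
})

test_that("polymorphism matrix layout and totals are conserved", {
  vt <- fixture_variants(1)
  m <- summarize_matrix(vt)
  expect_equal(rownames(m), c("Promoter", "Exon", "Intron", "Total"))
  for (cc in colnames(m))
    expect_equal(m["Total", cc], sum(m[c("Promoter", "Exon", "Intron"), cc]))
  ## diagnostic classes exclude nondiagnostic variants
  expect_lte(sum(m["Total", ]), nrow(vt))
  ## empty input gives an all-zero matrix
  empty <- summarize_matrix(vt[0, ])
  expect_true(all(as.matrix(empty) == 0L))
})
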