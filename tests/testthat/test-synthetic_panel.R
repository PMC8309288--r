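test_that("generator is deterministic and emits the configured layout", {
  p1 <- simulate_panel(seed = 11)
  p2 <- simulate_panel(seed = 11)
  expect_identical(as.character(p1$alleles), as.character(p2$alleles))
  expect_identical(attr(p1, "truth"), attr(p2, "truth"))

  m <- attr(p1, "model")
  expect_equal(sum(m$features$kind == "exon"), 7L)
  expect_equal(sum(m$features$kind == "intron"), 6L)
  expect_equal(m$features$end[m$features$kind == "promoter"], 1000L)
  expect_equal(length(p1$alleles), 8L)
  expect_equal(nrow(p1$meta), 4L)
})

test_that("background GC fraction matches the configured target", {
  ## 10 kb promoter-only-ish draw at GC 0.5; binomial sd ~ 0.005
  cfg <- generator_config(seed = 5, gc = 0.5, promoter_length = 8000L)
  ref <- generate_reference(cfg)
  b <- strsplit(ref$sequence, "")[[1]]
  gc_obs <- mean(b %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 0.03)
})

test_that("truth-set counts reproduce the polymorphism spec table per seed", {
  spec <- default_spec_table()
  for (seed in c(2, 9, 17)) {
    truth <- attr(fixture_panel(seed), "truth")
    for (i in seq_len(nrow(spec))) {
      got <- sum(truth$region_class == spec$region_class[i] &
                 truth$kind == spec$kind[i] &
                 truth$specificity == spec$specificity[i])
      expect_equal(got, spec$count[i],
                   info = sprintf("seed %d %s/%s/%s", seed, spec$region_class[i],
                                  spec$kind[i], spec$specificity[i]))
    }
  }
})

test_that("mandatory marker features are implanted as configured", {
  panel <- fixture_panel(1)
  truth <- attr(panel, "truth")
  ## 14-nt promoter insertion at ATG-relative -35, carried by the Wf clones
  id <- truth[truth$kind == "InDel" & truth$region == "promoter" &
              truth$indel_len == 14L, ]
  expect_equal(nrow(id), 1L)
  expect_equal(id$pos_atg, -35L)
  expect_setequal(strsplit(id$carriers, ",")[[1]],
                  c("WsWf_TT8_1", "WsWf_TT8_2", "RsWf_TT8_1", "RsWf_TT8_2"))
  ## (TC) microsatellite in intron 2: 13 repeats in Rf, 68 in Wf
  ssr <- truth[truth$kind == "SSR" & truth$unit == "TC" &
               truth$region == "intron_2", ]
  expect_equal(nrow(ssr), 1L)
  expect_equal(ssr$ref_repeats, 13L)
  expect_equal(ssr$alt_repeats, 68L)
  ## 3-nt InDel in intron 5 (CAT motif deleted in Wf)
  cat3 <- truth[truth$kind == "InDel" & truth$region == "intron_5" &
                truth$specificity == "Rf_vs_Wf", ]
  expect_equal(nrow(cat3), 1L)
  expect_equal(abs(cat3$indel_len), 3L)
  ## diagnostic exonic SNPs live in exon 6
  ex <- truth[truth$kind == "SNP" & truth$specificity == "Rf_vs_Wf" &
              truth$region_class == "Exon", ]
  expect_true(all(ex$region == "exon_6"))
  ## diagnostic promoter SNPs inside the -979..-818 window
  win <- truth[truth$kind == "SNP" & truth$specificity == "Rf_vs_Wf" &
               truth$region == "promoter" &
               truth$pos_atg >= -979L & truth$pos_atg <= -818L, ]
  expect_gte(nrow(win), 2L)
})

test_that("all-zero spec with mandatory features disabled is a no-op", {
  cfg <- generator_config(seed = 3)
  cfg$spec_table$count <- 0L
  cfg$promoter_indel$enabled <- FALSE
  cfg$ssr$enabled <- FALSE
  cfg$cat_indel$enabled <- FALSE
  cfg$exon6_snps <- 0L
  cfg$promoter_window_snps$count <- 0L
  cfg$pair_snps <- 0L
  cfg$line_snps <- 0L
  ref <- generate_reference(cfg)
  imp <- implant_variants(ref, cfg)
  expect_equal(nrow(imp$truth), 0L)
  expect_true(all(imp$haplotypes == ref$sequence))
})

test_that("accession plans control zygosity and allele sharing", {
  panel <- fixture_panel(1, "validation")
  expect_equal(nrow(panel$meta), 9L)
  ## heterozygous cultivars carry one allele from each group
  for (acc in c("RedSun", "Rupr", "Anthopol")) {
    ids <- strsplit(panel$meta$allele_ids[panel$meta$accession_id == acc], ",")[[1]]
    grp <- panel$allele_info$group[match(ids, panel$allele_info$allele_id)]
    expect_setequal(grp, c("Rf", "Wf"))
  }
  ## every allele belongs to exactly one accession
  expect_false(anyDuplicated(panel$allele_info$allele_id) > 0)
})

test_that("the SSR-homoplasy accession carries the Rf repeat count on a Wf background", {
  panel <- fixture_panel(1, "chengwoo")
  truth <- attr(panel, "truth")
  ssr <- truth[truth$kind == "SSR" & truth$unit == "TC" &
               truth$region == "intron_2", ]
  unit_len <- 2L
  run_rf <- strrep("TC", ssr$ref_repeats)
  run_wf <- strrep("TC", ssr$alt_repeats)
  ch <- as.character(accession_alleles(panel, "Chengwoo"))
  ws <- as.character(accession_alleles(panel, "HKR-519"))
  ## Chengwoo alleles contain the short (Rf-type) run, not the long Wf run
  expect_true(all(grepl(run_rf, ch, fixed = TRUE)))
  expect_false(any(grepl(run_wf, ch, fixed = TRUE)))
  ## while the true WsWf line carries the long run
  expect_true(all(grepl(run_wf, ws, fixed = TRUE)))
  ## and Chengwoo retains the Wf-diagnostic promoter insertion
  ins <- truth[truth$kind == "InDel" & truth$indel_len == 14L, ]
  expect_true(all(grepl(ins$ins_seq, ch, fixed = TRUE)))
})

test_that("panel FASTA bytes are identical across repeated builds", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_panel(simulate_panel(seed = 8, plan = validation_plan(TRUE)),
              f1, tempfile())
  write_panel(simulate_panel(seed = 8, plan = validation_plan(TRUE)),
              f2, tempfile())
  expect_identical(readLines(f1), readLines(f2))
})
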