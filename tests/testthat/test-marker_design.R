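test_that("Wallace melting temperatures follow 2(A+T) + 4(G+C)", {
  ## 20-mer with 10 G/C and 10 A/T -> 60
  expect_equal(compute_tm("GCGCGCGCGCATATATATAT"), 60)
  expect_equal(compute_tm("AAAAAAAA"), 16)
  ## composition invariance under reverse complement
  for (seed in 1:5) {
    p <- random_dna(20, seed = seed)
    expect_equal(compute_tm(p), compute_tm(fleshmark:::revcomp(p)))
  }
  expect_error(compute_tm("ACGTACGN"), "ambiguous")
  expect_error(compute_tm("ACGT"), "shorter")
})

test_that("nearest-neighbor Tm matches an independent thermodynamic implementation", {
  ## frozen from biopython MeltingTemp.Tm_NN (SantaLucia 1998 unified table,
  ## 62.5 nM effective duplex concentration, 50 mM Na+, entropic salt corr.)
  frozen <- c(ACGTGCTAGCTAGGCTAAGT = 54.623,
              TTGCAACGTGGATCCTTGCA = 57.214,
              GATTACAGATTACAGGCGCG = 53.334)
  for (p in names(frozen))
    expect_equal(compute_tm(p, method = "nn"), frozen[[p]], tolerance = 0.001)
})

test_that("length marker over the promoter insertion separates classes by 14 nt", {
  panel <- fixture_panel(1)
  suite <- fixture_suite(1)
  idp <- suite$markers[["ID-P"]]
  expect_s3_class(idp, "primer_set")
  expect_equal(idp$mode, "codominant_length")
  expect_equal(abs(idp$expected_sizes[["Wf"]] - idp$expected_sizes[["Rf"]]), 14L)
  ## the primers bind identically in every allele: virtual PCR on each allele
  ## yields exactly one product of the expected class size
  grp <- setNames(panel$allele_info$group, panel$allele_info$allele_id)
  for (id in names(panel$alleles)) {
    amp <- simulate_pcr(idp$primers$fw, idp$primers$rv,
                        as.character(panel$alleles[[id]]))
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$size, unname(idp$expected_sizes[[grp[[id]]]]))
  }
})

test_that("SSR length marker size difference equals the repeat spread", {
  suite <- fixture_suite(1)
  ssrp <- suite$markers[["SSR-P"]]
  ## (68 - 13) TC repeats -> 110 nt
  expect_equal(abs(ssrp$expected_sizes[["Wf"]] - ssrp$expected_sizes[["Rf"]]),
               (68L - 13L) * 2L)
})

test_that("allele-specific pairs anchor diagnostic sites and discriminate groups", {
  panel <- fixture_panel(1)
  suite <- fixture_suite(1)
  for (name in c("PS-P", "WD/AD-P")) {
    m <- suite$markers[[name]]
    expect_equal(m$mode, "dominant_allele_specific_pair")
    info <- panel$allele_info
    for (g in c("Rf", "Wf")) {
      own <- info$allele_id[info$group == g]
      oth <- info$allele_id[info$group != g]
      for (id in own) {
        amp <- simulate_pcr(m$primers[[g]]$fw, m$primers[[g]]$rv,
                            as.character(panel$alleles[[id]]))
        expect_equal(nrow(amp), 1L,
                     info = paste(name, g, "pair on own allele", id))
      }
      for (id in oth) {
        amp <- simulate_pcr(m$primers[[g]]$fw, m$primers[[g]]$rv,
                            as.character(panel$alleles[[id]]))
        expect_equal(nrow(amp), 0L,
                     info = paste(name, g, "pair on other-group allele", id))
      }
    }
  }
})

test_that("amplicon size arithmetic is exact on the reference", {
  panel <- fixture_panel(1)
  suite <- fixture_suite(1)
  idp <- suite$markers[["ID-P"]]
  ref_id <- reference_allele_id(panel)
  amp <- simulate_pcr(idp$primers$fw, idp$primers$rv,
                      as.character(panel$alleles[[ref_id]]))
  expect_equal(amp$size, amp$end - amp$start + 1L)
  expect_equal(amp$start, idp$fw_start)
  expect_equal(amp$end, idp$rv_end)
})

test_that("the suite attempts all four marker types and reports failures", {
  suite <- fixture_suite(1)
  expect_setequal(names(suite$markers), c("PS-P", "ID-P", "SSR-P", "WD/AD-P"))
  expect_length(suite$failures, 0L)

  ## panel generated without any SSR: SSR-P becomes a failure record
  cfg <- generator_config(seed = 2)
  cfg$ssr$enabled <- FALSE
  cfg$spec_table$count[cfg$spec_table$kind == "SSR"] <- 0L
  panel2 <- simulate_panel(seed = 2, config = cfg)
  vt2 <- call_variants(panel2, attr(panel2, "model"))
  suite2 <- design_marker_suite(panel2, vt2, attr(panel2, "model"))
  expect_false("SSR-P" %in% names(suite2$markers))
  expect_match(suite2$failures[["SSR-P"]], "no diagnostic SSR")
  expect_true(all(c("PS-P", "ID-P", "WD/AD-P") %in% names(suite2$markers)))

  ## infeasible constraints (short primers cannot reach Tm 70-71 within the
  ## GC bounds): everything fails, with diagnostics
  panel <- fixture_panel(1)
  vt <- fixture_variants(1)
  cons <- primer_constraints(length_range = c(18L, 18L), tm_range = c(70, 71))
  suite3 <- design_marker_suite(panel, vt, attr(panel, "model"),
                                constraints = cons)
  expect_length(suite3$markers, 0L)
  expect_length(suite3$failures, 4L)
})

test_that("marker choices are deterministic for identical inputs", {
  panel <- fixture_panel(1)
  vt <- fixture_variants(1)
  s1 <- design_marker_suite(panel, vt, attr(panel, "model"))
  s2 <- design_marker_suite(panel, vt, attr(panel, "model"))
  expect_identical(lapply(s1$markers, function(m) m$primers),
                   lapply(s2$markers, function(m) m$primers))
})
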