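test_that("binding-site search enforces the 3'-anchor annealing model", {
  tmpl <- paste0(random_dna(80, seed = 5), "ACGTGCTAGCTAGGCTAAGT",
                 random_dna(80, seed = 6))
  primer <- "ACGTGCTAGCTAGGCTAAGT"
  ## exact presence: one plus-strand site, 0 mismatches
  hit <- find_binding_sites(primer, tmpl)
  plus <- hit[hit$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$mismatches, 0L)
  expect_equal(plus$start, 81L)
  expect_equal(plus$three_prime_pos, 100L)
  ## a mismatch at the primer 3'-terminal base kills the site
  tmpl2 <- tmpl
  substr(tmpl2, 100, 100) <- "C"   # template base under the 3' end (was T)
  hit2 <- find_binding_sites(primer, tmpl2)
  expect_equal(nrow(hit2[hit2$strand == "+", ]), 0L)
  ## one internal mismatch is tolerated and counted
  tmpl3 <- tmpl
  substr(tmpl3, 90, 90) <- "A"     # internal position (was C)
  hit3 <- find_binding_sites(primer, tmpl3)
  plus3 <- hit3[hit3$strand == "+", ]
  expect_equal(nrow(plus3), 1L)
  expect_equal(plus3$mismatches, 1L)
  ## the reverse complement is found on the minus strand
  rc <- fleshmark:::revcomp(primer)
  hit4 <- find_binding_sites(rc, tmpl)
  expect_equal(nrow(hit4[hit4$strand == "-", ]), 1L)
  ## primer longer than template: empty with warning
  expect_warning(h <- find_binding_sites(strrep("ACGT", 20), "ACGTACGT"),
                 "longer")
  expect_equal(nrow(h), 0L)
})

test_that("raising max_mismatch never removes a binding site", {
  set.seed(11)
  for (rep in 1:20) {
    tmpl <- random_dna(400)
    primer <- substr(tmpl, 150, 169)
    ## mutate the template a little so mismatching sites exist
    v <- strsplit(tmpl, "")[[1]]
    pos <- sample(140:180, 2)
    for (p in pos) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
    tmpl <- paste(v, collapse = "")
    prev <- -1L
    for (mm in 0:3) {
      n <- nrow(find_binding_sites(primer, tmpl, max_mismatch = mm))
      expect_gte(n, prev)
      prev <- n
    }
  }
})

test_that("virtual PCR computes product sizes between outer 5' ends", {
  ## fw 5' at 100, rv 5' at 399 -> 300-nt product
  tmpl <- random_dna(600, seed = 21)
  fw <- substr(tmpl, 100, 119)
  rv <- fleshmark:::revcomp(substr(tmpl, 380, 399))
  amp <- simulate_pcr(fw, rv, tmpl, size_range = c(50, 1000))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, 300L)
  expect_equal(amp$start, 100L)
  expect_equal(amp$end, 399L)
  ## divergent orientation: no product
  amp2 <- simulate_pcr(fleshmark:::revcomp(fw), fleshmark:::revcomp(rv),
                       tmpl, size_range = c(50, 1000))
  expect_equal(nrow(amp2), 0L)
})

test_that("heterozygous accessions show the band union of their alleles", {
  panel <- fixture_panel(1, "validation")
  suite <- fixture_suite(1)
  idp <- suite$markers[["ID-P"]]
  ## Het cultivar: both class bands; homozygous lines: one band
  het <- call_marker_genotype(idp, accession_alleles(panel, "RedSun"))
  expect_equal(het$call, "Het")
  expect_setequal(het$bands$size, unname(idp$expected_sizes))
  hom <- call_marker_genotype(idp, accession_alleles(panel, "HKR-275"))
  expect_equal(hom$call, "Rf")
  ## union property: accession bands = union of per-allele bands
  ids <- strsplit(panel$meta$allele_ids[panel$meta$accession_id == "RedSun"],
                  ",")[[1]]
  per_allele <- unlist(lapply(ids, function(id)
    simulate_pcr(idp$primers$fw, idp$primers$rv,
                 as.character(panel$alleles[[id]]))$size))
  expect_setequal(het$bands$size, unique(per_allele))
})

test_that("genotype calls cover Rf, Wf, Het and fail outcomes", {
  panel <- fixture_panel(1, "validation")
  suite <- fixture_suite(1)
  for (m in suite$markers) {
    calls <- vapply(panel$meta$accession_id, function(acc)
      call_marker_genotype(m, accession_alleles(panel, acc))$call, character(1))
    expect_equal(unname(calls[c("HKR-397", "HKR-275")]), c("Rf", "Rf"))
    expect_equal(unname(calls[c("HKR-519", "HKR-513")]), c("Wf", "Wf"))
    expect_equal(unname(calls[c("RedSun", "Rupr", "Anthopol")]),
                 rep("Het", 3))
  }
  ## primers that bind nothing -> fail
  fake <- suite$markers[["ID-P"]]
  fake$primers$fw <- strrep("ACGT", 5)
  res <- call_marker_genotype(fake, accession_alleles(panel, "HKR-397"))
  expect_equal(res$call, "fail")
})

test_that("concordance is perfect on clean panels for every marker", {
  panel <- fixture_panel(1, "validation")
  suite <- fixture_suite(1)
  rep <- genotype_panel(suite, panel)
  expect_s3_class(rep, "concordance_report")
  expect_true(all(rep$concordance$fraction == 1))
  ## bucket counts partition the panel
  with(rep$concordance,
       expect_true(all(concordant + discordant + uncallable + segregating ==
                       nrow(panel$meta))))
})

test_that("SSR homoplasy breaks only the SSR marker's concordance", {
  panel <- fixture_panel(1, "chengwoo")
  suite <- fixture_suite(1)
  rep <- genotype_panel(suite, panel)
  cc <- rep$concordance
  expect_equal(cc$fraction[cc$marker == "SSR-P"] < 1, TRUE)
  expect_true(all(cc$fraction[cc$marker != "SSR-P"] == 1))
  expect_equal(rep$discordant[["SSR-P"]], "Chengwoo")
  ## the discordant call is an Rf-type SSR genotype on a white-fleshed line
  ch <- rep$calls[rep$calls$accession_id == "Chengwoo" &
                  rep$calls$marker == "SSR-P", ]
  expect_equal(ch$call, "Rf")
})

test_that("phenotype rules and unknown phenotypes are honored", {
  panel <- fixture_panel(1, "validation")
  suite <- fixture_suite(1)
  ## under the recessive rule, het red cultivars become discordant
  rep_rec <- genotype_panel(suite, panel, phenotype_rule = "recessive")
  cc <- rep_rec$concordance
  expect_true(all(cc$discordant >= 3))
  ## unknown phenotypes are uncallable, fraction NA when nothing is scorable
  panel2 <- panel
  panel2$meta$observed_flesh <- "unknown"
  rep_unk <- genotype_panel(suite, panel2)
  expect_true(all(is.na(rep_unk$concordance$fraction)))
  expect_true(all(rep_unk$concordance$uncallable == nrow(panel2$meta)))
  ## pink/segregating phenotypes land in the segregating bucket
  panel3 <- panel
  panel3$meta$observed_flesh[panel3$meta$accession_id == "RedSun"] <- "pink"
  rep_seg <- genotype_panel(suite, panel3)
  expect_true(all(rep_seg$concordance$segregating == 1))
})

test_that("non-SSR markers stay perfectly concordant across generator seeds", {
  for (seed in 1:20) {
    panel <- fixture_panel(seed, "chengwoo")
    suite <- fixture_suite(seed)
    ok <- c("PS-P", "ID-P", "WD/AD-P")
    expect_true(all(ok %in% names(suite$markers)), info = paste("seed", seed))
    rep <- genotype_panel(suite$markers[ok], panel)
    expect_true(all(rep$concordance$fraction == 1),
                info = paste("seed", seed))
    expect_true("SSR-P" %in% names(suite$markers))
    rep2 <- genotype_panel(suite$markers["SSR-P"], panel)
    expect_lt(rep2$concordance$fraction, 1)
  }
})
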