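test_that("relative anthocyanin content follows the published formula", {
  ## equal absorbances cancel exactly
  expect_equal(compute_rac(0.3, 0.3, 0.3), 0)
  ## (0.50 - 0.10) - 0.1 * (0.20 - 0.10) = 0.39
  expect_equal(compute_rac(0.50, 0.10, 0.20), 0.39)
  ## negative RAC is reported with a warning, not an error
  expect_warning(r <- compute_rac(0.0, 0.2, 0.2), "negative")
  expect_equal(r, -0.2)
  expect_error(compute_rac(-0.1, 0, 0), "nonnegative")
  ## adding a constant to all three absorbances does NOT cancel in general:
  ## RAC(a+c) = RAC(a) + 0.1*c... no: (A530+c - A620-c) terms cancel, and the
  ## 0.1 term also cancels, so a common offset leaves RAC unchanged exactly
  expect_equal(compute_rac(0.5 + 0.2, 0.1 + 0.2, 0.2 + 0.2),
               compute_rac(0.5, 0.1, 0.2))
})

test_that("total anthocyanin content is the verbatim product formula", {
  ## RAC=1, MW=449.2, DF=1, path=1 -> 449200; /1000 = 449.2
  expect_equal(compute_tac(1) / 1000, 449.2)
  expect_equal(compute_tac(0, df = 50), 0)
  ## RAC=0.39, DF=10 -> 0.39 * 449.2 * 10 * 1000 = 1,751,880
  expect_equal(compute_tac(0.39, df = 10), 1751880)
  ## linear in each factor
  expect_equal(compute_tac(0.2, mw = 2 * 449.2), 2 * compute_tac(0.2))
  expect_equal(compute_tac(0.2, df = 3), 3 * compute_tac(0.2))
  expect_equal(compute_tac(0.2, path_length = 2), 2 * compute_tac(0.2))
  expect_error(compute_tac(1, df = 0), "positive")
  ## conventional form divides by extinction x path
  expect_equal(compute_tac(0.39, df = 10, convention = "standard",
                           epsilon = 26900),
               0.39 * 449.2 * 10 * 1000 / 26900)
  expect_error(compute_tac(1, convention = "standard"), "epsilon")
})

test_that("the table interface appends RAC and TAC columns", {
  tab <- data.frame(sample = c("rf", "wf"),
                    A530 = c(0.50, 0.08), A620 = c(0.10, 0.05),
                    A650 = c(0.20, 0.06), DF = c(10, 1))
  out <- quantify_anthocyanin(tab)
  expect_equal(out$RAC[1], 0.39)
  expect_equal(out$TAC[1], 1751880)
  ## file round trip
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  out2 <- quantify_anthocyanin(f)
  expect_equal(out2$TAC, out$TAC)
})
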