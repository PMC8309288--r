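## Independent oracles and shared fixtures for the test suite.

## ---- memoized pipeline fixtures (shared across test files) ----------------
.fixture_cache <- new.env(parent = emptyenv())

fixture_panel <- function(seed, plan = "default") {
  key <- paste0("p", seed, "_", plan)
  if (!exists(key, .fixture_cache)) {
    plan_df <- switch(plan,
                      default = default_accession_plan(),
                      validation = validation_plan(FALSE),
                      chengwoo = validation_plan(TRUE))
    assign(key, simulate_panel(seed = seed, plan = plan_df), .fixture_cache)
  }
  get(key, .fixture_cache)
}

fixture_variants <- function(seed, plan = "default") {
  key <- paste0("v", seed, "_", plan)
  if (!exists(key, .fixture_cache)) {
    panel <- fixture_panel(seed, plan)
    assign(key, call_variants(panel, attr(panel, "model")), .fixture_cache)
  }
  get(key, .fixture_cache)
}

fixture_suite <- function(seed, plan = "default") {
  key <- paste0("s", seed, "_", plan)
  if (!exists(key, .fixture_cache)) {
    panel <- fixture_panel(seed, plan)
    assign(key,
           design_marker_suite(panel, fixture_variants(seed, plan),
                               attr(panel, "model")),
           .fixture_cache)
  }
  get(key, .fixture_cache)
}

## ---- brute-force SSR oracle ------------------------------------------------
## scan every start ascending per unit size, counting full repeats directly;
## an accepted run consumes its span, so each periodic stretch is reported
## once from its leftmost start with the maximal full-repeat count
brute_force_ssr <- function(sequence, min_unit = 1, max_unit = 6,
                            min_repeats = 4, min_length = 8) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  hits <- list()
  for (k in min_unit:max_unit) {
    i <- 1
    while (i + 2 * k - 1 <= n) {
      unit <- s[i:(i + k - 1)]
      ## unit must not be a repetition of a shorter unit
      periodic <- FALSE
      if (k > 1) for (d in 1:(k - 1)) {
        if (k %% d == 0 && all(unit == rep(unit[1:d], k / d))) periodic <- TRUE
      }
      if (periodic) { i <- i + 1; next }
      reps <- 1
      while (i + (reps + 1) * k - 1 <= n &&
             all(s[(i + reps * k):(i + (reps + 1) * k - 1)] == unit)) reps <- reps + 1
      if (reps >= min_repeats && reps * k >= min_length) {
        rots <- vapply(1:k, function(r)
          paste(c(unit[r:k], unit[seq_len(r - 1)]), collapse = ""), character(1))
        hits[[length(hits) + 1]] <- data.frame(
          unit = min(rots), unit_length = k, start = i,
          end = i + reps * k - 1, repeats = reps, stringsAsFactors = FALSE)
        i <- i + reps * k
      } else i <- i + 1
    }
  }
  if (!length(hits))
    return(data.frame(unit = character(), unit_length = integer(),
                      start = integer(), end = integer(), repeats = integer()))
  loci <- do.call(rbind, hits)
  ## longest total run wins overlaps (same rule as the detector)
  loci <- loci[order(-(loci$end - loci$start + 1), loci$start, loci$unit_length), ]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(loci)) > i)
    ov <- loci$start[later] <= loci$end[i] & loci$end[later] >= loci$start[i]
    keep[later[ov]] <- FALSE
  }
  loci <- loci[keep, ]
  loci <- loci[order(loci$start), ]
  rownames(loci) <- NULL
  loci
}

## ---- Gotoh affine-gap global alignment score oracle ------------------------
## gap of length L costs open + L * extend (matching the aligner convention)
gotoh_score <- function(a, b, match = 2, mismatch = -3, open = 8, extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)    # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)    # gap in b (deletion)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in a (insertion)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## ---- small hand-built panels ----------------------------------------------
## two-group panel from explicit haplotype sequences (one accession per allele)
tiny_panel <- function(rf_seqs, wf_seqs) {
  ids <- c(paste0("Rf", seq_along(rf_seqs)), paste0("Wf", seq_along(wf_seqs)))
  seqs <- c(rf_seqs, wf_seqs)
  meta <- data.frame(
    accession_id = paste0("acc_", ids), line_name = ids,
    subtype = c(rep("RsRf", length(rf_seqs)), rep("WsWf", length(wf_seqs))),
    group = c(rep("Rf", length(rf_seqs)), rep("Wf", length(wf_seqs))),
    observed_flesh = c(rep("red", length(rf_seqs)), rep("white", length(wf_seqs))),
    allele_ids = ids, stringsAsFactors = FALSE)
  allele_panel(stats::setNames(seqs, ids), meta)
}

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
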