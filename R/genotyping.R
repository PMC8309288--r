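## Virtual PCR genotyping.
##
## Primer annealing is modelled as: exact match over the 3'-terminal bases
## (default 3) plus at most `max_mismatch` mismatches elsewhere (default 2),
## a stand-in for stringent annealing at 62 degC. An accession's band set is
## the union of its alleles' band sets; codominant length markers call
## Rf/Wf/Het/fail by band size, dominant allele-specific pairs by which
## pair(s) amplify.

#' Find primer binding sites on a template
#'
#' Scans both strands. A site requires an exact match over the 3'-terminal
#' `exact_3prime` bases and at most `max_mismatch` mismatches over the rest;
#' `N` in the template counts as a mismatch.
#'
#' @param primer primer sequence (5'->3').
#' @param template template sequence (plus strand).
#' @param max_mismatch allowed mismatches outside the 3' anchor.
#' @param exact_3prime number of 3'-terminal bases requiring exact match.
#' @return data.frame with `strand` (`+` = primer extends rightward),
#'   `start`, `end` (template coords of the matched window),
#'   `three_prime_pos` (template coord of the primer 3' end), `mismatches`.
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 2L,
                               exact_3prime = 3L) {
  primer <- toupper(as.character(primer))
  template <- toupper(as.character(template))
  Lp <- nchar(primer); Lt <- nchar(template)
  empty <- data.frame(strand = character(), start = integer(), end = integer(),
                      three_prime_pos = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (Lp > Lt) {
    warning("primer longer than template")
    return(empty)
  }
  tmpl <- Biostrings::DNAString(template)
  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), tmpl,
                                     max.mismatch = max_mismatch, fixed = TRUE)
    if (!length(hits)) return(empty)
    st <- Biostrings::start(hits); en <- Biostrings::end(hits)
    rows <- lapply(seq_along(st), function(i) {
      win <- substr(template, st[i], en[i])
      mm_vec <- strsplit(win, "")[[1]] != strsplit(pat, "")[[1]]
      mm <- sum(mm_vec)
      if (strand == "+") {
        anchor_bad <- any(mm_vec[(Lp - exact_3prime + 1L):Lp])
        tpp <- en[i]
      } else {
        anchor_bad <- any(mm_vec[seq_len(exact_3prime)])
        tpp <- st[i]
      }
      if (anchor_bad || mm > max_mismatch) return(NULL)
      data.frame(strand = strand, start = st[i], end = en[i],
                 three_prime_pos = tpp, mismatches = mm,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(empty)
    do.call(rbind, rows)
  }
  plus <- scan_one(primer, "+")
  minus <- scan_one(revcomp(primer), "-")
  out <- rbind(plus, minus)
  rownames(out) <- NULL
  out
}

#' Simulate PCR of a primer pair on one template
#'
#' Reports an amplicon for every convergent pair of binding sites (a
#' plus-strand site of either primer upstream of a minus-strand site of
#' either primer) within the size range; amplicon size is the distance
#' between the outer primer 5' ends, inclusive.
#'
#' @param fw,rv primer sequences.
#' @param template template sequence.
#' @param size_range numeric length-2 allowed product size range (nt).
#' @param max_mismatch,exact_3prime annealing model (see
#'   [find_binding_sites()]).
#' @return data.frame with `size`, `start`, `end` (template coordinates of
#'   the product).
#' @export
simulate_pcr <- function(fw, rv, template, size_range = c(50L, 3000L),
                         max_mismatch = 2L, exact_3prime = 3L) {
  sites <- rbind(find_binding_sites(fw, template, max_mismatch, exact_3prime),
                 find_binding_sites(rv, template, max_mismatch, exact_3prime))
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(plus) && nrow(minus)) {
    for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
      a <- plus$start[i]              # fw 5' end
      b <- minus$end[j]               # rv 5' end
      if (plus$end[i] > minus$start[j]) next   # divergent / overlapping 3'
      size <- b - a + 1L
      if (size < size_range[1] || size > size_range[2]) next
      out[[length(out) + 1L]] <- data.frame(size = size, start = a, end = b)
    }
  }
  if (!length(out))
    return(data.frame(size = integer(), start = integer(), end = integer()))
  amp <- unique(do.call(rbind, out))
  amp <- amp[order(amp$start, amp$size), , drop = FALSE]
  rownames(amp) <- NULL
  amp
}

## band set of a primer set on one allele sequence
marker_bands <- function(marker, allele_seq, constraints_range = c(50L, 3000L)) {
  if (marker$mode == "codominant_length") {
    amp <- simulate_pcr(marker$primers$fw, marker$primers$rv, allele_seq,
                        size_range = constraints_range)
    data.frame(pair = rep("common", nrow(amp)), size = amp$size)
  } else {
    out <- list()
    for (g in names(marker$primers)) {
      amp <- simulate_pcr(marker$primers[[g]]$fw, marker$primers[[g]]$rv,
                          allele_seq, size_range = constraints_range)
      if (nrow(amp))
        out[[g]] <- data.frame(pair = g, size = amp$size)
    }
    if (!length(out)) data.frame(pair = character(), size = integer())
    else do.call(rbind, out)
  }
}

#' Call one marker's genotype for one accession
#'
#' Codominant length markers match the accession's band sizes (union over
#' its alleles) to the expected class sizes within `size_tol` nt: Rf size
#' only -> `Rf`, Wf only -> `Wf`, both -> `Het`, none -> `fail`. Dominant
#' allele-specific pairs call by which pair amplifies. If the two expected
#' class sizes are within tolerance of each other, the marker cannot
#' discriminate and the call is `fail` with a warning.
#'
#' @param marker a `primer_set`.
#' @param alleles `DNAStringSet` (1 or 2 sequences) of the accession.
#' @param size_tol band-size tolerance in nt (gel resolution stand-in).
#' @param size_range global allowed amplicon size range.
#' @return list with `call` (`Rf`/`Wf`/`Het`/`fail`) and `bands`
#'   (data.frame `pair`, `size`).
#' @export
call_marker_genotype <- function(marker, alleles, size_tol = 2L,
                                 size_range = c(50L, 3000L)) {
  stopifnot(length(alleles) >= 1L, length(alleles) <= 2L)
  bands <- do.call(rbind, lapply(seq_along(alleles), function(i)
    marker_bands(marker, as.character(alleles[[i]]), size_range)))
  bands <- unique(bands)
  if (marker$mode == "codominant_length") {
    erf <- marker$expected_sizes[["Rf"]]; ewf <- marker$expected_sizes[["Wf"]]
    if (abs(erf - ewf) <= size_tol) {
      warning("marker ", marker$marker_name,
              ": expected class sizes not distinguishable at the size tolerance")
      return(list(call = "fail", bands = bands))
    }
    has_rf <- any(abs(bands$size - erf) <= size_tol)
    has_wf <- any(abs(bands$size - ewf) <= size_tol)
  } else {
    has_rf <- any(bands$pair == "Rf")
    has_wf <- any(bands$pair == "Wf")
  }
  call <- if (has_rf && has_wf) "Het" else if (has_rf) "Rf"
          else if (has_wf) "Wf" else "fail"
  list(call = call, bands = bands)
}

#' Genotype a panel with a marker suite and report concordance
#'
#' Calls every marker on every accession and compares the marker-predicted
#' flesh color with the observed phenotype. Under the default `"dominant"`
#' rule an accession is predicted red when at least one Rf allele is
#' detected (`Rf` or `Het` call); under `"recessive"`, only `Rf` calls
#' predict red. Pink or still-segregating phenotypes are tallied in a
#' separate `segregating` bucket; unknown phenotypes and failed calls are
#' `uncallable`.
#'
#' @param markers named list of `primer_set` objects (or the `markers`
#'   element of [design_marker_suite()] output).
#' @param panel the `allele_panel`.
#' @param phenotype_rule `"dominant"` or `"recessive"`.
#' @param size_tol band-size tolerance (nt).
#' @return list of class `concordance_report` with `calls` (data.frame:
#'   accession, marker, call, bands) and `concordance` (per-marker counts
#'   and fraction concordant; `concordant + discordant + uncallable +
#'   segregating = panel size`).
#' @export
genotype_panel <- function(markers, panel,
                           phenotype_rule = c("dominant", "recessive"),
                           size_tol = 2L) {
  phenotype_rule <- match.arg(phenotype_rule)
  if (!is.null(markers$markers)) markers <- markers$markers
  calls <- list()
  for (mn in names(markers)) {
    for (acc in panel$meta$accession_id) {
      res <- call_marker_genotype(markers[[mn]], accession_alleles(panel, acc),
                                  size_tol = size_tol)
      calls[[length(calls) + 1L]] <- data.frame(
        accession_id = acc, marker = mn, call = res$call,
        bands = paste(res$bands$size[order(res$bands$size)], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  obs <- setNames(panel$meta$observed_flesh, panel$meta$accession_id)
  predict_color <- function(call) {
    if (call == "Rf") "red"
    else if (call == "Wf") "white"
    else if (call == "Het") if (phenotype_rule == "dominant") "red" else "white"
    else NA_character_
  }
  conc <- list(); discordant <- list()
  for (mn in names(markers)) {
    sub <- calls[calls$marker == mn, , drop = FALSE]
    n_conc <- n_disc <- n_unc <- n_seg <- 0L
    disc_ids <- character(0)
    for (r in seq_len(nrow(sub))) {
      o <- obs[[sub$accession_id[r]]]
      if (o %in% c("pink", "segregating")) { n_seg <- n_seg + 1L; next }
      pred <- predict_color(sub$call[r])
      if (is.na(pred) || !o %in% c("red", "white")) { n_unc <- n_unc + 1L; next }
      if (pred == o) n_conc <- n_conc + 1L
      else { n_disc <- n_disc + 1L; disc_ids <- c(disc_ids, sub$accession_id[r]) }
    }
    frac <- if (n_conc + n_disc > 0L) n_conc / (n_conc + n_disc) else NA_real_
    conc[[mn]] <- data.frame(marker = mn, n = nrow(sub), concordant = n_conc,
                             discordant = n_disc, uncallable = n_unc,
                             segregating = n_seg, fraction = frac,
                             stringsAsFactors = FALSE)
    discordant[[mn]] <- disc_ids
  }
  concordance <- do.call(rbind, conc)
  rownames(concordance) <- NULL
  structure(list(calls = calls, concordance = concordance,
                 discordant = discordant, phenotype_rule = phenotype_rule),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("genotype-phenotype concordance (rule:", x$phenotype_rule, ")\n")
  print(x$concordance, row.names = FALSE)
  invisible(x)
}
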