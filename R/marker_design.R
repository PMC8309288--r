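## PCR marker design from classified variants.
##
## Four marker types are attempted on a classified panel, mirroring the
## published marker set for flesh color:
##   PS-P   dominant allele-specific pair over diagnostic promoter SNPs in a
##          fixed upstream window,
##   ID-P   codominant length marker over the 14-nt promoter insertion,
##   SSR-P  codominant length marker over the (TC) microsatellite,
##   WD/AD-P dominant allele-specific pair anchored on the intron-5 CAT InDel
##          (forward) and a diagnostic exon-6 SNP (reverse).

#' Primer design constraints
#'
#' Defaults target the validation PCR program (annealing 62 degC): primer
#' length 18-24 nt, Wallace Tm 55-65 degC, GC 40-60%, amplicon 100-1200 bp,
#' mononucleotide runs of at most 4.
#'
#' @param length_range,tm_range,gc_range,amplicon_range numeric length-2
#'   vectors (min, max).
#' @param max_run maximum mononucleotide run length.
#' @param tm_method `"wallace"` (default) or `"nn"` (nearest-neighbor).
#' @return a `primer_constraints` list.
#' @export
primer_constraints <- function(length_range = c(18L, 24L),
                               tm_range = c(55, 65),
                               gc_range = c(40, 60),
                               amplicon_range = c(100L, 1200L),
                               max_run = 4L,
                               tm_method = c("wallace", "nn")) {
  tm_method <- match.arg(tm_method)
  stopifnot(length_range[1] <= length_range[2], tm_range[1] <= tm_range[2],
            gc_range[1] <= gc_range[2], amplicon_range[1] <= amplicon_range[2])
  structure(list(length_range = as.integer(length_range), tm_range = tm_range,
                 gc_range = gc_range, amplicon_range = as.integer(amplicon_range),
                 max_run = as.integer(max_run), tm_method = tm_method),
            class = "primer_constraints")
}

#' Primer melting temperature
#'
#' Default is the Wallace rule, Tm = 2(A+T) + 4(G+C) degC. `method = "nn"`
#' uses unified nearest-neighbor thermodynamics (SantaLucia-style dH/dS
#' increments with initiation and terminal corrections, monovalent-salt
#' entropy correction): Tm = 1000*dH / (dS_salt + R ln(C/4)) - 273.15.
#'
#' @param primer DNA string over A/C/G/T, length >= 8.
#' @param method `"wallace"` or `"nn"`.
#' @param conc_nM total primer concentration (nM; nn only).
#' @param na_mM monovalent cation concentration (mM; nn only).
#' @return Tm in degC.
#' @export
compute_tm <- function(primer, method = c("wallace", "nn"),
                       conc_nM = 250, na_mM = 50) {
  method <- match.arg(method)
  p <- toupper(as.character(primer))
  if (nchar(p) < 8L) stop("input error: primer shorter than 8 nt")
  b <- strsplit(p, "")[[1]]
  if (!all(b %in% BASES)) stop("input error: ambiguous base in primer")
  if (method == "wallace") {
    at <- sum(b %in% c("A", "T")); gc <- sum(b %in% c("G", "C"))
    return(2 * at + 4 * gc)
  }
  nn <- nn_params()
  pairs <- paste0(b[-length(b)], b[-1L])
  dH <- sum(nn$dH[pairs])
  dS <- sum(nn$dS[pairs])
  for (term in c(b[1L], b[length(b)])) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS_salt <- dS + 0.368 * (length(b) - 1L) * log(na_mM / 1000)
  R <- 1.987
  1000 * dH / (dS_salt + R * log(conc_nM * 1e-9 / 4)) - 273.15
}

## unified NN increments (kcal/mol, cal/mol/K), 5'->3' top-strand doublets
nn_params <- function() {
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  list(dH = dH, dS = dS)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

gc_percent <- function(x) {
  b <- strsplit(toupper(x), "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

max_mono_run <- function(x) {
  r <- rle(strsplit(toupper(x), "")[[1]])
  max(r$lengths)
}

## constraint screen for one primer sequence
primer_ok <- function(seq, constraints) {
  L <- nchar(seq)
  if (L < constraints$length_range[1] || L > constraints$length_range[2])
    return(FALSE)
  tm <- compute_tm(seq, method = constraints$tm_method)
  if (tm < constraints$tm_range[1] || tm > constraints$tm_range[2]) return(FALSE)
  gc <- gc_percent(seq)
  if (gc < constraints$gc_range[1] || gc > constraints$gc_range[2]) return(FALSE)
  if (max_mono_run(seq) > constraints$max_run) return(FALSE)
  TRUE
}

## ranking key: |Tm - 60|, then |GC - 50|, then leftmost 5' position
rank_key <- function(seq, pos5) {
  c(abs(compute_tm(seq) - 60), abs(gc_percent(seq) - 50), pos5)
}

## ---------------------------------------------------------------------------
## Variant-aware coordinate plumbing
## ---------------------------------------------------------------------------

## reference footprints of variants; length_varying marks InDel/SSR spans
variant_footprints <- function(variants) {
  if (!nrow(variants))
    return(data.frame(start = integer(), end = integer(),
                      length_varying = logical()))
  st <- variants$genomic_pos
  en <- variants$genomic_pos
  lv <- variants$kind != "SNP"
  for (i in seq_len(nrow(variants))) {
    if (variants$kind[i] == "InDel") {
      states <- allele_states(variants[i, ])
      if (any(startsWith(stats::na.omit(states), "+"))) {   # insertion
        st[i] <- variants$genomic_pos[i] - 1L
        en[i] <- variants$genomic_pos[i]
      } else {
        en[i] <- variants$genomic_pos[i] + variants$length[i] - 1L
      }
    } else if (variants$kind[i] == "SSR") {
      en[i] <- variants$genomic_pos[i] + variants$length[i] - 1L
    }
  }
  data.frame(start = st, end = en, length_varying = lv)
}

## logical mask over reference positions free of any variant footprint (+/-1)
conserved_mask <- function(variants, ref_len) {
  mask <- rep(TRUE, ref_len)
  fp <- variant_footprints(variants)
  for (i in seq_len(nrow(fp))) {
    a <- max(1L, fp$start[i] - 1L); b <- min(ref_len, fp$end[i] + 1L)
    mask[a:b] <- FALSE
  }
  mask
}

## precomputed per-allele length-offset tables: for allele `id`,
## offset_at(off[[id]], p) is the signed length difference vs the reference
## accumulated strictly before reference position p
build_offsets <- function(variants, ids) {
  ev <- lapply(ids, function(id) list(act = integer(0), delta = integer(0)))
  names(ev) <- ids
  for (i in seq_len(nrow(variants))) {
    kind <- variants$kind[i]
    if (kind == "SNP") next
    states <- allele_states(variants[i, ])
    pos <- variants$genomic_pos[i]
    for (id in ids) {
      stt <- states[[id]]
      if (is.na(stt)) next
      if (kind == "InDel") {
        if (startsWith(stt, "+")) {
          ev[[id]]$act <- c(ev[[id]]$act, pos)            # active for p >= pos
          ev[[id]]$delta <- c(ev[[id]]$delta, nchar(stt) - 1L)
        } else if (startsWith(stt, "-") && stt != "-") {
          L <- nchar(stt) - 1L
          ev[[id]]$act <- c(ev[[id]]$act, pos + L)        # active past deletion
          ev[[id]]$delta <- c(ev[[id]]$delta, -L)
        }
      } else {                                            # SSR
        k <- nchar(variants$unit[i])
        ref_rep <- variants$length[i] %/% k
        d <- (as.integer(stt) - ref_rep) * k
        if (d != 0L) {
          ev[[id]]$act <- c(ev[[id]]$act, pos + variants$length[i])
          ev[[id]]$delta <- c(ev[[id]]$delta, d)
        }
      }
    }
  }
  lapply(ev, function(e) {
    o <- order(e$act)
    list(act = e$act[o], cum = cumsum(e$delta[o]))
  })
}

offset_at <- function(off, p) {
  i <- findInterval(p, off$act)
  if (i == 0L) 0L else off$cum[i]
}

## signed length offset of `allele_id` relative to reference before ref pos p
allele_offset <- function(p, allele_id, variants, offsets = NULL) {
  if (is.null(offsets)) offsets <- build_offsets(variants, allele_id)
  offset_at(offsets[[allele_id]], p)
}

## reference position -> allele position (valid outside varying footprints)
map_ref_pos <- function(p, allele_id, variants, offsets = NULL)
  p + allele_offset(p, allele_id, variants, offsets)

## representative allele id per group (first by sorted id)
group_representatives <- function(panel) {
  info <- panel$allele_info
  vapply(GROUPS, function(g) {
    ids <- sort(info$allele_id[!is.na(info$group) & info$group == g])
    if (length(ids)) ids[1] else NA_character_
  }, character(1))
}

## ---------------------------------------------------------------------------
## Codominant length markers (InDel / SSR targets)
## ---------------------------------------------------------------------------

#' Design a codominant length marker over an InDel or SSR target
#'
#' Finds a conserved forward/reverse primer pair flanking the target so that
#' the primers bind identically in every panel allele and the amplicon
#' contains no other length-varying site; allele classes are then separable
#' by product size, and the Rf/Wf size difference equals the target's length
#' difference.
#'
#' @param target one row of a `variant_table` with kind `InDel` or `SSR`.
#' @param panel the `allele_panel`.
#' @param variants the full `variant_table` (for conservation and offsets).
#' @param constraints a [primer_constraints()].
#' @param search_span how far (nt) from the target to search for primer
#'   windows.
#' @param marker_name label for the resulting marker.
#' @return a `primer_set` (mode `codominant_length`); design failure raises
#'   an error with a diagnostic.
#' @export
design_length_marker <- function(target, panel, variants,
                                 constraints = primer_constraints(),
                                 search_span = 150L, marker_name = "LEN") {
  stopifnot(target$kind %in% c("InDel", "SSR"))
  ref_id <- reference_allele_id(panel)
  refseq <- as.character(panel$alleles[[ref_id]])
  L <- nchar(refseq)
  mask <- conserved_mask(variants, L)
  fp <- variant_footprints(variants)
  tfp <- variant_footprints(target)
  ts <- tfp$start[1]; te <- tfp$end[1]

  window_ok <- function(a, b) a >= 1L && b <= L && all(mask[a:b])
  candidates <- function(side) {
    out <- list()
    lens <- seq(constraints$length_range[1], constraints$length_range[2])
    if (side == "fw") {
      for (e in seq(ts - 1L, max(1L, ts - search_span))) {
        for (len in lens) {
          a <- e - len + 1L
          if (a < 1L || !window_ok(a, e)) next
          seqc <- substr(refseq, a, e)
          if (!primer_ok(seqc, constraints)) next
          out[[length(out) + 1L]] <- list(seq = seqc, start = a, end = e)
        }
      }
    } else {
      for (s in seq(te + 1L, min(L, te + search_span))) {
        for (len in lens) {
          b <- s + len - 1L
          if (b > L || !window_ok(s, b)) next
          seqc <- revcomp(substr(refseq, s, b))
          if (!primer_ok(seqc, constraints)) next
          out[[length(out) + 1L]] <- list(seq = seqc, start = s, end = b)
        }
      }
    }
    out
  }
  fw_cands <- candidates("fw")
  rv_cands <- candidates("rv")
  if (!length(fw_cands) || !length(rv_cands))
    stop("design failure (", marker_name,
         "): no conserved primer window flanking the target")
  order_by_rank <- function(cands)
    cands[order(vapply(cands, function(cc) rank_key(cc$seq, cc$start)[1], numeric(1)),
                vapply(cands, function(cc) rank_key(cc$seq, cc$start)[2], numeric(1)),
                vapply(cands, function(cc) cc$start, numeric(1)))]
  fw_cands <- order_by_rank(fw_cands)
  rv_cands <- order_by_rank(rv_cands)

  other_lv <- fp[fp$length_varying &
                 !(fp$start == ts & fp$end == te), , drop = FALSE]
  ids <- names(panel$alleles)
  offsets <- build_offsets(variants, ids)
  for (fw in fw_cands) for (rv in rv_cands) {
    ref_size <- rv$end - fw$start + 1L
    ## no other length-varying site inside the amplicon
    if (nrow(other_lv) &&
        any(other_lv$start <= rv$end & other_lv$end >= fw$start)) next
    sizes <- vapply(ids, function(id)
      ref_size + offset_at(offsets[[id]], rv$end + 1L) -
        offset_at(offsets[[id]], fw$start), integer(1))
    if (any(sizes < constraints$amplicon_range[1]) ||
        any(sizes > constraints$amplicon_range[2])) next
    grp <- panel$allele_info$group[match(ids, panel$allele_info$allele_id)]
    rf_sizes <- unique(sizes[grp %in% "Rf"]); wf_sizes <- unique(sizes[grp %in% "Wf"])
    if (length(rf_sizes) != 1L || length(wf_sizes) != 1L) next
    if (rf_sizes == wf_sizes) next
    ps <- structure(list(
      marker_name = marker_name, mode = "codominant_length",
      primers = list(fw = fw$seq, rv = rv$seq),
      fw_start = fw$start, rv_end = rv$end,
      expected_sizes = c(Rf = rf_sizes, Wf = wf_sizes),
      anchored_sites = data.frame(kind = target$kind,
                                  genomic_pos = target$genomic_pos,
                                  stringsAsFactors = FALSE),
      tm = c(fw = compute_tm(fw$seq), rv = compute_tm(rv$seq))),
      class = "primer_set")
    return(ps)
  }
  stop("design failure (", marker_name,
       "): no primer pair satisfies size and conservation constraints")
}

## ---------------------------------------------------------------------------
## Dominant allele-specific pairs (SNP / InDel anchored at the 3' end)
## ---------------------------------------------------------------------------

## allele coordinate of the 3' junction of an anchor site for one allele
anchor_end_pos <- function(site, allele_id, variants, offsets = NULL) {
  pos <- site$genomic_pos
  if (site$kind == "SNP") return(map_ref_pos(pos, allele_id, variants, offsets))
  states <- allele_states(site)
  ## insertions: map past the event; deletions: past the deleted span
  any_ins <- any(startsWith(stats::na.omit(states), "+"))
  after <- if (any_ins) pos else pos + site$length
  map_ref_pos(after, allele_id, variants, offsets) - 1L
}

#' Design a dominant allele-specific primer pair marker
#'
#' Builds one primer pair per group (Rf-specific and Wf-specific). Each
#' pair's primers are taken from that group's own haplotype with the 3'
#' terminus anchored on a diagnostic site (SNP base, or the InDel junction),
#' so the pair amplifies its own haplotype and fails on the other group's
#' (3'-terminal mismatch under the annealing model). The forward primer is
#' anchored on the leftmost usable site and the reverse on a downstream
#' site; validation is by in-silico PCR against every panel allele.
#'
#' @param sites rows of a `variant_table` with specificity `Rf_vs_Wf` to
#'   anchor on (>= 2 sites, or 1 InDel + 1 SNP, within amplicon range).
#' @param panel the `allele_panel`.
#' @param variants the full `variant_table`.
#' @param constraints a [primer_constraints()].
#' @param marker_name label.
#' @param annealing binding model used for validation (see
#'   [find_binding_sites()]).
#' @return a `primer_set` (mode `dominant_allele_specific_pair`); raises an
#'   error with a diagnostic on design failure.
#' @export
design_allele_specific_pair <- function(sites, panel, variants,
                                        constraints = primer_constraints(),
                                        marker_name = "AS",
                                        annealing = list(max_mismatch = 2L,
                                                         exact_3prime = 3L)) {
  sites <- sites[sites$specificity == "Rf_vs_Wf", , drop = FALSE]
  if (nrow(sites) < 2L)
    stop("design failure (", marker_name,
         "): need at least two diagnostic sites to anchor both primers")
  sites <- sites[order(sites$genomic_pos), , drop = FALSE]
  reps <- group_representatives(panel)
  if (anyNA(reps))
    stop("design failure (", marker_name, "): panel lacks one of the groups")
  seqs <- lapply(reps, function(id) as.character(panel$alleles[[id]]))
  names(seqs) <- names(reps)
  info <- panel$allele_info
  offsets <- build_offsets(variants, names(panel$alleles))

  build_primer <- function(site, group, orientation) {
    rep_id <- reps[[group]]
    s <- seqs[[group]]
    pa <- anchor_end_pos(site, rep_id, variants, offsets)
    extras <- if (site$kind == "SNP") 0L else 0L:3L
    best <- NULL
    for (extra in extras) {
      for (len in seq(constraints$length_range[1], constraints$length_range[2])) {
        if (orientation == "fw") {
          e <- pa + extra
          a <- e - len + 1L
          if (a < 1L || e > nchar(s)) next
          cand <- substr(s, a, e)
          pos5 <- a
        } else {
          a <- pa - extra
          b <- a + len - 1L
          if (a < 1L || b > nchar(s)) next
          cand <- revcomp(substr(s, a, b))
          pos5 <- b
        }
        if (!primer_ok(cand, constraints)) next
        ## discrimination: site on own haplotype, none on the other
        other <- setdiff(GROUPS, group)
        own_hit <- nrow(find_binding_sites(cand, s, max_mismatch = 0L,
                                           exact_3prime = annealing$exact_3prime))
        oth_hit <- nrow(find_binding_sites(cand, seqs[[other]],
                                           max_mismatch = annealing$max_mismatch,
                                           exact_3prime = annealing$exact_3prime))
        if (own_hit < 1L || oth_hit > 0L) next
        key <- rank_key(cand, pos5)
        if (is.null(best) ||
            key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]) ||
            (key[1] == best$key[1] && key[2] == best$key[2] && key[3] < best$key[3]))
          best <- list(seq = cand, key = key)
      }
    }
    if (is.null(best)) return(NULL)
    best$seq
  }

  ## candidate (fw site, rv site) pairs: leftmost anchor forward, downstream
  ## anchor reverse, within amplicon range
  n <- nrow(sites)
  for (i in seq_len(n - 1L)) for (j in seq(n, i + 1L)) {
    span <- sites$genomic_pos[j] - sites$genomic_pos[i] + 1L
    if (span < constraints$amplicon_range[1] - 40L ||
        span > constraints$amplicon_range[2]) next
    pair_ok <- TRUE
    primers <- list()
    for (g in GROUPS) {
      fw <- build_primer(sites[i, ], g, "fw")
      rv <- build_primer(sites[j, ], g, "rv")
      if (is.null(fw) || is.null(rv)) { pair_ok <- FALSE; break }
      primers[[g]] <- list(fw = fw, rv = rv)
    }
    if (!pair_ok) next
    ## validate by virtual PCR on every panel allele
    sizes <- c(Rf = NA_integer_, Wf = NA_integer_)
    valid <- TRUE
    for (g in GROUPS) {
      own_ids <- info$allele_id[!is.na(info$group) & info$group == g]
      oth_ids <- info$allele_id[!is.na(info$group) & info$group != g]
      own_sizes <- integer(0)
      for (id in own_ids) {
        amp <- simulate_pcr(primers[[g]]$fw, primers[[g]]$rv,
                            as.character(panel$alleles[[id]]),
                            size_range = constraints$amplicon_range)
        if (nrow(amp) != 1L) { valid <- FALSE; break }
        own_sizes <- c(own_sizes, amp$size)
      }
      if (!valid) break
      for (id in oth_ids) {
        amp <- simulate_pcr(primers[[g]]$fw, primers[[g]]$rv,
                            as.character(panel$alleles[[id]]),
                            size_range = constraints$amplicon_range)
        if (nrow(amp) > 0L) { valid <- FALSE; break }
      }
      if (!valid) break
      sizes[g] <- own_sizes[1]
    }
    if (!valid) next
    return(structure(list(
      marker_name = marker_name, mode = "dominant_allele_specific_pair",
      primers = primers,
      expected_sizes = sizes,
      anchored_sites = sites[c(i, j), c("kind", "genomic_pos"), drop = FALSE],
      tm = c(Rf_fw = compute_tm(primers$Rf$fw), Rf_rv = compute_tm(primers$Rf$rv),
             Wf_fw = compute_tm(primers$Wf$fw), Wf_rv = compute_tm(primers$Wf$rv))),
      class = "primer_set"))
  }
  stop("design failure (", marker_name,
       "): no diagnostic site pair yields discriminating primers under constraints")
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("primer_set %s [%s]\n", x$marker_name, x$mode))
  if (x$mode == "codominant_length") {
    cat("  fw:", x$primers$fw, "\n  rv:", x$primers$rv, "\n")
  } else {
    cat("  Rf-Sp fw:", x$primers$Rf$fw, " rv:", x$primers$Rf$rv, "\n")
    cat("  Wf-Sp fw:", x$primers$Wf$fw, " rv:", x$primers$Wf$rv, "\n")
  }
  cat(sprintf("  expected sizes: Rf=%s, Wf=%s\n",
              x$expected_sizes[["Rf"]], x$expected_sizes[["Wf"]]))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Marker suite
## ---------------------------------------------------------------------------

#' Design the four flesh-color marker types
#'
#' Attempts, in order: PS-P (allele-specific pair over diagnostic promoter
#' SNPs inside `promoter_window`), ID-P (length marker over the largest
#' group-diagnostic promoter InDel, ties broken toward the ATG), SSR-P
#' (length marker over the group-diagnostic SSR with the largest repeat-count
#' spread) and WD/AD-P (allele-specific pair anchored on a group-diagnostic
#' intronic InDel and a downstream exonic SNP). Failures are reported, not
#' raised.
#'
#' @param panel the `allele_panel`.
#' @param variants the classified `variant_table`.
#' @param model the `gene_model`.
#' @param constraints a [primer_constraints()].
#' @param promoter_window ATG-relative window for PS-P anchor SNPs.
#' @return list with `markers` (named list of `primer_set`) and `failures`
#'   (named character vector of diagnostics).
#' @export
design_marker_suite <- function(panel, variants, model,
                                constraints = primer_constraints(),
                                promoter_window = c(-979L, -818L)) {
  markers <- list(); failures <- character(0)
  diag <- variants[variants$specificity == "Rf_vs_Wf", , drop = FALSE]
  attempt <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (inherits(res, "primer_set")) markers[[name]] <<- res
    else failures[[name]] <<- as.character(res)
  }

  ## PS-P: promoter allele-specific pair
  attempt("PS-P", {
    win <- sort(from_anchor(promoter_window, model, "atg"))
    ps_sites <- diag[diag$kind == "SNP" & diag$region == "promoter" &
                     diag$genomic_pos >= win[1] & diag$genomic_pos <= win[2], ,
                     drop = FALSE]
    if (nrow(ps_sites) < 2L)
      stop("design failure (PS-P): fewer than two diagnostic SNPs in the promoter window")
    cons <- constraints
    cons$amplicon_range <- c(min(constraints$amplicon_range[1], 60L),
                             constraints$amplicon_range[2])
    design_allele_specific_pair(ps_sites, panel, variants, cons,
                                marker_name = "PS-P")
  })

  ## ID-P: promoter InDel length marker
  attempt("ID-P", {
    cand <- diag[diag$kind == "InDel" & diag$region == "promoter", , drop = FALSE]
    if (!nrow(cand)) stop("design failure (ID-P): no diagnostic promoter InDel")
    cand <- cand[order(-cand$length, -cand$genomic_pos), , drop = FALSE]
    design_length_marker(cand[1, ], panel, variants, constraints,
                         marker_name = "ID-P")
  })

  ## SSR-P: microsatellite length marker
  attempt("SSR-P", {
    cand <- diag[diag$kind == "SSR", , drop = FALSE]
    if (!nrow(cand)) stop("design failure (SSR-P): no diagnostic SSR locus")
    spread <- vapply(seq_len(nrow(cand)), function(i) {
      reps <- suppressWarnings(as.integer(allele_states(cand[i, ])))
      (max(reps, na.rm = TRUE) - min(reps, na.rm = TRUE)) * nchar(cand$unit[i])
    }, numeric(1))
    cand <- cand[order(-spread), , drop = FALSE]
    design_length_marker(cand[1, ], panel, variants, constraints,
                         marker_name = "SSR-P")
  })

  ## WD/AD-P: intron InDel (fw) + downstream exon SNP (rv)
  attempt("WD/AD-P", {
    ind <- diag[diag$kind == "InDel" & grepl("^intron_", diag$region), ,
                drop = FALSE]
    snp <- diag[diag$kind == "SNP" & grepl("^exon_", diag$region), , drop = FALSE]
    if (!nrow(ind) || !nrow(snp))
      stop("design failure (WD/AD-P): need an intronic diagnostic InDel and an exonic diagnostic SNP")
    snp <- snp[snp$genomic_pos > min(ind$genomic_pos), , drop = FALSE]
    if (!nrow(snp))
      stop("design failure (WD/AD-P): no exonic diagnostic SNP downstream of the InDel")
    sites <- rbind(ind[which.min(ind$genomic_pos), , drop = FALSE],
                   snp[order(snp$genomic_pos), , drop = FALSE])
    cons <- constraints
    cons$amplicon_range <- c(min(constraints$amplicon_range[1], 60L),
                             constraints$amplicon_range[2])
    design_allele_specific_pair(sites, panel, variants, cons,
                                marker_name = "WD/AD-P")
  })

  list(markers = markers, failures = failures)
}

#' Write a marker suite as TSV
#' @param suite result of [design_marker_suite()].
#' @param path output path.
#' @param header optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_markers <- function(suite, path, header = NULL) {
  rows <- lapply(suite$markers, function(m) {
    if (m$mode == "codominant_length")
      data.frame(marker = m$marker_name, mode = m$mode,
                 primer_class = "common", fw = m$primers$fw, rv = m$primers$rv,
                 size_Rf = m$expected_sizes[["Rf"]],
                 size_Wf = m$expected_sizes[["Wf"]], stringsAsFactors = FALSE)
    else
      data.frame(marker = m$marker_name, mode = m$mode,
                 primer_class = c("Rf-Sp", "Wf-Sp"),
                 fw = c(m$primers$Rf$fw, m$primers$Wf$fw),
                 rv = c(m$primers$Rf$rv, m$primers$Wf$rv),
                 size_Rf = c(m$expected_sizes[["Rf"]], NA),
                 size_Wf = c(NA, m$expected_sizes[["Wf"]]),
                 stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(), mode = character(),
               primer_class = character(), fw = character(), rv = character(),
               size_Rf = integer(), size_Wf = integer())
  if (length(suite$failures))
    df <- rbind(df, data.frame(marker = names(suite$failures), mode = "FAILED",
                               primer_class = NA, fw = NA, rv = NA,
                               size_Rf = NA, size_Wf = NA))
  write_tsv(df, path, header = header)
}
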