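## Variant identification and classification.
##
## Alleles are aligned pairwise against a reference allele (the first
## red-fleshed allele by sorted id); gap columns become InDel events, length
## variation inside a detected microsatellite locus becomes SSR repeat-count
## variation, and every polymorphism is classified by gene region and by
## group specificity (diagnostic between Rf and Wf, specific to one
## white-fleshed subtype, or nondiagnostic).

#' Global pairwise alignment of two allele sequences
#'
#' Needleman-Wunsch with affine gap penalties via
#' [Biostrings::pairwiseAlignment()] (defaults: match 2, mismatch -3, gap
#' open -8, gap extend -1; a gap of length L costs open + L*extend). `N`
#' scores 0 against everything so missing bases neither reward nor punish.
#'
#' @param reference,query DNA sequences (character or `DNAString`).
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   given as positive costs for the gap terms).
#' @return a `PairwiseAlignments` object.
#' @export
align_pair <- function(reference, query, match = 2, mismatch = -3,
                       gap_open = 8, gap_extend = 1) {
  stopifnot(nchar(as.character(reference)) > 0, nchar(as.character(query)) > 0)
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", ] <- 0; mat[, "N"] <- 0
  Biostrings::pairwiseAlignment(Biostrings::DNAString(as.character(reference)),
                                Biostrings::DNAString(as.character(query)),
                                type = "global", substitutionMatrix = mat,
                                gapOpening = gap_open, gapExtension = gap_extend)
}

#' Detect microsatellite (SSR) loci in a sequence
#'
#' Finds maximal tandem runs of units of 1-6 nt. A run must reach
#' `min_repeats` full repeats and `min_length` total nt. Units are reported
#' as their lexicographically smallest rotation; runs whose unit is itself a
#' repetition of a shorter unit are suppressed, and when runs of different
#' unit sizes overlap, the longer total run wins.
#'
#' @param sequence DNA character scalar.
#' @param min_unit,max_unit unit-length bounds (nt).
#' @param min_repeats minimum full repeat count.
#' @param min_length minimum run length (nt) counting full repeats only.
#' @return data.frame with `unit`, `unit_length`, `start`, `end`, `repeats`
#'   (full repeats; `end = start + repeats*unit_length - 1`).
#' @export
detect_ssr_loci <- function(sequence, min_unit = 1L, max_unit = 6L,
                            min_repeats = 4L, min_length = 8L) {
  stopifnot(min_unit >= 1L, max_unit >= min_unit, min_repeats > 0, min_length > 0)
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  n <- length(s)
  out <- list()
  for (k in min_unit:max_unit) {
    if (n < 2L * k) next
    m <- s[seq_len(n - k)] == s[(k + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      run_len <- r$lengths[i] + k          # total periodic stretch in nt
      reps <- run_len %/% k
      if (reps < min_repeats || reps * k < min_length) next
      a <- starts[i]
      unit <- paste(s[a:(a + k - 1L)], collapse = "")
      if (is_periodic_unit(unit)) next     # covered at a smaller unit size
      out[[length(out) + 1L]] <- data.frame(
        unit = canonical_rotation(unit), unit_length = k,
        start = a, end = a + reps * k - 1L, repeats = reps,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(unit = character(), unit_length = integer(),
                      start = integer(), end = integer(), repeats = integer(),
                      stringsAsFactors = FALSE))
  loci <- do.call(rbind, out)
  ## greedy resolution of overlaps: longest total run first
  loci <- loci[order(-(loci$end - loci$start + 1L), loci$start, loci$unit_length), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(loci)) > i)
    if (!length(later)) next
    ov <- loci$start[later] <= loci$end[i] & loci$end[later] >= loci$start[i]
    keep[later[ov]] <- FALSE
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

## smallest lexicographic rotation of a repeat unit
canonical_rotation <- function(unit) {
  k <- nchar(unit)
  rots <- vapply(seq_len(k), function(i)
    paste0(substr(unit, i, k), substr(unit, 1, i - 1L)), character(1))
  min(rots)
}

## TRUE if the unit is a whole-number repetition of a shorter unit
is_periodic_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(FALSE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (identical(strrep(substr(unit, 1, d), k %/% d), unit)) return(TRUE)
  }
  FALSE
}

## ---------------------------------------------------------------------------
## Alignment -> edit events
## ---------------------------------------------------------------------------

## parse one global alignment into per-allele edit events in reference coords:
## substitutions (pos, ref, alt) and indels (pos, len signed, seq)
alignment_events <- function(pa) {
  rp <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  qp <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  n <- length(rp)
  ref_pos <- cumsum(rp != "-")
  subs <- list(); indels <- list()
  i <- 1L
  while (i <= n) {
    if (rp[i] != "-" && qp[i] != "-") {
      if (rp[i] != qp[i])
        subs[[length(subs) + 1L]] <- data.frame(pos = ref_pos[i], ref = rp[i],
                                                alt = qp[i], stringsAsFactors = FALSE)
      i <- i + 1L
    } else if (rp[i] == "-") {            # insertion in query
      j <- i
      while (j <= n && rp[j] == "-") j <- j + 1L
      ins <- paste(qp[i:(j - 1L)], collapse = "")
      ## insertion point: reference base immediately after the gap block
      indels[[length(indels) + 1L]] <- data.frame(
        pos = ref_pos[i] + 1L, len = nchar(ins), seq = ins,
        stringsAsFactors = FALSE)
      i <- j
    } else {                              # deletion in query
      j <- i
      while (j <= n && qp[j] == "-") j <- j + 1L
      del <- paste(rp[i:(j - 1L)], collapse = "")
      indels[[length(indels) + 1L]] <- data.frame(
        pos = ref_pos[i], len = -nchar(del), seq = del,
        stringsAsFactors = FALSE)
      i <- j
    }
  }
  list(subs = if (length(subs)) do.call(rbind, subs) else NULL,
       indels = if (length(indels)) do.call(rbind, indels) else NULL,
       ref_len = max(ref_pos),
       ## reference position -> aligned column (for projections)
       ref_to_col = match(seq_len(max(ref_pos)), ref_pos * (rp != "-")),
       query_cols = qp)
}

## left-align an indel event against the reference (VCF-style normalization)
left_align_indel <- function(pos, len, seq, refv) {
  if (len > 0) {                          # insertion of `seq` before refv[pos]
    s <- strsplit(seq, "")[[1]]
    while (pos > 1L && s[length(s)] == refv[pos - 1L]) {
      s <- c(s[length(s)], s[-length(s)])
      pos <- pos - 1L
    }
    list(pos = pos, seq = paste(s, collapse = ""))
  } else {                                # deletion of refv[pos .. pos+|len|-1]
    d <- -len
    while (pos > 1L && refv[pos + d - 1L] == refv[pos - 1L]) pos <- pos - 1L
    list(pos = pos, seq = paste(refv[pos:(pos + d - 1L)], collapse = ""))
  }
}

#' Choose the reference allele of a panel
#'
#' The first red-fleshed (Rf) allele by sorted allele id; if the panel has no
#' Rf allele, the first allele by sorted id.
#'
#' @param panel an `allele_panel`.
#' @return allele id (character scalar).
#' @export
reference_allele_id <- function(panel) {
  info <- panel$allele_info
  rf <- sort(info$allele_id[!is.na(info$group) & info$group == "Rf"])
  if (length(rf)) rf[1] else sort(info$allele_id)[1]
}

#' Call SNP, InDel and SSR variants across an allele panel
#'
#' Aligns every allele to the panel's reference allele, merges gap columns
#' into left-aligned InDel events, converts length variation inside a
#' reference microsatellite locus into SSR repeat-count variation (never
#' InDels), drops substitutions supported only by `N` bases, classifies each
#' variant's group specificity and coding effect, and returns one row per
#' variant with the state of every allele.
#'
#' @param panel an `allele_panel`.
#' @param model the `gene_model` for the reference allele.
#' @param reference_id reference allele id; default [reference_allele_id()].
#' @param ssr_min_repeats,ssr_min_length thresholds for [detect_ssr_loci()]
#'   on the reference.
#' @param anchor anchor for reported positions (`"atg"` default).
#' @return data.frame of class `variant_table`: `kind`, `genomic_pos`,
#'   `pos_atg` (or TSS-relative when `anchor = "tss"`), `region`,
#'   `region_class`, `length`, `unit`, `specificity`, `coding_effect`,
#'   `ambiguous`, plus one `state.<allele_id>` column per allele (base for
#'   SNPs, `-`/`+SEQ`/`-SEQ` for InDels, integer repeat count for SSRs).
#' @export
call_variants <- function(panel, model, reference_id = reference_allele_id(panel),
                          ssr_min_repeats = 4L, ssr_min_length = 8L,
                          anchor = c("atg", "tss")) {
  anchor <- match.arg(anchor)
  ids <- names(panel$alleles)
  stopifnot(reference_id %in% ids)
  refseq <- as.character(panel$alleles[[reference_id]])
  refv <- strsplit(refseq, "")[[1]]
  others <- setdiff(ids, reference_id)
  loci <- detect_ssr_loci(refseq, min_repeats = ssr_min_repeats,
                          min_length = ssr_min_length)

  subs <- list(); indels <- list(); ssr_len <- list()
  for (id in others) {
    ev <- alignment_events(align_pair(refseq, as.character(panel$alleles[[id]])))
    ## assign indel events to reference SSR loci: an event fully inside a
    ## locus (+/- 1 nt) is repeat variation; a partial overlap is ambiguous
    ins_locus <- integer(0); amb <- logical(0)
    if (!is.null(ev$indels)) {
      ins_locus <- rep(NA_integer_, nrow(ev$indels))
      amb <- rep(FALSE, nrow(ev$indels))
      if (nrow(loci)) {
        for (r in seq_len(nrow(ev$indels))) {
          p1 <- ev$indels$pos[r] - 1L
          p2 <- ev$indels$pos[r] + pmax(0L, -ev$indels$len[r])
          inside <- loci$start - 1L <= p1 & loci$end + 1L >= p2
          partial <- !inside & loci$start <= p2 & loci$end >= p1
          if (any(inside)) ins_locus[r] <- which(inside)[1]
          else if (any(partial)) amb[r] <- TRUE   # spans a locus boundary
        }
      }
    }
    ## per-allele length occupied at each reference SSR locus
    if (nrow(loci)) {
      lens <- loci$end - loci$start + 1L
      if (length(ins_locus))
        for (r in which(!is.na(ins_locus)))
          lens[ins_locus[r]] <- lens[ins_locus[r]] + ev$indels$len[r]
      ssr_len[[id]] <- lens
    }
    if (!is.null(ev$subs)) {
      ev$subs$allele <- id
      subs[[id]] <- ev$subs
    }
    if (!is.null(ev$indels)) {
      ev$indels$ambiguous <- amb
      ev$indels <- ev$indels[is.na(ins_locus), , drop = FALSE]
      if (nrow(ev$indels)) {
        norm <- lapply(seq_len(nrow(ev$indels)), function(r)
          left_align_indel(ev$indels$pos[r], ev$indels$len[r],
                           ev$indels$seq[r], refv))
        ev$indels$pos <- vapply(norm, `[[`, integer(1), "pos")
        ev$indels$seq <- vapply(norm, `[[`, character(1), "seq")
        ev$indels$allele <- id
        indels[[id]] <- ev$indels
      }
    }
  }

  variants <- list()
  add <- function(row) variants[[length(variants) + 1L]] <<- row
  state_cols <- function(states) {
    df <- as.data.frame(as.list(states), optional = TRUE, stringsAsFactors = FALSE)
    names(df) <- paste0("state.", names(states))
    df
  }
  base_row <- function(kind, pos, len, unit, states, ambiguous = FALSE) {
    region <- feature_at(pos, model)
    cbind(data.frame(kind = kind, genomic_pos = as.integer(pos),
                     pos_anchor = to_anchor(pos, model, anchor),
                     region = region, region_class = region_class(region),
                     length = as.integer(len), unit = as.character(unit),
                     ambiguous = ambiguous, stringsAsFactors = FALSE),
          state_cols(states))
  }

  ## --- SNP sites -----------------------------------------------------------
  allsubs <- if (length(subs)) do.call(rbind, subs) else NULL
  if (!is.null(allsubs)) {
    for (p in sort(unique(allsubs$pos))) {
      here <- allsubs[allsubs$pos == p, , drop = FALSE]
      states <- setNames(rep(refv[p], length(ids)), ids)
      states[here$allele] <- here$alt
      states[states == "N"] <- NA_character_       # N = missing, not a state
      if (refv[p] == "N") next
      if (length(unique(stats::na.omit(states))) < 2L) next
      add(base_row("SNP", p, 1L, NA, states))
    }
  }

  ## --- InDel events --------------------------------------------------------
  allind <- if (length(indels)) do.call(rbind, indels) else NULL
  if (!is.null(allind)) {
    key <- paste(allind$pos, allind$len, allind$seq)
    for (kk in unique(key)) {
      here <- allind[key == kk, , drop = FALSE]
      ev1 <- here[1, ]
      states <- setNames(rep("-", length(ids)), ids)
      states[here$allele] <- if (ev1$len > 0) paste0("+", ev1$seq)
                             else paste0("-", ev1$seq)
      add(base_row("InDel", ev1$pos, abs(ev1$len), NA, states,
                   ambiguous = any(here$ambiguous)))
    }
  }

  ## --- SSR repeat-count variation -----------------------------------------
  if (nrow(loci) && length(ssr_len)) {
    for (li in seq_len(nrow(loci))) {
      ref_len <- loci$end[li] - loci$start[li] + 1L
      lens <- setNames(rep(ref_len, length(ids)), ids)
      for (id in names(ssr_len)) lens[id] <- ssr_len[[id]][li]
      if (length(unique(lens)) < 2L) next
      reps <- as.integer(round(lens / loci$unit_length[li]))
      add(base_row("SSR", loci$start[li], ref_len, loci$unit[li],
                   setNames(as.character(reps), ids)))
    }
  }

  if (!length(variants)) {
    empty <- data.frame(kind = character(), genomic_pos = integer(),
                        pos_anchor = integer(), region = character(),
                        region_class = character(), length = integer(),
                        unit = character(), ambiguous = logical(),
                        specificity = character(), coding_effect = character(),
                        stringsAsFactors = FALSE)
    class(empty) <- c("variant_table", "data.frame")
    return(empty)
  }
  vt <- do.call(rbind, variants)
  vt <- vt[order(vt$genomic_pos, vt$kind), , drop = FALSE]
  rownames(vt) <- NULL
  names(vt)[names(vt) == "pos_anchor"] <- if (anchor == "atg") "pos_atg" else "pos_tss"
  vt$specificity <- vapply(seq_len(nrow(vt)), function(i)
    classify_specificity(allele_states(vt[i, ]), panel$allele_info), character(1))
  vt$coding_effect <- vapply(seq_len(nrow(vt)), function(i)
    annotate_coding_effect(vt[i, ], model, reference_sequence = refseq),
    character(1))
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Extract the per-allele states of one variant row
#' @param variant one row of a `variant_table`.
#' @return named character vector (allele id -> state).
#' @export
allele_states <- function(variant) {
  cols <- grep("^state\\.", names(variant), value = TRUE)
  setNames(vapply(cols, function(cc) as.character(variant[[cc]]), character(1)),
           sub("^state\\.", "", cols))
}

#' Classify a variant's group specificity
#'
#' `Rf_vs_Wf` when all red-fleshed alleles share one state and all
#' white-fleshed alleles share a different one; `WsWf_specific`
#' (`RsWf_specific`) when that subtype's alleles share a state different from
#' the single state shared by every other allele; otherwise `nondiagnostic`.
#' Alleles with a missing state (`NA`) are excluded from the vote.
#'
#' @param states named per-allele state vector (see [allele_states()]).
#' @param allele_info data.frame with `allele_id`, `group`, `subtype`.
#' @return one of `"Rf_vs_Wf"`, `"WsWf_specific"`, `"RsWf_specific"`,
#'   `"nondiagnostic"`.
#' @export
classify_specificity <- function(states, allele_info) {
  info <- allele_info[match(names(states), allele_info$allele_id), , drop = FALSE]
  ok <- !is.na(states)
  states <- states[ok]; info <- info[ok, , drop = FALSE]
  if (!length(states)) return("nondiagnostic")
  uni <- function(x) if (length(x) && length(unique(x)) == 1L) unique(x) else NULL
  rf <- uni(states[info$group %in% "Rf"])
  wf <- uni(states[info$group %in% "Wf"])
  if (!is.null(rf) && !is.null(wf) && rf != wf) return("Rf_vs_Wf")
  for (sub in c("WsWf", "RsWf")) {
    inside <- uni(states[info$subtype %in% sub])
    outside <- uni(states[!(info$subtype %in% sub)])
    if (!is.null(inside) && !is.null(outside) && inside != outside)
      return(paste0(sub, "_specific"))
  }
  "nondiagnostic"
}

#' Annotate the coding effect of a variant
#'
#' Promoter/intron variants are `noncoding`. Exonic SNPs are translated in
#' the reading frame derived from the ATG anchor (`synonymous` or
#' `nonsynonymous`); exonic InDels are `in_frame_indel` when the length is a
#' multiple of 3, else `frameshift`. Exonic SSR length variation is treated
#' like an InDel of the repeat-length difference.
#'
#' @param variant one row of a `variant_table`.
#' @param model the `gene_model`.
#' @param reference_sequence the reference allele sequence (needed for codon
#'   context of exonic SNPs; without it an exonic SNP is labelled
#'   `"coding_snp"`).
#' @return effect label (character scalar).
#' @export
annotate_coding_effect <- function(variant, model, reference_sequence = NULL) {
  pos <- variant$genomic_pos
  if (pos < 1L || pos > model_span(model))
    stop("coordinate error: variant outside model span")
  region <- feature_at(pos, model)
  if (!grepl("^exon_", region)) return("noncoding")
  if (pos < model$atg_pos) return("noncoding")     # 5' UTR
  states <- allele_states(variant)
  if (variant$kind == "SNP") {
    cp <- cds_position(pos, model)
    if (is.na(cp) || cp < 1L) return("noncoding")
    if (is.null(reference_sequence)) return("coding_snp")
    v <- strsplit(as.character(reference_sequence), "")[[1]]
    cd <- codon_at(pos, v, model)
    gc <- Biostrings::GENETIC_CODE
    aa_ref <- gc[[cd$codon]]
    alts <- setdiff(unique(stats::na.omit(states)), v[pos])
    if (!length(alts)) return("synonymous")
    effects <- vapply(alts, function(b) {
      codon2 <- cd$codon
      substr(codon2, cd$frame + 1L, cd$frame + 1L) <- b
      if (gc[[codon2]] == aa_ref) "synonymous" else "nonsynonymous"
    }, character(1))
    if (all(effects == "synonymous")) "synonymous" else "nonsynonymous"
  } else if (variant$kind == "InDel") {
    if (variant$length %% 3L == 0L) "in_frame_indel" else "frameshift"
  } else {                                          # SSR
    reps <- suppressWarnings(as.integer(states))
    dl <- (max(reps, na.rm = TRUE) - min(reps, na.rm = TRUE)) * nchar(variant$unit)
    if (dl %% 3L == 0L) "in_frame_indel" else "frameshift"
  }
}

#' Summarize classified variants in the published table layout
#'
#' Counts variants by region class (Promoter / Exon / Intron) and kind (SNP /
#' InDel / SSR) for the three diagnostic specificity classes, with a Total
#' row equal to the column sums. Nondiagnostic variants are excluded.
#'
#' @param variants a `variant_table`.
#' @return data.frame of class `polymorphism_matrix`: rows Promoter, Exon,
#'   Intron, Total; columns `<class>_<kind>` for each specificity class.
#' @export
summarize_matrix <- function(variants) {
  classes <- c("Rf_vs_Wf", "WsWf_specific", "RsWf_specific")
  kinds <- c("SNP", "InDel", "SSR")
  regions <- c("Promoter", "Exon", "Intron")
  m <- matrix(0L, nrow = 4L, ncol = 9L,
              dimnames = list(c(regions, "Total"),
                              paste(rep(classes, each = 3L), kinds, sep = "_")))
  if (nrow(variants)) {
    for (cl in classes) for (kd in kinds) {
      sel <- variants$specificity == cl & variants$kind == kd
      if (!any(sel)) next
      tab <- table(factor(variants$region_class[sel], levels = regions))
      m[regions, paste(cl, kd, sep = "_")] <- as.integer(tab)
    }
  }
  m["Total", ] <- colSums(m[regions, , drop = FALSE])
  out <- as.data.frame(m)
  class(out) <- c("polymorphism_matrix", "data.frame")
  out
}

#' Write a polymorphism matrix as TSV
#' @param mat a `polymorphism_matrix`.
#' @param path output path.
#' @param header optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, header = NULL) {
  df <- cbind(Region = rownames(mat), as.data.frame(mat))
  write_tsv(df, path, header = header)
}

#' Write a variant table as TSV
#' @param variants a `variant_table`.
#' @param path output path.
#' @param header optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, header = NULL) {
  write_tsv(as.data.frame(variants), path, header = header)
}
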