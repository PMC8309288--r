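## Synthetic allele-panel generator.
##
## Emulates the structure of a cloned single-gene allele panel from four
## radish inbred lines (GsRf, RsRf = red-fleshed group Rf; WsWf, RsWf =
## white-fleshed group Wf), two clones per line, with SNP/InDel/SSR
## polymorphisms implanted at the published per-region / per-specificity
## counts, and emits a machine-readable truth set for recovery testing.

BASES <- c("A", "C", "G", "T")

## run code under a local, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default polymorphism specification table
#'
#' Per-region, per-kind, per-specificity polymorphism counts implanted by the
#' generator: 28/3/3 group-diagnostic (Rf vs Wf) SNPs/InDels/SSRs, 6/7/3
#' WsWf-specific and 9/1/1 RsWf-specific, with the promoter carrying 16
#' diagnostic SNPs, 2 diagnostic InDels and 1 diagnostic SSR. Dashes in the
#' published table are zeros.
#'
#' @return data.frame with columns `region_class`, `kind`, `specificity`,
#'   `count`.
#' @export
default_spec_table <- function() {
  tab <- rbind(
    ## region, SNP, InDel, SSR per specificity class
    data.frame(region_class = "Promoter", kind = c("SNP", "InDel", "SSR"),
               specificity = "Rf_vs_Wf", count = c(16L, 2L, 1L)),
    data.frame(region_class = "Exon", kind = c("SNP", "InDel", "SSR"),
               specificity = "Rf_vs_Wf", count = c(2L, 0L, 0L)),
    data.frame(region_class = "Intron", kind = c("SNP", "InDel", "SSR"),
               specificity = "Rf_vs_Wf", count = c(10L, 1L, 2L)),
    data.frame(region_class = "Promoter", kind = c("SNP", "InDel", "SSR"),
               specificity = "WsWf_specific", count = c(2L, 4L, 1L)),
    data.frame(region_class = "Exon", kind = c("SNP", "InDel", "SSR"),
               specificity = "WsWf_specific", count = c(1L, 0L, 0L)),
    data.frame(region_class = "Intron", kind = c("SNP", "InDel", "SSR"),
               specificity = "WsWf_specific", count = c(3L, 3L, 2L)),
    data.frame(region_class = "Promoter", kind = c("SNP", "InDel", "SSR"),
               specificity = "RsWf_specific", count = c(2L, 0L, 0L)),
    data.frame(region_class = "Exon", kind = c("SNP", "InDel", "SSR"),
               specificity = "RsWf_specific", count = c(3L, 1L, 0L)),
    data.frame(region_class = "Intron", kind = c("SNP", "InDel", "SSR"),
               specificity = "RsWf_specific", count = c(4L, 0L, 1L)))
  rownames(tab) <- NULL
  tab
}

#' Generator configuration
#'
#' Defaults encode the study conditions the generator emulates: a 1-kb
#' promoter, seven exons and six introns, a 14-nt promoter insertion carried
#' by the white-fleshed (Wf) haplotypes 35 nt upstream of the ATG, a (TC)
#' microsatellite at the start of intron 2 with 13 repeats in Rf and 68 in Wf
#' alleles, a 3-nt CAT InDel in intron 5, both group-diagnostic exonic SNPs
#' placed in exon 6, and four diagnostic promoter SNPs inside the
#' -979..-818 (ATG-relative) marker window. Exon/intron lengths are package
#' choices sized so that every mandatory feature is placeable.
#'
#' @param seed integer seed; the same seed always yields an identical panel.
#' @param promoter_length promoter length in nt.
#' @param utr5_length nt between TSS and ATG (both in exon 1).
#' @param exon_lengths,intron_lengths integer vectors (7 and 6 entries).
#' @param gc target GC fraction of the random background sequence.
#' @param spec_table polymorphism counts as from [default_spec_table()].
#' @param promoter_indel list: `enabled`, `length`, `rel_pos` (ATG-relative
#'   insertion point), carrier group is Wf.
#' @param ssr list: `enabled`, `unit`, `intron`, `rf_repeats`, `wf_repeats`.
#' @param cat_indel list: `enabled`, `seq`, `intron`; the Rf reference carries
#'   the motif, Wf alleles delete it.
#' @param exon6_snps how many of the Rf-vs-Wf exonic SNPs to force into exon 6
#'   (for the CDS-region allele-specific marker).
#' @param promoter_window_snps list: `count` and ATG-relative `window` for
#'   diagnostic promoter SNPs reserved for the promoter-specific marker.
#' @param pair_snps private (nondiagnostic) SNPs separating the two clones of
#'   each line.
#' @param line_snps private nondiagnostic SNPs separating the second
#'   red-fleshed line from the reference line.
#' @param protein_conserving place exonic SNPs at synonymous third codon
#'   positions where possible; exonic InDel lengths stay multiples of 3.
#' @param protect_margin half-width (nt) of the variant-free zone kept around
#'   each mandatory marker target so flanking primers remain designable.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             promoter_length = 1000L,
                             utr5_length = 20L,
                             exon_lengths = c(240L, 150L, 120L, 110L, 160L, 280L, 220L),
                             intron_lengths = c(150L, 350L, 150L, 150L, 200L, 150L),
                             gc = 0.40,
                             spec_table = default_spec_table(),
                             promoter_indel = list(enabled = TRUE, length = 14L, rel_pos = -35L),
                             ssr = list(enabled = TRUE, unit = "TC", intron = 2L,
                                        rf_repeats = 13L, wf_repeats = 68L),
                             cat_indel = list(enabled = TRUE, seq = "CAT", intron = 5L),
                             exon6_snps = 2L,
                             promoter_window_snps = list(count = 4L, window = c(-979L, -818L)),
                             pair_snps = 3L,
                             line_snps = 2L,
                             protein_conserving = TRUE,
                             protect_margin = 80L) {
  stopifnot(length(exon_lengths) == 7L, length(intron_lengths) == 6L,
            promoter_length > 0, utr5_length >= 3,
            all(exon_lengths > 0), all(intron_lengths > 0),
            gc > 0, gc < 1)
  cfg <- list(seed = as.integer(seed), promoter_length = as.integer(promoter_length),
              utr5_length = as.integer(utr5_length),
              exon_lengths = as.integer(exon_lengths),
              intron_lengths = as.integer(intron_lengths),
              gc = gc, spec_table = spec_table,
              promoter_indel = promoter_indel, ssr = ssr, cat_indel = cat_indel,
              exon6_snps = as.integer(exon6_snps),
              promoter_window_snps = promoter_window_snps,
              pair_snps = as.integer(pair_snps), line_snps = as.integer(line_snps),
              protein_conserving = isTRUE(protein_conserving),
              protect_margin = as.integer(protect_margin))
  class(cfg) <- "generator_config"
  ## mandatory features must be placeable
  if (isTRUE(ssr$enabled)) {
    need <- nchar(ssr$unit) * max(ssr$rf_repeats, ssr$wf_repeats) + 60L
    if (intron_lengths[ssr$intron] < nchar(ssr$unit) * ssr$rf_repeats + 50L)
      stop("config error: intron ", ssr$intron, " too short for the SSR locus")
    invisible(need)
  }
  if (isTRUE(promoter_indel$enabled) &&
      (utr5_length + abs(promoter_indel$rel_pos) > promoter_length + utr5_length))
    stop("config error: promoter too short for the mandatory InDel")
  cfg
}

## feature table for a config
config_features <- function(cfg) {
  kinds <- c("promoter",
             as.vector(rbind(paste0("exon", 1:6), paste0("intron", 1:6))), "exon7")
  lens <- c(cfg$promoter_length,
            as.vector(rbind(cfg$exon_lengths[1:6], cfg$intron_lengths)),
            cfg$exon_lengths[7])
  kind <- c("promoter", rep(c("exon", "intron"), 6), "exon")
  index <- c(1L, as.vector(rbind(1:6, 1:6)), 7L)
  start <- cumsum(c(1L, lens[-length(lens)]))
  data.frame(kind = kind, index = index,
             start = as.integer(start),
             end = as.integer(start + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Generate the random reference allele and its gene model
#'
#' Draws the background sequence at the configured GC fraction, writes the
#' mandatory reference motifs (the (TC) microsatellite run with the Rf repeat
#' count, and the CAT motif in intron 5), and returns the sequence together
#' with a validated `gene_model`. Deterministic for a fixed seed.
#'
#' @param config a [generator_config()].
#' @return list with `sequence` (character scalar), `model` (`gene_model`),
#'   and `anchors` (genomic positions of the mandatory features).
#' @export
generate_reference <- function(config = generator_config()) {
  cfg <- config
  feats <- config_features(cfg)
  L <- max(feats$end)
  tss <- cfg$promoter_length + 1L
  atg <- tss + cfg$utr5_length
  model <- gene_model(feats, tss_pos = tss, atg_pos = atg,
                      reference_allele_id = "GsRf_TT8_1", n_exons = 7L)
  anchors <- list()
  v <- with_seed(cfg$seed, {
    p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
    v <- sample(BASES, L, replace = TRUE, prob = p)
    v
  })
  ## the promoter marker window must support spread-out, designable anchor
  ## SNPs (a primer pair has to span it); resample its background until the
  ## designable positions cover at least two well-separated clusters
  if (cfg$promoter_window_snps$count > 0) {
    w <- sort(cfg$promoter_window_snps$window)
    win <- c(atg + w[1], atg + w[2])          # negative offsets: no +1 shift
    v <- with_seed(cfg$seed + 7919L, {
      ok <- FALSE
      for (try in 1:100) {
        cand <- seq.int(win[1] + 10L, win[2] - 10L)
        ## exclude tandem-repeat runs (+/-4 nt), as variant placement will
        a <- max(1L, win[1] - 30L)
        runs <- detect_ssr_loci(paste(v[a:(win[2] + 30L)], collapse = ""),
                                min_unit = 1L, max_unit = 6L,
                                min_repeats = 3L, min_length = 6L)
        if (nrow(runs)) {
          bad <- unlist(lapply(seq_len(nrow(runs)), function(i)
            (runs$start[i] + a - 1L - 4L):(runs$end[i] + a - 1L + 4L)))
          cand <- setdiff(cand, bad)
        }
        cand <- cand[vapply(cand, function(p)
          anchorable_window(v, p, "fw") && anchorable_window(v, p, "rv") &&
            !is.null(pick_anchor_alt(v, p)), logical(1))]
        if (length(cand) >= cfg$promoter_window_snps$count + 1L &&
            max(cand) - min(cand) >= 70L) { ok <- TRUE; break }
        p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
        v[win[1]:win[2]] <- sample(BASES, win[2] - win[1] + 1L,
                                   replace = TRUE, prob = p)
      }
      if (!ok) stop("config error: promoter marker window not designable")
      v
    })
  }
  ## mandatory SSR run (Rf/reference repeat count) near the start of its intron
  if (isTRUE(cfg$ssr$enabled)) {
    it <- feats[feats$kind == "intron" & feats$index == cfg$ssr$intron, ]
    start <- it$start + 20L
    v <- write_ssr_run(v, start, cfg$ssr$unit, cfg$ssr$rf_repeats)
    anchors$ssr <- c(start = start,
                     end = start + nchar(cfg$ssr$unit) * cfg$ssr$rf_repeats - 1L)
  }
  ## mandatory CAT motif in its intron (deleted in Wf haplotypes later);
  ## the position is chosen so that a forward primer can be anchored on the
  ## deletion junction under the default design constraints
  if (isTRUE(cfg$cat_indel$enabled)) {
    it <- feats[feats$kind == "intron" & feats$index == cfg$cat_indel$intron, ]
    s <- nchar(cfg$cat_indel$seq)
    start <- NA_integer_
    for (cand in seq(it$start + 30L, it$start + 120L)) {
      v2 <- v
      v2[cand:(cand + s - 1L)] <- strsplit(cfg$cat_indel$seq, "")[[1]]
      last <- substr(cfg$cat_indel$seq, s, s)
      first <- substr(cfg$cat_indel$seq, 1L, 1L)
      if (v2[cand - 1L] == last)
        v2[cand - 1L] <- setdiff(BASES, c(last, v2[cand - 2L]))[1]
      if (v2[cand + s] == first)
        v2[cand + s] <- setdiff(BASES, c(first, v2[cand + s + 1L]))[1]
      v3 <- v2[-(cand:(cand + s - 1L))]     # deletion-carrier haplotype locally
      if (anchorable_window(v2, cand + s + 1L, "fw") &&
          anchorable_window(v3, cand + 1L, "fw")) { start <- cand; v <- v2; break }
    }
    if (is.na(start))
      stop("config error: no designable position for the intron motif")
    anchors$cat <- c(start = start, end = start + s - 1L)
  }
  list(sequence = paste(v, collapse = ""), model = model, anchors = anchors)
}

## write a maximal tandem run unit^count at `start`, breaking periodic
## extension on both sides so a detector reports exactly `count` repeats
write_ssr_run <- function(v, start, unit, count) {
  u <- strsplit(unit, "")[[1]]
  k <- length(u)
  run <- rep(u, count)
  end <- start + k * count - 1L
  v[start:end] <- run
  ## boundary breakers: positions i just outside must not satisfy v[i] == v[i+k]
  for (i in (start - k):(start - 1L)) {
    if (i >= 1L && v[i] == v[i + k])
      v[i] <- setdiff(BASES, c(v[i + k], if (i > 1) v[i - 1L]))[1]
  }
  for (i in (end + 1L):(end + k)) {
    if (i <= length(v) && v[i] == v[i - k])
      v[i] <- setdiff(BASES, c(v[i - k], if (i < length(v)) v[i + 1L]))[1]
  }
  v
}

## TRUE if a primer window anchored with its 3' end (orient "fw") or 5' end
## (orient "rv") at `p` can satisfy default design constraints (length 18-24,
## Wallace Tm 55-65, GC 40-60%, mononucleotide runs <= 4) on sequence v
anchorable_window <- function(v, p, orient = c("fw", "rv")) {
  orient <- match.arg(orient)
  n <- length(v)
  for (len in 18:24) {
    a <- if (orient == "fw") p - len + 1L else p
    b <- if (orient == "fw") p else p + len - 1L
    if (a < 1L || b > n) next
    w <- v[a:b]
    gcn <- sum(w %in% c("G", "C"))
    tm <- 2L * len + 2L * gcn
    if (tm < 55 || tm > 65) next
    gcp <- 100 * gcn / len
    if (gcp < 40 || gcp > 60) next
    if (max(rle(w)$lengths) > 4L) next
    return(TRUE)
  }
  FALSE
}

## CDS coordinate of a genomic position (NA outside exons / upstream of ATG)
cds_position <- function(pos, model) {
  ex <- model$features[model$features$kind == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[i] && pos <= ex$end[i]) {
      cds <- cum + pos - ex$start[i] + 1L
      offset <- model$atg_pos - ex$start[1]  # UTR bases in exon 1
      return(cds - offset)
    }
    cum <- cum + ex$end[i] - ex$start[i] + 1L
  }
  NA_integer_
}

## codon (genomic positions + sequence) containing a CDS position
codon_at <- function(pos, v, model) {
  cp <- cds_position(pos, model)
  if (is.na(cp) || cp < 1L) return(NULL)
  frame <- (cp - 1L) %% 3L          # 0,1,2 within codon
  ## genomic positions of the codon bases: walk the exon map
  ex <- model$features[model$features$kind == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  cds_start <- cp - frame
  g <- integer(3)
  for (j in 0:2) {
    target <- cds_start + j
    cum <- 0L
    offset <- model$atg_pos - ex$start[1]
    for (i in seq_len(nrow(ex))) {
      len <- ex$end[i] - ex$start[i] + 1L
      if (target + offset <= cum + len) {
        g[j + 1L] <- ex$start[i] + (target + offset - cum) - 1L
        break
      }
      cum <- cum + len
    }
  }
  list(genomic = g, frame = frame, codon = paste(v[g], collapse = ""))
}

## choose an alternative base at pos; prefer a synonymous change when asked
pick_alt_base <- function(v, pos, model, protein_conserving, in_exon) {
  ref <- v[pos]
  alts <- setdiff(BASES, ref)
  if (!in_exon || !protein_conserving) return(sample(alts, 1L))
  cd <- codon_at(pos, v, model)
  if (is.null(cd)) return(sample(alts, 1L))
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- gc[[cd$codon]]
  syn <- character(0)
  for (b in alts) {
    codon2 <- cd$codon
    substr(codon2, cd$frame + 1L, cd$frame + 1L) <- b
    if (!is.null(gc[[codon2]]) && gc[[codon2]] == aa_ref) syn <- c(syn, b)
  }
  if (length(syn)) sample(syn, 1L) else sample(alts, 1L)
}

## choose an alt base at a marker-anchor SNP so that both haplotypes keep a
## designable primer window: prefer the GC-class-preserving swap (A<->T,
## C<->G), optionally intersected with synonymous changes, and verify the
## mutated sequence still satisfies anchorable_window in both orientations
pick_anchor_alt <- function(v, p, model = NULL, want_synonymous = FALSE) {
  ref <- v[p]
  swap <- c(A = "T", T = "A", C = "G", G = "C")[[ref]]
  cand <- c(swap, setdiff(BASES, c(ref, swap)))
  if (want_synonymous && !is.null(model)) {
    gc <- Biostrings::GENETIC_CODE
    cd <- codon_at(p, v, model)
    if (!is.null(cd)) {
      syn <- cand[vapply(cand, function(b) {
        codon2 <- cd$codon
        substr(codon2, cd$frame + 1L, cd$frame + 1L) <- b
        !is.null(gc[[codon2]]) && gc[[codon2]] == gc[[cd$codon]]
      }, logical(1))]
      cand <- c(syn, setdiff(cand, syn))
    }
  }
  for (b in cand) {
    v2 <- v; v2[p] <- b
    if (anchorable_window(v2, p, "fw") && anchorable_window(v2, p, "rv"))
      return(b)
  }
  NULL
}

## TRUE if pos sits at a third codon position with a synonymous alt available
synonymous_site <- function(v, pos, model) {
  cd <- codon_at(pos, v, model)
  if (is.null(cd) || cd$frame != 2L) return(FALSE)
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- gc[[cd$codon]]
  for (b in setdiff(BASES, v[pos])) {
    codon2 <- cd$codon
    substr(codon2, 3L, 3L) <- b
    if (!is.null(gc[[codon2]]) && gc[[codon2]] == aa_ref) return(TRUE)
  }
  FALSE
}

HAPLOTYPES <- c("GsRf_TT8_1", "GsRf_TT8_2", "RsRf_TT8_1", "RsRf_TT8_2",
                "WsWf_TT8_1", "WsWf_TT8_2", "RsWf_TT8_1", "RsWf_TT8_2")

carriers_for <- function(specificity) {
  switch(specificity,
         Rf_vs_Wf = c("WsWf_TT8_1", "WsWf_TT8_2", "RsWf_TT8_1", "RsWf_TT8_2"),
         WsWf_specific = c("WsWf_TT8_1", "WsWf_TT8_2"),
         RsWf_specific = c("RsWf_TT8_1", "RsWf_TT8_2"),
         stop("no default carrier set for specificity ", specificity))
}

#' Implant the configured polymorphisms and build the eight haplotypes
#'
#' Places every variant of the spec table (SNPs, InDels, SSR repeat-count
#' differences) plus the mandatory marker-region features into the reference,
#' with collision-free footprints, stable (non-shiftable) InDel placements,
#' and variant-free protection zones around the four marker targets. Two
#' clone haplotypes per line are produced; clones differ only at private
#' nondiagnostic SNPs.
#'
#' @param reference output of [generate_reference()] (or a list with
#'   `sequence`, `model`, `anchors`).
#' @param config the same [generator_config()] used for the reference.
#' @return list with `haplotypes` (named character vector of 8 sequences),
#'   `truth` (truth-set data.frame: one row per implanted variant with kind,
#'   genomic and ATG-relative position, region, specificity, length/unit/
#'   repeat counts and carrier haplotypes), `edits` (internal edit table) and
#'   `model`.
#' @export
implant_variants <- function(reference, config = generator_config()) {
  cfg <- config
  model <- reference$model
  v <- strsplit(reference$sequence, "")[[1]]
  L <- length(v)
  feats <- model$features
  margin <- 6L

  with_seed(cfg$seed + 104729L, {
    occupied <- rep(FALSE, L)
    mark <- function(from, to) {
      from <- max(1L, from); to <- min(L, to)
      occupied[from:to] <<- TRUE
    }
    ## keep sequence ends and feature boundaries clean
    mark(1L, 30L); mark(L - 30L, L)
    for (i in seq_len(nrow(feats))) {
      mark(feats$start[i] - 3L, feats$start[i] + 3L)
      mark(feats$end[i] - 3L, feats$end[i] + 3L)
    }
    edits <- list()
    truth <- list()
    add_variant <- function(kind, pos, specificity, carriers, ref_state = NA,
                            alt_state = NA, indel_len = NA_integer_,
                            ins_seq = NA_character_, del_len = NA_integer_,
                            unit = NA_character_, ref_repeats = NA_integer_,
                            alt_repeats = NA_integer_, footprint = c(pos, pos),
                            guard = margin) {
      mark(footprint[1] - guard, footprint[2] + guard)
      region <- feature_at(pos, model)
      row <- data.frame(kind = kind, genomic_pos = as.integer(pos),
                        pos_atg = to_anchor(pos, model, "atg"),
                        region = region, region_class = region_class(region),
                        specificity = specificity,
                        ref_state = as.character(ref_state),
                        alt_state = as.character(alt_state),
                        indel_len = as.integer(indel_len),
                        ins_seq = as.character(ins_seq),
                        unit = as.character(unit),
                        ref_repeats = as.integer(ref_repeats),
                        alt_repeats = as.integer(alt_repeats),
                        carriers = paste(carriers, collapse = ","),
                        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- row
      edits[[length(edits) + 1L]] <<- row
    }

    region_positions <- function(rclass) {
      if (rclass == "Promoter") {
        pr <- feats[feats$kind == "promoter", ]
        seq.int(pr$start, pr$end)
      } else {
        kk <- if (rclass == "Exon") "exon" else "intron"
        unlist(lapply(which(feats$kind == kk),
                      function(i) seq.int(feats$start[i], feats$end[i])))
      }
    }
    free_in <- function(positions, need_left = 0L, need_right = 0L) {
      ok <- positions[!occupied[positions]]
      if (need_left + need_right == 0L) return(ok)
      keep <- vapply(ok, function(p) {
        a <- max(1L, p - need_left); b <- min(L, p + need_right)
        !any(occupied[a:b])
      }, logical(1))
      ok[keep]
    }

    ## ---- forbid placements inside pre-existing tandem-repeat runs -------
    pre_loci <- detect_ssr_loci(paste(v, collapse = ""), min_unit = 1L,
                                max_unit = 6L, min_repeats = 3L, min_length = 6L)
    if (nrow(pre_loci))
      for (i in seq_len(nrow(pre_loci)))
        mark(pre_loci$start[i] - 4L, pre_loci$end[i] + 4L)
    runs_mask <- occupied    # snapshot: marker anchors must avoid these too

    ## ---- protection zones so marker flanks stay variant-free ------------
    pm <- cfg$protect_margin
    zones <- list()
    if (isTRUE(cfg$promoter_indel$enabled)) {
      p_ins <- from_anchor(cfg$promoter_indel$rel_pos, model, "atg")
      zones$id <- c(p_ins - pm, p_ins + pm)
    }
    if (isTRUE(cfg$ssr$enabled))
      zones$ssr <- c(reference$anchors$ssr["start"] - pm,
                     reference$anchors$ssr["end"] + pm)
    if (isTRUE(cfg$cat_indel$enabled))
      zones$cat <- c(reference$anchors$cat["start"] - pm,
                     reference$anchors$cat["end"] + pm)
    win <- NULL
    if (cfg$promoter_window_snps$count > 0) {
      win <- sort(from_anchor(cfg$promoter_window_snps$window, model, "atg"))
      zones$ps <- c(win[1] - 30L, win[2] + 30L)
    }
    ex6 <- feats[feats$kind == "exon" & feats$index == 6L, ]
    if (!is.null(zones$cat)) zones$wd <- c(zones$cat[1], ex6$start + 120L)
    for (z in zones) mark(z[1], z[2])

    ## ---- mandatory variants (inside their own zones) ---------------------
    remaining <- cfg$spec_table
    take <- function(rclass, kind, spec, n = 1L) {
      i <- which(remaining$region_class == rclass & remaining$kind == kind &
                 remaining$specificity == spec)
      if (!length(i) || remaining$count[i] < n)
        stop("placement error: spec table exhausted for ", rclass, "/", kind, "/", spec)
      remaining$count[i] <<- remaining$count[i] - n
      invisible(NULL)
    }

    if (isTRUE(cfg$promoter_indel$enabled)) {
      take("Promoter", "InDel", "Rf_vs_Wf")
      p_ins <- from_anchor(cfg$promoter_indel$rel_pos, model, "atg")
      len <- cfg$promoter_indel$length
      repeat {
        S <- sample(BASES, len, replace = TRUE)
        periodic <- any(vapply(1:3, function(k)
          k < len && len %% k == 0 && all(S == rep(S[1:k], len / k)), logical(1)))
        if (S[1] != v[p_ins] && S[len] != v[p_ins - 1L] && !periodic) break
      }
      add_variant("InDel", p_ins, "Rf_vs_Wf", carriers_for("Rf_vs_Wf"),
                  indel_len = len, ins_seq = paste(S, collapse = ""),
                  footprint = c(p_ins - 1L, p_ins))
    }
    if (isTRUE(cfg$ssr$enabled)) {
      take("Intron", "SSR", "Rf_vs_Wf")
      a <- reference$anchors$ssr
      add_variant("SSR", a["start"], "Rf_vs_Wf", carriers_for("Rf_vs_Wf"),
                  unit = cfg$ssr$unit, ref_repeats = cfg$ssr$rf_repeats,
                  alt_repeats = cfg$ssr$wf_repeats,
                  footprint = c(a["start"] - 2L, a["end"] + 2L))
    }
    if (isTRUE(cfg$cat_indel$enabled)) {
      take("Intron", "InDel", "Rf_vs_Wf")
      a <- reference$anchors$cat
      add_variant("InDel", a["start"], "Rf_vs_Wf", carriers_for("Rf_vs_Wf"),
                  indel_len = -(a["end"] - a["start"] + 1L),
                  footprint = c(a["start"] - 1L, a["end"] + 1L))
    }
    if (cfg$exon6_snps > 0) {
      take("Exon", "SNP", "Rf_vs_Wf", cfg$exon6_snps)
      ## anchor SNPs for the CDS marker's reverse primer: keep them out of
      ## repeat runs and require a designable primer window
      cand <- seq.int(ex6$start + 20L, ex6$end - 30L)
      cand <- cand[!runs_mask[cand] &
                   vapply(cand, function(p) anchorable_window(v, p, "rv") &&
                                            anchorable_window(v, p, "fw"),
                          logical(1))]
      alts <- lapply(cand, function(p)
        pick_anchor_alt(v, p, model, want_synonymous = cfg$protein_conserving))
      keep <- !vapply(alts, is.null, logical(1))
      cand <- cand[keep]; alts <- alts[keep]
      if (length(cand) < cfg$exon6_snps)
        stop("placement error: no designable anchor positions in exon 6")
      sel <- sort(sample.int(length(cand), cfg$exon6_snps))
      for (try in 1:100) {
        if (all(diff(cand[sel]) >= 8L)) break   # keep anchors separable
        sel <- sort(sample.int(length(cand), cfg$exon6_snps))
      }
      picks <- cand[sel]
      for (ii in seq_along(sel))
        add_variant("SNP", cand[sel[ii]], "Rf_vs_Wf", carriers_for("Rf_vs_Wf"),
                    ref_state = v[cand[sel[ii]]], alt_state = alts[[sel[ii]]])
      zones$wd[2] <- max(zones$wd[2], max(picks) + 40L)
      mark(zones$wd[1], zones$wd[2])
    }
    if (cfg$promoter_window_snps$count > 0) {
      take("Promoter", "SNP", "Rf_vs_Wf", cfg$promoter_window_snps$count)
      n <- cfg$promoter_window_snps$count
      cand <- seq.int(win[1] + 10L, win[2] - 10L)
      cand <- cand[!runs_mask[cand] &
                   vapply(cand, function(p) anchorable_window(v, p, "fw") &&
                                            anchorable_window(v, p, "rv"),
                          logical(1))]
      win_alt <- lapply(cand, function(p) pick_anchor_alt(v, p))
      keep <- !vapply(win_alt, is.null, logical(1))
      cand <- cand[keep]
      win_alt <- stats::setNames(unlist(win_alt[keep]), cand)
      if (length(cand) < n)
        stop("placement error: no designable anchor positions in the promoter window")
      ## spread picks across the window, snapping to designable positions
      slots <- round(seq(win[1] + 15L, win[2] - 15L, length.out = n))
      picks <- integer(0)
      for (sl in slots) {
        avail <- setdiff(cand, unlist(lapply(picks, function(q) (q - 11L):(q + 11L))))
        if (!length(avail)) next
        picks <- c(picks, avail[which.min(abs(avail - sl))])
      }
      if (length(picks) < 2L)
        stop("placement error: promoter window anchors too sparse")
      for (minsep in c(4L, 1L, 0L)) {   # top up, allowing clustered SNPs
        if (length(picks) >= n) break
        extra <- setdiff(cand, unlist(lapply(picks, function(q)
          (q - minsep):(q + minsep))))
        picks <- c(picks, extra[seq_len(min(length(extra), n - length(picks)))])
      }
      if (length(picks) < n)
        stop("placement error: promoter window anchors too sparse")
      for (p in sort(picks))
        add_variant("SNP", p, "Rf_vs_Wf", carriers_for("Rf_vs_Wf"),
                    ref_state = v[p],
                    alt_state = win_alt[[as.character(p)]])
    }

    ## ---- random placements for the rest of the spec table ----------------
    place_snp <- function(rclass, spec, carriers) {
      pos <- free_in(region_positions(rclass))
      if (!length(pos)) stop("placement error: no free position in ", rclass)
      in_exon <- rclass == "Exon"
      if (in_exon && cfg$protein_conserving) {
        syn <- pos[vapply(pos, function(p) synonymous_site(v, p, model), logical(1))]
        if (length(syn)) pos <- syn
      }
      p <- pos[sample.int(length(pos), 1L)]
      add_variant("SNP", p, spec, carriers, ref_state = v[p],
                  alt_state = pick_alt_base(v, p, model, cfg$protein_conserving, in_exon))
    }
    place_indel <- function(rclass, spec, carriers) {
      len <- if (rclass == "Exon") 3L * sample(1:2, 1L) else sample(2:10, 1L)
      insertion <- runif(1) < 0.5
      for (try in 1:300) {
        pos <- free_in(region_positions(rclass), need_left = 2L,
                       need_right = if (insertion) 2L else len + 1L)
        if (!length(pos)) break
        p <- pos[sample.int(length(pos), 1L)]
        if (insertion) {
          S <- sample(BASES, len, replace = TRUE)
          periodic <- any(vapply(1:3, function(k)
            k < len && len %% k == 0 && all(S == rep(S[1:k], len / k)), logical(1)))
          if (S[1] == v[p] || S[len] == v[p - 1L] || periodic) next
          ## insertion must stay inside one feature
          if (feature_at(p - 1L, model) != feature_at(p, model)) next
          add_variant("InDel", p, spec, carriers, indel_len = len,
                      ins_seq = paste(S, collapse = ""), footprint = c(p - 1L, p))
        } else {
          if (feature_at(p, model) != feature_at(p + len - 1L, model)) next
          D <- v[p:(p + len - 1L)]
          if (v[p - 1L] == D[len] || v[p + len] == D[1]) next
          add_variant("InDel", p, spec, carriers, indel_len = -len,
                      footprint = c(p - 1L, p + len))
        }
        return(invisible(NULL))
      }
      stop("placement error: could not place InDel in ", rclass, " (",
           sum(!occupied[region_positions(rclass)]), " free of ",
           length(region_positions(rclass)), " positions; windowed free ",
           length(free_in(region_positions(rclass), 2L, len + 1L)),
           "; len ", len, " ins ", insertion, ")")
    }
    place_ssr <- function(rclass, spec, carriers) {
      for (try in 1:300) {
        unit <- sample(c("AC", "AG", "AT", "CT", "GT", "TC", "GA", "CA"), 1L)
        ref_n <- sample(8:12, 1L)
        alt_n <- ref_n + sample(c(-4:-3, 3:8), 1L)
        if (alt_n < 5L) next
        span <- 2L * ref_n
        pos <- free_in(region_positions(rclass), need_left = 4L, need_right = span + 4L)
        if (!length(pos)) next
        p <- pos[sample.int(length(pos), 1L)]
        if (feature_at(p, model) != feature_at(p + span - 1L, model)) next
        v <<- write_ssr_run(v, p, unit, ref_n)
        add_variant("SSR", p, spec, carriers, unit = unit,
                    ref_repeats = ref_n, alt_repeats = alt_n,
                    footprint = c(p - 4L, p + span + 3L))
        return(invisible(NULL))
      }
      stop("placement error: could not place SSR in ", rclass)
    }

    for (i in seq_len(nrow(remaining))) {
      n <- remaining$count[i]
      if (n <= 0) next
      rclass <- remaining$region_class[i]
      kind <- remaining$kind[i]
      spec <- remaining$specificity[i]
      car <- carriers_for(spec)
      for (j in seq_len(n)) {
        switch(kind,
               SNP = place_snp(rclass, spec, car),
               InDel = place_indel(rclass, spec, car),
               SSR = place_ssr(rclass, spec, car))
      }
    }

    ## ---- private nondiagnostic SNPs --------------------------------------
    ## line-level: second red line differs from the reference line
    if (cfg$line_snps > 0) {
      for (j in seq_len(cfg$line_snps))
        place_snp(sample(c("Promoter", "Intron"), 1L), "nondiagnostic",
                  c("RsRf_TT8_1", "RsRf_TT8_2"))
    }
    ## clone-level: second clone of every line
    if (cfg$pair_snps > 0) {
      for (sub in SUBTYPES) {
        for (j in seq_len(cfg$pair_snps))
          place_snp(sample(c("Promoter", "Intron"), 1L), "nondiagnostic",
                    paste0(sub, "_TT8_2"))
      }
    }

    if (length(truth)) {
      truth <- do.call(rbind, truth)
      truth$variant_id <- sprintf("var%03d", seq_len(nrow(truth)))
      truth <- truth[order(truth$genomic_pos), , drop = FALSE]
      rownames(truth) <- NULL
    } else {
      truth <- data.frame(kind = character(), genomic_pos = integer(),
                          pos_atg = integer(), region = character(),
                          region_class = character(), specificity = character(),
                          ref_state = character(), alt_state = character(),
                          indel_len = integer(), ins_seq = character(),
                          unit = character(), ref_repeats = integer(),
                          alt_repeats = integer(), carriers = character(),
                          variant_id = character(), stringsAsFactors = FALSE)
    }

    haps <- vapply(HAPLOTYPES, function(h) {
      apply_edits(v, truth[vapply(strsplit(truth$carriers, ","),
                                  function(cc) h %in% cc, logical(1)), ,
                           drop = FALSE])
    }, character(1))
    ## reference haplotype sanity: GsRf_TT8_1 carries no edits
    stopifnot(identical(haps[["GsRf_TT8_1"]], paste(v, collapse = "")))
    list(haplotypes = haps, truth = truth, model = model,
         reference = paste(v, collapse = ""))
  })
}

## apply alt-carrier edits (rows of the truth table) to the reference vector
apply_edits <- function(refv, edits) {
  v <- refv
  if (nrow(edits)) {
    edits <- edits[order(edits$genomic_pos, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(edits))) {
      e <- edits[i, ]
      p <- e$genomic_pos
      if (e$kind == "SNP") {
        v[p] <- e$alt_state
      } else if (e$kind == "InDel") {
        if (e$indel_len > 0) {
          v <- append(v, strsplit(e$ins_seq, "")[[1]], after = p - 1L)
        } else {
          v <- v[-(p:(p - e$indel_len - 1L))]
        }
      } else if (e$kind == "SSR") {
        k <- nchar(e$unit)
        old_span <- p:(p + k * e$ref_repeats - 1L)
        v <- append(v[-old_span], rep(strsplit(e$unit, "")[[1]], e$alt_repeats),
                    after = p - 1L)
      }
    }
  }
  paste(v, collapse = "")
}

#' Default accession plan: the four study-like inbred lines
#'
#' One homozygous accession per subtype, each contributing its two clone
#' alleles, phenotype red for the Rf lines and white for the Wf lines.
#'
#' @return data.frame with `accession_id`, `line_name`, `zygosity`,
#'   `phenotype`.
#' @export
default_accession_plan <- function() {
  data.frame(
    accession_id = c("HKR-397", "HKR-275", "HKR-519", "HKR-513"),
    line_name = c("HKR-397", "HKR-275", "HKR-519", "HKR-513"),
    zygosity = c("GsRf/GsRf", "RsRf/RsRf", "WsWf/WsWf", "RsWf/RsWf"),
    phenotype = c("red", "red", "white", "white"),
    stringsAsFactors = FALSE)
}

#' Validation accession plan: inbred lines plus heterozygous cultivars
#'
#' The default plan extended with three heterozygous red-fleshed commercial
#' cultivars and two further white-fleshed accessions; with
#' `chengwoo = TRUE`, a white-fleshed accession carrying the Rf-type SSR
#' repeat count (SSR homoplasy) is appended.
#'
#' @param chengwoo append the SSR-homoplasy accession.
#' @return accession-plan data.frame.
#' @export
validation_plan <- function(chengwoo = FALSE) {
  plan <- rbind(default_accession_plan(),
                data.frame(
                  accession_id = c("RedSun", "Rupr", "Anthopol", "W-101", "W-205"),
                  line_name = c("RedSun", "Rupr", "Anthopol", "W-101", "W-205"),
                  zygosity = c("RsRf/WsWf", "RsRf/WsWf", "GsRf/RsWf",
                               "WsWf/WsWf", "RsWf/RsWf"),
                  phenotype = c("red", "red", "red", "white", "white"),
                  stringsAsFactors = FALSE))
  if (chengwoo)
    plan <- rbind(plan, data.frame(accession_id = "Chengwoo",
                                   line_name = "Chengwoo",
                                   zygosity = "chengwoo",
                                   phenotype = "white",
                                   stringsAsFactors = FALSE))
  plan
}

#' Assemble a diploid accession panel from the implanted haplotypes
#'
#' Homozygous accessions (`"GsRf/GsRf"` etc., or `"Rf/Rf"`/`"Wf/Wf"` which
#' map to the RsRf and WsWf lines) receive the two clone haplotypes of their
#' line; heterozygous accessions (`"RsRf/WsWf"`, or `"Rf/Wf"`) receive clone 1
#' of each named line. The special zygosity `"chengwoo"` builds a
#' white-fleshed accession whose SSR repeat count equals the Rf value while
#' every other Wf variant is retained (SSR homoplasy).
#'
#' @param implant output of [implant_variants()].
#' @param plan accession plan (see [default_accession_plan()]).
#' @param config the generator configuration.
#' @return an `allele_panel` with attribute `truth` (the truth set).
#' @export
build_panel <- function(implant, plan = default_accession_plan(),
                        config = generator_config()) {
  stopifnot(nrow(plan) > 0)
  haps <- implant$haplotypes
  truth <- implant$truth
  expand_zyg <- function(z) {
    z <- sub("^Rf$", "RsRf", sub("^Wf$", "WsWf", strsplit(z, "/")[[1]]))
    z
  }
  seqs <- character(0); seq_names <- character(0)
  meta <- list()
  for (i in seq_len(nrow(plan))) {
    acc <- plan$accession_id[i]
    zyg <- plan$zygosity[i]
    if (identical(zyg, "chengwoo")) {
      ## WsWf clones, with the mandatory SSR reverted to the Rf repeat count
      ssr_row <- which(truth$kind == "SSR" & truth$specificity == "Rf_vs_Wf" &
                       truth$region_class == "Intron" &
                       truth$unit == config$ssr$unit)
      refv <- strsplit(implant$reference, "")[[1]]
      pair <- vapply(c("WsWf_TT8_1", "WsWf_TT8_2"), function(h) {
        rows <- truth[vapply(strsplit(truth$carriers, ","),
                             function(cc) h %in% cc, logical(1)), , drop = FALSE]
        rows <- rows[setdiff(rownames(rows), rownames(truth)[ssr_row]), , drop = FALSE]
        apply_edits(refv, rows)
      }, character(1))
      ids <- paste0(acc, "_TT8_", 1:2)
      seqs <- c(seqs, unname(pair)); seq_names <- c(seq_names, ids)
      meta[[i]] <- data.frame(accession_id = acc, line_name = plan$line_name[i],
                              subtype = "WsWf", group = "Wf",
                              observed_flesh = plan$phenotype[i],
                              allele_ids = paste(ids, collapse = ","),
                              stringsAsFactors = FALSE)
      next
    }
    subs <- expand_zyg(zyg)
    if (length(subs) != 2L || !all(subs %in% SUBTYPES))
      stop("plan error: bad zygosity '", zyg, "'")
    homo <- subs[1] == subs[2]
    hap_ids <- if (homo) paste0(subs[1], "_TT8_", 1:2)
               else paste0(subs, "_TT8_1")
    use_plain <- sum(vapply(plan$zygosity, function(z)
      any(expand_zyg(if (identical(z, "chengwoo")) "WsWf/WsWf" else z) %in% subs),
      logical(1))) == 1L && homo
    ids <- if (use_plain) hap_ids else paste0(acc, "_", hap_ids)
    seqs <- c(seqs, unname(haps[hap_ids])); seq_names <- c(seq_names, ids)
    grp <- unique(subtype_group(subs))
    meta[[i]] <- data.frame(accession_id = acc, line_name = plan$line_name[i],
                            subtype = if (homo) subs[1] else NA_character_,
                            group = if (length(grp) == 1L) grp else NA_character_,
                            observed_flesh = plan$phenotype[i],
                            allele_ids = paste(ids, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  alleles <- Biostrings::DNAStringSet(setNames(seqs, seq_names))
  panel <- allele_panel(alleles, do.call(rbind, meta))
  ## per-allele subtype labels (needed for specificity classification)
  hap_sub <- function(id) {
    m <- regmatches(id, regexpr("(GsRf|RsRf|WsWf|RsWf)", id))
    if (length(m)) m else NA_character_
  }
  subs <- vapply(panel$allele_info$allele_id, hap_sub, character(1))
  chg <- grepl("^Chengwoo", panel$allele_info$allele_id)
  subs[chg] <- "WsWf"
  panel$allele_info$subtype <- unname(subs)
  panel$allele_info$group <- subtype_group(panel$allele_info$subtype)
  attr(panel, "truth") <- truth
  panel
}

#' One-call synthetic panel generation
#'
#' Chains [generate_reference()], [implant_variants()] and [build_panel()].
#'
#' @param seed integer seed.
#' @param plan accession plan; default the four-line study panel.
#' @param config optional full [generator_config()]; its seed is overridden
#'   by `seed` when both are given.
#' @return an `allele_panel` with attributes `truth` and `model`.
#' @export
simulate_panel <- function(seed = 1L, plan = default_accession_plan(),
                           config = NULL) {
  if (is.null(config)) config <- generator_config(seed = seed)
  else config$seed <- as.integer(seed)
  ref <- generate_reference(config)
  imp <- implant_variants(ref, config)
  panel <- build_panel(imp, plan, config)
  attr(panel, "model") <- imp$model
  attr(panel, "config") <- config
  panel
}
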