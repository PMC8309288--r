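#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

GROUPS   <- c("Rf", "Wf")
SUBTYPES <- c("GsRf", "RsRf", "WsWf", "RsWf")

#' Map a skin/flesh subtype to its flesh-color haplotype group
#'
#' `GsRf` and `RsRf` lines are red-fleshed (`Rf`); `WsWf` and `RsWf` are
#' white-fleshed (`Wf`). Unknown subtypes map to `NA`.
#'
#' @param subtype character vector of subtypes.
#' @return character vector of `"Rf"`/`"Wf"`/`NA`.
#' @export
subtype_group <- function(subtype) {
  out <- rep(NA_character_, length(subtype))
  out[subtype %in% c("GsRf", "RsRf")] <- "Rf"
  out[subtype %in% c("WsWf", "RsWf")] <- "Wf"
  out
}

## ---------------------------------------------------------------------------
## GeneModel
## ---------------------------------------------------------------------------

#' Construct and validate a single-gene model
#'
#' A gene model describes one allele sequence laid out in gene orientation as a
#' promoter followed by alternating exons and introns (1-based inclusive
#' coordinates), with transcription start (TSS) and start-codon (ATG) anchors.
#' When `n_exons = 7` this is the layout of the radish *RsTT8* gene
#' (7 exons, 6 introns).
#'
#' @param features data.frame with columns `kind` (`promoter`/`exon`/`intron`),
#'   `index` (1 for the promoter, exon/intron ordinal otherwise), `start`,
#'   `end` (1-based inclusive).
#' @param tss_pos 1-based transcription start position.
#' @param atg_pos 1-based position of the A of the start codon.
#' @param reference_allele_id id of the allele the coordinates refer to.
#' @param n_exons expected exon count; `NULL` skips the count check.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(features, tss_pos, atg_pos,
                       reference_allele_id = "reference", n_exons = 7L) {
  stopifnot(is.data.frame(features),
            all(c("kind", "index", "start", "end") %in% names(features)))
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  m <- structure(list(reference_allele_id = reference_allele_id,
                      features = features,
                      tss_pos = as.integer(tss_pos),
                      atg_pos = as.integer(atg_pos),
                      strand = "+"),
                 class = "gene_model")
  validate_gene_model(m, n_exons = n_exons)
  m
}

#' Validate gene-model invariants
#'
#' Checks that the promoter ends immediately before the TSS, that exons and
#' introns tile the transcribed span without gaps or overlaps (exon i is
#' followed directly by intron i), that the ATG lies at or after the TSS, and
#' (optionally) that the exon count matches `n_exons`.
#'
#' @param model a `gene_model`.
#' @param n_exons required exon count or `NULL`.
#' @return the model, invisibly; stops with a model error otherwise.
#' @export
validate_gene_model <- function(model, n_exons = 7L) {
  f <- model$features
  if (!all(f$kind %in% c("promoter", "exon", "intron")))
    stop("gene model error: unknown feature kind")
  if (any(f$end < f$start)) stop("gene model error: feature end < start")
  ex <- f[f$kind == "exon", , drop = FALSE]
  it <- f[f$kind == "intron", , drop = FALSE]
  pr <- f[f$kind == "promoter", , drop = FALSE]
  if (nrow(pr) != 1L) stop("gene model error: exactly one promoter required")
  if (!is.null(n_exons)) {
    if (nrow(ex) != n_exons || nrow(it) != n_exons - 1L)
      stop(sprintf("gene model error: expected %d exons / %d introns, found %d / %d",
                   n_exons, n_exons - 1L, nrow(ex), nrow(it)))
  }
  if (pr$end + 1L != model$tss_pos)
    stop("gene model error: promoter must end immediately before the TSS")
  if (model$atg_pos < model$tss_pos)
    stop("gene model error: ATG anchor upstream of TSS")
  ## exons/introns must alternate and tile the span with no gap or overlap
  tx <- f[f$kind != "promoter", , drop = FALSE]
  tx <- tx[order(tx$start), , drop = FALSE]
  if (nrow(tx) > 0) {
    if (tx$start[1] != model$tss_pos)
      stop("gene model error: first exon must start at the TSS")
    if (tx$kind[1] != "exon")
      stop("gene model error: transcribed span must start with an exon")
    if (nrow(tx) > 1) {
      gaps <- tx$start[-1] - tx$end[-nrow(tx)]
      if (any(gaps != 1L))
        stop("gene model error: adjacent features must abut (gap/overlap found)")
      kinds <- tx$kind
      if (any(kinds[-1] == kinds[-length(kinds)]))
        stop("gene model error: exons and introns must alternate")
    }
  }
  ex1 <- ex[which.min(ex$start), ]
  if (model$atg_pos < ex1$start || model$atg_pos > ex1$end)
    stop("gene model error: ATG anchor must lie in the first exon")
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  ex <- sum(x$features$kind == "exon")
  it <- sum(x$features$kind == "intron")
  cat(sprintf("gene_model on '%s': promoter %d nt, %d exons / %d introns, TSS %d, ATG %d, span 1..%d\n",
              x$reference_allele_id,
              x$features$end[x$features$kind == "promoter"][1],
              ex, it, x$tss_pos, x$atg_pos, max(x$features$end)))
  invisible(x)
}

#' Total reference span covered by a gene model
#' @param model a `gene_model`.
#' @return integer length.
#' @export
model_span <- function(model) max(model$features$end)

#' Name the gene-model feature containing a genomic position
#'
#' @param pos vector of 1-based genomic positions on the reference allele.
#' @param model a `gene_model`.
#' @return character vector like `"promoter"`, `"exon_3"`, `"intron_5"`; `NA`
#'   outside the model span.
#' @export
feature_at <- function(pos, model) {
  f <- model$features
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(f))) {
    hit <- pos >= f$start[i] & pos <= f$end[i]
    out[hit] <- if (f$kind[i] == "promoter") "promoter"
                else paste(f$kind[i], f$index[i], sep = "_")
  }
  out
}

#' Collapse a feature label to its Table-style region class
#' @param region character vector of feature labels (`exon_3` etc.).
#' @return `"Promoter"`, `"Exon"` or `"Intron"`.
#' @export
region_class <- function(region) {
  cls <- rep(NA_character_, length(region))
  cls[region == "promoter"] <- "Promoter"
  cls[grepl("^exon_", region)] <- "Exon"
  cls[grepl("^intron_", region)] <- "Intron"
  cls
}

## ---------------------------------------------------------------------------
## Anchor-relative coordinates
## ---------------------------------------------------------------------------

#' Convert genomic positions to signed anchor-relative coordinates
#'
#' The anchor base itself is `+1`; the base immediately 5' of it is `-1`.
#' There is no position 0, matching the field's "-35", "-979 to -818" usage.
#'
#' @param pos 1-based genomic positions on the reference allele.
#' @param model a `gene_model`.
#' @param anchor `"atg"` (default) or `"tss"`.
#' @return signed nonzero integers.
#' @seealso [from_anchor()] for the inverse.
#' @export
to_anchor <- function(pos, model, anchor = c("atg", "tss")) {
  anchor <- match.arg(anchor)
  a <- if (anchor == "atg") model$atg_pos else model$tss_pos
  if (any(pos < 1L | pos > model_span(model)))
    stop("coordinate error: position outside reference span")
  ifelse(pos >= a, pos - a + 1L, pos - a)
}

#' Convert signed anchor-relative coordinates back to genomic positions
#'
#' Inverse of [to_anchor()]. Zero is not a valid anchor-relative position.
#'
#' @param rel signed nonzero anchor-relative positions.
#' @param model a `gene_model`.
#' @param anchor `"atg"` (default) or `"tss"`.
#' @return 1-based genomic positions.
#' @export
from_anchor <- function(rel, model, anchor = c("atg", "tss")) {
  anchor <- match.arg(anchor)
  if (any(rel == 0L)) stop("coordinate error: anchor-relative position 0 does not exist")
  a <- if (anchor == "atg") model$atg_pos else model$tss_pos
  pos <- ifelse(rel > 0L, a + rel - 1L, a + rel)
  if (any(pos < 1L | pos > model_span(model)))
    stop("coordinate error: position outside reference span")
  as.integer(pos)
}

## ---------------------------------------------------------------------------
## Gene-model GFF3 I/O
## ---------------------------------------------------------------------------

#' Read a gene model from a GFF3 subset
#'
#' Expects one `gene` record carrying `tss_pos` and `atg_pos` attributes plus
#' `promoter`/`exon`/`intron` features on the same sequence. Model invariants
#' are checked on construction.
#'
#' @param path GFF3 file path.
#' @param n_exons required exon count (`7` for the *RsTT8* layout); `NULL`
#'   skips the check.
#' @return a `gene_model`.
#' @export
read_gene_model <- function(path, n_exons = 7L) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  gene <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gene) != 1L) stop("gene model error: exactly one gene record required")
  if (is.null(gene$tss_pos) || is.null(gene$atg_pos) ||
      is.na(gene$tss_pos) || is.na(gene$atg_pos))
    stop("gene model error: gene record must carry tss_pos and atg_pos attributes")
  feats <- df[df$type %in% c("promoter", "exon", "intron"), , drop = FALSE]
  idx <- suppressWarnings(as.integer(feats$feature_index))
  if (all(is.na(idx))) {
    ## fall back to positional numbering within kind
    idx <- stats::ave(seq_len(nrow(feats)), feats$type, FUN = seq_along)
  }
  features <- data.frame(kind = as.character(feats$type),
                         index = as.integer(idx),
                         start = feats$start, end = feats$end,
                         stringsAsFactors = FALSE)
  gene_model(features,
             tss_pos = as.integer(as.character(gene$tss_pos)),
             atg_pos = as.integer(as.character(gene$atg_pos)),
             reference_allele_id = as.character(df$seqnames[1]),
             n_exons = n_exons)
}

#' Write a gene model as a GFF3 subset
#'
#' @param model a `gene_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  f <- model$features
  span <- model_span(model)
  gr <- GenomicRanges::GRanges(
    seqnames = model$reference_allele_id,
    ranges = IRanges::IRanges(start = c(1L, f$start), end = c(span, f$end)),
    strand = "+",
    type = c("gene", f$kind),
    source = "fleshmark",
    feature_index = c(NA_integer_, f$index),
    tss_pos = c(model$tss_pos, rep(NA_integer_, nrow(f))),
    atg_pos = c(model$atg_pos, rep(NA_integer_, nrow(f))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Allele panel
## ---------------------------------------------------------------------------

#' Assemble an allele panel object
#'
#' @param alleles named `DNAStringSet` (or named character vector) of allele
#'   sequences in gene orientation.
#' @param meta data.frame with one row per accession: `accession_id`,
#'   `line_name`, `subtype` (or `NA`), `group` (`Rf`/`Wf`, derived from the
#'   subtype when missing), `observed_flesh`
#'   (`red`/`white`/`pink`/`segregating`/`unknown`) and `allele_ids`
#'   (comma-separated, 1 or 2 per diploid accession).
#' @return an object of class `allele_panel` with elements `alleles`
#'   (`DNAStringSet`), `allele_info` (one row per allele) and `meta`.
#' @export
allele_panel <- function(alleles, meta) {
  if (is.character(alleles)) alleles <- Biostrings::DNAStringSet(alleles)
  stopifnot(methods::is(alleles, "DNAStringSet"))
  ids <- names(alleles)
  if (is.null(ids) || anyDuplicated(ids))
    stop("format error: allele sequences must carry unique ids")
  if (any(Biostrings::width(alleles) == 0))
    stop("format error: empty allele sequence")
  need <- c("accession_id", "line_name", "observed_flesh", "allele_ids")
  stopifnot(is.data.frame(meta), all(need %in% names(meta)))
  if (is.null(meta$subtype)) meta$subtype <- NA_character_
  if (is.null(meta$group)) meta$group <- subtype_group(meta$subtype)
  bad <- !is.na(meta$subtype) & !is.na(meta$group) &
    subtype_group(meta$subtype) != meta$group
  if (any(bad))
    stop("format error: group label inconsistent with subtype for accession(s) ",
         paste(meta$accession_id[bad], collapse = ", "))
  spl <- strsplit(as.character(meta$allele_ids), ",", fixed = TRUE)
  spl <- lapply(spl, trimws)
  if (any(lengths(spl) > 2L))
    stop("format error: more than two alleles for a diploid accession")
  all_ids <- unlist(spl)
  missing <- setdiff(all_ids, ids)
  if (length(missing))
    stop("linkage error: metadata references missing allele(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(all_ids))
    stop("linkage error: allele assigned to more than one accession")
  orphan <- setdiff(ids, all_ids)
  if (length(orphan))
    warning("allele(s) not referenced by any accession: ",
            paste(orphan, collapse = ", "))
  info <- data.frame(
    allele_id = all_ids,
    accession_id = rep(meta$accession_id, lengths(spl)),
    group = rep(meta$group, lengths(spl)),
    subtype = rep(meta$subtype, lengths(spl)),
    stringsAsFactors = FALSE)
  info <- info[match(ids[ids %in% all_ids], info$allele_id), , drop = FALSE]
  rownames(info) <- NULL
  structure(list(alleles = alleles, allele_info = info, meta = meta),
            class = "allele_panel")
}

#' @export
print.allele_panel <- function(x, ...) {
  cat(sprintf("allele_panel: %d alleles across %d accessions (%s)\n",
              length(x$alleles), nrow(x$meta),
              paste(sprintf("%s=%d", names(table(x$allele_info$group)),
                            as.integer(table(x$allele_info$group))),
                    collapse = ", ")))
  invisible(x)
}

#' Read an allele panel from FASTA plus a metadata TSV
#'
#' The metadata table has columns `accession_id`, `line_name`, `subtype`
#' (optional), `group` (optional), `flesh_phenotype` and `allele_ids`
#' (comma-separated FASTA ids). Unknown phenotypes are preserved, never
#' guessed. Lines starting with `#` are treated as comments.
#'
#' @param fasta_path FASTA of allele sequences.
#' @param meta_path metadata TSV.
#' @return an `allele_panel`; an empty FASTA yields an empty panel with a
#'   warning.
#' @export
read_panel <- function(fasta_path, meta_path) {
  alleles <- Biostrings::readDNAStringSet(fasta_path)
  names(alleles) <- sub("\\s.*$", "", names(alleles))
  if (length(alleles) == 0L) {
    warning("empty allele FASTA: returning empty panel")
    meta <- data.frame(accession_id = character(), line_name = character(),
                       subtype = character(), group = character(),
                       observed_flesh = character(), allele_ids = character(),
                       stringsAsFactors = FALSE)
    return(structure(list(alleles = alleles,
                          allele_info = data.frame(allele_id = character(),
                                                   accession_id = character(),
                                                   group = character(),
                                                   subtype = character(),
                                                   stringsAsFactors = FALSE),
                          meta = meta),
                     class = "allele_panel"))
  }
  if (anyDuplicated(names(alleles)))
    stop("format error: duplicate allele id in FASTA")
  tab <- read.delim(meta_path, comment.char = "#", stringsAsFactors = FALSE)
  if ("flesh_phenotype" %in% names(tab) && !"observed_flesh" %in% names(tab))
    names(tab)[names(tab) == "flesh_phenotype"] <- "observed_flesh"
  allele_panel(alleles, tab)
}

#' Write an allele panel to FASTA plus a metadata TSV
#'
#' Round-trips with [read_panel()]: sequences and metadata are preserved
#' byte-for-byte (modulo the provenance header, which is deterministic for a
#' fixed seed).
#'
#' @param panel an `allele_panel`.
#' @param fasta_path,meta_path output paths.
#' @param header optional provenance header lines (without the leading `#`).
#' @return invisibly, a character vector of the two paths.
#' @export
write_panel <- function(panel, fasta_path, meta_path, header = NULL) {
  Biostrings::writeXStringSet(panel$alleles, fasta_path, width = 80L)
  meta <- panel$meta
  names(meta)[names(meta) == "observed_flesh"] <- "flesh_phenotype"
  write_tsv(meta, meta_path, header = header)
  invisible(c(fasta_path, meta_path))
}

#' Extract the allele sequences belonging to one accession
#' @param panel an `allele_panel`.
#' @param accession_id accession id.
#' @return `DNAStringSet` of 1 or 2 alleles.
#' @export
accession_alleles <- function(panel, accession_id) {
  ids <- panel$allele_info$allele_id[panel$allele_info$accession_id == accession_id]
  if (!length(ids)) stop("unknown accession: ", accession_id)
  panel$alleles[ids]
}

## ---------------------------------------------------------------------------
## TSV plumbing
## ---------------------------------------------------------------------------

## internal: TSV writer with optional '#' provenance header
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## internal: standard provenance header lines
provenance_header <- function(seed = NA, config_hash = NA) {
  c(sprintf("fleshmark %s", as.character(utils::packageVersion("fleshmark"))),
    sprintf("seed=%s", as.character(seed)),
    sprintf("config=%s", as.character(config_hash)))
}
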