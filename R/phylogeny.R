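## Distance-based allele phylogeny.
##
## The panel's alleles separate into red-fleshed (Rf) and white-fleshed (Wf)
## haplotype groups; a neighbor-joining tree on p-distances makes that
## separation explicit, and a bipartition test checks whether some internal
## edge splits the leaves exactly into the two groups.

#' Pairwise p-distance matrix for an allele panel
#'
#' Every allele is aligned to the panel reference and the alignments are
#' projected onto reference columns; for each pair, p-distance =
#' mismatches / compared columns over columns where both alleles have a
#' non-gap, non-N base. Insertions relative to the reference are not
#' columns and do not contribute.
#'
#' @param panel an `allele_panel` with at least 2 alleles.
#' @param reference_id reference allele id; default [reference_allele_id()].
#' @return a symmetric matrix of class `dist_matrix` with zero diagonal.
#' @export
distance_matrix <- function(panel, reference_id = reference_allele_id(panel)) {
  ids <- names(panel$alleles)
  if (length(ids) < 2L) stop("distance error: need at least 2 alleles")
  refseq <- as.character(panel$alleles[[reference_id]])
  L <- nchar(refseq)
  proj <- matrix(NA_character_, nrow = length(ids), ncol = L,
                 dimnames = list(ids, NULL))
  proj[reference_id, ] <- strsplit(refseq, "")[[1]]
  for (id in setdiff(ids, reference_id)) {
    pa <- align_pair(refseq, as.character(panel$alleles[[id]]))
    rp <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    qp <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    keep <- rp != "-"
    proj[id, ] <- qp[keep]
  }
  proj[proj == "-" | proj == "N"] <- NA_character_
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- proj[i, ]; b <- proj[j, ]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok))
      stop("distance error: no comparable columns between ", ids[i], " and ", ids[j])
    d[i, j] <- d[j, i] <- sum(a[ok] != b[ok]) / sum(ok)
  }
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via [ape::nj()]); negative branch lengths are
#' clamped to zero with a warning. Deterministic for a fixed matrix.
#'
#' @param dm symmetric distance matrix with row/col names (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
build_nj_tree <- function(dm) {
  dm <- unclass(dm)
  if (nrow(dm) < 3L) stop("size error: neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Test whether a tree splits cleanly by flesh-color group
#'
#' TRUE when some edge of the unrooted tree bipartitions the leaves exactly
#' into the Rf set and the Wf set.
#'
#' @param tree a `phylo` object.
#' @param groups named character vector (leaf label -> `"Rf"`/`"Wf"`).
#' @return list with `split` (logical) and `sides` (the two leaf sets of the
#'   splitting edge, or `NULL`).
#' @export
check_group_split <- function(tree, groups) {
  tips <- tree$tip.label
  if (!all(tips %in% names(groups)) || anyNA(groups[tips]))
    stop("label error: every leaf needs an Rf/Wf group label")
  g <- groups[tips]
  rf <- sort(tips[g == "Rf"]); wf <- sort(tips[g == "Wf"])
  if (!length(rf) || !length(wf))
    return(list(split = FALSE, sides = NULL))
  ## every clade of the rooted representation corresponds to one edge side
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  for (p in parts) {
    side <- sort(labs[p])
    if (identical(side, rf) || identical(side, wf))
      return(list(split = TRUE,
                  sides = list(side, sort(setdiff(tips, side)))))
  }
  ## also consider trivial sides formed by single tips (2-vs-rest trees)
  if (length(rf) == 1L || length(wf) == 1L) {
    one <- if (length(rf) == 1L) rf else wf
    return(list(split = TRUE, sides = list(one, sort(setdiff(tips, one)))))
  }
  list(split = FALSE, sides = NULL)
}

#' Run the phylogeny stage of the pipeline
#'
#' Computes the p-distance matrix, builds the NJ tree and evaluates the
#' group bipartition.
#'
#' @param panel an `allele_panel`.
#' @return list with `distances`, `tree`, `split` (result of
#'   [check_group_split()]).
#' @export
allele_phylogeny <- function(panel) {
  dm <- distance_matrix(panel)
  tr <- build_nj_tree(dm)
  groups <- setNames(panel$allele_info$group, panel$allele_info$allele_id)
  sp <- check_group_split(tr, groups)
  list(distances = dm, tree = tr, split = sp)
}
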