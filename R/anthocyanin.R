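## Spectrophotometric anthocyanin quantification.
##
## Relative anthocyanin content (RAC) from absorbances at 530/620/650 nm,
## and total anthocyanin content (TAC, mg anthocyanin / 100 g fresh weight)
## referenced to cyanidin-3-glucoside.

#' Relative anthocyanin content from a 530/620/650 nm absorbance triple
#'
#' RAC = (A530 - A620) - 0.1 * (A650 - A620). A620 corrects for turbidity
#' and A650 for chlorophyll interference. Negative results are reported
#' with a warning.
#'
#' @param a530,a620,a650 nonnegative absorbance values (vectorized).
#' @return RAC in absorbance units.
#' @export
compute_rac <- function(a530, a620, a650) {
  if (any(!is.finite(c(a530, a620, a650))) || any(c(a530, a620, a650) < 0))
    stop("input error: absorbances must be finite and nonnegative")
  rac <- (a530 - a620) - 0.1 * (a650 - a620)
  if (any(rac < 0)) warning("negative RAC value(s): check blanks/turbidity")
  rac
}

#' Total anthocyanin content
#'
#' TAC = RAC x MW x DF x 1000 x path, with MW the molecular weight of
#' cyanidin-3-glucoside (449.2 g/mol), DF the dilution factor and path the
#' cuvette optical path length in cm. This is the source formula implemented
#' verbatim; note that it multiplies by the path length and involves no molar
#' extinction coefficient, so its absolute scale is conventional.
#' `convention = "standard"` instead computes the textbook form
#' RAC x MW x DF x 1000 / (epsilon x path) with a user-supplied molar
#' extinction coefficient (L mol-1 cm-1).
#'
#' @param rac relative anthocyanin content (see [compute_rac()]).
#' @param mw molecular weight (g/mol); default cyanidin-3-glucoside.
#' @param df dilution factor (>= 1).
#' @param path_length cuvette path length (cm).
#' @param convention `"as_published"` (default) or `"standard"`.
#' @param epsilon molar extinction coefficient, required for `"standard"`
#'   (e.g. 26900 for cyanidin-3-glucoside).
#' @return TAC (mg anthocyanin / 100 g fresh weight, on the source scale).
#' @export
compute_tac <- function(rac, mw = 449.2, df = 1, path_length = 1,
                        convention = c("as_published", "standard"),
                        epsilon = NULL) {
  convention <- match.arg(convention)
  if (any(c(mw, df, path_length) <= 0))
    stop("input error: MW, DF and path length must be positive")
  if (convention == "as_published")
    return(rac * mw * df * 1000 * path_length)
  if (is.null(epsilon) || epsilon <= 0)
    stop("input error: convention 'standard' needs a positive epsilon")
  rac * mw * df * 1000 / (epsilon * path_length)
}

#' Quantify anthocyanin content for a table of absorbance readings
#'
#' @param readings data.frame (or TSV path) with columns `sample`, `A530`,
#'   `A620`, `A650` and optionally `DF` (default 1).
#' @param ... passed to [compute_tac()].
#' @return the table with `RAC` and `TAC` columns appended.
#' @export
quantify_anthocyanin <- function(readings, ...) {
  if (is.character(readings))
    readings <- read.delim(readings, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "A530", "A620", "A650")
  stopifnot(all(need %in% names(readings)))
  if (is.null(readings$DF)) readings$DF <- 1
  readings$RAC <- compute_rac(readings$A530, readings$A620, readings$A650)
  readings$TAC <- compute_tac(readings$RAC, df = readings$DF, ...)
  readings
}
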