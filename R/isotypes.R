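#' Constant-gene isotypes in IGH locus order
#'
#' The nine human heavy-chain constant genes in their genomic order on the
#' IGH locus. Class-switch recombination is deletional, so a cell can only
#' switch to a constant gene downstream of its current one.
#'
#' @format Character vector of length 9.
#' @export
IGH_ISOTYPES <- c("IGHM", "IGHD", "IGHG3", "IGHG1", "IGHA1",
                  "IGHG2", "IGHG4", "IGHE", "IGHA2")

# reporting-granularity class labels
.ISOTYPE_CLASS_MAP <- c(
  IGHM = "IgM", IGHD = "IgD", IGHG3 = "IgG3", IGHG1 = "IgG1/2",
  IGHG2 = "IgG1/2", IGHG4 = "IgG4", IGHA1 = "IgA1/2", IGHA2 = "IgA1/2",
  IGHE = "IgE")

#' Group raw isotype labels into reporting classes
#'
#' Two grouping schemes are used throughout the analyses:
#' \describe{
#'   \item{`"class"`}{IgM, IgD, IgG3, IgG1/2, IgG4, IgA1/2, IgE — the
#'     granularity used for clone-level isotype-class counting.}
#'   \item{`"overlap"`}{as `"class"` but with IgM and IgD merged into one
#'     IgD/M class. IgM reads are partly sequenced from IgD transcripts via
#'     alternative splicing, so the two cannot be distinguished reliably and
#'     are analysed together for overlap and frequency reporting.}
#' }
#'
#' @param x Character vector of raw isotype labels (e.g. `"IGHG1"`).
#' @param scheme `"overlap"` (default) or `"class"`.
#' @return Character vector of grouped class labels.
#' @examples
#' group_isotypes(c("IGHM", "IGHD", "IGHG2"))
#' @export
group_isotypes <- function(x, scheme = c("overlap", "class")) {
  scheme <- match.arg(scheme)
  bad <- setdiff(unique(x), c(names(.ISOTYPE_CLASS_MAP), NA))
  if (length(bad)) stop("unknown isotype label(s): ", paste(bad, collapse = ", "))
  out <- unname(.ISOTYPE_CLASS_MAP[x])
  if (scheme == "overlap") out[out %in% c("IgM", "IgD")] <- "IgD/M"
  out
}

#' Levels of the grouped isotype classes
#'
#' @param scheme `"overlap"` or `"class"` (see [group_isotypes()]).
#' @return Character vector of class levels in locus order.
#' @export
isotype_class_levels <- function(scheme = c("overlap", "class")) {
  scheme <- match.arg(scheme)
  if (scheme == "overlap") c("IgD/M", "IgG3", "IgG1/2", "IgA1/2", "IgG4", "IgE")
  else c("IgM", "IgD", "IgG3", "IgG1/2", "IgA1/2", "IgG4", "IgE")
}

#' Is an isotype class-switched?
#'
#' Switched means any isotype other than IgM or IgD (consistent with the
#' IgM-IgD- grouping used for clone-level reporting).
#'
#' @param x Character vector of raw isotype labels.
#' @return Logical vector.
#' @export
is_switched <- function(x) !(x %in% c("IGHM", "IGHD"))
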