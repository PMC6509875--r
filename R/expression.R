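#' Read a two-condition expression table
#'
#' Reads a tab-separated expression table with a header.  Two layouts are
#' accepted: `gene_id`, `expr_control`, `expr_treatment` (abundances on the
#' linear scale), which yields an [ExpressionPair-class]; or `gene_id`,
#' `logfc` (precomputed log fold changes), which yields a
#' [DifferentiationProfile-class] directly.
#'
#' Precomputed fold changes are assumed to be on the natural-log scale; set
#' `logfcBase = 2` for log2 input, in which case values are rescaled to
#' natural log on read so internal semantics never change.  (The BASE score
#' is scale-free, so this rescaling does not affect inference; it only keeps
#' reported d values on one scale.)
#'
#' @param path path to a TSV file with a header row.
#' @param logfcBase base of precomputed log fold changes: `exp(1)` (default)
#'   or `2`.
#' @return An [ExpressionPair-class] or [DifferentiationProfile-class],
#'   depending on the columns found.
#' @export
readExpression <- function(path, logfcBase = exp(1)) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(tab)
  if (all(c("gene_id", "expr_control", "expr_treatment") %in% cols)) {
    ExpressionPair(tab$gene_id, tab$expr_control, tab$expr_treatment)
  } else if (all(c("gene_id", "logfc") %in% cols)) {
    d <- as.numeric(tab$logfc)
    if (!isTRUE(all.equal(logfcBase, exp(1)))) d <- d * log(logfcBase)
    DifferentiationProfile(tab$gene_id, d)
  } else {
    stop("expression table must have columns (gene_id, expr_control, ",
         "expr_treatment) or (gene_id, logfc); found: ",
         paste(cols, collapse = ", "))
  }
}

#' Compute the expression differentiation profile
#'
#' Converts paired control/treatment abundances into per-gene log fold
#' changes d_i = ln(e_i1 / e_i0).  Genes whose abundance is zero or
#' negative in either condition cannot enter the log and are dropped with a
#' message reporting how many.
#'
#' @param pair an [ExpressionPair-class].
#' @return A [DifferentiationProfile-class] over the retained genes.
#' @examples
#' pair <- ExpressionPair(c("g1", "g2"), e0 = c(1, 1), e1 = c(2, 0.5))
#' logFoldChange(diffExpression(pair))   # (ln 2, -ln 2)
#' @export
diffExpression <- function(pair) {
  stopifnot(is(pair, "ExpressionPair"))
  keep <- pair@e0 > 0 & pair@e1 > 0
  if (!any(keep))
    stop("no genes with strictly positive abundance in both conditions")
  if (!all(keep))
    message("diffExpression: dropped ", sum(!keep),
            " gene(s) with nonpositive abundance")
  DifferentiationProfile(pair@geneIds[keep],
                         log(pair@e1[keep] / pair@e0[keep]))
}
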