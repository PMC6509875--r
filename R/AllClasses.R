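#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Paired two-condition expression abundances
#'
#' Holds gene-level expression abundances for exactly two samples, a control
#' and a treatment, in matched gene order.  This is the raw input of the
#' differentiation step: abundances are on the original (linear) expression
#' scale, in arbitrary but common units.
#'
#' @slot geneIds character vector of unique gene identifiers (length N).
#' @slot e0 numeric vector of control abundances (non-negative, length N).
#' @slot e1 numeric vector of treatment abundances (non-negative, length N).
#'
#' @seealso [diffExpression()] which converts an `ExpressionPair` into a
#'   [DifferentiationProfile-class].
#' @export
setClass("ExpressionPair",
  representation(geneIds = "character", e0 = "numeric", e1 = "numeric"))

setValidity("ExpressionPair", function(object) {
  n <- length(object@geneIds)
  if (n < 1L) return("at least one gene is required")
  if (anyDuplicated(object@geneIds)) return("gene identifiers must be unique")
  if (length(object@e0) != n || length(object@e1) != n)
    return("geneIds, e0 and e1 must have identical length")
  if (any(!is.finite(object@e0)) || any(!is.finite(object@e1)))
    return("abundances must be finite")
  if (any(object@e0 < 0) || any(object@e1 < 0))
    return("abundances must be non-negative")
  TRUE
})

#' Construct an ExpressionPair
#'
#' @param geneIds character vector of unique gene identifiers.
#' @param e0,e1 numeric abundances under control and treatment, same order
#'   and length as `geneIds`.
#' @return An [ExpressionPair-class] object.
#' @examples
#' ExpressionPair(c("g1", "g2"), e0 = c(1, 2), e1 = c(2, 1))
#' @export
ExpressionPair <- function(geneIds, e0, e1) {
  new("ExpressionPair", geneIds = as.character(geneIds),
      e0 = as.numeric(e0), e1 = as.numeric(e1))
}

#' Per-gene expression differentiation profile
#'
#' Stores the per-gene log fold change d between treatment and control on
#' the natural-log scale, d_i = ln(e_i1 / e_i0).  The directional
#' components d+ = max(d, 0) and d- = max(-d, 0) are derived on access so
#' that d+ - d- reconstructs d bit-exactly and d+ * d- == 0 always holds.
#'
#' @slot geneIds character vector of unique gene identifiers (length N).
#' @slot d numeric log fold changes (natural log), length N.
#'
#' @seealso [dUp()], [dDown()], [runBase()].
#' @export
setClass("DifferentiationProfile",
  representation(geneIds = "character", d = "numeric"))

setValidity("DifferentiationProfile", function(object) {
  n <- length(object@geneIds)
  if (n < 1L) return("at least one gene is required")
  if (anyDuplicated(object@geneIds)) return("gene identifiers must be unique")
  if (length(object@d) != n) return("geneIds and d must have identical length")
  if (any(!is.finite(object@d))) return("log fold changes must be finite")
  TRUE
})

#' Construct a DifferentiationProfile
#'
#' @param geneIds character vector of unique gene identifiers.
#' @param d numeric log fold changes on the natural-log scale, same order
#'   and length as `geneIds`.
#' @return A [DifferentiationProfile-class] object.
#' @examples
#' pr <- DifferentiationProfile(c("g1", "g2"), d = c(0.7, -1.2))
#' dUp(pr)
#' dDown(pr)
#' @export
DifferentiationProfile <- function(geneIds, d) {
  new("DifferentiationProfile", geneIds = as.character(geneIds),
      d = as.numeric(d))
}

#' Position weight matrix for one cis-regulatory motif
#'
#' An L x 4 matrix over the (A, C, G, T) alphabet, one row per motif
#' position.  Rows hold either raw observation counts or probabilities; the
#' `isProbability` flag records which.  Count matrices are converted with a
#' pseudocount of 0.5 per cell before scanning (see [normalizePWM()]).
#'
#' @slot motifId motif identifier, e.g. `"V$PPARA_01"` or a JASPAR accession.
#' @slot factorName label of the associated trans-acting factor.
#' @slot matrix numeric L x 4 matrix, columns named A, C, G, T.
#' @slot isProbability logical; `TRUE` when rows are normalized to sum 1.
#'
#' @seealso [parsePWMs()], [scoreWindow()], [countHits()].
#' @export
setClass("MotifPWM",
  representation(motifId = "character", factorName = "character",
                 matrix = "matrix", isProbability = "logical"))

setValidity("MotifPWM", function(object) {
  m <- object@matrix
  if (!is.numeric(m)) return("matrix must be numeric")
  if (nrow(m) < 1L) return("matrix must have at least one row (L >= 1)")
  if (ncol(m) != 4L) return("matrix must have exactly 4 columns (A, C, G, T)")
  if (any(!is.finite(m)) || any(m < 0)) return("matrix entries must be finite and >= 0")
  if (isTRUE(object@isProbability)) {
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-6))
      return("probability rows must sum to 1 within 1e-6")
  }
  TRUE
})

#' Construct a MotifPWM
#'
#' @param motifId motif identifier string.
#' @param matrix numeric L x 4 matrix (rows = positions, columns = A, C, G,
#'   T), holding counts or probabilities.
#' @param factorName trans-factor label; defaults to `motifId`.
#' @param isProbability logical; set when rows are already normalized to sum
#'   to 1.  When missing it is inferred from the row sums.
#' @return A [MotifPWM-class] object.
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01,
#'               0.01, 0.97, 0.01, 0.01), nrow = 2, byrow = TRUE)
#' MotifPWM("AC_toy", m)
#' @export
MotifPWM <- function(motifId, matrix, factorName = motifId,
                     isProbability = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  colnames(matrix) <- c("A", "C", "G", "T")
  if (is.null(isProbability))
    isProbability <- all(abs(rowSums(matrix) - 1) <= 1e-6)
  new("MotifPWM", motifId = as.character(motifId),
      factorName = as.character(factorName), matrix = matrix,
      isProbability = isProbability)
}

#' Promoter regions with their extracted sequences
#'
#' One promoter per gene: a genomic window around the transcription start
#' site together with the extracted nucleotide sequence.  For minus-strand
#' genes the stored sequence is the reverse complement of the reference
#' slice, so position 0 of each sequence is the most 5' promoter base
#' relative to transcription.  Ranges are stored as a
#' [GenomicRanges::GRanges] (1-based, closed, the Bioconductor convention);
#' [writePromoterBed()] emits the equivalent 0-based half-open BED records.
#'
#' @slot ranges `GRanges` with one range per gene; metadata columns
#'   `gene_id` and `clipped` (whether the window hit a chromosome boundary).
#' @slot seqs [Biostrings::DNAStringSet] of extracted sequences named by
#'   gene id, alphabet ACGTN, parallel to `ranges`.
#'
#' @seealso [extractPromoters()], [buildCountMatrix()].
#' @export
setClass("PromoterRegions",
  representation(ranges = "GRanges", seqs = "DNAStringSet"))

setValidity("PromoterRegions", function(object) {
  if (length(object@ranges) != length(object@seqs))
    return("ranges and seqs must be parallel")
  if (length(object@ranges) == 0L) return("empty promoter set")
  ids <- object@ranges$gene_id
  if (is.null(ids) || anyDuplicated(ids))
    return("ranges must carry unique gene_id metadata")
  if (!identical(unname(GenomicRanges::width(object@ranges)),
                 unname(Biostrings::width(object@seqs))))
    return("sequence lengths must equal range widths")
  TRUE
})

#' Gene x motif occurrence count matrix
#'
#' Holds tau, the number of above-threshold motif occurrences in each
#' gene's promoter: the condition-free proxy for the binding strength of a
#' trans-factor on a gene.  Rows are genes, columns are motifs.
#'
#' @slot counts integer matrix, genes x motifs, dimnames = gene and motif
#'   identifiers, all entries >= 0.
#' @slot factorNames character vector parallel to the motif columns giving
#'   the trans-factor label of each motif.
#'
#' @seealso [buildCountMatrix()], [countsToBinding()], [runBase()].
#' @export
setClass("BindingCountMatrix",
  representation(counts = "matrix", factorNames = "character"))

setValidity("BindingCountMatrix", function(object) {
  m <- object@counts
  if (!is.numeric(m)) return("counts must be numeric")
  if (nrow(m) < 1L || ncol(m) < 1L) return("counts must be non-empty")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry gene and motif dimnames")
  if (anyDuplicated(rownames(m))) return("gene identifiers must be unique")
  if (anyDuplicated(colnames(m))) return("motif identifiers must be unique")
  if (any(!is.finite(m)) || any(m < 0)) return("counts must be finite and >= 0")
  if (any(m != round(m))) return("counts must be integers")
  if (length(object@factorNames) != ncol(m))
    return("factorNames must be parallel to the motif columns")
  TRUE
})

#' Construct a BindingCountMatrix
#'
#' @param counts integer matrix of motif occurrence counts with gene row
#'   names and motif column names.
#' @param factorNames optional character vector of trans-factor labels, one
#'   per motif column; defaults to the motif ids.
#' @return A [BindingCountMatrix-class] object.
#' @examples
#' m <- matrix(c(0L, 1L, 2L), ncol = 1,
#'             dimnames = list(c("g1", "g2", "g3"), "motifA"))
#' BindingCountMatrix(m)
#' @export
BindingCountMatrix <- function(counts, factorNames = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.numeric(counts) && any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  new("BindingCountMatrix", counts = counts,
      factorNames = as.character(factorNames))
}

#' Named collection of gene sets
#'
#' Gene subsets (pathways, GO terms, ...) used by the Wilcoxon rank-sum
#' enrichment companion.  Duplicate members within a set are removed on
#' construction; empty sets are rejected.
#'
#' @slot sets named list of character vectors of member gene ids.
#' @slot descriptions character vector of set descriptions, parallel to
#'   `sets`.
#'
#' @seealso [readGmt()], [wilcoxonEnrichment()].
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) == 0L) return("collection must contain at least one set")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("sets must be uniquely named")
  if (any(vapply(object@sets, length, 0L) == 0L))
    return("member lists must be non-empty")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    return("duplicate members must be removed on construction")
  if (length(object@descriptions) != length(object@sets))
    return("descriptions must be parallel to sets")
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of member gene ids.
#'   Duplicate members within a set are dropped.
#' @param descriptions optional character vector of descriptions, recycled
#'   from `""`.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' GeneSetCollection(list(lipid = c("g1", "g2"), immune = c("g3", "g4")))
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("GeneSetCollection", sets = sets,
      descriptions = as.character(descriptions))
}

#' BASE inference results
#'
#' A `DataFrame` subclass with one row per (motif, direction) test carrying
#' the BASE score delta, the permutation p-value, the FDR-adjusted q-value,
#' and diagnostic flags.  Rows are sorted by p-value within direction.
#'
#' Columns: `motif_id`, `factor_name`, `direction` (`"up"` or `"down"`),
#' `delta`, `p_value`, `q_value`, `n_genes`, `n_permutations`, `flags`.
#'
#' @seealso [runBase()].
#' @export
setClass("BaseResults", contains = "DFrame")
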