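#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionPair", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("geneIds", "DifferentiationProfile", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("geneIds", "BindingCountMatrix", function(x) rownames(x@counts))

#' @rdname accessors
#' @export
setMethod("geneIds", "PromoterRegions", function(x) x@ranges$gene_id)

#' @rdname accessors
#' @export
setMethod("logFoldChange", "DifferentiationProfile", function(x) x@d)

#' @rdname accessors
#' @export
setMethod("dUp", "DifferentiationProfile", function(x) pmax(x@d, 0))

#' @rdname accessors
#' @export
setMethod("dDown", "DifferentiationProfile", function(x) pmax(-x@d, 0))

#' @rdname accessors
#' @export
setMethod("motifId", "MotifPWM", function(x) x@motifId)

#' @rdname accessors
#' @export
setMethod("factorName", "MotifPWM", function(x) x@factorName)

#' @rdname accessors
#' @export
setMethod("pwmMatrix", "MotifPWM", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("isProbability", "MotifPWM", function(x) x@isProbability)

#' @rdname accessors
#' @export
setMethod("motifLength", "MotifPWM", function(x) nrow(x@matrix))

#' @rdname accessors
#' @export
setMethod("countsMatrix", "BindingCountMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("motifIds", "BindingCountMatrix", function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setMethod("factorNames", "BindingCountMatrix", function(x) {
  stats::setNames(x@factorNames, colnames(x@counts))
})

#' @rdname accessors
#' @export
setMethod("promoterRanges", "PromoterRegions", function(x) x@ranges)

#' @rdname accessors
#' @export
setMethod("promoterSeqs", "PromoterRegions", function(x) x@seqs)

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) {
  stats::setNames(x@descriptions, names(x@sets))
})

#' @describeIn accessors number of genes / sets in the container.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname accessors
#' @export
setMethod("length", "PromoterRegions", function(x) length(x@ranges))

#' @rdname accessors
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn accessors dimensions of the gene x motif count matrix.
#' @export
setMethod("dim", "BindingCountMatrix", function(x) dim(x@counts))

setMethod("show", "ExpressionPair", function(object) {
  cat("ExpressionPair with", length(object@geneIds), "genes\n")
  cat("  control abundance range: [",
      format(min(object@e0)), ", ", format(max(object@e0)), "]\n", sep = "")
  cat("  treatment abundance range: [",
      format(min(object@e1)), ", ", format(max(object@e1)), "]\n", sep = "")
})

setMethod("show", "DifferentiationProfile", function(object) {
  d <- object@d
  cat("DifferentiationProfile with", length(d), "genes\n")
  cat(sprintf("  d (ln fold change): median %.3g, range [%.3g, %.3g]\n",
              stats::median(d), min(d), max(d)))
  cat(sprintf("  up-regulated: %d, down-regulated: %d, unchanged: %d\n",
              sum(d > 0), sum(d < 0), sum(d == 0)))
})

setMethod("show", "MotifPWM", function(object) {
  cat("MotifPWM", object@motifId, "(factor:", object@factorName, ")\n")
  cat("  length:", nrow(object@matrix), "bp;",
      if (object@isProbability) "probability" else "count", "matrix\n")
  cat("  consensus:", consensusSequence(object), "\n")
})

setMethod("show", "PromoterRegions", function(object) {
  w <- GenomicRanges::width(object@ranges)
  cat("PromoterRegions with", length(object@ranges), "promoters on",
      length(unique(as.character(GenomicRanges::seqnames(object@ranges)))),
      "sequence(s)\n")
  cat("  widths:", paste(range(w), collapse = "-"), "bp;",
      sum(object@ranges$clipped), "clipped at a boundary\n")
})

setMethod("show", "BindingCountMatrix", function(object) {
  m <- object@counts
  cat("BindingCountMatrix:", nrow(m), "genes x", ncol(m), "motifs\n")
  cat(sprintf("  counts: total %d, max %d, %.1f%% zero\n",
              sum(m), max(m), 100 * mean(m == 0)))
})

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- vapply(object@sets, length, 0L)
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  cat("  set sizes:", paste(range(sizes), collapse = "-"), "genes\n")
})

setMethod("show", "BaseResults", function(object) {
  cat("BaseResults:", nrow(object), "motif-direction tests\n")
  if (nrow(object) > 0) {
    for (dir in unique(object$direction)) {
      sub <- object[object$direction == dir, ]
      cat(sprintf("  %s: %d tests, %d with q <= 0.05; top: %s (p = %.4g)\n",
                  dir, nrow(sub), sum(sub$q_value <= 0.05),
                  sub$motif_id[1L], sub$p_value[1L]))
    }
  }
  invisible(NULL)
})
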