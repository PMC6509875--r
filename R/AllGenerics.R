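#' Accessor generics
#'
#' Small accessor family for the package's S4 containers.  Slot access is
#' never needed by user code.
#'
#' @param x an object of one of the package's classes.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("logFoldChange", function(x) standardGeneric("logFoldChange"))

#' @rdname accessors
#' @export
setGeneric("dUp", function(x) standardGeneric("dUp"))

#' @rdname accessors
#' @export
setGeneric("dDown", function(x) standardGeneric("dDown"))

#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @rdname accessors
#' @export
setGeneric("motifIds", function(x) standardGeneric("motifIds"))

#' @rdname accessors
#' @export
setGeneric("factorName", function(x) standardGeneric("factorName"))

#' @rdname accessors
#' @export
setGeneric("factorNames", function(x) standardGeneric("factorNames"))

#' @rdname accessors
#' @export
setGeneric("pwmMatrix", function(x) standardGeneric("pwmMatrix"))

#' @rdname accessors
#' @export
setGeneric("isProbability", function(x) standardGeneric("isProbability"))

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' @rdname accessors
#' @export
setGeneric("promoterRanges", function(x) standardGeneric("promoterRanges"))

#' @rdname accessors
#' @export
setGeneric("promoterSeqs", function(x) standardGeneric("promoterSeqs"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
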