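#' Read a gene x motif count matrix from TSV
#'
#' Expects a header row whose first column is `gene_id` and remaining
#' columns are motif identifiers; body rows hold non-negative integer
#' counts.  An optional comment line `#factor_names: <tab-separated>`
#' restores the trans-factor labels written by [writeCountMatrix()].
#'
#' @param path path to a TSV file.
#' @return A [BindingCountMatrix-class].
#' @export
readCountMatrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  facLine <- grep("^#factor_names:", lines, value = TRUE)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene_id")
    stop("first column of a count matrix must be 'gene_id'")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  facs <- colnames(m)
  if (length(facLine)) {
    parsed <- strsplit(sub("^#factor_names:\\s*", "", facLine[1L]), "\t")[[1L]]
    if (length(parsed) == ncol(m)) facs <- parsed
  }
  BindingCountMatrix(m, factorNames = facs)
}

#' Write a gene x motif count matrix as TSV
#'
#' @param counts a [BindingCountMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(counts, path) {
  stopifnot(is(counts, "BindingCountMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#factor_names:\t",
                    paste(factorNames(counts), collapse = "\t")), con)
  writeLines(paste(c("gene_id", motifIds(counts)), collapse = "\t"), con)
  m <- countsMatrix(counts)
  body <- apply(cbind(rownames(m), m), 1L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write motif hits as BED-like TSV
#'
#' Gene-relative 0-based half-open coordinates: gene_id, start, end,
#' motif_id, score, strand.
#'
#' @param hits a hit data.frame from [countHits()].
#' @param motifLen motif length in bp (defines the end coordinate).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHitsBed <- function(hits, motifLen, path) {
  bed <- data.frame(gene_id = hits$gene_id, start = hits$offset,
                    end = hits$offset + motifLen, motif_id = hits$motif_id,
                    score = hits$score, strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write BASE results as TSV
#'
#' Columns: motif_id, factor_name, direction, delta, p_value, q_value,
#' n_genes, n_permutations, flags.
#'
#' @param results a [BaseResults-class] (or compatible `DataFrame`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBaseResults <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest next to an output file
#'
#' Records the command, all parameter values, the package version, and the
#' MD5 checksum of every input and output file, so a result can be traced
#' and reproduced exactly.  The manifest is written as
#' `<output>.manifest.json`.
#'
#' @param outputPath the result file the manifest describes.
#' @param command short name of the producing command.
#' @param parameters named list of parameter values (must include the seed
#'   actually used for any stochastic stage).
#' @param inputs named character vector of input file paths.
#' @return The manifest path, invisibly.
#' @export
writeManifest <- function(outputPath, command, parameters, inputs = character()) {
  checksum <- function(p) unname(tools::md5sum(p))
  manifest <- list(
    tool = "baseTFA",
    version = as.character(utils::packageVersion("baseTFA")),
    command = command,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = parameters,
    inputs = lapply(stats::setNames(as.list(inputs), names(inputs)),
                    function(p) list(path = p, md5 = checksum(p))),
    outputs = list(list(path = outputPath, md5 = checksum(outputPath))))
  path <- paste0(outputPath, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
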