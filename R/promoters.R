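#' @importFrom GenomicRanges GRanges seqnames strand width start end mcols
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#'   writeXStringSet subseq
NULL

#' Choose one transcription start site per gene
#'
#' Resolves a gene with several transcripts to a single TSS by taking the
#' 5'-most transcript start: the minimum start coordinate on the + strand,
#' the maximum end coordinate on the - strand.  The choice is deterministic
#' under any reordering of the transcript records.  Coordinates are 0-based
#' half-open; on the - strand the returned coordinate is the half-open end,
#' whose last covered base (`end - 1`) is the TSS base.
#'
#' @param starts,ends integer vectors of transcript coordinates (0-based
#'   half-open), one element per transcript of the gene.
#' @param strands character vector of `"+"`/`"-"`, one per transcript.
#' @return A list with `tss` (the 5'-most coordinate) and `strand`, or
#'   `NULL` (with a warning) when the transcripts disagree on strand.
#' @examples
#' chooseTss(c(100, 150), c(500, 600), c("+", "+"))$tss   # 100
#' chooseTss(c(10, 20), c(300, 280), c("-", "-"))$tss     # 300
#' @export
chooseTss <- function(starts, ends, strands) {
  stopifnot(length(starts) >= 1L, length(starts) == length(ends),
            length(starts) == length(strands))
  strands <- unique(strands)
  if (length(strands) != 1L || !strands %in% c("+", "-")) {
    warning("transcripts on conflicting or missing strands; gene skipped")
    return(NULL)
  }
  tss <- if (strands == "+") min(starts) else max(ends)
  list(tss = tss, strand = strands)
}

#' Extract promoter sequences around transcription start sites
#'
#' Takes a fixed window around every gene's TSS — by default 1000 bp
#' upstream to 200 bp downstream — and extracts the corresponding genomic
#' sequence.  One promoter is produced per gene, at its 5'-most TSS (see
#' [chooseTss()]).  For a + strand gene with TSS t (0-based) the window is
#' `[t - upstream, t + downstream)`; for a - strand gene with TSS base t it
#' is `[t - downstream + 1, t + upstream + 1)` and the stored sequence is
#' the reverse complement of the reference slice, so every stored sequence
#' reads 5' to 3' relative to transcription.  Windows are clipped at
#' chromosome boundaries (reported via a message and the `clipped` flag).
#' Characters outside ACGT become N and are never matched by the scanner.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#'   Sequence names are truncated at the first whitespace.
#' @param annotation a `GRanges`, or a path to a GFF3/GTF or BED6 file
#'   (dispatched on the file extension).  GFF3/GTF transcripts are grouped
#'   by gene; BED records are taken one per gene with the `name` field as
#'   the gene id.
#' @param upstream,downstream window extent in bp on either side of the
#'   TSS; both >= 0 and their sum >= 1.
#' @return A [PromoterRegions-class].
#' @export
extractPromoters <- function(genome, annotation, upstream = 1000L,
                             downstream = 200L) {
  if (upstream < 0L || downstream < 0L || upstream + downstream < 1L)
    stop("upstream and downstream must be >= 0 and sum to >= 1")
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  tss <- .annotationToTss(annotation)
  if (nrow(tss) == 0L) stop("no usable gene records in the annotation")

  known <- tss$chrom %in% names(genome)
  if (!all(known)) {
    warning("skipping ", sum(!known),
            " gene(s) on chromosomes absent from the FASTA: ",
            paste(utils::head(unique(tss$chrom[!known]), 3L), collapse = ", "))
    tss <- tss[known, , drop = FALSE]
  }
  if (nrow(tss) == 0L) stop("no genes left after chromosome filtering")

  chromLen <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- nrow(tss)
  start0 <- end0 <- integer(n)
  for (i in seq_len(n)) {
    t0 <- tss$tss[i]
    if (tss$strand[i] == "+") {
      start0[i] <- t0 - upstream
      end0[i] <- t0 + downstream
    } else {
      tbase <- t0 - 1L  # TSS base on the minus strand
      start0[i] <- tbase - downstream + 1L
      end0[i] <- tbase + upstream + 1L
    }
  }
  len <- chromLen[tss$chrom]
  clipped <- start0 < 0L | end0 > len
  start0 <- pmax(start0, 0L)
  end0 <- pmin(end0, len)
  if (any(clipped))
    message("extractPromoters: clipped ", sum(clipped),
            " window(s) at chromosome boundaries")
  ok <- end0 > start0
  if (!all(ok)) {
    warning("skipping ", sum(!ok), " gene(s) with empty window after clipping")
    tss <- tss[ok, , drop = FALSE]
    start0 <- start0[ok]; end0 <- end0[ok]; clipped <- clipped[ok]
  }
  if (nrow(tss) == 0L) stop("no promoters could be extracted")

  seqs <- character(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    s <- subseq(genome[[tss$chrom[i]]], start0[i] + 1L, end0[i])
    if (tss$strand[i] == "-") s <- reverseComplement(s)
    seqs[i] <- gsub("[^ACGT]", "N", toupper(as.character(s)))
  }
  gr <- GRanges(tss$chrom, IRanges(start0 + 1L, end0), strand = tss$strand,
                gene_id = tss$gene_id, clipped = unname(clipped))
  dss <- DNAStringSet(stats::setNames(seqs, tss$gene_id))
  new("PromoterRegions", ranges = gr, seqs = dss)
}

## Normalize an annotation (path or GRanges) into a data.frame with one
## row per gene: gene_id, chrom, tss (0-based, see chooseTss), strand.
.annotationToTss <- function(annotation) {
  if (is.character(annotation)) {
    if (!file.exists(annotation)) stop("annotation file not found: ", annotation)
    annotation <- rtracklayer::import(annotation)
  }
  stopifnot(is(annotation, "GRanges"))
  mc <- mcols(annotation)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      tss = integer(), strand = character())

  if ("type" %in% names(mc)) {  # GFF3 / GTF
    type <- as.character(mc$type)
    isTx <- grepl("transcript|RNA", type, ignore.case = TRUE)
    rec <- if (any(isTx)) annotation[isTx] else annotation[type == "gene"]
    if (length(rec) == 0L) return(empty)
    ids <- .geneIdsFromMcols(mcols(rec))
    keep <- !is.na(ids) & nzchar(ids)
    if (!all(keep)) {
      warning("skipping ", sum(!keep), " record(s) without a gene identifier")
      rec <- rec[keep]; ids <- ids[keep]
    }
  } else if ("name" %in% names(mc)) {  # BED
    rec <- annotation
    ids <- as.character(mc$name)
  } else {
    rec <- annotation
    ids <- names(annotation)
    if (is.null(ids)) stop("annotation carries no gene identifiers")
  }

  rows <- list()
  for (g in unique(ids)) {
    sel <- ids == g
    ## convert 1-based closed GRanges to 0-based half-open
    ct <- chooseTss(start(rec)[sel] - 1L, end(rec)[sel],
                    as.character(strand(rec))[sel])
    if (is.null(ct)) next
    chromSel <- unique(as.character(seqnames(rec))[sel])
    if (length(chromSel) != 1L) {
      warning("gene '", g, "' spans multiple chromosomes; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, chrom = chromSel, tss = ct$tss, strand = ct$strand)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

.geneIdsFromMcols <- function(mc) {
  n <- nrow(mc)
  ids <- rep(NA_character_, n)
  if ("gene_id" %in% names(mc))
    ids <- as.character(mc$gene_id)
  if ("Parent" %in% names(mc)) {
    par <- vapply(as.list(mc$Parent),
                  function(x) if (length(x)) as.character(x)[1L] else NA_character_,
                  "")
    ids[is.na(ids)] <- par[is.na(ids)]
  }
  if ("ID" %in% names(mc))
    ids[is.na(ids)] <- as.character(mc$ID)[is.na(ids)]
  ids
}

#' Write extracted promoters as FASTA
#'
#' Headers are the gene identifiers; sequences are the stored
#' transcription-oriented promoter sequences.
#'
#' @param promoters a [PromoterRegions-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePromoterFasta <- function(promoters, path) {
  stopifnot(is(promoters, "PromoterRegions"))
  writeXStringSet(promoterSeqs(promoters), filepath = path)
  invisible(path)
}

#' Write promoter regions as BED6
#'
#' Emits 0-based half-open records: chrom, start, end, gene id, score 0,
#' strand.
#'
#' @inheritParams writePromoterFasta
#' @return `path`, invisibly.
#' @export
writePromoterBed <- function(promoters, path) {
  stopifnot(is(promoters, "PromoterRegions"))
  gr <- promoterRanges(promoters)
  bed <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    name = gr$gene_id, score = 0L,
                    strand = as.character(strand(gr)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
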