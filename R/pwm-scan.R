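#' Information-weighted matrix similarity score of one window
#'
#' Scores a nucleotide window of length L against a PWM with the
#' MATCH-style matrix similarity score
#' `MSS = (Current - Min) / (Max - Min)`, where
#' `Current = sum_pos I(pos) * f(pos, base)`, Max and Min substitute the
#' row-wise maximal and minimal frequencies, and
#' `I(pos) = sum_b f(pos, b) * ln(4 f(pos, b))` is the positional
#' information weight (zero for a uniform position, ln 4 for a fixed one).
#' The score is 1 exactly on the consensus and 0 on the anti-consensus.
#' A window containing any N scores 0.  A fully degenerate motif (every
#' position uniform, so Max equals Min) scores 0 everywhere and raises a
#' warning, since such a motif carries no information.
#'
#' Count PWMs are normalized internally (pseudocount 0.5) before scoring.
#'
#' @param pwm a [MotifPWM-class].
#' @param window a character string of length equal to the motif length.
#' @return A similarity score in \[0, 1\].
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01,
#'               0.01, 0.97, 0.01, 0.01), nrow = 2, byrow = TRUE)
#' pwm <- MotifPWM("toy", m)
#' scoreWindow(pwm, "AC")   # 1 (consensus)
#' @export
scoreWindow <- function(pwm, window) {
  stopifnot(is(pwm, "MotifPWM"))
  window <- as.character(window)
  if (nchar(window) != motifLength(pwm))
    stop("window length ", nchar(window), " does not match motif length ",
         motifLength(pwm))
  .scanScores(pwm, window)
}

#' Normalize a count PWM to probabilities
#'
#' Adds `pseudocount` to every cell and renormalizes each position row to
#' sum to 1.  Probability matrices are returned unchanged.
#'
#' @param pwm a [MotifPWM-class].
#' @param pseudocount value added per cell before normalization.
#' @return A probability [MotifPWM-class].
#' @export
normalizePWM <- function(pwm, pseudocount = 0.5) {
  stopifnot(is(pwm, "MotifPWM"))
  if (isProbability(pwm)) return(pwm)
  m <- pwm@matrix + pseudocount
  MotifPWM(motifId(pwm), m / rowSums(m), factorName(pwm),
           isProbability = TRUE)
}

## Score every window of `seq` (one strand) against the PWM.  Returns a
## numeric vector of length nchar(seq) - L + 1 (empty when the sequence is
## shorter than the motif).  Vectorized across offsets: one pass per motif
## position.
.scanScores <- function(pwm, seq) {
  pwm <- normalizePWM(pwm)
  M <- unname(pwm@matrix)
  L <- nrow(M)
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T"))
  nWin <- length(codes) - L + 1L
  if (nWin < 1L) return(numeric())
  iw <- rowSums(ifelse(M > 0, M * log(4 * M), 0))
  maxS <- sum(iw * apply(M, 1L, max))
  minS <- sum(iw * apply(M, 1L, min))
  if (maxS - minS <= 1e-12) {
    warning("degenerate motif '", motifId(pwm),
            "' (no informative position); all windows score 0")
    return(numeric(nWin))
  }
  cur <- numeric(nWin)
  hasN <- logical(nWin)
  off <- seq_len(nWin) - 1L
  for (p in seq_len(L)) {
    cp <- codes[off + p]
    nas <- is.na(cp)
    hasN <- hasN | nas
    cp[nas] <- 1L
    cur <- cur + iw[p] * M[p, ][cp]
  }
  scores <- (cur - minS) / (maxS - minS)
  scores[hasN] <- 0
  scores
}

#' Count motif occurrences in a promoter sequence
#'
#' Slides the PWM across every offset of the promoter sequence and of its
#' reverse complement, and counts windows whose matrix similarity score
#' (see [scoreWindow()]) reaches `threshold`.  Both strands are always
#' scanned, and for palindromic motifs double hits are kept: tau is a hit
#' count, each hit being one candidate Bernoulli binding trial under the
#' binding model.  Hits are reported with 0-based offsets on the promoter
#' sequence, in ascending offset order with + before - at equal offset.
#'
#' @param pwm a [MotifPWM-class].
#' @param promoter a character string, a [Biostrings::DNAString], or a
#'   single-gene [PromoterRegions-class].
#' @param threshold minimal similarity score in \[0, 1\] (default 0.85).
#' @param geneId gene identifier recorded in the hit table (taken from a
#'   `PromoterRegions` input automatically).
#' @return A list with `tau` (integer hit count) and `hits` (a data.frame
#'   with columns gene_id, motif_id, offset, strand, score).  A sequence
#'   shorter than the motif yields tau = 0.
#' @examples
#' m <- matrix(rep(c(0.97, 0.01, 0.01, 0.01), 4)[1:16], 4, 4, byrow = TRUE)
#' pwm <- MotifPWM("polyA", m)
#' countHits(pwm, "AAAATTTT", threshold = 0.95)$tau   # 1 forward + 1 reverse
#' @export
countHits <- function(pwm, promoter, threshold = 0.85, geneId = NA_character_) {
  stopifnot(is(pwm, "MotifPWM"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (is(promoter, "PromoterRegions")) {
    if (length(promoter) != 1L)
      stop("pass a single-gene PromoterRegions (subset first)")
    geneId <- geneIds(promoter)
    promoter <- as.character(promoterSeqs(promoter)[[1L]])
  } else if (is(promoter, "DNAString")) {
    promoter <- as.character(promoter)
  }
  promoter <- toupper(as.character(promoter))
  L <- motifLength(pwm)
  emptyHits <- data.frame(gene_id = character(), motif_id = character(),
                          offset = integer(), strand = character(),
                          score = numeric())
  if (nchar(promoter) < L) return(list(tau = 0L, hits = emptyHits))
  fw <- .scanScores(pwm, promoter)
  rcSeq <- as.character(reverseComplement(DNAStringSet(promoter))[[1L]])
  rv <- .scanScores(pwm, rcSeq)
  len <- nchar(promoter)
  hitF <- which(fw >= threshold)
  hitR <- which(rv >= threshold)
  hits <- rbind(
    if (length(hitF)) data.frame(gene_id = geneId, motif_id = motifId(pwm),
                                 offset = hitF - 1L, strand = "+",
                                 score = fw[hitF]),
    if (length(hitR)) data.frame(gene_id = geneId, motif_id = motifId(pwm),
                                 offset = len - L - (hitR - 1L), strand = "-",
                                 score = rv[hitR]))
  if (is.null(hits)) hits <- emptyHits
  hits <- hits[order(hits$offset, match(hits$strand, c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(tau = length(hitF) + length(hitR), hits = hits)
}

#' Build the gene x motif occurrence count matrix
#'
#' Applies [countHits()] to every (gene, motif) pair and assembles the
#' result into a [BindingCountMatrix-class].  By default the matrix covers
#' exactly the promoter genes; `extraGenes` appends explicit all-zero rows
#' for genes without a promoter, should a downstream join need them.
#'
#' @param pwms a list of [MotifPWM-class] objects.
#' @param promoters a [PromoterRegions-class].
#' @param threshold minimal similarity score (see [countHits()]).
#' @param extraGenes optional character vector of additional gene ids to
#'   include as zero rows.
#' @return A [BindingCountMatrix-class].
#' @export
buildCountMatrix <- function(pwms, promoters, threshold = 0.85,
                             extraGenes = NULL) {
  if (is(pwms, "MotifPWM")) pwms <- list(pwms)
  stopifnot(length(pwms) >= 1L, is(promoters, "PromoterRegions"))
  genes <- geneIds(promoters)
  if (anyDuplicated(genes)) stop("duplicate gene ids among promoters")
  seqs <- as.character(promoterSeqs(promoters))
  motifs <- unname(vapply(pwms, motifId, ""))
  counts <- matrix(0L, length(genes), length(pwms),
                   dimnames = list(genes, motifs))
  for (m in seq_along(pwms)) {
    for (i in seq_along(genes)) {
      counts[i, m] <- countHits(pwms[[m]], seqs[i], threshold,
                                geneId = genes[i])$tau
    }
  }
  if (!is.null(extraGenes)) {
    extraGenes <- setdiff(unique(extraGenes), genes)
    if (length(extraGenes)) {
      zero <- matrix(0L, length(extraGenes), length(pwms),
                     dimnames = list(extraGenes, motifs))
      counts <- rbind(counts, zero)
    }
  }
  BindingCountMatrix(counts,
                     factorNames = unname(vapply(pwms, factorName, "")))
}

#' Calibrate a scan threshold against a background false-positive rate
#'
#' The per-motif score cutoffs shipped with commercial motif scanners are
#' not redistributable, so this utility estimates a threshold empirically:
#' it scores a long i.i.d. uniform-ACGT background sequence and returns the
#' score quantile at which the per-window false-positive rate equals
#' `targetFpr`.
#'
#' @param pwm a [MotifPWM-class].
#' @param targetFpr desired probability that a random background window
#'   scores at or above the returned threshold.
#' @param nWindows number of background windows to score.
#' @param seed integer seed for background generation.
#' @return A threshold in \[0, 1\].
#' @export
calibrateThreshold <- function(pwm, targetFpr = 0.001, nWindows = 100000L,
                               seed = 1L) {
  stopifnot(is(pwm, "MotifPWM"), targetFpr > 0, targetFpr < 1)
  set.seed(seed)
  L <- motifLength(pwm)
  bg <- paste(sample(c("A", "C", "G", "T"), nWindows + L - 1L,
                     replace = TRUE), collapse = "")
  scores <- .scanScores(pwm, bg)
  unname(stats::quantile(scores, probs = 1 - targetFpr, type = 8))
}
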