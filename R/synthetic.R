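#' Simulation configuration
#'
#' Bundles the parameters of the expression/count simulators.  Defaults
#' describe the calibration conditions used throughout the package's tests:
#' 500 genes, 50 motifs, planted effect size 3, unit-mean Poisson
#' background counts and unit-variance log fold changes.
#'
#' @slot nGenes number of genes (>= 2).
#' @slot nMotifs number of motifs.
#' @slot effectSize coupling strength between up-differentiation and the
#'   planted motif's counts (dimensionless multiplier on the Poisson mean).
#' @slot backgroundCountMean Poisson mean of null motif counts (> 0).
#' @slot noiseSd standard deviation of the log fold changes.
#' @slot dispersion negative-binomial size parameter; `NA` (default) keeps
#'   pure Poisson counts, a finite value adds overdispersion.
#' @slot dDistribution `"normal"` (default) draws signed log fold changes,
#'   so roughly half the genes differentiate in each direction;
#'   `"half-normal"` draws d = |Normal(0, noiseSd)|, an all-up profile used
#'   for directional power studies.
#' @slot seed integer seed; a fixed seed makes all outputs bit-reproducible.
#'
#' @seealso [simulationConfig()], [simulateNull()], [simulateAlternative()].
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", nMotifs = "integer",
                 effectSize = "numeric", backgroundCountMean = "numeric",
                 noiseSd = "numeric", dispersion = "numeric",
                 dDistribution = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nGenes < 2L) return("nGenes must be >= 2")
  if (object@nMotifs < 1L) return("nMotifs must be >= 1")
  if (object@backgroundCountMean <= 0) return("backgroundCountMean must be > 0")
  if (object@noiseSd <= 0) return("noiseSd must be > 0")
  if (!is.na(object@dispersion) && object@dispersion <= 0)
    return("dispersion must be > 0 when set")
  if (!object@dDistribution %in% c("normal", "half-normal"))
    return("dDistribution must be 'normal' or 'half-normal'")
  TRUE
})

#' @rdname SimulationConfig-class
#' @param nGenes,nMotifs,effectSize,backgroundCountMean,noiseSd,dispersion,dDistribution,seed
#'   see the class slots.
#' @return A `SimulationConfig`.
#' @examples
#' simulationConfig(nGenes = 100, nMotifs = 10, seed = 7)
#' @export
simulationConfig <- function(nGenes = 500L, nMotifs = 50L, effectSize = 3,
                             backgroundCountMean = 1, noiseSd = 1,
                             dispersion = NA_real_,
                             dDistribution = c("normal", "half-normal"),
                             seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      nMotifs = as.integer(nMotifs), effectSize = as.numeric(effectSize),
      backgroundCountMean = as.numeric(backgroundCountMean),
      noiseSd = as.numeric(noiseSd), dispersion = as.numeric(dispersion),
      dDistribution = match.arg(dDistribution), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes x", object@nMotifs,
      "motifs\n")
  cat("  effectSize:", object@effectSize,
      " backgroundCountMean:", object@backgroundCountMean,
      " noiseSd:", object@noiseSd, "\n")
  cat("  counts:", if (is.na(object@dispersion)) "Poisson"
      else paste0("negative binomial (size ", object@dispersion, ")"),
      " seed:", object@seed, "\n")
})

.simCounts <- function(n, lambda, dispersion) {
  if (is.na(dispersion)) stats::rpois(n, lambda)
  else stats::rnbinom(n, size = dispersion, mu = lambda)
}

#' Simulate an exchangeable null ensemble
#'
#' Draws log fold changes d i.i.d. Normal(0, noiseSd) and motif counts
#' i.i.d. Poisson(backgroundCountMean) — or negative binomial when a
#' dispersion is configured — independently of d.  This realizes the
#' exchangeability null of the permutation test: no motif carries
#' information about the differentiation.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with `profile` (a [DifferentiationProfile-class]) and
#'   `counts` (a [BindingCountMatrix-class]).
#' @examples
#' sim <- simulateNull(simulationConfig(nGenes = 20, nMotifs = 3))
#' @export
simulateNull <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  .simulate(config, plantedMotifIndex = NA_integer_)
}

#' Simulate a planted-regulator alternative
#'
#' Identical to [simulateNull()] except that one motif's counts are coupled
#' to the up-differentiation: for the planted motif,
#' `tau_i ~ Poisson(backgroundCountMean * (1 + effectSize * d+_i / max d+))`.
#' The coupling enters through d+ (not the signed d), so the planted signal
#' is specifically directional: an effective up-regulator concentrates its
#' binding weight on the most up-differentiated genes, with no effect on
#' the down side.  `effectSize = 0` reproduces the null draw bit-exactly
#' under the same seed.
#'
#' @param config a [SimulationConfig-class].
#' @param plantedMotifIndex 1-based column index of the planted motif.
#' @return As [simulateNull()].
#' @export
simulateAlternative <- function(config, plantedMotifIndex = 1L) {
  stopifnot(is(config, "SimulationConfig"))
  plantedMotifIndex <- as.integer(plantedMotifIndex)
  if (plantedMotifIndex < 1L || plantedMotifIndex > config@nMotifs)
    stop("plantedMotifIndex must lie in [1, nMotifs]")
  .simulate(config, plantedMotifIndex)
}

.simulate <- function(config, plantedMotifIndex) {
  set.seed(config@seed)
  n <- config@nGenes
  m <- config@nMotifs
  d <- stats::rnorm(n, 0, config@noiseSd)
  if (config@dDistribution == "half-normal") d <- abs(d)
  genes <- sprintf("g%05d", seq_len(n))
  motifs <- sprintf("motif_%03d", seq_len(m))
  counts <- matrix(0L, n, m, dimnames = list(genes, motifs))
  dUp <- pmax(d, 0)
  maxUp <- max(dUp)
  for (j in seq_len(m)) {
    lambda <- config@backgroundCountMean
    if (!is.na(plantedMotifIndex) && j == plantedMotifIndex && maxUp > 0)
      lambda <- lambda * (1 + config@effectSize * dUp / maxUp)
    counts[, j] <- .simCounts(n, lambda, config@dispersion)
  }
  list(profile = DifferentiationProfile(genes, d),
       counts = BindingCountMatrix(counts))
}

#' Generate a toy genome with planted motif occurrences
#'
#' Builds a single synthetic chromosome carrying `nGenes` gene models on
#' alternating strands, with i.i.d. uniform-ACGT background sequence and
#' exact consensus copies of randomly generated, information-rich,
#' non-palindromic motifs planted at known non-overlapping offsets inside
#' each gene's promoter window (`upstream` bp before to `downstream` bp
#' after the TSS, on the transcribed strand).  The return value includes
#' the ground-truth plant table, so end-to-end promoter extraction and
#' motif counting can be verified exactly.
#'
#' Motif consensus strings are drawn uniformly and redrawn until
#' non-palindromic; their PWMs put probability ~0.985 on the consensus base
#' per position (counts 97 with pseudocount 0.5), so an exact copy scores 1
#' while any single mismatch falls below a 0.95 scan threshold.
#'
#' @param nGenes number of genes.
#' @param plants data.frame with columns `gene` (1-based gene index),
#'   `motif` (1-based motif index) and `copies`; defaults to one copy of
#'   motif 1 per gene.
#' @param nMotifs number of motifs to generate (default: largest index in
#'   `plants`).
#' @param motifLength consensus length in bp.
#' @param upstream,downstream promoter window extent (bp around the TSS).
#' @param clipFirstGene place gene 1 so close to the chromosome start that
#'   its upstream window is clipped (for boundary testing).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A list with `fasta`, `gff`, `pwm` (character vectors of file
#'   lines), `truth` (data.frame gene_id, motif_id, copies), and
#'   `consensus` (character vector of motif consensus strings).
#' @examples
#' toy <- makeToyGenome(nGenes = 2, seed = 1)
#' toy$truth
#' @export
makeToyGenome <- function(nGenes = 6L, plants = NULL, nMotifs = NULL,
                          motifLength = 10L, upstream = 1000L,
                          downstream = 200L, clipFirstGene = FALSE,
                          seed = 1L) {
  stopifnot(nGenes >= 1L, motifLength >= 4L)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  if (is.null(plants))
    plants <- data.frame(gene = seq_len(nGenes), motif = 1L, copies = 1L)
  stopifnot(all(c("gene", "motif", "copies") %in% names(plants)))
  if (is.null(nMotifs)) nMotifs <- max(plants$motif, 1L)
  if (any(plants$gene < 1L | plants$gene > nGenes))
    stop("plant table references a gene outside 1..nGenes")
  if (any(plants$motif < 1L | plants$motif > nMotifs))
    stop("plant table references a motif outside 1..nMotifs")

  ## non-palindromic, mutually distinct consensus strings
  consensus <- character(nMotifs)
  for (j in seq_len(nMotifs)) {
    repeat {
      cs <- paste(sample(bases, motifLength, replace = TRUE), collapse = "")
      rc <- as.character(reverseComplement(DNAStringSet(cs))[[1L]])
      if (cs != rc && !cs %in% consensus) break
    }
    consensus[j] <- cs
  }
  pwmLines <- unlist(lapply(seq_len(nMotifs), function(j) {
    chars <- strsplit(consensus[j], "")[[1L]]
    rows <- vapply(bases, function(b) {
      paste0(b, " [ ", paste(ifelse(chars == b, 97L, 1L), collapse = " "),
             " ]")
    }, "")
    c(paste0(">toy_motif_", j, " toyTF_", j), unname(rows))
  }), use.names = FALSE)

  window <- upstream + downstream
  spacing <- 2L * (window + 100L)
  geneBody <- 500L
  tssList <- integer(nGenes)
  strands <- rep(c("+", "-"), length.out = nGenes)
  for (i in seq_len(nGenes)) {
    tssList[i] <- (window + 200L) + (i - 1L) * spacing
  }
  if (clipFirstGene) {
    strands[1L] <- "+"
    tssList[1L] <- max(upstream %/% 3L, motifLength + 1L)
  }
  chromLen <- tssList[nGenes] + window + geneBody + 200L
  chrom <- sample(bases, chromLen, replace = TRUE)

  ## per-gene promoter windows (0-based half-open, clipped), promoter-sense
  truthRows <- list()
  geneIds <- sprintf("toygene_%02d", seq_len(nGenes))
  for (i in seq_len(nGenes)) {
    t0 <- tssList[i]
    if (strands[i] == "+") {
      ws <- t0 - upstream; we <- t0 + downstream
    } else {
      ws <- t0 - downstream + 1L; we <- t0 + upstream + 1L
    }
    ws <- max(ws, 0L); we <- min(we, chromLen)
    wlen <- we - ws
    pl <- plants[plants$gene == i, , drop = FALSE]
    offsets <- integer(0)
    for (r in seq_len(nrow(pl))) {
      mj <- pl$motif[r]
      for (cp in seq_len(pl$copies[r])) {
        if ((length(offsets) + 1L) * motifLength > wlen)
          stop("plants do not fit in the promoter window of gene ", i)
        placed <- FALSE
        for (try in seq_len(500L)) {
          o <- sample.int(wlen - motifLength + 1L, 1L) - 1L
          if (!any(abs(o - offsets) < motifLength)) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place plants without overlap in gene ", i)
        offsets <- c(offsets, o)
        chars <- strsplit(consensus[mj], "")[[1L]]
        if (strands[i] == "+") {
          idx <- ws + o + seq_len(motifLength)  # 1-based genome positions
          chrom[idx] <- chars
        } else {
          ## promoter offset o counts from the window's 5' end, which is
          ## the genomic right edge; write the reverse complement
          rcChars <- rev(c(T = "A", G = "C", C = "G", A = "T")[chars])
          idx <- we - o - motifLength + seq_len(motifLength)
          chrom[idx] <- rcChars
        }
      }
    }
    planted <- pl[pl$copies > 0L, , drop = FALSE]
    if (nrow(planted))
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        gene_id = geneIds[i], motif_id = paste0("toy_motif_", planted$motif),
        copies = planted$copies, strand = strands[i])
  }

  ## GFF3 (1-based closed): gene + mRNA records per gene
  gffRows <- character()
  for (i in seq_len(nGenes)) {
    t0 <- tssList[i]
    if (strands[i] == "+") {
      gs <- t0 + 1L; ge <- min(t0 + geneBody, chromLen)
    } else {
      gs <- max(t0 + 1L - geneBody + 1L, 1L); ge <- t0 + 1L
    }
    attrsG <- sprintf("ID=%s;gene_id=%s", geneIds[i], geneIds[i])
    attrsT <- sprintf("ID=%s.t1;Parent=%s;gene_id=%s", geneIds[i],
                      geneIds[i], geneIds[i])
    gffRows <- c(gffRows,
      paste("toychr", "toy", "gene", gs, ge, ".", strands[i], ".", attrsG,
            sep = "\t"),
      paste("toychr", "toy", "mRNA", gs, ge, ".", strands[i], ".", attrsT,
            sep = "\t"))
  }
  truth <- if (length(truthRows)) do.call(rbind, truthRows)
    else data.frame(gene_id = character(), motif_id = character(),
                    copies = integer(), strand = character())
  list(fasta = c(">toychr", paste(chrom, collapse = "")),
       gff = c("##gff-version 3", gffRows),
       pwm = pwmLines, truth = truth, consensus = consensus)
}
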