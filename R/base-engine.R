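#' Binding-weighted and unweighted cumulative differentiation functions
#'
#' The heart of the BASE statistic.  Genes are sorted by their directional
#' differentiation `dDir` (d+ for up-regulation, d- for down-regulation) in
#' descending order with stable ties (original index order).  Two
#' cumulative fractions are then formed along that order:
#' `f0(i) = sum_{j<=i} d_sorted(j) / sum_j d_sorted(j)` (the unweighted
#' reference) and `f1(i) = sum_{j<=i} d_sorted(j) * b_sorted(j) / total`
#' (the binding-weighted one).  Both are nondecreasing and reach 1 at i =
#' N.  If the weight vector `b` is constant, the weights cancel and f1
#' equals f0 elementwise.
#'
#' Both cumulative functions use the directional component `dDir`; this
#' keeps f0 monotone and treats the up and down directions symmetrically.
#' For users who want the reference function built on a different vector
#' (e.g. the raw signed d), `f0Source` overrides the numerator of f0.
#'
#' @param dDir non-negative numeric vector: the directional differentiation
#'   component (d+ or d-) per gene.
#' @param b non-negative numeric vector of binding strengths (typically the
#'   motif counts tau), parallel to `dDir`.
#' @param f0Source optional numeric vector used instead of `dDir` inside
#'   f0 (sorted by the same permutation); the default `NULL` uses `dDir`.
#' @return A list with components `f0`, `f1` (numeric, length N) and
#'   `order` (the sorting permutation of the input indices).
#' @examples
#' baseCdfs(c(3, 2, 1), b = c(1, 0, 0))  # f0 = (1/2, 5/6, 1), f1 = (1, 1, 1)
#' @export
baseCdfs <- function(dDir, b, f0Source = NULL) {
  n <- length(dDir)
  if (length(b) != n) stop("dDir and b must have equal length")
  if (any(!is.finite(dDir)) || any(dDir < 0))
    stop("dDir must be finite and non-negative")
  if (any(!is.finite(b)) || any(b < 0))
    stop("b must be finite and non-negative")
  ord <- order(dDir, decreasing = TRUE, method = "radix")
  ds <- dDir[ord]
  totD <- sum(ds)
  if (totD <= 0) stop("no differentiation in this direction")
  w <- ds * b[ord]
  totW <- sum(w)
  if (totW <= 0) stop("motif has no weight on differentiated genes")
  if (is.null(f0Source)) {
    f0 <- cumsum(ds) / totD
  } else {
    s <- f0Source[ord]
    f0 <- cumsum(s) / sum(s)
  }
  list(f0 = f0, f1 = cumsum(w) / totW, order = ord)
}

#' BASE score: maximum gap between the two cumulative functions
#'
#' `delta = max_i [f1(i) - f0(i)]`.  A strongly positive delta means the
#' binding weight of the motif is concentrated on the most differentiated
#' genes.  The score always lies in \[-1, 1\] and is scale-free in both the
#' differentiation and the binding vector.
#'
#' @param f0,f1 cumulative fraction vectors from [baseCdfs()].
#' @return The BASE score, a single number in \[-1, 1\].
#' @examples
#' cdfs <- baseCdfs(c(3, 2, 1), b = c(1, 0, 0))
#' baseScore(cdfs$f0, cdfs$f1)   # 1/2
#' @export
baseScore <- function(f0, f1) {
  if (length(f0) != length(f1)) stop("f0 and f1 must have equal length")
  max(f1 - f0)
}

#' Permutation p-value of the BASE score
#'
#' Computes the observed score delta for the true gene-to-weight pairing,
#' then draws `K` uniformly random permutations of the weight vector `b`,
#' recomputes the score for each, and reports `p = #\{delta* > delta\} / K`
#' (strict inequality).  With `exact = TRUE` and N <= 8 the full set of N!
#' pairings is enumerated instead of sampled, giving the exact permutation
#' p-value.
#'
#' @inheritParams baseCdfs
#' @param K number of random permutations (ignored in exact mode).
#' @param seed optional integer seed for the permutation draws.
#' @param exact enumerate all N! pairings (N <= 8) instead of sampling.
#' @param addOne use the add-one estimator p = (1 + #\{delta* > delta\}) /
#'   (1 + K), which cannot return 0; off by default.
#' @return A list with `p` (the p-value), `delta` (the observed score),
#'   `nullScores` (numeric vector of delta* values), and `flags`
#'   (character vector of diagnostic flags, possibly empty).
#' @examples
#' permutationPvalue(c(3, 2, 1), b = c(0, 1, 0), exact = TRUE)$p   # 2/6
#' @export
permutationPvalue <- function(dDir, b, K = 10000L, seed = NULL,
                              exact = FALSE, addOne = FALSE,
                              f0Source = NULL) {
  flags <- character()
  if (stats::var(b) == 0) flags <- c(flags, "constant_b")
  cdfs <- baseCdfs(dDir, b, f0Source = f0Source)
  delta <- baseScore(cdfs$f0, cdfs$f1)
  ds <- dDir[cdfs$order]
  f0 <- cdfs$f0
  if (exact) {
    n <- length(dDir)
    if (n > 8L) stop("exact mode enumerates N! pairings; limited to N <= 8")
    perms <- .allPermutations(n)
    bs <- b[cdfs$order]
    nullScores <- vapply(perms, function(idx) {
      w <- ds * bs[idx]
      tot <- sum(w)
      if (tot <= 0) return(0)
      max(cumsum(w) / tot - f0)
    }, 0)
    K <- length(nullScores)
  } else {
    if (K < 1L) stop("K must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    nullScores <- .permNullScores(ds, b, f0, as.integer(K))
  }
  exceed <- sum(nullScores > delta)
  p <- if (addOne) (1 + exceed) / (1 + K) else exceed / K
  list(p = p, delta = delta, nullScores = nullScores, flags = flags)
}

## All permutations of 1..n, as a list of integer vectors (n <= 8).
.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

## Deterministic per-test seed derived from the master seed, the motif
## column index and the direction, kept inside 32-bit integer range.
.deriveSeed <- function(seed, motifIndex, dirCode) {
  as.integer((as.numeric(seed) * 48271 + motifIndex * 16807 +
              dirCode * 69621) %% 2147483647)
}

#' Run the full BASE inference over a motif count matrix
#'
#' For every motif, tests both regulatory directions: "up" pairs the
#' up-differentiation d+ with the motif's binding weights, "down" uses d-.
#' Each test reports the BASE score delta, a permutation p-value with `K`
#' draws (seeded reproducibly per motif and direction from the master
#' seed), and an FDR-adjusted q-value computed within each direction's
#' family.  Genes present in only one of the two inputs are dropped (inner
#' join) with a message; zero-filling absent genes would manufacture
#' signal.
#'
#' Degenerate situations are flagged rather than erroring so the ranking
#' stays total: a direction with no differentiation at all
#' (`no_differentiation`), a motif with zero weight on every differentiated
#' gene (`zero_weight`; reported as delta = 0, p = 1), and a constant
#' weight vector (`constant_b`; delta and all null scores are 0, so the
#' strict-inequality p is 0).
#'
#' With `rankBased = TRUE` both the directional differentiation and the
#' binding weights are replaced by their ranks (average ranks for ties, so
#' the zeros share the average of their positions) before scoring; this
#' trades power for robustness and makes the result invariant under
#' strictly increasing transforms of d.
#'
#' @param profile a [DifferentiationProfile-class].
#' @param counts a [BindingCountMatrix-class], or a numeric gene x motif
#'   matrix of user-supplied real-valued binding strengths (rownames =
#'   genes).
#' @param K permutations per test (default 10000).
#' @param seed master integer seed; per-test seeds are derived from it.
#' @param rankBased replace d and b by their ranks before scoring.
#' @param fdrMethod `"bh"` (Benjamini-Hochberg, default) or `"storey"`.
#' @param exact use exhaustive enumeration instead of sampling (N <= 8).
#' @param addOne passed to [permutationPvalue()].
#' @param literalF0 build f0 from the raw signed d instead of the
#'   directional component (not recommended: f0 is then non-monotone over
#'   genes differentiated in the other direction).
#' @return A [BaseResults-class] (a `DataFrame`) with one row per (motif,
#'   direction), sorted by p-value within direction.
#' @examples
#' set.seed(1)
#' pr <- DifferentiationProfile(paste0("g", 1:50), rnorm(50))
#' cm <- BindingCountMatrix(matrix(rpois(100, 1), 50, 2,
#'         dimnames = list(paste0("g", 1:50), c("m1", "m2"))))
#' runBase(pr, cm, K = 100, seed = 1)
#' @export
runBase <- function(profile, counts, K = 10000L, seed = 1L,
                    rankBased = FALSE, fdrMethod = c("bh", "storey"),
                    exact = FALSE, addOne = FALSE, literalF0 = FALSE) {
  stopifnot(is(profile, "DifferentiationProfile"))
  fdrMethod <- match.arg(fdrMethod)
  if (is(counts, "BindingCountMatrix")) {
    bmat <- countsToBinding(counts)
    facs <- factorNames(counts)
  } else if (is.matrix(counts) && is.numeric(counts)) {
    bmat <- counts
    if (is.null(rownames(bmat)) || is.null(colnames(bmat)))
      stop("a binding matrix must carry gene and motif dimnames")
    facs <- stats::setNames(colnames(bmat), colnames(bmat))
  } else {
    stop("counts must be a BindingCountMatrix or a numeric matrix")
  }
  common <- intersect(geneIds(profile), rownames(bmat))
  if (length(common) == 0L)
    stop("no genes shared between the profile and the count matrix")
  dropped <- length(geneIds(profile)) - length(common)
  if (dropped > 0L)
    message("runBase: dropped ", dropped,
            " profile gene(s) absent from the count matrix")
  d <- logFoldChange(profile)[match(common, geneIds(profile))]
  bmat <- bmat[common, , drop = FALSE]
  motifs <- colnames(bmat)
  dirs <- list(up = pmax(d, 0), down = pmax(-d, 0))

  rows <- vector("list", 2L * length(motifs))
  k <- 0L
  for (dirIdx in seq_along(dirs)) {
    dirName <- names(dirs)[dirIdx]
    dDir <- dirs[[dirIdx]]
    dirOk <- sum(dDir) > 0
    dUse <- if (rankBased) rank(dDir) else dDir
    f0Src <- if (literalF0) d else NULL
    for (m in seq_along(motifs)) {
      k <- k + 1L
      b <- bmat[, m]
      bUse <- if (rankBased) rank(b) else b
      if (!dirOk) {
        rows[[k]] <- list(motifs[m], dirName, 0, 1, NA_integer_,
                          "no_differentiation")
        next
      }
      if (sum(dUse * bUse) <= 0) {
        rows[[k]] <- list(motifs[m], dirName, 0, 1, NA_integer_,
                          "zero_weight")
        next
      }
      pv <- permutationPvalue(dUse, bUse, K = K,
                              seed = .deriveSeed(seed, m, dirIdx),
                              exact = exact, addOne = addOne,
                              f0Source = f0Src)
      rows[[k]] <- list(motifs[m], dirName, pv$delta, pv$p,
                        as.integer(if (exact) length(pv$nullScores) else K),
                        paste(pv$flags, collapse = ";"))
    }
  }
  res <- DataFrame(
    motif_id = vapply(rows, `[[`, "", 1L),
    factor_name = unname(facs[vapply(rows, `[[`, "", 1L)]),
    direction = vapply(rows, `[[`, "", 2L),
    delta = vapply(rows, `[[`, 0, 3L),
    p_value = vapply(rows, `[[`, 0, 4L),
    q_value = NA_real_,
    n_genes = length(common),
    n_permutations = vapply(rows, `[[`, 0L, 5L),
    flags = vapply(rows, `[[`, "", 6L))
  for (dirName in names(dirs)) {
    sel <- res$direction == dirName
    res$q_value[sel] <- adjustFdr(res$p_value[sel], method = fdrMethod)
  }
  ord <- order(match(res$direction, names(dirs)), res$p_value,
               method = "radix")
  res <- res[ord, ]
  rownames(res) <- NULL
  new("BaseResults", res)
}

#' FDR adjustment of permutation p-values
#'
#' `"bh"` applies the Benjamini-Hochberg step-up adjustment (via
#' [stats::p.adjust()]).  `"storey"` computes Storey q-values with the
#' fixed-lambda (0.5) pi0 estimate `pi0 = min(1, #\{p > 0.5\} / (0.5 m))`,
#' enforced monotone from the largest p downwards and floored at the raw
#' p-value.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` (default) or `"storey"`.
#' @return Numeric vector of adjusted values, same length and order as
#'   `p`.
#' @examples
#' adjustFdr(c(0.01, 0.02, 0.03))   # all 0.03
#' @export
adjustFdr <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  m <- length(p)
  lambda <- 0.5
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  ord <- order(p, decreasing = TRUE, method = "radix")
  q <- numeric(m)
  running <- Inf
  for (i in seq_len(m)) {
    idx <- ord[i]
    rank_i <- m - i + 1L
    running <- min(running, pi0 * p[idx] * m / rank_i)
    q[idx] <- running
  }
  pmin(pmax(q, p), 1)
}
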