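#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields set name,
#' description, then member gene ids.  Duplicate members within a set are
#' removed (with a message); empty lines are skipped.
#'
#' @param path path to a GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 0L) < 3L
  if (any(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  ndup <- sum(vapply(members, function(m) length(m) - length(unique(m)), 0L))
  if (ndup > 0L)
    message("readGmt: removed ", ndup, " duplicate member(s)")
  GeneSetCollection(stats::setNames(members, nm), desc)
}

#' Gene-set enrichment by the Wilcoxon rank-sum test
#'
#' Ranks all genes by their signed expression difference d (average ranks
#' for ties) and compares the ranks of genes inside each set against those
#' outside with the two-sample Wilcoxon rank-sum test.  No differential
#' expression cutoff is needed.  Each direction gets its own one-sided
#' p-value: "up" asks whether in-set genes sit at larger d than
#' exchangeability predicts, "down" whether they sit at smaller d.
#'
#' For small sets (fewer than 10 members after intersection) the exact
#' null distribution of the rank-sum statistic is used: the tie-free exact
#' distribution where the ranks are untied, otherwise full enumeration of
#' the \eqn{C(N, n_{in})} membership assignments when that is tractable.
#' Larger sets use the normal approximation with continuity and tie
#' correction.  Sets with fewer than `minSize` members present, or
#' covering all genes (no out-group), are skipped with a message.
#'
#' @param profile a [DifferentiationProfile-class].
#' @param sets a [GeneSetCollection-class].
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @param minSize minimum number of set members present in the profile.
#' @param exactLimit maximum number of membership assignments to enumerate
#'   when ties preclude the closed-form exact distribution.
#' @return A `DataFrame` with columns `set_name`, `direction`, `p_value`,
#'   `n_in_set`, `n_out_set`, `rank_sum_statistic`, sorted by p-value
#'   within direction.
#' @examples
#' pr <- DifferentiationProfile(paste0("g", 1:6), c(6, 5, 1, 2, 3, 4) / 10)
#' gs <- GeneSetCollection(list(top = c("g1", "g2")))
#' wilcoxonEnrichment(pr, gs, "up")   # exact p = 1 / choose(6, 2) = 1/15
#' @export
wilcoxonEnrichment <- function(profile, sets, direction = c("both", "up", "down"),
                               minSize = 2L, exactLimit = 200000) {
  stopifnot(is(profile, "DifferentiationProfile"),
            is(sets, "GeneSetCollection"))
  direction <- match.arg(direction)
  dirs <- if (direction == "both") c("up", "down") else direction
  genes <- geneIds(profile)
  r <- rank(logFoldChange(profile))
  N <- length(genes)
  rows <- list()
  for (nm in names(sets)) {
    inSet <- genes %in% geneSets(sets)[[nm]]
    nIn <- sum(inSet)
    if (nIn < minSize) {
      message("wilcoxonEnrichment: skipping '", nm, "' (", nIn,
              " member(s) present)")
      next
    }
    if (nIn == N) {
      message("wilcoxonEnrichment: skipping '", nm, "' (no out-group)")
      next
    }
    W <- sum(r[inSet])
    ps <- .rankSumPvalues(r, inSet, exactLimit = exactLimit)
    for (dir in dirs) {
      rows[[length(rows) + 1L]] <- list(
        nm, dir, if (dir == "up") ps[["up"]] else ps[["down"]],
        nIn, N - nIn, W)
    }
  }
  if (length(rows) == 0L)
    stop("no testable gene sets after intersection with the profile")
  res <- DataFrame(
    set_name = vapply(rows, `[[`, "", 1L),
    direction = vapply(rows, `[[`, "", 2L),
    p_value = vapply(rows, `[[`, 0, 3L),
    n_in_set = vapply(rows, `[[`, 0L, 4L),
    n_out_set = vapply(rows, `[[`, 0L, 5L),
    rank_sum_statistic = vapply(rows, `[[`, 0, 6L))
  res <- res[order(match(res$direction, c("up", "down")), res$p_value,
                   method = "radix"), ]
  rownames(res) <- NULL
  res
}

## One-sided rank-sum p-values for in-set ranks being large ("up") or
## small ("down").  r: average ranks of all N genes; inSet: logical mask.
.rankSumPvalues <- function(r, inSet, exactLimit = 200000) {
  m <- sum(inSet)
  n <- sum(!inSet)
  W <- sum(r[inSet])
  hasTies <- anyDuplicated(r) > 0L
  if (m < 10L) {
    if (!hasTies) {
      ## ranks are the integers 1..N here, so U is a whole number
      u <- round(W - m * (m + 1) / 2)
      return(c(up = 1 - stats::pwilcox(u - 1, m, n),
               down = stats::pwilcox(u, m, n)))
    }
    if (choose(m + n, m) <= exactLimit) {
      combs <- utils::combn(m + n, m)
      sums <- colSums(matrix(r[combs], nrow = m))
      eps <- 1e-9
      return(c(up = mean(sums >= W - eps), down = mean(sums <= W + eps)))
    }
  }
  ## normal approximation with tie correction and continuity correction
  Ntot <- m + n
  mu <- m * (Ntot + 1) / 2
  tieTab <- table(r)
  tieAdj <- sum(tieTab^3 - tieTab) / (Ntot * (Ntot - 1))
  sigma2 <- m * n / 12 * ((Ntot + 1) - tieAdj)
  sigma <- sqrt(sigma2)
  c(up = stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE),
    down = stats::pnorm((W - mu + 0.5) / sigma))
}

#' Threshold-based Fisher-exact enrichment (secondary mode)
#'
#' The classical enrichment recipe the rank-sum approach improves upon:
#' declare genes with |d| above a user-chosen cutoff differentially
#' expressed, cross-tabulate DE status against set membership, and apply
#' the one-sided Fisher exact test for over-representation.  Provided for
#' comparison; its outcome depends on the arbitrary cutoff.
#'
#' @inheritParams wilcoxonEnrichment
#' @param cutoff absolute log fold change defining differential
#'   expression.
#' @return A `DataFrame` with columns `set_name`, `p_value`, `n_de_in`,
#'   `n_in_set`, `n_de`, sorted by p-value.
#' @export
fisherEnrichment <- function(profile, sets, cutoff, minSize = 2L) {
  stopifnot(is(profile, "DifferentiationProfile"),
            is(sets, "GeneSetCollection"), cutoff > 0)
  genes <- geneIds(profile)
  de <- abs(logFoldChange(profile)) >= cutoff
  rows <- list()
  for (nm in names(sets)) {
    inSet <- genes %in% geneSets(sets)[[nm]]
    if (sum(inSet) < minSize || sum(inSet) == length(genes)) next
    tab <- table(factor(de, c(TRUE, FALSE)), factor(inSet, c(TRUE, FALSE)))
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    rows[[length(rows) + 1L]] <- list(nm, p, sum(de & inSet), sum(inSet),
                                      sum(de))
  }
  if (length(rows) == 0L) stop("no testable gene sets")
  res <- DataFrame(
    set_name = vapply(rows, `[[`, "", 1L),
    p_value = vapply(rows, `[[`, 0, 2L),
    n_de_in = vapply(rows, `[[`, 0L, 3L),
    n_in_set = vapply(rows, `[[`, 0L, 4L),
    n_de = vapply(rows, `[[`, 0L, 5L))
  res <- res[order(res$p_value, method = "radix"), ]
  rownames(res) <- NULL
  res
}
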