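# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything from first principles and share no
# code with the package internals.

# All permutations of 1..n as rows of a matrix, built by iterative insertion.
allPermsMatrix <- function(n) {
  p <- matrix(1L, 1L, 1L)
  if (n == 1L) return(p)
  for (k in 2L:n) {
    p <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(p[, seq_len(pos - 1L), drop = FALSE], k,
            p[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  p
}

# BASE score recomputed from scratch for one pairing of d and b.
oracleDelta <- function(dDir, b) {
  ord <- order(dDir, decreasing = TRUE)
  ds <- dDir[ord]
  ws <- ds * b[ord]
  if (sum(ws) <= 0) return(0)
  max(cumsum(ws) / sum(ws) - cumsum(ds) / sum(ds))
}

# Exact permutation p-value by full enumeration over all N! pairings.
oracleExactP <- function(dDir, b) {
  obs <- oracleDelta(dDir, b)
  perms <- allPermsMatrix(length(b))
  null <- apply(perms, 1L, function(idx) oracleDelta(dDir, b[idx]))
  list(p = mean(null > obs), delta = obs, null = null)
}

# MATCH-style similarity score recomputed from scratch for one window.
oracleScore <- function(M, window) {
  iw <- vapply(seq_len(nrow(M)), function(p) {
    f <- M[p, ]
    sum(ifelse(f > 0, f * log(4 * f), 0))
  }, 0)
  idx <- match(strsplit(window, "")[[1L]], c("A", "C", "G", "T"))
  if (any(is.na(idx))) return(0)
  cur <- sum(iw * M[cbind(seq_len(nrow(M)), idx)])
  mx <- sum(iw * apply(M, 1L, max))
  mn <- sum(iw * apply(M, 1L, min))
  if (mx - mn <= 1e-12) 0 else (cur - mn) / (mx - mn)
}

# Hit count recomputed by explicit window enumeration on both strands.
oracleCountHits <- function(M, seq, threshold) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }
  L <- nrow(M)
  n <- 0L
  for (s in c(seq, rc(seq))) {
    if (nchar(s) < L) next
    for (o in seq_len(nchar(s) - L + 1L)) {
      if (oracleScore(M, substr(s, o, o + L - 1L)) >= threshold) n <- n + 1L
    }
  }
  n
}

# One-sided rank-sum p-values by enumerating all in-set membership choices.
oracleRankSumP <- function(d, inSet) {
  r <- rank(d)
  m <- sum(inSet)
  W <- sum(r[inSet])
  sums <- colSums(matrix(r[utils::combn(length(d), m)], nrow = m))
  eps <- 1e-9
  c(up = mean(sums >= W - eps), down = mean(sums <= W + eps))
}

randomInstance <- function(n, zeros = TRUE) {
  dDir <- abs(rnorm(n))
  if (zeros && n > 2L) dDir[sample.int(n, 1L)] <- 0
  b <- rpois(n, 1.5)
  if (sum(dDir * b) <= 0) b <- b + 1L
  list(dDir = dDir, b = b)
}

writeToyFiles <- function(toy, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "toy.fa")
  gff <- file.path(dir, "toy.gff3")
  pwm <- file.path(dir, "toy_pwms.txt")
  writeLines(toy$fasta, fa)
  writeLines(toy$gff, gff)
  writeLines(toy$pwm, pwm)
  list(fasta = fa, gff = gff, pwm = pwm)
}
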