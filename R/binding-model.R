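#' Probability that a factor binds a region with tau candidate sites
#'
#' Under the binding model, each of the tau above-threshold motif
#' occurrences in a promoter is an independent Bernoulli binding trial with
#' per-site probability `p0`.  The probability that the factor binds the
#' region at least once is then 1 - (1 - p0)^tau.
#'
#' @param tau non-negative integer vector of site counts.
#' @param p0 per-site binding probability, strictly inside (0, 1).
#' @return Numeric vector of binding probabilities in \[0, 1\].
#' @examples
#' bindingProbability(0:3, 0.01)
#' @export
bindingProbability <- function(tau, p0) {
  .checkTauP0(tau, p0)
  1 - (1 - p0)^tau
}

#' Error of the linear small-p0 approximation
#'
#' For small `p0` the binding probability 1 - (1 - p0)^tau is approximated
#' by `tau * p0`; the common factor p0 then cancels from the BASE score, so
#' raw counts can stand in for binding strengths.  This returns the signed
#' approximation error `tau * p0 - (1 - (1 - p0)^tau)`, which is always
#' >= 0 (the union bound) and bounded above by tau * (tau - 1) * p0^2 / 2.
#'
#' @inheritParams bindingProbability
#' @return Numeric vector of non-negative approximation errors.
#' @examples
#' linearApproximationError(3, 0.01)   # 0.000299, under the 3e-4 bound
#' @export
linearApproximationError <- function(tau, p0) {
  .checkTauP0(tau, p0)
  ## expm1/log1p keep the difference accurate for small p0; the result is
  ## mathematically >= 0, so sub-epsilon negative residue is clamped
  pmax(tau * p0 + expm1(tau * log1p(-p0)), 0)
}

.checkTauP0 <- function(tau, p0) {
  if (any(!is.finite(tau)) || any(tau < 0) || any(tau != round(tau)))
    stop("tau must be a non-negative integer")
  if (length(p0) != 1L || !is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must be a single value strictly inside (0, 1)")
  invisible(NULL)
}

#' Convert motif counts to binding strength vectors
#'
#' The default (`p0 = NULL`) returns the counts themselves: because the
#' per-site probability p0 cancels from the BASE cumulative functions, the
#' inference needs only the motif frequencies and no estimate of p0.  A
#' supplied `p0` instead applies the exact formula 1 - (1 - p0)^tau, which
#' is useful for sensitivity analysis (for large p0 the exact binding
#' probabilities are visibly non-proportional to tau).
#'
#' @param counts a [BindingCountMatrix-class].
#' @param p0 optional per-site binding probability in (0, 1).
#' @return Numeric matrix of binding strengths, same dimnames as the
#'   counts.
#' @examples
#' m <- BindingCountMatrix(matrix(c(0L, 1L, 2L), ncol = 1,
#'                         dimnames = list(paste0("g", 1:3), "motifA")))
#' countsToBinding(m)            # identical to the counts
#' countsToBinding(m, p0 = 0.5)  # (0, 0.5, 0.75): approximation breaks
#' @export
countsToBinding <- function(counts, p0 = NULL) {
  stopifnot(is(counts, "BindingCountMatrix"))
  m <- counts@counts
  storage.mode(m) <- "double"
  if (is.null(p0)) return(m)
  .checkTauP0(0L, p0)
  1 - (1 - p0)^m
}
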