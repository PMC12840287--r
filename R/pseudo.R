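#' @include npmle.R
NULL

#' RMST jackknife pseudo-observations
#'
#' Converts a censored cohort into a regression-ready response matrix. The
#' full-sample NPMLE is fitted once; then, for every subject i, a
#' leave-one-out NPMLE is refitted on the full-sample Turnbull support with
#' subject i's membership removed, warm-started from the full-sample masses.
#' The pseudo-observation at horizon \eqn{\tau_k} is
#' \deqn{\tilde y_i(\tau_k) = n\,\hat\mu(\tau_k) - (n-1)\,\hat\mu^{(-i)}(\tau_k),}
#' where \eqn{\hat\mu(\tau) = \int_0^\tau \hat S(t)\,dt} is the restricted
#' mean survival time of the fitted curve. When every observation is exact
#' the construction returns \eqn{\tilde y_i(\tau) = \min(T_i, \tau)}
#' (the jackknife of a sample mean reproduces the observations).
#'
#' Pseudo-values are computed once on the full cohort; any later
#' train/validation/test split reuses them, so the test-set "observed RMST"
#' is well defined. Values outside \eqn{[0, \tau]} are possible and are not
#' clipped.
#'
#' @param data an [IntervalSurv-class] object with at least 3 subjects.
#' @param taus strictly increasing positive RMST horizons.
#' @param tol,maxIter convergence settings for the full-sample fit.
#' @param looMaxIter iteration cap for each warm-started leave-one-out fit.
#' @param keepLOO retain the n x K leave-one-out RMST matrix.
#' @return a [PseudoValues-class] object.
#' @examples
#' t <- c(0.5, 1.2, 2.5, 3.1)
#' d <- IntervalSurv(t, t, matrix(0, 4, 1))
#' pseudoMatrix(pseudoRMST(d, taus = 2))   # equals pmin(t, 2)
#' @export
pseudoRMST <- function(data, taus, tol = 1e-7, maxIter = 500L,
                       looMaxIter = 100L, keepLOO = FALSE) {
  taus <- as.numeric(taus)
  if (any(taus <= 0) || is.unsorted(taus, strictly = TRUE))
    stop("taus must be strictly increasing and positive")
  n <- nSubjects(data)
  if (n < 3L) stop("pseudo-observations require at least 3 subjects")
  K <- length(taus)

  state <- .npmleState(data@left, data@right, data@ids)
  full <- .fitTurnbull(state, tol, maxIter)
  muFull <- .rmstFromProb(state, full$prob, taus)

  loo <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    si <- state
    si$li <- state$li[-i]; si$ri <- state$ri[-i]; si$n <- n - 1L
    fi <- tryCatch(
      .fitTurnbull(si, tol, looMaxIter, warmStart = full$prob),
      error = function(e)
        stop("leave-one-out fit failed when excluding subject ",
             data@ids[i], ": ", conditionMessage(e)))
    loo[i, ] <- .rmstFromProb(state, fi$prob, taus)
  }
  values <- n * matrix(muFull, n, K, byrow = TRUE) - (n - 1) * loo
  dimnames(values) <- list(data@ids, paste0("tau", taus))
  new("PseudoValues", values = values, taus = taus, popRMST = muFull,
      looRMST = if (keepLOO) loo else matrix(numeric(0), 0, 0),
      ids = data@ids)
}

## RMST of a mass vector on a given Turnbull state (no TurnbullFit overhead)
.rmstFromProb <- function(state, prob, taus) {
  q <- state$q
  ends <- c(0, state$pts[-1L])
  Bfin <- c(0, cumsum(prob[seq_len(q)]))
  vapply(taus, function(tt) {
    segL <- pmin(ends[-1L], tt) - pmin(ends[-length(ends)], tt)
    area <- sum((1 - Bfin[seq_len(q)]) * segL)
    if (tt > ends[length(ends)])
      area <- area + (1 - Bfin[q + 1L]) * (tt - ends[length(ends)])
    area
  }, numeric(1))
}

#' @rdname pseudoMatrix
#' @export
setMethod("pseudoMatrix", "PseudoValues", function(x) x@values)

#' @rdname popRMST
#' @export
setMethod("popRMST", "PseudoValues", function(x) x@popRMST)

#' @rdname taus
#' @export
setMethod("taus", "PseudoValues", function(x) x@taus)

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "PseudoValues", function(x) nrow(x@values))

setMethod("show", "PseudoValues", function(object) {
  cat("PseudoValues:", nrow(object@values), "subjects x",
      length(object@taus), "horizons (tau =",
      paste(object@taus, collapse = ", "), ")\n")
  cat("  population RMST:",
      paste(format(object@popRMST, digits = 4), collapse = ", "), "\n")
})
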