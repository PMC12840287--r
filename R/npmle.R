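#' @include AllGenerics.R
NULL

#' Construct an interval-censored dataset
#'
#' @param left numeric vector of left bounds \eqn{L \ge 0}.
#' @param right numeric vector of right bounds; `Inf` or `NA` encode right
#'   censoring. `left == right` marks an exactly observed event.
#' @param features numeric covariate matrix with one row per subject. A
#'   vector is treated as a single covariate.
#' @param ids optional subject identifiers (defaults to `"s1"..."sn"`).
#' @return an [IntervalSurv-class] object.
#' @examples
#' d <- IntervalSurv(c(0, 1), c(2, 2), matrix(rnorm(4), 2))
#' censorClass(d)
#' @export
IntervalSurv <- function(left, right, features, ids = NULL) {
  right[is.na(right)] <- Inf
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(ids)) ids <- paste0("s", seq_along(left))
  new("IntervalSurv", left = as.numeric(left), right = as.numeric(right),
      features = features, ids = as.character(ids))
}

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "IntervalSurv", function(x) length(x@left))

#' @rdname nFeatures
#' @export
setMethod("nFeatures", "IntervalSurv", function(x) ncol(x@features))

#' @rdname features
#' @export
setMethod("features", "IntervalSurv", function(x) x@features)

#' @rdname leftBound
#' @export
setMethod("leftBound", "IntervalSurv", function(x) x@left)

#' @rdname rightBound
#' @export
setMethod("rightBound", "IntervalSurv", function(x) x@right)

#' @rdname censorClass
#' @export
setMethod("censorClass", "IntervalSurv", function(x) {
  cls <- ifelse(x@left == x@right, "exact",
         ifelse(!is.finite(x@right), "right",
         ifelse(x@left == 0, "left", "interval")))
  factor(cls, levels = c("left", "interval", "right", "exact"))
})

setMethod("show", "IntervalSurv", function(object) {
  cat("IntervalSurv with", nSubjects(object), "subjects and",
      nFeatures(object), "covariates\n")
  print(table(censorClass(object)))
})

## ---- internal NPMLE state --------------------------------------------------
## The Turnbull support is the ordered unique set {0, L_i, finite R_i}; the
## Turnbull intervals are the gaps between consecutive support points plus,
## when right-censored subjects exist, a terminal interval beyond the last
## finite point. Each observation covers a contiguous run of intervals, so
## membership is stored as (first, last) interval indices instead of the full
## binary matrix; all EM/ICM updates then run in O(n + m) per sweep.
.npmleState <- function(left, right, ids = NULL) {
  if (length(left) == 0L) stop("empty dataset")
  if (is.null(ids)) ids <- paste0("s", seq_along(left))
  pts <- sort(unique(c(0, left, right[is.finite(right)])))
  q <- length(pts) - 1L
  hasInf <- any(!is.finite(right))
  m <- q + as.integer(hasInf)
  li <- integer(length(left)); ri <- integer(length(left))
  for (i in seq_along(left)) {
    if (left[i] == right[i]) {                  # exact event at t = left[i]
      j <- match(left[i], pts) - 1L             # interval ending at t
      if (is.na(j) || j < 1L)
        stop("subject ", ids[i], " has no admissible Turnbull interval ",
             "(exact event at time 0)")
      li[i] <- j; ri[i] <- j
    } else {
      li[i] <- match(left[i], pts)              # first interval after L
      ri[i] <- if (is.finite(right[i])) match(right[i], pts) - 1L else m
      if (li[i] > ri[i])
        stop("subject ", ids[i], " has empty Turnbull membership")
    }
  }
  list(pts = pts, q = q, hasInf = hasInf, m = m, li = li, ri = ri,
       n = length(left), ids = ids)
}

## per-observation interval probability P_i = beta[ri] - beta[li - 1]
.obsProb <- function(state, prob) {
  B <- c(0, cumsum(prob))
  B[state$ri + 1L] - B[state$li]
}

.logLikState <- function(state, prob) {
  P <- .obsProb(state, prob)
  if (any(P <= 0)) return(-Inf)
  sum(log(P))
}

## E-step: self-consistency update rho_j <- d_j / n with
## d_j = sum_i alpha_ij rho_j / sum_l alpha_il rho_l,
## computed with a difference array over the contiguous membership runs.
.emStep <- function(state, prob) {
  P <- .obsProb(state, prob)
  if (any(P <= 0))
    stop("numerical degeneracy: zero mass on an observation's intervals")
  inc <- numeric(state$m + 1L)
  w <- 1 / P
  inc_add <- tapply(w, state$li, sum)
  inc[as.integer(names(inc_add))] <-
    inc[as.integer(names(inc_add))] + as.numeric(inc_add)
  inc_sub <- tapply(w, state$ri + 1L, sum)
  inc[as.integer(names(inc_sub))] <-
    inc[as.integer(names(inc_sub))] - as.numeric(inc_sub)
  cover <- cumsum(inc[seq_len(state$m)])
  d <- prob * cover
  d / state$n
}

## M-step (iterative convex minorant): one projected-Newton step on the CDF
## beta under the monotonicity constraint, using the diagonal of the negative
## Hessian as working curvature, projected with weighted PAVA, with
## step-halving so the log-likelihood never decreases. beta_m = 1 is fixed.
.icmStep <- function(state, prob, eps = 1e-8) {
  m <- state$m
  if (m <= 1L) return(prob)
  P <- .obsProb(state, prob)
  if (any(P <= 0))
    stop("numerical degeneracy: zero mass on an observation's intervals")
  free <- m - 1L
  grad <- numeric(free); curv <- numeric(free)
  w1 <- 1 / P; w2 <- w1^2
  # beta_j gains +1/P_i when j is observation i's last interval,
  # -1/P_i when j is the interval just before its first.
  ridx <- state$ri[state$ri <= free]
  g1 <- tapply(w1[state$ri <= free], ridx, sum)
  grad[as.integer(names(g1))] <- grad[as.integer(names(g1))] + as.numeric(g1)
  lidx <- state$li - 1L
  keep <- lidx >= 1L
  g2 <- tapply(w1[keep], lidx[keep], sum)
  grad[as.integer(names(g2))] <- grad[as.integer(names(g2))] - as.numeric(g2)
  c1 <- tapply(w2[state$ri <= free], ridx, sum)
  curv[as.integer(names(c1))] <- curv[as.integer(names(c1))] + as.numeric(c1)
  c2 <- tapply(w2[keep], lidx[keep], sum)
  curv[as.integer(names(c2))] <- curv[as.integer(names(c2))] + as.numeric(c2)
  if (any(!is.finite(grad)))
    stop("numerical degeneracy: non-finite ICM gradient")
  wts <- pmax(curv, eps)
  B <- cumsum(prob)[seq_len(free)]
  target <- B + grad / wts
  proposal <- pmin(pmax(pava(target, wts), 1e-10), 1 - 1e-10)
  ll0 <- .logLikState(state, prob)
  lam <- 1
  for (h in 1:25) {
    Bnew <- (1 - lam) * B + lam * proposal
    probNew <- diff(c(0, Bnew, 1))
    ll <- .logLikState(state, probNew)
    if (is.finite(ll) && ll >= ll0 - 1e-12) return(probNew)
    lam <- lam / 2
  }
  prob
}

.fitTurnbull <- function(state, tol = 1e-7, maxIter = 500L,
                         warmStart = NULL) {
  m <- state$m
  prob <- if (is.null(warmStart)) rep(1 / m, m) else {
    p <- pmax(warmStart, 1e-12)
    p / sum(p)
  }
  if (length(prob) != m) stop("warm start has wrong length")
  trace <- numeric(0)
  ll <- .logLikState(state, prob)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    prob <- .emStep(state, prob)
    prob <- .icmStep(state, prob)
    llNew <- .logLikState(state, prob)
    trace <- c(trace, llNew)
    if (is.finite(ll) && llNew - ll < tol) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  list(prob = prob, logLik = ll, trace = trace, converged = converged,
       iterations = it)
}

#' Turnbull NPMLE of the survival function via hybrid EM-ICM
#'
#' Fits the nonparametric maximum-likelihood estimator of the survival
#' function for arbitrarily censored data: probability masses \eqn{\rho_j}
#' on the Turnbull intervals between consecutive points of the ordered
#' unique set \eqn{\{0, L_i, R_i\}} maximising \eqn{\sum_i \log \sum_j
#' \alpha_{ij}\rho_j}, where \eqn{\alpha_{ij}} indicates that interval j is
#' contained in \eqn{(L_i, R_i]}. Each outer iteration runs one
#' self-consistency (EM) sweep followed by one iterative-convex-minorant
#' sweep (a projected Newton step on the CDF with weighted-PAVA projection
#' and step-halving), so the log-likelihood is nondecreasing.
#'
#' Exact observations (`left == right`) are treated as events at that time
#' (membership in the Turnbull interval ending there), which makes the
#' estimator reduce to the empirical survival function when no censoring is
#' present. Mass that the likelihood pushes beyond the largest finite bound
#' is held on a terminal infinite interval and the fitted curve plateaus.
#'
#' @param data an [IntervalSurv-class] object.
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param maxIter maximum number of outer EM-ICM iterations; if reached
#'   without convergence a warning is emitted and the best iterate returned.
#' @param warmStart optional initial mass vector (length = number of
#'   Turnbull intervals).
#' @return a [TurnbullFit-class] object.
#' @examples
#' d <- IntervalSurv(c(0, 1), c(2, 2), matrix(0, 2, 1))
#' fit <- fitNPMLE(d)
#' survProb(fit, c(0.5, 1.5, 2.5))
#' @export
fitNPMLE <- function(data, tol = 1e-7, maxIter = 500L, warmStart = NULL) {
  stopifnot(tol > 0, maxIter >= 1L)
  state <- .npmleState(data@left, data@right, data@ids)
  res <- .fitTurnbull(state, tol, maxIter, warmStart)
  if (!res$converged)
    warning("NPMLE did not converge in ", maxIter,
            " iterations; returning the last iterate")
  new("TurnbullFit",
      support = state$pts, hasInf = state$hasInf, prob = res$prob,
      cdf = cumsum(res$prob),
      intervalIndex = cbind(first = state$li, last = state$ri),
      logLik = res$logLik, trace = res$trace,
      converged = res$converged, iterations = as.integer(res$iterations))
}

#' @rdname survProb
#' @export
setMethod("survProb", "TurnbullFit", function(fit, times) {
  q <- length(fit@support) - 1L
  ends <- fit@support[-1L]                 # right endpoints of finite intervals
  Bfin <- c(0, cumsum(fit@prob[seq_len(q)]))
  idx <- findInterval(times, ends)
  1 - Bfin[idx + 1L]
})

#' @rdname rmst
#' @export
setMethod("rmst", "TurnbullFit", function(fit, tau) {
  if (any(tau <= 0)) stop("rmst: tau must be positive")
  q <- length(fit@support) - 1L
  ends <- c(0, fit@support[-1L])
  Bfin <- c(0, cumsum(fit@prob[seq_len(q)]))   # CDF after interval j
  vapply(tau, function(tt) {
    # survival is 1 - Bfin[j] on [ends[j], ends[j+1]) (0-based segment j)
    segL <- pmin(ends[-1L], tt) - pmin(ends[-length(ends)], tt)
    area <- sum((1 - Bfin[seq_len(q)]) * segL)
    if (tt > ends[length(ends)])
      area <- area + (1 - Bfin[q + 1L]) * (tt - ends[length(ends)])
    area
  }, numeric(1))
})

setMethod("show", "TurnbullFit", function(object) {
  cat("TurnbullFit:", length(object@prob), "Turnbull intervals,",
      "logLik", format(object@logLik, digits = 6), "\n")
  cat("  ", object@iterations, "EM-ICM iterations,",
      if (object@converged) "converged" else "NOT converged", "\n")
  if (object@hasInf)
    cat("  terminal mass beyond", max(object@support), ":",
        format(object@prob[length(object@prob)], digits = 4), "\n")
})

#' Fitted survival curve as a table
#'
#' @param fit a [TurnbullFit-class].
#' @return data.frame with columns `time` and `surv`: the value of the step
#'   survival function on `[time[k], time[k+1])`.
#' @export
survCurve <- function(fit) {
  q <- length(fit@support) - 1L
  Bfin <- cumsum(fit@prob[seq_len(q)])
  data.frame(time = fit@support, surv = c(1, 1 - Bfin))
}
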