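# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths.

# Dense grid search over the probability simplex: maximises the
# interval-censored log-likelihood sum_i log(sum_j alpha_ij rho_j) by brute
# force. alpha is the full n x m binary membership matrix; step is the grid
# resolution. Only sensible for m <= 3.
bruteForceSimplexLogLik <- function(alpha, step = 1e-3) {
  m <- ncol(alpha)
  if (m == 1L) return(0)
  g <- seq(0, 1, by = step)
  if (m == 2L) {
    P <- cbind(g, 1 - g)
  } else if (m == 3L) {
    P <- as.matrix(expand.grid(g, g))
    P <- P[rowSums(P) <= 1 + 1e-12, ]
    P <- cbind(P, pmax(1 - rowSums(P), 0))
  } else stop("brute force limited to m <= 3")
  probs <- P %*% t(alpha)          # candidate x observation
  ll <- rowSums(log(probs))
  max(ll[is.finite(ll)])
}

# Full binary membership matrix computed from first principles (interval
# inclusion of support gaps), independent of the package's run-length
# representation.
membershipMatrix <- function(left, right) {
  pts <- sort(unique(c(0, left, right[is.finite(right)])))
  hasInf <- any(!is.finite(right))
  lo <- pts[-length(pts)]; hi <- pts[-1]
  if (hasInf) { lo <- c(lo, pts[length(pts)]); hi <- c(hi, Inf) }
  alpha <- matrix(0L, length(left), length(lo))
  for (i in seq_along(left)) {
    if (left[i] == right[i]) {
      alpha[i, which(hi == left[i])] <- 1L
    } else {
      alpha[i, ] <- as.integer(lo >= left[i] & hi <= right[i])
    }
  }
  alpha
}

# Central finite differences of a scalar function of a parameter list.
numericGradient <- function(f, params, h = 1e-5) {
  out <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    if (!length(params[[nm]])) next
    for (j in seq_along(params[[nm]])) {
      up <- params; up[[nm]][j] <- up[[nm]][j] + h
      dn <- params; dn[[nm]][j] <- dn[[nm]][j] - h
      out[[nm]][j] <- (f(up) - f(dn)) / (2 * h)
    }
  }
  out
}

# A small random interval-censored dataset covering all censoring classes.
randomIntervalData <- function(n, seed, p = 2) {
  set.seed(seed)
  T <- rexp(n, rate = 1)
  v1 <- runif(n, 0, 2)
  v2 <- v1 + runif(n)
  L <- ifelse(T < v1, 0, ifelse(T > v2, v2, v1))
  R <- ifelse(T < v1, v1, ifelse(T > v2, Inf, v2))
  IntervalSurv(L, R, matrix(rnorm(n * p), n, p))
}
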