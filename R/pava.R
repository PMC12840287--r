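#' Weighted pool-adjacent-violators algorithm
#'
#' Computes the weighted least-squares isotonic (nondecreasing) fit: the
#' minimiser of \eqn{\sum_j w_j (x_j - y_j)^2} over nondecreasing vectors
#' \eqn{x}. Adjacent violators are pooled into blocks whose fitted value is
#' the weighted mean of the pooled observations, so block totals
#' \eqn{\sum w_j y_j} are conserved.
#'
#' This is the projection step used inside the iterative-convex-minorant
#' update of [fitNPMLE()], where the weights are the working curvatures of
#' the log-likelihood.
#'
#' @param values numeric vector to be fitted.
#' @param weights positive weights, same length as `values`.
#' @return numeric vector, the nondecreasing fit.
#' @examples
#' pava(c(3, 1, 2), c(1, 1, 1))   # all pooled: rep(2, 3)
#' pava(c(2, 1), c(3, 1))         # weighted pooled mean 1.75
#' @export
pava <- function(values, weights = rep(1, length(values))) {
  m <- length(values)
  if (m == 0L) stop("pava: empty input")
  if (length(weights) != m) stop("pava: values and weights differ in length")
  if (any(weights <= 0) || any(!is.finite(weights)))
    stop("pava: weights must be positive and finite")
  # stack of blocks: running (weighted sum, weight, multiplicity)
  mean_ <- numeric(m); wt <- numeric(m); size <- integer(m)
  top <- 0L
  for (j in seq_len(m)) {
    top <- top + 1L
    mean_[top] <- values[j]; wt[top] <- weights[j]; size[top] <- 1L
    while (top > 1L && mean_[top - 1L] > mean_[top]) {
      w <- wt[top - 1L] + wt[top]
      mean_[top - 1L] <- (wt[top - 1L] * mean_[top - 1L] +
                            wt[top] * mean_[top]) / w
      wt[top - 1L] <- w
      size[top - 1L] <- size[top - 1L] + size[top]
      top <- top - 1L
    }
  }
  rep.int(mean_[seq_len(top)], size[seq_len(top)])
}
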