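#' @include AllGenerics.R
NULL

## Soft binary decision tree, heap-indexed.
##
## Internal nodes are 1 .. 2^depth - 1 in level order; node e has children
## 2e (left) and 2e+1 (right); leaves occupy heap slots 2^depth ..
## 2^(depth+1) - 1. d_e = sigmoid(f_e) is the probability of routing LEFT
## (a fixed convention; the sign of every gradient below follows from it).

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Leaf routing probabilities of a soft decision tree
#'
#' Given one routing score per internal node, returns for each sample the
#' probability of reaching each leaf: the product over the path of
#' \eqn{d_e} (left branches) and \eqn{1 - d_e} (right branches), with
#' \eqn{d_e = \mathrm{sigmoid}(f_e)}. Rows sum to 1.
#'
#' @param scores n x (2^depth - 1) matrix of routing scores \eqn{f_e}.
#' @param depth tree depth (>= 1).
#' @return n x 2^depth matrix of leaf probabilities.
#' @export
routingProbs <- function(scores, depth) {
  .routing(.sigmoid(scores), depth)$leaf
}

## node- and leaf-reach probabilities from left-probabilities d (n x |E|)
.routing <- function(d, depth) {
  n <- nrow(d)
  nE <- 2L^depth - 1L
  if (ncol(d) != nE) stop("routing: wrong number of internal nodes")
  P <- matrix(0, n, 2L * nE + 1L)
  P[, 1L] <- 1
  for (e in seq_len(nE)) {
    P[, 2L * e] <- P[, e] * d[, e]
    P[, 2L * e + 1L] <- P[, e] * (1 - d[, e])
  }
  list(node = P, leaf = P[, (nE + 1L):(2L * nE + 1L), drop = FALSE])
}

## backprop through the routing: given dL/dPleaf, return dL/dscores and
## dL/dPnode (the latter re-used by nothing else but kept for clarity).
.routingBackward <- function(d, route, dLeaf, depth) {
  n <- nrow(d)
  nE <- 2L^depth - 1L
  dP <- matrix(0, n, 2L * nE + 1L)
  dP[, (nE + 1L):(2L * nE + 1L)] <- dLeaf
  dF <- matrix(0, n, nE)
  for (e in rev(seq_len(nE))) {
    dP[, e] <- dP[, e] + dP[, 2L * e] * d[, e] + dP[, 2L * e + 1L] * (1 - d[, e])
    dd <- (dP[, 2L * e] - dP[, 2L * e + 1L]) * route$node[, e]
    dF[, e] <- dd * d[, e] * (1 - d[, e])
  }
  dF
}

## prediction of the subtree rooted at every heap node: list over heap slots
## of n x K matrices. Leaf subtrees are constant at their lambda vector.
.subtreeOutputs <- function(d, leaves, depth, n) {
  nE <- 2L^depth - 1L
  K <- ncol(leaves)
  A <- vector("list", 2L * nE + 1L)
  for (l in seq_len(2L^depth))
    A[[nE + l]] <- matrix(leaves[l, ], n, K, byrow = TRUE)
  for (e in rev(seq_len(nE)))
    A[[e]] <- d[, e] * A[[2L * e]] + (1 - d[, e]) * A[[2L * e + 1L]]
  A
}

#' Closed-form gradients of the pseudo-value loss for the tree parameters
#'
#' Evaluates the analytic gradient expressions for the decision-node routing
#' scores and the leaf RMST values, written in terms of the prediction
#' residual \eqn{r_{ik} = g_{ik} - \hat y_{ik}}, the node uncertainty
#' \eqn{d_e \bar d_e}, the probability \eqn{P_e(X_i)} of reaching node e,
#' and the difference between the left and right subtree predictions:
#' \deqn{\frac{\partial L}{\partial f_e(X_i)} = \frac{2}{nK}\, d_e \bar d_e\,
#'   P_e(X_i) \sum_k r_{ik}\,(A_{el}(k) - A_{el}^{r}(k)), \qquad
#'   \frac{\partial L}{\partial \lambda_{lk}} = \frac{2}{nK} \sum_i r_{ik}\,
#'   p_l(X_i),}
#' under this package's convention that \eqn{d_e} routes left. These are
#' exact gradients of the mean-squared pseudo-value loss and are verified
#' against central finite differences in the test suite; the trainer itself
#' uses the backpropagation pass, so these serve as an independent check.
#'
#' @param scores n x |E| routing-score matrix \eqn{f_e(X_i)}.
#' @param leaves |L| x K leaf RMST matrix.
#' @param depth tree depth.
#' @param resid n x K residual matrix \eqn{g - \hat y} (zero rows for
#'   samples outside the loss mask).
#' @param nLoss the n used in the 1/(nK) loss normalisation (number of
#'   samples in the loss mask).
#' @return list with `node` (n x |E| per-sample score gradients) and
#'   `leaf` (|L| x K gradient matrix).
#' @export
treeGradients <- function(scores, leaves, depth, resid, nLoss = nrow(resid)) {
  n <- nrow(scores)
  K <- ncol(leaves)
  d <- .sigmoid(scores)
  route <- .routing(d, depth)
  A <- .subtreeOutputs(d, leaves, depth, n)
  nE <- 2L^depth - 1L
  gnode <- matrix(0, n, nE)
  for (e in seq_len(nE)) {
    diffLR <- A[[2L * e]] - A[[2L * e + 1L]]     # left minus right subtree
    gnode[, e] <- 2 / (nLoss * K) * d[, e] * (1 - d[, e]) *
      route$node[, e] * rowSums(resid * diffLR)
  }
  gleaf <- 2 / (nLoss * K) * crossprod(route$leaf, resid)
  list(node = gnode, leaf = gleaf)
}
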