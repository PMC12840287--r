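#' @include tree.R graph.R
NULL

.relu <- function(x) (x > 0) * x

## architecture descriptor shared by the four model variants
.arch <- function(method, depth, K) {
  list(method = method,
       useGraph = method %in% c("gt", "gcn"),   # propagate over A-hat
       useBias = method %in% c("dnn", "ndf"),   # dense layers carry biases
       treeHead = method %in% c("gt", "ndf"),
       depth = as.integer(depth), K = as.integer(K))
}

.paramsFromModel <- function(model) {
  list(W0 = model@W0, b0 = model@b0, W1 = model@W1, b1 = model@b1,
       headW = model@headW, headB = model@headB, leaves = model@leaves)
}

## Forward pass. PX is the (pre-propagated) input to layer 1: A-hat %*% X for
## graph variants, X itself otherwise; M is A-hat (or NULL). Dropout is
## applied after each hidden ReLU, inverted-scaled, only when training.
.forward <- function(params, PX, M, arch, dropout = 0, training = FALSE) {
  n <- nrow(PX)
  Z1 <- PX %*% params$W0
  if (arch$useBias) Z1 <- Z1 + rep(params$b0, each = n)
  H1 <- .relu(Z1)
  mask1 <- NULL
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask1 <- matrix((stats::runif(length(H1)) < keep) / keep, n)
    H1 <- H1 * mask1
  }
  P1 <- if (arch$useGraph) M %*% H1 else H1
  Z2 <- P1 %*% params$W1
  if (arch$useBias) Z2 <- Z2 + rep(params$b1, each = n)
  H2 <- .relu(Z2)
  mask2 <- NULL
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask2 <- matrix((stats::runif(length(H2)) < keep) / keep, n)
    H2 <- H2 * mask2
  }
  if (arch$treeHead) {
    FF <- H2 %*% params$headW + rep(params$headB, each = n)
    d <- .sigmoid(FF)
    route <- .routing(d, arch$depth)
    G <- route$leaf %*% params$leaves
    list(Z1 = Z1, mask1 = mask1, P1 = P1, Z2 = Z2, mask2 = mask2, H2 = H2,
         FF = FF, d = d, route = route, G = G)
  } else {
    G <- H2 %*% params$headW + rep(params$headB, each = n)
    list(Z1 = Z1, mask1 = mask1, P1 = P1, Z2 = Z2, mask2 = mask2, H2 = H2,
         G = G)
  }
}

## Mean-squared pseudo-value loss restricted to the rows in idx:
## L = 1/(|idx| K) sum_{i in idx} sum_k (g_ik - y_ik)^2
.maskedLoss <- function(G, y, idx) {
  r <- G[idx, , drop = FALSE] - y[idx, , drop = FALSE]
  sum(r * r) / (length(idx) * ncol(y))
}

## loss as a pure function of the parameters (used by the finite-difference
## oracle in the tests; forward-only, shares no code with the backward pass)
.lossFromParams <- function(params, PX, M, arch, y, idx) {
  .maskedLoss(.forward(params, PX, M, arch)$G, y, idx)
}

## Exact gradient of the masked loss w.r.t. every parameter, by manual
## backpropagation through head, dropout, ReLU and graph propagation.
.networkGradients <- function(params, cache, PX, M, arch, y, idx, dropout) {
  n <- nrow(PX); K <- arch$K
  dG <- matrix(0, n, K)
  dG[idx, ] <- 2 / (length(idx) * K) *
    (cache$G[idx, , drop = FALSE] - y[idx, , drop = FALSE])
  if (arch$treeHead) {
    gLeaves <- crossprod(cache$route$leaf, dG)
    dLeaf <- dG %*% t(params$leaves)
    dF <- .routingBackward(cache$d, cache$route, dLeaf, arch$depth)
    gHeadW <- crossprod(cache$H2, dF)
    gHeadB <- colSums(dF)
    dH2 <- dF %*% t(params$headW)
  } else {
    gLeaves <- matrix(numeric(0), 0, 0)
    gHeadW <- crossprod(cache$H2, dG)
    gHeadB <- colSums(dG)
    dH2 <- dG %*% t(params$headW)
  }
  if (!is.null(cache$mask2)) dH2 <- dH2 * cache$mask2
  dZ2 <- dH2 * (cache$Z2 > 0)
  gW1 <- crossprod(cache$P1, dZ2)
  gB1 <- if (arch$useBias) colSums(dZ2) else numeric(0)
  dH1 <- dZ2 %*% t(params$W1)
  if (arch$useGraph) dH1 <- M %*% dH1          # M is symmetric
  if (!is.null(cache$mask1)) dH1 <- dH1 * cache$mask1
  dZ1 <- dH1 * (cache$Z1 > 0)
  gW0 <- crossprod(PX, dZ1)
  gB0 <- if (arch$useBias) colSums(dZ1) else numeric(0)
  list(W0 = gW0, b0 = gB0, W1 = gW1, b1 = gB1,
       headW = gHeadW, headB = gHeadB, leaves = gLeaves)
}

#' Mean-squared pseudo-value loss
#'
#' The training objective: \eqn{L = \frac{1}{nK}\sum_i \sum_k (\hat y_{ik} -
#' g_{ik})^2}, averaging squared residuals over all subjects and horizons.
#'
#' @param pred n x K prediction matrix.
#' @param obs n x K pseudo-observation matrix.
#' @return nonnegative scalar, zero iff the matrices match.
#' @export
pseudoLoss <- function(pred, obs) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  if (!all(dim(pred) == dim(obs))) stop("pseudoLoss: shape mismatch")
  mean((pred - obs)^2)
}

#' @rdname predictRMST
#' @export
setMethod("predictRMST", "GTModel", function(model, X, graph = NULL) {
  if (is(X, "IntervalSurv")) X <- features(X)
  X <- as.matrix(X)
  arch <- .arch(model@method, model@depth, length(model@taus))
  M <- NULL
  if (arch$useGraph) {
    if (is.null(graph)) stop("graph-based model needs a PatientGraph")
    M <- normalizedAdjacency(graph)
    if (nrow(M) != nrow(X)) stop("graph and X disagree on subject count")
  }
  if (ncol(X) != nrow(model@W0)) stop("X has wrong number of covariates")
  PX <- if (arch$useGraph) M %*% X else X
  out <- .forward(.paramsFromModel(model), PX, M, arch)$G
  dimnames(out) <- list(rownames(X), paste0("tau", model@taus))
  out
})

#' @rdname taus
#' @export
setMethod("taus", "GTModel", function(x) x@taus)

setMethod("show", "GTModel", function(object) {
  lab <- c(gt = "GCN + soft decision tree", gcn = "GCN, linear head",
           dnn = "fully connected, linear head",
           ndf = "fully connected + soft decision tree")[object@method]
  cat("GTModel [", object@method, "]: ", lab, "\n", sep = "")
  cat("  layers:", nrow(object@W0), "->", ncol(object@W0), "->",
      ncol(object@W1),
      if (object@depth > 0) paste("-> tree depth", object@depth) else
        "-> linear", "\n")
  cat("  horizons:", paste(object@taus, collapse = ", "), "\n")
  if (length(object@history$val))
    cat("  best epoch:", object@history$bestEpoch, "of",
        length(object@history$train), "(val MSE",
        format(min(object@history$val), digits = 4), ")\n")
})

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single file holding the weights, tree topology,
#' horizon grid and the training configuration; reloading reproduces
#' predictions bitwise on the same input.
#'
#' @param model a [GTModel-class].
#' @param path file path.
#' @return `loadModel` returns the restored [GTModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "GTModel")) stop("checkpoint does not contain a GTModel")
  model
}
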