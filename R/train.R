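#' @include model.R
NULL

#' Training configuration
#'
#' Builds and validates the configuration used by [gtTrain()]. Unknown
#' fields are rejected.
#'
#' @param kn KNN neighbourhood size used when the caller builds the graph.
#' @param hidden hidden-layer widths, length 2.
#' @param depth soft-tree depth (tree-headed architectures).
#' @param lr Adam learning rate.
#' @param epochs maximum number of full-batch epochs.
#' @param dropout dropout probability applied after each hidden ReLU during
#'   training.
#' @param weightDecay L2 coefficient added to the gradient of the weight
#'   matrices (hidden layers and head map; biases and leaf values are not
#'   decayed).
#' @param patience early-stopping patience, in epochs without validation
#'   improvement; the best-validation weights are restored.
#' @param seed RNG seed governing initialisation and dropout.
#' @return named list.
#' @export
gtConfig <- function(kn = 10L, hidden = c(64L, 32L), depth = 3L, lr = 0.001,
                     epochs = 1000L, dropout = 0.1, weightDecay = 1e-4,
                     patience = 50L, seed = 1L) {
  cfg <- list(kn = as.integer(kn), hidden = as.integer(hidden),
              depth = as.integer(depth), lr = lr,
              epochs = as.integer(epochs), dropout = dropout,
              weightDecay = weightDecay, patience = as.integer(patience),
              seed = as.integer(seed))
  stopifnot(length(cfg$hidden) == 2L, all(cfg$hidden >= 1L),
            cfg$hidden[1] >= cfg$hidden[2],
            cfg$depth >= 1L, cfg$lr > 0, cfg$epochs >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$weightDecay >= 0,
            cfg$patience >= 1L)
  cfg
}

.validateConfig <- function(config) {
  known <- names(formals(gtConfig))
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown configuration fields: ", paste(extra, collapse = ", "))
  do.call(gtConfig, config)
}

.glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

.initParams <- function(p, arch, config, leafInit) {
  h1 <- config$hidden[1]; h2 <- config$hidden[2]
  params <- list(W0 = .glorot(p, h1),
                 b0 = if (arch$useBias) numeric(h1) else numeric(0),
                 W1 = .glorot(h1, h2),
                 b1 = if (arch$useBias) numeric(h2) else numeric(0))
  if (arch$treeHead) {
    nE <- 2L^arch$depth - 1L
    nL <- 2L^arch$depth
    params$headW <- .glorot(h2, nE)
    params$headB <- numeric(nE)
    # leaves start at the training-mean pseudo-value per horizon, plus a
    # small symmetry-breaking perturbation
    params$leaves <- matrix(leafInit, nL, arch$K, byrow = TRUE) +
      matrix(stats::rnorm(nL * arch$K, sd = 0.01), nL, arch$K)
  } else {
    params$headW <- .glorot(h2, arch$K)
    params$headB <- numeric(arch$K)
    params$leaves <- matrix(numeric(0), 0, 0)
  }
  params
}

#' Train an RMST network on pseudo-observations
#'
#' Fits one of the four architectures (see [GTModel-class]) by full-batch
#' Adam on the mean-squared pseudo-value loss. Training is transductive for
#' the graph variants: every forward pass propagates over the whole graph
#' (all subjects), while the loss is masked to `trainIdx`. Early stopping
#' monitors the validation loss (evaluation-mode forward pass, no dropout)
#' and restores the best weights.
#'
#' @param X covariate matrix (all subjects) or an [IntervalSurv-class].
#' @param pseudo a [PseudoValues-class] (or plain n x K matrix, in which
#'   case `tauGrid` must be given).
#' @param graph a [PatientGraph-class] over the same subjects; required for
#'   methods `"gt"` and `"gcn"`.
#' @param method one of `"gt"`, `"gcn"`, `"dnn"`, `"ndf"`.
#' @param trainIdx indices of subjects whose residuals enter the loss.
#' @param valIdx indices monitored for early stopping (may be empty, in
#'   which case all epochs are run and the final weights kept).
#' @param config a configuration list from [gtConfig()].
#' @param tauGrid horizons when `pseudo` is a plain matrix.
#' @return a fitted [GTModel-class] with the training history attached.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 30, 2)
#' y <- matrix(pmin(abs(X[, 1]) + 0.3, 1), 30, 1)
#' g <- patientGraph(X, k = 3)
#' fit <- gtTrain(X, y, g, method = "gt", trainIdx = 1:24, valIdx = 25:30,
#'                config = gtConfig(hidden = c(8, 4), depth = 2,
#'                                  epochs = 50), tauGrid = 1)
#' @export
gtTrain <- function(X, pseudo, graph = NULL,
                    method = c("gt", "gcn", "dnn", "ndf"),
                    trainIdx, valIdx = integer(0),
                    config = gtConfig(), tauGrid = NULL) {
  method <- match.arg(method)
  config <- .validateConfig(config)
  if (is(X, "IntervalSurv")) X <- features(X)
  X <- as.matrix(X)
  if (is(pseudo, "PseudoValues")) {
    y <- pseudoMatrix(pseudo)
    tauGrid <- taus(pseudo)
  } else {
    y <- as.matrix(pseudo)
    if (is.null(tauGrid)) stop("tauGrid required with a plain matrix")
  }
  if (nrow(y) != nrow(X)) stop("pseudo-values and X disagree on subjects")
  K <- ncol(y)
  arch <- .arch(method, config$depth, K)
  trainIdx <- as.integer(trainIdx); valIdx <- as.integer(valIdx)
  if (length(intersect(trainIdx, valIdx)))
    stop("training and validation indices overlap")

  M <- NULL
  if (arch$useGraph) {
    if (is.null(graph)) stop("method '", method, "' needs a PatientGraph")
    M <- normalizedAdjacency(graph)
    if (nrow(M) != nrow(X)) stop("graph and X disagree on subject count")
  }
  PX <- if (arch$useGraph) M %*% X else X

  set.seed(config$seed)
  params <- .initParams(ncol(X), arch, config,
                        leafInit = colMeans(y[trainIdx, , drop = FALSE]))
  # Adam state
  mState <- lapply(params, function(p) p * 0)
  vState <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  decayed <- c("W0", "W1", "headW")   # weight matrices only

  trainLoss <- numeric(config$epochs)
  valLoss <- numeric(config$epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  monitor <- length(valIdx) > 0L

  epoch <- 0L
  while (epoch < config$epochs) {
    epoch <- epoch + 1L
    cache <- .forward(params, PX, M, arch, dropout = config$dropout,
                      training = TRUE)
    grads <- .networkGradients(params, cache, PX, M, arch, y, trainIdx,
                               config$dropout)
    for (nm in names(params)) {
      if (!length(params[[nm]])) next
      g <- grads[[nm]]
      if (nm %in% decayed && config$weightDecay > 0)
        g <- g + config$weightDecay * params[[nm]]
      mState[[nm]] <- b1 * mState[[nm]] + (1 - b1) * g
      vState[[nm]] <- b2 * vState[[nm]] + (1 - b2) * g * g
      mHat <- mState[[nm]] / (1 - b1^epoch)
      vHat <- vState[[nm]] / (1 - b2^epoch)
      params[[nm]] <- params[[nm]] - config$lr * mHat / (sqrt(vHat) + adamEps)
    }
    evalG <- .forward(params, PX, M, arch)$G
    trainLoss[epoch] <- .maskedLoss(evalG, y, trainIdx)
    if (!is.finite(trainLoss[epoch]))
      stop("training diverged at epoch ", epoch,
           " (non-finite loss); lower the learning rate")
    if (monitor) {
      valLoss[epoch] <- .maskedLoss(evalG, y, valIdx)
      if (valLoss[epoch] < best$loss - 1e-12) {
        best <- list(loss = valLoss[epoch], params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (monitor && is.finite(best$loss)) params <- best$params
  history <- list(train = trainLoss[seq_len(epoch)],
                  val = if (monitor) valLoss[seq_len(epoch)] else numeric(0),
                  bestEpoch = if (monitor) best$epoch else epoch,
                  epochs = epoch)

  new("GTModel", method = method,
      W0 = params$W0, W1 = params$W1, b0 = params$b0, b1 = params$b1,
      headW = params$headW, headB = params$headB,
      leaves = params$leaves,
      depth = if (arch$treeHead) arch$depth else 0L,
      taus = as.numeric(tauGrid), config = config, history = history)
}
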