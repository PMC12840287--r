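#' @include train.R simulate.R pseudo.R
NULL

#' Test-set RMST prediction metrics
#'
#' Computes the evaluation metrics with the per-subject sum over horizons
#' averaged over subjects:
#' \deqn{MSE = \frac{1}{n}\sum_i \sum_k (\hat y_{ik} - g_{ik})^2, \qquad
#'       MAE = \frac{1}{n}\sum_i \sum_k |\hat y_{ik} - g_{ik}|.}
#' Note the denominator is n, not nK (the training loss of [gtTrain()]
#' divides by nK); for K = 1 the two conventions agree.
#'
#' @param pred n x K predictions.
#' @param observed n x K observed (pseudo-value) RMSTs.
#' @return named numeric vector with elements `mse` and `mae`.
#' @export
rmstMetrics <- function(pred, observed) {
  pred <- as.matrix(pred); observed <- as.matrix(observed)
  if (!all(dim(pred) == dim(observed))) stop("rmstMetrics: shape mismatch")
  r <- observed - pred
  c(mse = mean(rowSums(r * r)), mae = mean(rowSums(abs(r))))
}

#' Train/validation/test split
#'
#' One fold of the evaluation scheme: 20% of subjects held out as the test
#' set, 10% of the remaining training portion as the validation set.
#' `makeFolds` returns all five rotations (every subject appears in exactly
#' one test fold); `makeSplit` returns one of them. Deterministic given the
#' seed.
#'
#' @param n number of subjects (>= 10).
#' @param seed RNG seed.
#' @param fold which rotation to return (1-5).
#' @return list with integer vectors `train`, `val`, `test`.
#' @export
makeSplit <- function(n, seed, fold = 1L) {
  makeFolds(n, seed)[[fold]]
}

#' @rdname makeSplit
#' @export
makeFolds <- function(n, seed) {
  stopifnot(n >= 10)
  set.seed(seed)
  perm <- sample.int(n)
  bounds <- round(seq(0, n, length.out = 6L))
  lapply(seq_len(5L), function(f) {
    test <- sort(perm[(bounds[f] + 1L):bounds[f + 1L]])
    trainval <- perm[-((bounds[f] + 1L):bounds[f + 1L])]
    nVal <- max(1L, round(0.1 * length(trainval)))
    list(train = sort(trainval[-seq_len(nVal)]),
         val = sort(trainval[seq_len(nVal)]),
         test = test)
  })
}

.nParams <- function(p, hidden, depth, K, treeHead) {
  h1 <- hidden[1]; h2 <- hidden[2]
  base <- p * h1 + h1 * h2
  if (treeHead) base + h2 * (2^depth - 1) + (2^depth - 1) + 2^depth * K
  else base + h2 * K + K
}

#' Hyperparameter grid search on the validation fold
#'
#' Exhaustively trains every combination of neighbourhood size, hidden
#' widths and tree depth, and returns the configuration with the smallest
#' validation MSE. Ties are broken by smaller parameter count, then by
#' listed order.
#'
#' @param X covariate matrix or [IntervalSurv-class].
#' @param pseudo a [PseudoValues-class].
#' @param split a split from [makeSplit()].
#' @param method architecture to tune (see [gtTrain()]).
#' @param knGrid candidate neighbourhood sizes.
#' @param hiddenGrid list of candidate hidden-width pairs.
#' @param depthGrid candidate tree depths.
#' @param config base configuration (lr, epochs, dropout, ...).
#' @return list with elements `config` (the winning [gtConfig()]), `valMSE`
#'   and `table` (all candidates with their validation MSE).
#' @export
gridSearch <- function(X, pseudo, split, method = "gt",
                       knGrid = c(5L, 10L, 15L, 20L),
                       hiddenGrid = list(c(64L, 32L), c(128L, 64L),
                                         c(256L, 128L)),
                       depthGrid = c(2L, 3L, 4L, 5L),
                       config = gtConfig()) {
  if (is(X, "IntervalSurv")) X <- features(X)
  useGraph <- method %in% c("gt", "gcn")
  treeHead <- method %in% c("gt", "ndf")
  if (!useGraph) knGrid <- knGrid[1]
  if (!treeHead) depthGrid <- depthGrid[1]
  K <- length(taus(pseudo))
  rows <- list(); iRow <- 0L
  best <- NULL
  for (kn in knGrid) {
    graph <- if (useGraph) patientGraph(X, kn) else NULL
    for (hidden in hiddenGrid) for (depth in depthGrid) {
      cfg <- config
      cfg$kn <- as.integer(kn); cfg$hidden <- as.integer(hidden)
      cfg$depth <- as.integer(depth)
      fit <- tryCatch(
        gtTrain(X, pseudo, graph, method = method,
                trainIdx = split$train, valIdx = split$val, config = cfg),
        error = function(e) NULL)
      val <- if (is.null(fit)) Inf else min(fit@history$val)
      np <- .nParams(ncol(X), hidden, depth, K, treeHead)
      iRow <- iRow + 1L
      rows[[iRow]] <- data.frame(kn = kn, h1 = hidden[1], h2 = hidden[2],
                                 depth = depth, valMSE = val, nParams = np)
      if (is.finite(val) &&
          (is.null(best) || val < best$valMSE ||
           (val == best$valMSE && np < best$nParams)))
        best <- list(config = cfg, valMSE = val, nParams = np)
    }
  }
  if (is.null(best)) stop("grid search: every candidate diverged")
  list(config = best$config, valMSE = best$valMSE,
       table = do.call(rbind, rows))
}

#' Variance and information-gain feature screening
#'
#' Optional preprocessing for very high-dimensional inputs: removes columns
#' whose variance falls below the given quantile of all column variances,
#' ranks the survivors by the information gain of the quartile-discretised
#' outcome given the quartile-discretised feature, and keeps the top `topM`.
#'
#' @param X covariate matrix.
#' @param outcome numeric outcome vector (e.g. a pseudo-value column).
#' @param topM number of features to keep.
#' @param varQuantile variance-quantile threshold for the low-variation
#'   filter.
#' @return integer vector of selected column indices (information-gain
#'   order, descending).
#' @export
screenFeatures <- function(X, outcome, topM, varQuantile = 0.1) {
  stopifnot(topM >= 1)
  vars <- apply(X, 2, stats::var)
  keep <- unname(which(vars > stats::quantile(vars, varQuantile)))
  if (!length(keep)) keep <- unname(which(vars > 0))  # never drop everything
  yD <- .quartileBin(outcome)
  ig <- vapply(keep, function(j) .infoGain(yD, .quartileBin(X[, j])),
               numeric(1))
  if (topM > length(keep)) {
    warning("topM exceeds surviving columns; returning all ", length(keep))
    topM <- length(keep)
  }
  keep[order(-ig, keep)][seq_len(topM)]
}

.quartileBin <- function(x) {
  br <- unique(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1)))
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

.entropy <- function(f) {
  p <- table(f) / length(f)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.infoGain <- function(y, x) {
  hy <- .entropy(y)
  cond <- 0
  for (lev in levels(x)) {
    sel <- x == lev
    if (any(sel)) cond <- cond + mean(sel) * .entropy(y[sel])
  }
  hy - cond
}

#' Replicated simulation experiment
#'
#' The end-to-end harness: for each replication it simulates a cohort,
#' computes RMST pseudo-observations on the full cohort, draws the
#' train/validation/test split (identical for every method within a
#' replication), builds the patient graph, trains each requested method and
#' evaluates test-set MSE/MAE per [rmstMetrics()]. Replication r uses seed
#' `baseSeed + r` for every stochastic stream.
#'
#' In fast mode a fixed mid-grid configuration (`config`, default kn = 10,
#' hidden 64/32, depth 3) replaces the per-fold grid search.
#'
#' @param experiment simulation design (1, 2 or 3).
#' @param n,p cohort dimensions.
#' @param tauGrid RMST horizons.
#' @param reps number of replications.
#' @param methods architectures to compare (subset of gt, gcn, dnn, ndf).
#' @param baseSeed base seed.
#' @param config fixed configuration used in fast mode (also the base
#'   configuration for the grid search).
#' @param fast skip the grid search and use `config` as is.
#' @param knGrid,hiddenGrid,depthGrid grids used when `fast = FALSE`.
#' @param testTarget reference for the test metrics: `"true"` scores
#'   predictions against the generative conditional RMST
#'   (see [trueRMST()]), which is what a simulation study can and should
#'   measure; `"pseudo"` scores against the full-sample pseudo-values, the
#'   only option available on real data.
#' @param verbose print per-replication progress.
#' @return list with `perRep` (one row per method and successful
#'   replication), `summary` (means and SDs across replications), and
#'   `failures` (count of excluded replications).
#' @export
runExperiment <- function(experiment, n, p, tauGrid = 1, reps = 10L,
                          methods = c("gt", "gcn", "dnn"), baseSeed = 1L,
                          config = gtConfig(), fast = TRUE,
                          knGrid = c(5L, 10L, 15L, 20L),
                          hiddenGrid = list(c(64L, 32L), c(128L, 64L),
                                            c(256L, 128L)),
                          depthGrid = c(2L, 3L, 4L, 5L),
                          testTarget = c("true", "pseudo"),
                          verbose = FALSE) {
  stopifnot(reps >= 1)
  testTarget <- match.arg(testTarget)
  methods <- match.arg(methods, c("gt", "gcn", "dnn", "ndf"),
                       several.ok = TRUE)
  perRep <- list(); iRow <- 0L; failures <- 0L
  for (r in seq_len(reps)) {
    seed <- baseSeed + r
    res <- tryCatch({
      coh <- simulateCohort(n, p, experiment, seed = seed)
      X <- features(coh)
      pv <- pseudoRMST(cohortData(coh), tauGrid)
      target <- if (testTarget == "true") trueRMST(coh, tauGrid)
                else pseudoMatrix(pv)
      split <- makeSplit(n, seed)
      out <- list()
      for (mth in methods) {
        cfg <- config
        cfg$seed <- seed
        if (!fast) {
          gs <- gridSearch(X, pv, split, method = mth, knGrid = knGrid,
                           hiddenGrid = hiddenGrid, depthGrid = depthGrid,
                           config = cfg)
          cfg <- gs$config
        }
        graph <- if (mth %in% c("gt", "gcn")) patientGraph(X, cfg$kn)
                 else NULL
        fit <- gtTrain(X, pv, graph, method = mth,
                       trainIdx = split$train, valIdx = split$val,
                       config = cfg)
        pred <- predictRMST(fit, X, graph)
        mtr <- rmstMetrics(pred[split$test, , drop = FALSE],
                           target[split$test, , drop = FALSE])
        out[[mth]] <- data.frame(method = mth, rep = r, seed = seed,
                                 mse = mtr[["mse"]], mae = mtr[["mae"]])
      }
      do.call(rbind, out)
    }, error = function(e) {
      warning("replication ", r, " failed and was excluded: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L
    else { iRow <- iRow + 1L; perRep[[iRow]] <- res }
    if (verbose) message("replication ", r, "/", reps, " done")
  }
  if (!length(perRep)) stop("all replications failed")
  perRep <- do.call(rbind, perRep)
  rownames(perRep) <- NULL
  summary <- do.call(rbind, lapply(split(perRep, perRep$method), function(d)
    data.frame(method = d$method[1], reps = nrow(d),
               mse_mean = mean(d$mse), mse_sd = stats::sd(d$mse),
               mae_mean = mean(d$mae), mae_sd = stats::sd(d$mae))))
  rownames(summary) <- NULL
  list(perRep = perRep, summary = summary, failures = failures,
       settings = list(experiment = experiment, n = n, p = p,
                       tauGrid = tauGrid, reps = reps, baseSeed = baseSeed,
                       fast = fast))
}
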