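# Soft decision tree, GCN forward pass, loss, and gradient correctness.

makeToyModel <- function(method = "gt", n = 5, p = 3, K = 2, depth = 2,
                         hidden = c(4, 3), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- matrix(runif(n * K), n, K)
  g <- patientGraph(X, 2)
  arch <- GTsurv:::.arch(method, depth, K)
  cfg <- gtConfig(hidden = hidden, depth = depth, seed = seed)
  params <- GTsurv:::.initParams(p, arch, cfg, leafInit = colMeans(y))
  M <- normalizedAdjacency(g)
  PX <- if (arch$useGraph) M %*% X else X
  list(X = X, y = y, M = M, PX = PX, arch = arch, params = params)
}

test_that("routing probabilities form exact probability vectors", {
  # zero scores: uniform routing at every depth
  expect_equal(routingProbs(matrix(0, 3, 1), 1), matrix(0.5, 3, 2))
  expect_equal(routingProbs(matrix(0, 2, 3), 2), matrix(0.25, 2, 4))
  # saturated root routes everything left (d_e is the left probability)
  pr <- routingProbs(cbind(rep(50, 3)), 1)
  expect_equal(pr[, 1], rep(1, 3), tolerance = 1e-12)
  # rows sum to one for arbitrary scores and depths
  set.seed(4)
  for (depth in 1:4) {
    pr <- routingProbs(matrix(rnorm(6 * (2^depth - 1), sd = 3), 6), depth)
    expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-9)
    expect_true(all(pr > 0 & pr < 1))
  }
})

test_that("the GCN forward pass follows the propagation formula", {
  # identity graph and identity weights pass nonnegative X through
  n <- 4; p <- 3
  X <- abs(matrix(rnorm(n * p), n, p))
  arch <- GTsurv:::.arch("gcn", 1L, 1L)
  params <- list(W0 = diag(p), W1 = diag(p), b0 = numeric(0),
                 b1 = numeric(0), headW = matrix(1, p, 1), headB = 0,
                 leaves = matrix(numeric(0), 0, 0))
  out <- GTsurv:::.forward(params, X, diag(n), arch)
  expect_equal(out$H2, X)
  # zero input stays zero
  out0 <- GTsurv:::.forward(params, X * 0, diag(n), arch)
  expect_equal(out0$G, matrix(0, n, 1))
  # two-node complete graph averages the features: A-hat X = [[2],[2]]
  A <- normalizeAdjacency(rbind(c(0, 1), c(1, 0)))
  expect_equal(A %*% matrix(c(1, 3), 2, 1), matrix(2, 2, 1))
})

test_that("tree predictions stay in the convex hull of the leaves", {
  toy <- makeToyModel(depth = 3, K = 1, seed = 8)
  # constant leaves: constant prediction regardless of routing
  toy$params$leaves[] <- 0.7
  out <- GTsurv:::.forward(toy$params, toy$PX, toy$M, toy$arch)
  expect_equal(out$G, matrix(0.7, 5, 1), tolerance = 1e-12)
  # depth-1 fair split averages the two leaves
  pr <- routingProbs(matrix(0, 1, 1), 1)
  expect_equal(drop(pr %*% c(2, 6)), 4)
  # random leaves: min/max bound
  set.seed(9)
  toy$params$leaves <- matrix(rnorm(8), 8, 1)
  out <- GTsurv:::.forward(toy$params, toy$PX, toy$M, toy$arch)
  expect_true(all(out$G >= min(toy$params$leaves) - 1e-12))
  expect_true(all(out$G <= max(toy$params$leaves) + 1e-12))
})

test_that("the pseudo-value loss is the mean squared cell error", {
  expect_equal(pseudoLoss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  expect_equal(pseudoLoss(matrix(0, 1, 1), matrix(2, 1, 1)), 4)
  expect_equal(pseudoLoss(matrix(c(1, -1), 2, 1), matrix(0, 2, 1)), 1)
  expect_error(pseudoLoss(matrix(0, 2, 1), matrix(0, 1, 1)), "shape")
})

test_that("backpropagation matches finite differences for all methods", {
  for (method in c("gt", "gcn", "dnn", "ndf")) {
    toy <- makeToyModel(method, seed = 30 + match(method,
                        c("gt", "gcn", "dnn", "ndf")))
    idx <- 1:4
    cache <- GTsurv:::.forward(toy$params, toy$PX, toy$M, toy$arch)
    grads <- GTsurv:::.networkGradients(toy$params, cache, toy$PX, toy$M,
                                        toy$arch, toy$y, idx, 0)
    num <- numericGradient(function(p)
      GTsurv:::.lossFromParams(p, toy$PX, toy$M, toy$arch, toy$y, idx),
      toy$params)
    for (nm in names(toy$params)) {
      if (!length(toy$params[[nm]])) next
      scale <- max(1e-6, max(abs(num[[nm]])))
      expect_lt(max(abs(num[[nm]] - grads[[nm]])) / scale, 1e-5)
    }
  }
})

test_that("closed-form tree gradients match finite differences", {
  set.seed(44)
  for (r in 1:4) {
    n <- sample(3:5, 1); K <- sample(1:3, 1)
    depth <- sample(1:3, 1)
    FF <- matrix(rnorm(n * (2^depth - 1)), n)
    leaves <- matrix(rnorm(2^depth * K), 2^depth, K)
    y <- matrix(rnorm(n * K), n, K)
    G <- routingProbs(FF, depth) %*% leaves
    resid <- G - y
    cf <- treeGradients(FF, leaves, depth, resid)
    lossAt <- function(FFv, leavesv) {
      mean((routingProbs(FFv, depth) %*% leavesv - y)^2)
    }
    h <- 1e-5
    numNode <- FF * 0
    for (i in seq_len(n)) for (e in seq_len(2^depth - 1)) {
      up <- FF; up[i, e] <- up[i, e] + h
      dn <- FF; dn[i, e] <- dn[i, e] - h
      numNode[i, e] <- (lossAt(up, leaves) - lossAt(dn, leaves)) / (2 * h)
    }
    expect_lt(max(abs(numNode - cf$node)) / max(abs(numNode)), 1e-4)
    numLeaf <- leaves * 0
    for (l in seq_len(2^depth)) for (k in seq_len(K)) {
      up <- leaves; up[l, k] <- up[l, k] + h
      dn <- leaves; dn[l, k] <- dn[l, k] - h
      numLeaf[l, k] <- (lossAt(FF, up) - lossAt(FF, dn)) / (2 * h)
    }
    expect_lt(max(abs(numLeaf - cf$leaf)) / max(abs(numLeaf)), 1e-6)
  }
})

test_that("saturated decision nodes receive no gradient", {
  n <- 4; depth <- 2; K <- 1
  FF <- matrix(rnorm(n * 3), n, 3)
  FF[, 1] <- 40                      # root saturated left
  leaves <- matrix(rnorm(4), 4, 1)
  y <- matrix(rnorm(n), n, 1)
  resid <- routingProbs(FF, depth) %*% leaves - y
  cf <- treeGradients(FF, leaves, depth, resid)
  expect_lt(max(abs(cf$node[, 1])), 1e-12)
  # equal subtrees: zero gradient even at d_e = 0.5
  leavesEq <- matrix(1.3, 4, 1)
  residEq <- routingProbs(FF * 0, depth) %*% leavesEq - y
  cfEq <- treeGradients(FF * 0, leavesEq, depth, residEq)
  expect_equal(cfEq$node, matrix(0, n, 3), tolerance = 1e-14)
})

test_that("training fits representable targets and is seed-deterministic", {
  set.seed(10)
  X <- matrix(rnorm(80), 40, 2)
  g <- patientGraph(X, 5)
  # constant targets are representable by the leaves alone
  yc <- matrix(0.8, 40, 1)
  fit <- gtTrain(X, yc, g, method = "gt", trainIdx = 1:32, valIdx = 33:40,
                 config = gtConfig(hidden = c(8, 4), depth = 2,
                                   epochs = 300, seed = 5), tauGrid = 1)
  pred <- predictRMST(fit, X, g)
  expect_lt(mean((pred - 0.8)^2), 1e-3)
  # two separated clusters with distinct RMST: beat the constant predictor
  X2 <- rbind(matrix(rnorm(40, -3, 0.3), 20, 2),
              matrix(rnorm(40, 3, 0.3), 20, 2))
  y2 <- matrix(c(rep(0.3, 20), rep(0.9, 20)) + rnorm(40, sd = 0.02), 40, 1)
  g2 <- patientGraph(X2, 5)
  idx <- c(1:16, 21:36); val <- c(17:18, 37:38); test <- c(19:20, 39:40)
  fit2 <- gtTrain(X2, y2, g2, method = "gt", trainIdx = idx, valIdx = val,
                  config = gtConfig(hidden = c(8, 4), depth = 2,
                                    epochs = 500, seed = 5), tauGrid = 1)
  pred2 <- predictRMST(fit2, X2, g2)
  expect_lt(mean((pred2[test, ] - y2[test, ])^2), var(y2[idx, ]))
  # same seed, same result; training loss mostly decreasing
  fit2b <- gtTrain(X2, y2, g2, method = "gt", trainIdx = idx, valIdx = val,
                   config = gtConfig(hidden = c(8, 4), depth = 2,
                                     epochs = 500, seed = 5), tauGrid = 1)
  expect_identical(fit2@history$train, fit2b@history$train)
  expect_identical(predictRMST(fit2b, X2, g2), pred2)
  expect_gt(mean(diff(fit2@history$train) < 0), 0.5)
})

test_that("a GCN on an edgeless graph matches the bias-free dense network", {
  set.seed(12)
  n <- 10; p <- 3; K <- 2
  X <- matrix(rnorm(n * p), n, p)
  arch <- GTsurv:::.arch("gcn", 1L, K)
  cfg <- gtConfig(hidden = c(5, 4))
  set.seed(3)
  params <- GTsurv:::.initParams(p, arch, cfg, leafInit = rep(0, K))
  gOut <- GTsurv:::.forward(params, diag(n) %*% X, diag(n), arch)$G
  archD <- GTsurv:::.arch("dnn", 1L, K)
  paramsD <- params
  paramsD$b0 <- numeric(5); paramsD$b1 <- numeric(4)
  dOut <- GTsurv:::.forward(paramsD, X, NULL, archD)$G
  expect_equal(gOut, dOut)
})

test_that("checkpoints reload to bitwise-identical predictions", {
  toy <- makeToyModel(seed = 61)
  g <- patientGraph(toy$X, 2)
  fit <- gtTrain(toy$X, toy$y, g, method = "gt", trainIdx = 1:4,
                 valIdx = 5, config = gtConfig(hidden = c(4, 3), depth = 2,
                                               epochs = 30, seed = 2),
                 tauGrid = c(1, 2))
  f <- tempfile(fileext = ".rds")
  saveModel(fit, f)
  back <- loadModel(f)
  expect_identical(predictRMST(back, toy$X, g), predictRMST(fit, toy$X, g))
  expect_identical(back@config, fit@config)
})

test_that("training rejects inconsistent inputs", {
  toy <- makeToyModel(seed = 62)
  g <- patientGraph(toy$X, 2)
  expect_error(gtTrain(toy$X, toy$y, NULL, method = "gt", trainIdx = 1:4,
                       config = gtConfig(), tauGrid = c(1, 2)),
               "PatientGraph")
  expect_error(gtTrain(toy$X, toy$y, g, method = "gt", trainIdx = 1:4,
                       valIdx = 4, config = gtConfig(), tauGrid = c(1, 2)),
               "overlap")
  expect_error(gtTrain(toy$X, toy$y, g, method = "gt", trainIdx = 1:4,
                       config = c(gtConfig(), list(bogus = 1)),
                       tauGrid = c(1, 2)),
               "unknown")
})
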