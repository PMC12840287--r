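# Turnbull NPMLE via EM-ICM: grid construction, E-step, ICM step,
# likelihood, and full fits against analytic and brute-force oracles.

test_that("Turnbull membership covers the forced small examples", {
  s <- GTsurv:::.npmleState(c(0, 1), c(1, 2))
  expect_equal(s$pts, c(0, 1, 2))
  expect_equal(s$m, 2L)
  expect_equal(cbind(s$li, s$ri), cbind(c(1L, 2L), c(1L, 2L)))

  s2 <- GTsurv:::.npmleState(c(0, 1), c(2, 2))
  expect_equal(cbind(s2$li, s2$ri), cbind(c(1L, 2L), c(2L, 2L)))

  # exact times select the single interval ending at the event time
  s3 <- GTsurv:::.npmleState(c(1, 3), c(1, 3))
  expect_equal(cbind(s3$li, s3$ri), cbind(c(1L, 2L), c(1L, 2L)))

  # exact event at 0 has no admissible interval
  expect_error(GTsurv:::.npmleState(0, 0), "admissible")
})

test_that("membership representation agrees with the binary alpha matrix", {
  for (seed in 1:5) {
    d <- randomIntervalData(25, seed)
    s <- GTsurv:::.npmleState(leftBound(d), rightBound(d))
    alpha <- membershipMatrix(leftBound(d), rightBound(d))
    for (i in 1:25) {
      expect_equal(which(alpha[i, ] == 1L), seq(s$li[i], s$ri[i]))
    }
  }
})

test_that("the E-step implements the self-consistency update", {
  # disjoint intervals: uniform masses are a fixed point
  s <- GTsurv:::.npmleState(c(0, 1), c(1, 2))
  expect_equal(GTsurv:::.emStep(s, c(0.5, 0.5)), c(0.5, 0.5))
  # overlapping intervals, hand computation: d = (0.5, 1.5)
  s2 <- GTsurv:::.npmleState(c(0, 1), c(2, 2))
  expect_equal(GTsurv:::.emStep(s2, c(0.5, 0.5)), c(0.25, 0.75))
  # alpha all ones (every interval covers everything): any simplex rho is a
  # fixed point; state built by hand since such membership needs no support
  # point between the bounds
  s3 <- list(pts = c(0, 1, 2), q = 2L, hasInf = FALSE, m = 2L,
             li = c(1L, 1L, 1L), ri = c(2L, 2L, 2L), n = 3L)
  rho <- c(0.3, 0.7)
  expect_equal(GTsurv:::.emStep(s3, rho), rho)
  # expected event counts sum to n exactly
  for (seed in 1:5) {
    d <- randomIntervalData(30, seed)
    s <- GTsurv:::.npmleState(leftBound(d), rightBound(d))
    rho <- rep(1 / s$m, s$m)
    for (it in 1:3) {
      dcount <- GTsurv:::.emStep(s, rho) * s$n
      expect_equal(sum(dcount), s$n, tolerance = 1e-12)
      rho <- dcount / s$n
    }
  }
})

test_that("the log-likelihood matches direct evaluation", {
  s <- GTsurv:::.npmleState(c(0, 1), c(1, 2))
  expect_equal(GTsurv:::.logLikState(s, c(0.5, 0.5)), 2 * log(0.5))
  # one sample covering every interval has total mass 1: log-likelihood 0
  s2 <- list(pts = c(0, 1, 2), q = 2L, hasInf = FALSE, m = 2L,
             li = 1L, ri = 2L, n = 1L)
  expect_equal(GTsurv:::.logLikState(s2, c(0.4, 0.6)), 0)
  # zero mass on a sample's only interval gives -Inf
  s3 <- GTsurv:::.npmleState(c(0, 1), c(1, 2))
  expect_identical(GTsurv:::.logLikState(s3, c(1, 0)), -Inf)
})

test_that("the ICM step converges to analytic maximisers", {
  # L(rho) = log(rho1 + rho2) + log(rho2) is maximised at rho = (0, 1)
  s <- GTsurv:::.npmleState(c(0, 1), c(2, 2))
  rho <- c(0.5, 0.5)
  for (it in 1:200) rho <- GTsurv:::.icmStep(s, GTsurv:::.emStep(s, rho))
  expect_equal(rho, c(0, 1), tolerance = 1e-6)
  # stationary point stays put
  s2 <- GTsurv:::.npmleState(c(0, 1), c(1, 2))
  expect_equal(GTsurv:::.icmStep(s2, c(0.5, 0.5)), c(0.5, 0.5),
               tolerance = 1e-9)
})

test_that("fitNPMLE reduces to the empirical survival curve on exact data", {
  t <- c(1, 3)
  fit <- fitNPMLE(IntervalSurv(t, t, matrix(0, 2, 1)))
  expect_equal(survProb(fit, c(0.5, 1, 2, 3, 4)), c(1, 0.5, 0.5, 0, 0))
  expect_equal(rmst(fit, 2), 1.5)
  expect_equal(rmst(fit, 1.5), 1.25)
  set.seed(3)
  tt <- round(rexp(40), 3)
  fit2 <- fitNPMLE(IntervalSurv(tt, tt, matrix(0, 40, 1)))
  grid <- seq(0, max(tt) + 1, length.out = 97)
  emp <- vapply(grid, function(g) mean(tt > g), numeric(1))
  expect_equal(survProb(fit2, grid), emp, tolerance = 1e-9)
})

test_that("right-censored-only data place no mass before the censoring time", {
  fit <- fitNPMLE(IntervalSurv(rep(5, 4), rep(Inf, 4), matrix(0, 4, 1)))
  expect_equal(survProb(fit, c(1, 5)), c(1, 1))
  expect_true(fit@hasInf)
  expect_equal(rmst(fit, 5), 5)
})

test_that("the EM-ICM log-likelihood ascends and stays on the simplex", {
  for (seed in 1:6) {
    d <- randomIntervalData(35, seed)
    fit <- fitNPMLE(d)
    expect_true(all(diff(fit@trace) > -1e-9))   # likelihood ascent
    expect_true(all(fit@prob >= 0))
    expect_lt(abs(sum(fit@prob) - 1), 1e-10)
    expect_false(is.unsorted(fit@cdf + 1e-12))
    expect_true(fit@converged)
  }
})

test_that("fitNPMLE matches a dense simplex grid search on small instances", {
  cases <- list(
    list(L = c(0, 1), R = c(2, 2)),
    list(L = c(0, 1, 0), R = c(1, 2, 2)),
    list(L = c(0, 1, 2), R = c(2, 3, 3)),
    list(L = c(0.5, 0, 0), R = c(1, 0.5, 1))
  )
  for (cs in cases) {
    d <- IntervalSurv(cs$L, cs$R, matrix(0, length(cs$L), 1))
    fit <- fitNPMLE(d)
    oracle <- bruteForceSimplexLogLik(membershipMatrix(cs$L, cs$R))
    expect_lt(abs(fit@logLik - oracle), 1e-4)
  }
})

test_that("the NPMLE likelihood agrees with the survival package estimator", {
  library(survival)
  d <- randomIntervalData(60, 9)
  fit <- fitNPMLE(d)
  L <- leftBound(d); R <- rightBound(d)
  sf <- survfit(Surv(ifelse(L == 0, NA, L), ifelse(is.finite(R), R, NA),
                     type = "interval2") ~ 1)
  sfun <- stats::stepfun(sf$time, c(1, sf$surv))
  # masses that the survival package assigns to this package's Turnbull
  # intervals, evaluated under this package's likelihood
  st <- GTsurv:::.npmleState(L, R)
  q <- st$q
  loB <- sfun(st$pts[-length(st$pts)] + 1e-9)
  hiB <- sfun(st$pts[-1] + 1e-9)
  rhoSf <- pmax(loB - hiB, 0)
  if (st$hasInf) rhoSf <- c(rhoSf, max(0, 1 - sum(rhoSf)))
  rhoSf <- rhoSf / sum(rhoSf)
  llSf <- GTsurv:::.logLikState(st, pmax(rhoSf, 1e-12) /
                                  sum(pmax(rhoSf, 1e-12)))
  expect_lt(abs(fit@logLik - llSf), 1e-3)
  expect_gte(fit@logLik, llSf - 1e-3)   # never worse than the oracle
})

test_that("survCurve and writeSurvCurve export a valid step function", {
  d <- randomIntervalData(20, 5)
  fit <- fitNPMLE(d)
  sc <- survCurve(fit)
  expect_equal(sc$surv[1], 1)
  expect_true(all(diff(sc$surv) < 1e-12))
  expect_true(all(sc$surv >= 0 & sc$surv <= 1))
  f <- tempfile(fileext = ".csv")
  writeSurvCurve(fit, f)
  back <- read.csv(f)
  expect_equal(back$survival, sc$surv)
})
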