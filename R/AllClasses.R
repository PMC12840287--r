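#' @import methods
NULL

#' Interval-censored survival data with covariates
#'
#' Container for a cohort of subjects whose event times are only known to lie
#' in an observed interval \eqn{[L, R]}, together with a numeric covariate
#' matrix (subjects in rows). The censoring taxonomy is: \eqn{L = 0, R <
#' \infty} left-censored; \eqn{0 < L < R < \infty} strictly interval-censored;
#' \eqn{R = \infty} right-censored; \eqn{L = R} an exactly observed event
#' time.
#'
#' @slot left numeric vector of left interval bounds (\eqn{L \ge 0}).
#' @slot right numeric vector of right bounds; `Inf` encodes right censoring.
#' @slot features numeric matrix, one row per subject.
#' @slot ids character vector of subject identifiers.
#'
#' @seealso [IntervalSurv()] for the user-facing constructor,
#'   [fitNPMLE()], [pseudoRMST()].
#' @export
setClass("IntervalSurv",
  representation(
    left = "numeric",
    right = "numeric",
    features = "matrix",
    ids = "character"
  )
)

setValidity("IntervalSurv", function(object) {
  n <- length(object@left)
  msg <- character(0)
  if (length(object@right) != n)
    msg <- c(msg, "left and right bounds differ in length")
  if (nrow(object@features) != n)
    msg <- c(msg, "feature matrix must have one row per subject")
  if (length(object@ids) != n)
    msg <- c(msg, "ids must have one entry per subject")
  if (anyNA(object@left) || anyNA(object@right))
    msg <- c(msg, "interval bounds must not contain NA")
  if (n > 0 && any(object@left < 0))
    msg <- c(msg, "left bounds must be nonnegative")
  if (n > 0 && any(object@right < object@left))
    msg <- c(msg, "right bound below left bound")
  if (any(!is.finite(object@left)))
    msg <- c(msg, "left bounds must be finite")
  if (!is.numeric(object@features))
    msg <- c(msg, "features must be numeric")
  if (length(msg)) msg else TRUE
})

#' Turnbull NPMLE fit
#'
#' State of the nonparametric maximum-likelihood estimator of the survival
#' function for arbitrarily censored data. Probability mass `prob[j]` sits on
#' the Turnbull interval \eqn{(s_{j-1}, s_j]} between consecutive support
#' points; when `hasInf` is `TRUE` a terminal interval \eqn{(s_q, \infty)}
#' receives the mass that right-censored observations may push beyond the
#' last finite support point, and the survival curve plateaus there.
#'
#' The fitted survival function is the right-continuous step function
#' \eqn{\hat S(t) = 1 - \hat\beta_j} for \eqn{t \in [s_j, s_{j+1})}, i.e.
#' mass is placed at the right endpoint of each Turnbull interval, which
#' makes the estimator reduce exactly to the empirical survival function
#' when all observations are exact.
#'
#' @slot support ordered finite support points, starting at 0.
#' @slot hasInf logical; whether a terminal infinite interval carries mass.
#' @slot prob masses on the Turnbull intervals (simplex vector).
#' @slot cdf cumulative masses \eqn{\beta_j}.
#' @slot intervalIndex integer matrix (n x 2): first and last Turnbull
#'   interval covered by each observation.
#' @slot logLik final log-likelihood.
#' @slot trace log-likelihood after each outer EM-ICM iteration.
#' @slot converged logical.
#' @slot iterations number of outer iterations used.
#'
#' @seealso [fitNPMLE()], [survProb()], [rmst()]
#' @export
setClass("TurnbullFit",
  representation(
    support = "numeric",
    hasInf = "logical",
    prob = "numeric",
    cdf = "numeric",
    intervalIndex = "matrix",
    logLik = "numeric",
    trace = "numeric",
    converged = "logical",
    iterations = "integer"
  )
)

setValidity("TurnbullFit", function(object) {
  msg <- character(0)
  m <- length(object@prob)
  if (is.unsorted(object@support, strictly = TRUE))
    msg <- c(msg, "support must be strictly increasing")
  if (length(object@support) && object@support[1] != 0)
    msg <- c(msg, "support must start at 0")
  if (m != length(object@support) - 1L + as.integer(object@hasInf))
    msg <- c(msg, "prob length inconsistent with support")
  if (any(object@prob < -1e-12))
    msg <- c(msg, "negative interval mass")
  if (m > 0 && abs(sum(object@prob) - 1) > 1e-8)
    msg <- c(msg, "interval masses must sum to 1")
  if (length(object@cdf) != m || (m > 0 && is.unsorted(object@cdf + 1e-12)))
    msg <- c(msg, "cdf must be nondecreasing of length m")
  if (length(msg)) msg else TRUE
})

#' RMST jackknife pseudo-observations
#'
#' Matrix of per-subject pseudo-values \eqn{\tilde y_i(\tau_k) = n \hat\mu(\tau_k)
#' - (n-1)\hat\mu^{(-i)}(\tau_k)} together with the population RMST and
#' (optionally) the retained leave-one-out estimates. Pseudo-values may fall
#' outside \eqn{[0, \tau_k]}; they are deliberately not clipped.
#'
#' @slot values n x K matrix of pseudo-values.
#' @slot taus the K RMST horizons.
#' @slot popRMST population RMST \eqn{\hat\mu(\tau_k)} (length K).
#' @slot looRMST n x K matrix of leave-one-out RMSTs (may be 0 x 0).
#' @slot ids subject identifiers.
#' @export
setClass("PseudoValues",
  representation(
    values = "matrix",
    taus = "numeric",
    popRMST = "numeric",
    looRMST = "matrix",
    ids = "character"
  )
)

setValidity("PseudoValues", function(object) {
  msg <- character(0)
  K <- length(object@taus)
  if (ncol(object@values) != K)
    msg <- c(msg, "values must have one column per horizon")
  if (length(object@popRMST) != K)
    msg <- c(msg, "popRMST must have length K")
  if (K > 1 && is.unsorted(object@taus, strictly = TRUE))
    msg <- c(msg, "horizons must be strictly increasing")
  if (any(object@taus <= 0))
    msg <- c(msg, "horizons must be positive")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "pseudo-values must be finite")
  if (length(msg)) msg else TRUE
})

#' KNN patient-similarity graph
#'
#' Undirected unweighted graph over subjects: an edge joins i and j when one
#' is among the other's `k` nearest neighbours in Euclidean distance over the
#' covariates (union symmetrisation). Holds the binary adjacency \eqn{A}, and
#' the self-looped, degree-symmetric-normalised propagation matrix
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} used by the GCN.
#'
#' @slot adjacency binary symmetric matrix with zero diagonal.
#' @slot normalized the normalised self-looped adjacency \eqn{\hat A}.
#' @slot k neighbourhood size used.
#' @export
setClass("PatientGraph",
  representation(
    adjacency = "matrix",
    normalized = "matrix",
    k = "integer"
  )
)

setValidity("PatientGraph", function(object) {
  msg <- character(0)
  A <- object@adjacency
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  else {
    if (any(A != t(A))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
  }
  if (!all(dim(object@normalized) == dim(A)))
    msg <- c(msg, "normalized adjacency has wrong dimensions")
  if (length(msg)) msg else TRUE
})

#' Fitted RMST network model
#'
#' A trained predictor mapping covariates (propagated over the patient graph
#' for the GCN variants) to RMST predictions at K horizons. Four
#' architectures share this container:
#' \describe{
#'   \item{`"gt"`}{two GCN layers feeding a soft binary decision tree
#'     (the full hybrid model).}
#'   \item{`"gcn"`}{two GCN layers with a linear K-output head.}
#'   \item{`"dnn"`}{two fully connected layers with a linear head
#'     (no graph propagation).}
#'   \item{`"ndf"`}{two fully connected layers feeding the soft tree.}
#' }
#' For tree heads, `headW`/`headB` parameterise one shared affine map from
#' the last hidden layer to one routing score per internal node; `leaves`
#' holds the per-leaf RMST vectors \eqn{\lambda_{lk}}. For linear heads,
#' `headW`/`headB` are the output layer and `leaves` is empty.
#'
#' @slot method one of "gt", "gcn", "dnn", "ndf".
#' @slot W0,W1 hidden-layer weight matrices.
#' @slot b0,b1 hidden-layer biases (length 0 for the bias-free GCN layers).
#' @slot headW,headB head parameters (routing scores or linear output).
#' @slot leaves leaf RMST matrix (2^depth x K), empty for linear heads.
#' @slot depth tree depth (0 for linear heads).
#' @slot taus RMST horizons the model predicts.
#' @slot config training configuration used.
#' @slot history training history (loss traces, best epoch).
#' @export
setClass("GTModel",
  representation(
    method = "character",
    W0 = "matrix", W1 = "matrix",
    b0 = "numeric", b1 = "numeric",
    headW = "matrix", headB = "numeric",
    leaves = "matrix",
    depth = "integer",
    taus = "numeric",
    config = "list",
    history = "list"
  )
)

setValidity("GTModel", function(object) {
  msg <- character(0)
  if (!object@method %in% c("gt", "gcn", "dnn", "ndf"))
    msg <- c(msg, "unknown method")
  if (object@method %in% c("gt", "ndf")) {
    if (object@depth < 1L) msg <- c(msg, "tree head requires depth >= 1")
    else {
      if (ncol(object@headW) != 2^object@depth - 1L)
        msg <- c(msg, "headW must have one column per internal node")
      if (nrow(object@leaves) != 2^object@depth)
        msg <- c(msg, "leaves must have 2^depth rows")
      if (ncol(object@leaves) != length(object@taus))
        msg <- c(msg, "leaves must have one column per horizon")
    }
  } else if (ncol(object@headW) != length(object@taus)) {
    msg <- c(msg, "linear head must emit one output per horizon")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated interval-censored cohort
#'
#' Output of the simulation engine: the observable [IntervalSurv-class]
#' object plus the latent event times, the censoring class of each subject
#' and the generative nuisance quantities (linear coefficients, clamp count)
#' retained for testing.
#'
#' @slot data the observable interval-censored dataset.
#' @slot trueTime latent event times \eqn{T_i}.
#' @slot censorClass factor with levels left/interval/right.
#' @slot rate subject-specific exponential rates \eqn{\eta(X_i)} (after
#'   clamping).
#' @slot gamma linear coefficients (experiments 2-3; length 0 otherwise).
#' @slot clamped number of subjects whose rate was clamped at the floor.
#' @slot experiment experiment id (1, 2 or 3).
#' @slot seed,gammaSeed seeds used.
#' @export
setClass("SimulatedCohort",
  representation(
    data = "IntervalSurv",
    trueTime = "numeric",
    censorClass = "factor",
    rate = "numeric",
    gamma = "numeric",
    clamped = "integer",
    experiment = "integer",
    seed = "integer",
    gammaSeed = "integer"
  )
)

setValidity("SimulatedCohort", function(object) {
  n <- length(object@data@left)
  msg <- character(0)
  if (length(object@trueTime) != n)
    msg <- c(msg, "trueTime length mismatch")
  if (length(object@censorClass) != n)
    msg <- c(msg, "censorClass length mismatch")
  if (n > 0 && (any(object@trueTime < object@data@left) ||
                any(object@trueTime > object@data@right)))
    msg <- c(msg, "latent time outside observed interval")
  if (length(msg)) msg else TRUE
})
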