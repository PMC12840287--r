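#' @include AllClasses.R
NULL

#' Number of subjects
#' @param x an object holding a cohort.
#' @return integer count.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Number of covariates
#' @param x an object holding a covariate matrix.
#' @return integer count.
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Covariate matrix accessor
#' @param x an object holding a covariate matrix.
#' @return numeric matrix, subjects in rows.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' Left interval bounds
#' @param x an [IntervalSurv-class] or derived object.
#' @return numeric vector.
#' @export
setGeneric("leftBound", function(x) standardGeneric("leftBound"))

#' Right interval bounds
#' @param x an [IntervalSurv-class] or derived object.
#' @return numeric vector (`Inf` for right-censored subjects).
#' @export
setGeneric("rightBound", function(x) standardGeneric("rightBound"))

#' Censoring class of each subject
#' @param x an [IntervalSurv-class] or [SimulatedCohort-class] object.
#' @return factor with levels left, interval, right, exact.
#' @export
setGeneric("censorClass", function(x) standardGeneric("censorClass"))

#' Evaluate a fitted survival curve
#' @param fit a fitted survival estimator.
#' @param times numeric vector of evaluation times.
#' @return numeric vector of survival probabilities \eqn{\hat S(t)}.
#' @export
setGeneric("survProb", function(fit, times) standardGeneric("survProb"))

#' Restricted mean survival time of a fitted curve
#'
#' Exact integral of the fitted step survival function over \eqn{[0, \tau]}.
#' @param fit a fitted survival estimator.
#' @param tau positive horizon (may be a vector).
#' @return numeric vector of \eqn{\hat\mu(\tau) = \int_0^\tau \hat S(t) dt}.
#' @export
setGeneric("rmst", function(fit, tau) standardGeneric("rmst"))

#' Pseudo-value matrix accessor
#' @param x a [PseudoValues-class] object.
#' @return n x K numeric matrix.
#' @export
setGeneric("pseudoMatrix", function(x) standardGeneric("pseudoMatrix"))

#' Population RMST accessor
#' @param x a [PseudoValues-class] object.
#' @return numeric vector of \eqn{\hat\mu(\tau_k)}.
#' @export
setGeneric("popRMST", function(x) standardGeneric("popRMST"))

#' RMST horizons accessor
#' @param x an object carrying a horizon grid.
#' @return numeric vector of horizons.
#' @export
setGeneric("taus", function(x) standardGeneric("taus"))

#' Binary adjacency accessor
#' @param x a [PatientGraph-class].
#' @return binary symmetric matrix with zero diagonal.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Normalised self-looped adjacency accessor
#' @param x a [PatientGraph-class].
#' @return the propagation matrix \eqn{\hat A}.
#' @export
setGeneric("normalizedAdjacency",
           function(x) standardGeneric("normalizedAdjacency"))

#' Latent event times of a simulated cohort
#' @param x a [SimulatedCohort-class].
#' @return numeric vector.
#' @export
setGeneric("trueTimes", function(x) standardGeneric("trueTimes"))

#' Predict RMST at the model's horizons
#'
#' Runs the forward pass (no dropout) over all subjects and returns the
#' predicted RMST matrix.
#' @param model a fitted [GTModel-class].
#' @param X covariate matrix (all subjects, the same ordering used to build
#'   the graph).
#' @param graph a [PatientGraph-class]; ignored by graph-free architectures.
#' @return n x K matrix of predicted RMSTs.
#' @export
setGeneric("predictRMST",
           function(model, X, graph = NULL) standardGeneric("predictRMST"))
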