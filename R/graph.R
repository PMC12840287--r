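#' @include AllGenerics.R
NULL

#' Pairwise Euclidean distances between subjects
#'
#' @param X numeric matrix, subjects in rows.
#' @return symmetric n x n matrix \eqn{D_{ij} = \sqrt{\sum_m (X_{im}-X_{jm})^2}}
#'   with zero diagonal.
#' @export
pairwiseDistances <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X)))
    stop("pairwiseDistances: X must be finite")
  as.matrix(stats::dist(X, method = "euclidean"))
}

#' Union-symmetrised KNN adjacency
#'
#' Builds the binary adjacency of the patient-similarity graph: an
#' undirected, uniformly weighted edge joins i and j if one is among the
#' other's `k` nearest neighbours (union symmetrisation, not mutual KNN).
#' Distance ties are broken by ascending subject index so the graph is
#' deterministic across runs and platforms.
#'
#' @param D symmetric nonnegative distance matrix.
#' @param k neighbourhood size, between 1 and n - 1.
#' @return binary symmetric matrix with zero diagonal.
#' @export
knnAdjacency <- function(D, k) {
  n <- nrow(D)
  if (k < 1L || k > n - 1L) stop("knnAdjacency: k must be in [1, n - 1]")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf                               # exclude self
    nb <- order(d, seq_len(n))[seq_len(k)]    # stable tie-break by index
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                          # union symmetrisation
  diag(A) <- 0
  A
}

#' Symmetric normalisation of a self-looped adjacency
#'
#' Computes the GCN propagation matrix
#' \eqn{\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}}, where
#' \eqn{\tilde D} is the diagonal degree matrix of \eqn{A + I}. All
#' eigenvalues of \eqn{\hat A} lie in \eqn{[-1, 1]}.
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @return the normalised matrix \eqn{\hat A}.
#' @export
normalizeAdjacency <- function(A) {
  At <- A + diag(nrow(A))
  dInv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dInv)
}

#' Build the KNN patient-similarity graph
#'
#' Combines [pairwiseDistances()], [knnAdjacency()] and
#' [normalizeAdjacency()]. The graph is transductive: it is built over all
#' subjects supplied (training and test alike), since graph propagation at
#' prediction time needs every node. Features are used as given; any
#' standardisation is the caller's responsibility.
#'
#' @param X covariate matrix (subjects in rows) or an [IntervalSurv-class].
#' @param k neighbourhood size.
#' @return a [PatientGraph-class] object.
#' @examples
#' g <- patientGraph(matrix(c(0, 1, 3), 3, 1), k = 1)
#' adjacency(g)
#' @export
patientGraph <- function(X, k) {
  if (is(X, "IntervalSurv")) X <- features(X)
  D <- pairwiseDistances(X)
  A <- knnAdjacency(D, as.integer(k))
  new("PatientGraph", adjacency = A, normalized = normalizeAdjacency(A),
      k = as.integer(k))
}

#' @rdname adjacency
#' @export
setMethod("adjacency", "PatientGraph", function(x) x@adjacency)

#' @rdname normalizedAdjacency
#' @export
setMethod("normalizedAdjacency", "PatientGraph", function(x) x@normalized)

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "PatientGraph", function(x) nrow(x@adjacency))

setMethod("show", "PatientGraph", function(object) {
  cat("PatientGraph:", nSubjects(object), "nodes,",
      sum(object@adjacency) / 2, "edges (k =", object@k, ")\n")
})

#' Export the graph as an edge list
#'
#' @param graph a [PatientGraph-class].
#' @param zeroBased use 0-based node indices (default), for external tools.
#' @return data.frame with columns `i`, `j`, one row per undirected edge
#'   (i < j).
#' @export
edgeList <- function(graph, zeroBased = TRUE) {
  idx <- which(upper.tri(graph@adjacency) & graph@adjacency == 1,
               arr.ind = TRUE)
  off <- if (zeroBased) 1L else 0L
  data.frame(i = idx[, 1] - off, j = idx[, 2] - off)
}
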