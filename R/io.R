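#' @include npmle.R pseudo.R
NULL

## delimited-table dialect: comma-separated, header row, "." decimal;
## right bound "", "inf" or "Inf" means +infinity; L == R marks an exact time

#' Read interval-censored data from delimited tables
#'
#' The intervals table must have columns `id`, `L`, `R`; `R` may be empty,
#' `"inf"` or `"Inf"` for right censoring. The optional features table needs
#' an `id` column followed by numeric covariates; rows are matched to the
#' intervals by id.
#'
#' @param intervalsPath path to the intervals table.
#' @param featuresPath optional path to the covariate table.
#' @return an [IntervalSurv-class] object.
#' @export
readIntervalData <- function(intervalsPath, featuresPath = NULL) {
  tab <- utils::read.csv(intervalsPath, colClasses = "character")
  need <- c("id", "L", "R")
  if (!all(need %in% names(tab)))
    stop("intervals table must have columns id, L, R")
  L <- as.numeric(tab$L)
  Rraw <- trimws(tab$R)
  R <- ifelse(Rraw == "" | tolower(Rraw) == "inf", Inf,
              suppressWarnings(as.numeric(Rraw)))
  bad <- which(is.na(L) | is.na(R) | R < L | L < 0)
  if (length(bad))
    stop("invalid interval on line ", bad[1] + 1L, " of ", intervalsPath,
         " (need 0 <= L <= R)")
  X <- matrix(0, length(L), 0)
  if (!is.null(featuresPath)) {
    ft <- utils::read.csv(featuresPath)
    if (!"id" %in% names(ft)) stop("features table must have an id column")
    idx <- match(tab$id, as.character(ft$id))
    if (anyNA(idx)) stop("features table is missing some subject ids")
    X <- as.matrix(ft[idx, setdiff(names(ft), "id"), drop = FALSE])
  }
  IntervalSurv(L, R, X, ids = tab$id)
}

#' Write interval-censored data
#' @param data an [IntervalSurv-class].
#' @param path output path for the intervals table.
#' @return the path, invisibly.
#' @export
writeIntervalData <- function(data, path) {
  tab <- data.frame(id = data@ids, L = data@left,
                    R = ifelse(is.finite(data@right), data@right, "inf"))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a covariate table
#' @param data an [IntervalSurv-class] (or matrix with an `ids` attribute).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatures <- function(data, path) {
  X <- features(data)
  colnames(X) <- if (is.null(colnames(X))) paste0("x", seq_len(ncol(X)))
                 else colnames(X)
  utils::write.csv(data.frame(id = data@ids, X, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pseudo-values as a long table
#'
#' Columns: `id`, `tau`, `pseudo_value`.
#' @param pv a [PseudoValues-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePseudoValues <- function(pv, path) {
  v <- pseudoMatrix(pv)
  tab <- data.frame(id = rep(pv@ids, times = ncol(v)),
                    tau = rep(taus(pv), each = nrow(v)),
                    pseudo_value = as.vector(v))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pseudo-value table back into a matrix
#' @param path path to a table written by [writePseudoValues()].
#' @return a [PseudoValues-class] with an empty leave-one-out slot.
#' @export
readPseudoValues <- function(path) {
  tab <- utils::read.csv(path)
  tt <- sort(unique(tab$tau))
  ids <- unique(tab$id)
  v <- matrix(NA_real_, length(ids), length(tt),
              dimnames = list(ids, paste0("tau", tt)))
  v[cbind(match(tab$id, ids), match(tab$tau, tt))] <- tab$pseudo_value
  if (anyNA(v)) stop("pseudo-value table is not a complete id x tau grid")
  new("PseudoValues", values = v, taus = tt,
      popRMST = colMeans(v), looRMST = matrix(numeric(0), 0, 0),
      ids = as.character(ids))
}

#' Write a fitted survival curve
#' @param fit a [TurnbullFit-class].
#' @param path output path (columns `time`, `survival`).
#' @return the path, invisibly.
#' @export
writeSurvCurve <- function(fit, path) {
  sc <- survCurve(fit)
  utils::write.csv(data.frame(time = sc$time, survival = sc$surv), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
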