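#' Validate and normalize a similarity matrix
#'
#' The universal currency of this package is a symmetric, non-negative
#' `n x n` similarity matrix with unique row/column identifiers. The
#' diagonal carries no information (self-similarity is undefined for
#' Dasgupta's objective, which sums over unordered pairs only) and is
#' forced to zero on validation.
#'
#' @param W numeric matrix, symmetric with non-negative off-diagonal
#'   entries, `n >= 2`. If it has no dimnames, identifiers
#'   `item001, item002, ...` are attached.
#' @param ids optional character vector of identifiers to attach
#'   (overrides existing dimnames).
#' @return the validated matrix with zeroed diagonal and matching
#'   row/column names.
#' @export
as_similarity <- function(W, ids = NULL) {
  if (!is.matrix(W)) W <- as.matrix(W)
  storage.mode(W) <- "double"
  n <- nrow(W)
  if (n < 2L || ncol(W) != n) {
    stop("similarity matrix must be square with n >= 2, got ",
         n, " x ", ncol(W))
  }
  if (anyNA(W) || any(!is.finite(W))) {
    stop("similarity matrix contains NA/NaN/Inf values")
  }
  if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W)))) {
    stop("similarity matrix is not symmetric")
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (any(W < 0)) stop("similarity matrix has negative off-diagonal entries")
  if (!is.null(ids)) {
    if (length(ids) != n) stop("ids length does not match matrix dimension")
    dimnames(W) <- list(ids, ids)
  } else if (is.null(rownames(W))) {
    ids <- sprintf("item%03d", seq_len(n))
    dimnames(W) <- list(ids, ids)
  } else {
    colnames(W) <- rownames(W)
  }
  if (anyDuplicated(rownames(W))) stop("similarity matrix ids are not unique")
  W
}

#' Reorder a similarity matrix to a given identifier order
#'
#' @param W validated similarity matrix.
#' @param ids character vector; must be a permutation of `rownames(W)`.
#' @return `W` with rows and columns in the order of `ids`.
#' @export
align_similarity <- function(W, ids) {
  have <- rownames(W)
  if (is.null(have)) stop("similarity matrix has no identifiers")
  if (length(ids) != length(have) || !setequal(ids, have)) {
    stop("identifier mismatch between similarity matrix and requested ids")
  }
  W[ids, ids, drop = FALSE]
}

#' Gaussian-kernel similarity from a feature matrix
#'
#' Converts pairwise Euclidean distances to similarities via
#' `S = exp(-d^2 / (2 sigma^2))`. The bandwidth defaults to the median
#' off-diagonal distance, a standard parameter-free heuristic.
#'
#' @param X numeric feature matrix (rows = items).
#' @param sigma optional positive bandwidth; default median off-diagonal
#'   Euclidean distance.
#' @return a similarity matrix (diagonal zero) with ids from `rownames(X)`.
#' @export
gaussian_kernel_similarity <- function(X, sigma = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 items")
  D <- as.matrix(stats::dist(X))
  if (is.null(sigma)) sigma <- stats::median(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0) {
    stop("Gaussian kernel bandwidth must be positive; ",
         "identical points give a zero median distance")
  }
  S <- exp(-D^2 / (2 * sigma^2))
  diag(S) <- 0
  as_similarity(S, ids = rownames(X))
}

#' Hamming similarity for categorical features
#'
#' `S = 1 - (fraction of mismatched features)`; every column is treated
#' as categorical, including numeric-coded ones.
#'
#' @param X matrix or data frame of categorical features (rows = items).
#' @return a similarity matrix in `[0, 1]` with zero diagonal.
#' @export
hamming_similarity <- function(X) {
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  n <- nrow(X)
  d <- ncol(X)
  if (d == 0L) stop("Hamming similarity needs at least one feature")
  if (n < 2L) stop("need at least 2 items")
  mism <- matrix(0, n, n)
  for (j in seq_len(d)) {
    v <- as.character(X[[j]])
    mism <- mism + outer(v, v, FUN = "!=")
  }
  S <- 1 - mism / d
  diag(S) <- 0
  as_similarity(S, ids = rownames(X))
}
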