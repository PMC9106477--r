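#' Mean training image
#'
#' The elementwise average \eqn{\psi = (1/M) \sum_i \Gamma_i} of the
#' flattened training images.
#'
#' @param X d x M numeric matrix, one flattened image per column
#'   (row-major flattening of N x N inputs to length N^2).
#' @return Numeric vector of length d.
#' @export
meanImage <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("meanImage: empty training set")
  rowMeans(X)
}

#' Center a training set
#'
#' Subtracts the mean image from every column:
#' \eqn{\Phi_i = \Gamma_i - \psi}. When \code{psi} is the set's own mean,
#' the rows of the result sum to zero.
#'
#' @param X d x M matrix of flattened images.
#' @param psi mean image of length d (default: computed from \code{X}).
#' @return The d x M difference matrix A.
#' @export
centerImages <- function(X, psi = meanImage(X)) {
  X <- as.matrix(X)
  if (length(psi) != nrow(X)) stop("centerImages: psi has wrong length")
  sweep(X, 1L, psi)
}

#' Snapshot covariance
#'
#' The small M x M Gram matrix \eqn{C = A^T A} of the centered image matrix,
#' symmetric positive semidefinite; its nonzero eigenvalues equal those of
#' the huge d x d covariance \eqn{A A^T}.
#'
#' @param A d x M centered image matrix from [centerImages()].
#' @return M x M matrix.
#' @export
snapshotCovariance <- function(A) {
  crossprod(as.matrix(A))
}

#' Total scatter matrix
#'
#' \eqn{S_T = \sum_k (x_k - \mu)(x_k - \mu)^T}; when \code{mu} is the sample
#' mean this equals \eqn{A A^T} of the centered matrix. Only sensible at
#' small d (it is d x d) — the snapshot route covers the large-d case.
#'
#' @param X d x M sample matrix (columns are samples).
#' @param mu center vector (default: sample mean).
#' @return d x d matrix.
#' @export
totalScatter <- function(X, mu = meanImage(X)) {
  A <- centerImages(X, mu)
  tcrossprod(A)
}

#' Snapshot eigen-decomposition
#'
#' Diagonalizes the M x M snapshot covariance and lifts its eigenvectors to
#' image space via \eqn{U_i = A V_i}, normalizing each to unit length; the
#' top-f eigenimages (by eigenvalue) form the component matrix. The lifted
#' nonzero spectrum equals that of the direct d x d decomposition.
#'
#' @param C M x M snapshot covariance from [snapshotCovariance()].
#' @param A the d x M centered matrix that produced \code{C}.
#' @param f number of components to retain; at most M - 1 (the rank bound
#'   for a centered set).
#' @param tau detection threshold stored in the model (default 1; usually
#'   set later by [trainEigenModel()]).
#' @return An [EigenModel-class].
#' @export
eigenDecompose <- function(C, A, f, tau = 1) {
  C <- as.matrix(C); A <- as.matrix(A)
  M <- ncol(A)
  if (f > M - 1L && M > 1L) stop("f exceeds the rank bound M - 1")
  if (f < 1L) stop("f must be at least 1")
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  U <- A %*% e$vectors                      # lift: U_i = A V_i
  nrm <- sqrt(colSums(U^2))
  keep <- which(nrm > 1e-12)[seq_len(f)]
  if (anyNA(keep)) stop("requested f exceeds the numerical rank of C")
  W <- t(U[, keep, drop = FALSE] / rep(nrm[keep], each = nrow(U)))
  new("EigenModel", mean = numeric(nrow(A)), components = W,
      eigenvalues = lambda[keep], f = as.integer(f), tau = as.numeric(tau))
}

#' Train an eigenimage model
#'
#' The full snapshot-PCA route: mean image, centered differences, M x M
#' covariance, lifted orthonormal eigenimages. The retained dimension f
#' defaults to the smallest f capturing at least \code{varExplained} of the
#' total eigenvalue mass (capped at M - 1); the detection threshold tau
#' defaults to 3x the median nearest-neighbor distance among the projected
#' training images.
#'
#' @param X d x M matrix of flattened training images (columns).
#' @param f retained dimension; \code{NULL} for the variance rule.
#' @param varExplained eigenvalue-mass fraction for the default f (0.95).
#' @param tau detection threshold; \code{NULL} for the gallery rule.
#' @return An [EigenModel-class] with its training-set \code{mean} filled in.
#' @examples
#' X <- matrix(rnorm(16 * 5), 16, 5)
#' m <- trainEigenModel(X)
#' m
#' @export
trainEigenModel <- function(X, f = NULL, varExplained = 0.95, tau = NULL) {
  X <- as.matrix(X)
  M <- ncol(X)
  if (M < 2L) stop("trainEigenModel: need at least 2 images")
  psi <- meanImage(X)
  A <- centerImages(X, psi)
  C <- snapshotCovariance(A)
  lambda <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
  rank <- sum(lambda > max(lambda) * 1e-10)
  rank <- min(rank, M - 1L)
  if (rank < 1L) stop("trainEigenModel: degenerate training set (zero variance)")
  if (is.null(f)) {
    cum <- cumsum(lambda[seq_len(rank)]) / sum(lambda[seq_len(rank)])
    f <- which(cum >= varExplained)[1]
  }
  f <- min(as.integer(f), rank)
  model <- eigenDecompose(C, A, f)
  model@mean <- psi
  gallery <- projectSet(X, model)
  if (is.null(tau)) {
    if (M >= 2L) {
      dm <- as.matrix(stats::dist(t(gallery)))
      diag(dm) <- Inf
      nn <- apply(dm, 1L, min)
      tau <- 3 * stats::median(nn)
      if (!is.finite(tau) || tau <= 0) tau <- 1
    } else tau <- 1
  }
  model@tau <- as.numeric(tau)
  validObject(model)
  model
}

#' Project an image into the eigenimage space
#'
#' \eqn{y = W (x - \psi)}: the length-f feature vector of a flattened image.
#' Because the rows of W are orthonormal, \eqn{\|y\| \le \|x - \psi\|}.
#'
#' @param x flattened image of length d.
#' @param model an [EigenModel-class].
#' @return Numeric feature vector of length f.
#' @export
projectImage <- function(x, model) {
  stopifnot(is(model, "EigenModel"))
  x <- as.numeric(x)
  if (length(x) != length(model@mean))
    stop("projectImage: image length does not match model dimension d")
  drop(model@components %*% (x - model@mean))
}

#' Project many images at once
#'
#' @param X d x M matrix of flattened images (columns).
#' @param model an [EigenModel-class].
#' @return f x M matrix of feature vectors.
#' @export
projectSet <- function(X, model) {
  stopifnot(is(model, "EigenModel"))
  X <- as.matrix(X)
  if (nrow(X) != length(model@mean))
    stop("projectSet: image length does not match model dimension d")
  model@components %*% sweep(X, 1L, model@mean)
}

#' Reconstruct an image from its feature vector
#'
#' \eqn{\hat{x} = W^T y + \psi}; reconstruction error is non-increasing in f.
#'
#' @param y feature vector of length f.
#' @param model an [EigenModel-class].
#' @return Flattened image of length d.
#' @export
reconstructImage <- function(y, model) {
  stopifnot(is(model, "EigenModel"))
  drop(crossprod(model@components, y)) + model@mean
}

#' Euclidean-distance matching against a gallery
#'
#' Finds the gallery feature vector nearest to \code{y}; the query is
#' declared detected when that distance is strictly below \code{tau}.
#' Ties are broken toward the lowest gallery index.
#'
#' @param y feature vector.
#' @param gallery list of feature vectors, or an f x M matrix (columns).
#' @param tau positive detection threshold.
#' @return A list of class \code{"MatchResult"}: \code{distance},
#'   \code{detected}, \code{nearestIndex}.
#' @examples
#' matchFeature(c(3, 4), list(c(0, 0)), tau = 5)  # distance 5, not detected
#' @export
matchFeature <- function(y, gallery, tau) {
  stopifnot(tau > 0)
  G <- if (is.list(gallery)) do.call(cbind, gallery) else as.matrix(gallery)
  if (is.null(G) || ncol(G) == 0L) stop("matchFeature: empty gallery")
  y <- as.numeric(y)
  if (length(y) != nrow(G)) stop("matchFeature: dimension mismatch")
  d2 <- colSums((G - y)^2)
  i <- which.min(d2)                 # which.min takes the first minimum
  dist <- sqrt(d2[i])
  structure(list(distance = dist, detected = dist < tau,
                 nearestIndex = as.integer(i)),
            class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult: distance %.4g, %s (nearest gallery index %d)\n",
              x$distance, if (x$detected) "DETECTED" else "not detected",
              x$nearestIndex))
  invisible(x)
}

#' Serialize an eigen model to a plain-text archive
#'
#' Writes the arrays (mean, components, eigenvalues) as CSV plus a JSON
#' sidecar with f, tau, and provenance fields.
#'
#' @param model an [EigenModel-class].
#' @param dir destination directory (created if absent).
#' @param provenance named list merged into the sidecar (e.g. seed, M, d).
#' @return \code{dir}, invisibly.
#' @export
saveEigenModel <- function(model, dir, provenance = list()) {
  stopifnot(is(model, "EigenModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(mean = model@mean),
                   file.path(dir, "mean.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model@components),
                   file.path(dir, "components.csv"), row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = model@eigenvalues),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  meta <- c(list(f = model@f, tau = model@tau, d = length(model@mean)),
            provenance)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load an eigen model saved by [saveEigenModel()]
#'
#' @param dir archive directory.
#' @return An [EigenModel-class].
#' @export
loadEigenModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  new("EigenModel",
      mean = utils::read.csv(file.path(dir, "mean.csv"))$mean,
      components = as.matrix(utils::read.csv(file.path(dir, "components.csv"))),
      eigenvalues = utils::read.csv(file.path(dir, "eigenvalues.csv"))$eigenvalue,
      f = as.integer(meta$f), tau = as.numeric(meta$tau))
}
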