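#' Symmetric normalization of a weighted adjacency matrix
#'
#' Adds a unit self-loop to every node (A~ = A + I), forms the degree matrix
#' D~ from the row sums of A~, and returns D~^{-1/2} A~ D~^{-1/2}. The self
#' loop guarantees every degree is at least 1, so the normalization is always
#' defined; the result is symmetric with spectrum in [-1, 1].
#'
#' @param A square, symmetric, nonnegative numeric matrix.
#' @return normalized matrix of the same dimension.
#' @export
normalizeAdjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (max(abs(A - t(A))) > .SYM_TOL) stop("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Glorot-style uniform weight initialization
#'
#' Uniform on [-b, b] with b = sqrt(6 / (fanIn + fanOut)). Draws from the
#' current RNG state; seed control lives in \code{\link{initModelParams}}.
#'
#' @param fanIn,fanOut layer dimensions.
#' @return fanIn x fanOut matrix.
#' @export
glorotInit <- function(fanIn, fanOut) {
  b <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -b, b), fanIn, fanOut)
}

#' One graph convolution layer
#'
#' Computes \code{activation(Anorm \%*\% Z \%*\% weight)}: the propagation
#' rule of a symmetric-normalized graph convolution. With identity
#' activation and an identity weight matrix this is exactly one step of
#' normalized message passing.
#'
#' @param Anorm output of \code{\link{normalizeAdjacency}}.
#' @param Z N x inDim input features.
#' @param weight inDim x outDim parameter matrix.
#' @param activation "relu" (default) or "identity".
#' @return N x outDim matrix.
#' @export
gcnLayer <- function(Anorm, Z, weight, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  Z <- as.matrix(Z)
  weight <- as.matrix(weight)
  if (ncol(Anorm) != nrow(Z)) stop("Anorm and Z dimensions do not conform")
  if (ncol(Z) != nrow(weight)) stop("Z and weight dimensions do not conform")
  out <- Anorm %*% Z %*% weight
  if (activation == "relu") out <- pmax(out, 0)
  out
}

#' A stacked block of graph convolution layers
#'
#' Normalizes the adjacency once and applies the layers sequentially; depth k
#' gives each node a k-hop receptive field.
#'
#' @param A raw (un-normalized) adjacency.
#' @param Z input node features.
#' @param layers list of layers, each \code{list(weight=, activation=)};
#'   activation defaults to "relu".
#' @return node latent feature matrix (rows = nodes, cols = last layer's
#'   output dimension).
#' @export
gcnBlock <- function(A, Z, layers) {
  if (!length(layers)) stop("gcnBlock needs at least one layer")
  Anorm <- normalizeAdjacency(A)
  for (ly in layers) {
    act <- if (is.null(ly$activation)) "relu" else ly$activation
    Z <- gcnLayer(Anorm, Z, ly$weight, act)
  }
  Z
}
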