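## Generalized Procrustes analysis on 2-D landmark configurations.
##
## Convention: configurations are centred and fixed at unit centroid size;
## GPA iterations only rotate (no reflection, determinant +1), matching the
## behaviour of the standard "Procrustes fit" in morphometrics software.

#' Centroid size of a configuration
#'
#' Square root of the summed squared deviations of all landmark coordinates
#' from their centroid; the size variable removed by Procrustes fitting.
#'
#' @param config p x 2 numeric matrix.
#' @return positive scalar.
#' @examples
#' centroidSize(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroidSize <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("need at least 2 landmarks")
  centred <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(centred^2))
  if (cs == 0) stop("degenerate shape: all landmarks identical")
  cs
}

# centre and scale to unit centroid size
.preshape <- function(config) {
  centred <- sweep(config, 2, colMeans(config))
  centred / sqrt(sum(centred^2))
}

# optimal rotation (det +1) of unit pre-shape X onto reference C:
# R = U S V' from the SVD of X'C with S correcting the determinant sign
.optimalRotation <- function(X, C) {
  s <- svd(crossprod(X, C))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

# full Procrustes distance between two configurations via planar complex
# coordinates: with b = <uB, uA> the optimal rotation-and-scale fit of uB
# onto uA, d_F = ||uA - b uB|| ( = sqrt(1 - |b|^2), but the residual form
# stays accurate when the shapes nearly coincide)
.fullProcrustesDistance <- function(A, B) {
  zA <- complex(real = A[, 1], imaginary = A[, 2])
  zB <- complex(real = B[, 1], imaginary = B[, 2])
  zA <- zA - mean(zA); zB <- zB - mean(zB)
  zA <- zA / sqrt(sum(Mod(zA)^2)); zB <- zB / sqrt(sum(Mod(zB)^2))
  b <- sum(Conj(zB) * zA)
  sqrt(sum(Mod(zA - b * zB)^2))
}

#' Optimal pairwise Procrustes superimposition
#'
#' Finds the similarity transform (rotation with determinant +1, scale,
#' translation) of \code{B} minimizing the summed squared distance to
#' \code{A} after both are centred and scaled to unit centroid size, and
#' reports the minimized root-sum-of-squares (the full Procrustes
#' distance). Reflections are never used, so a mirrored copy of an
#' asymmetric shape has positive distance.
#'
#' @param A,B p x 2 matrices with the same p.
#' @return list with \code{rotation} (angle, radians), \code{scale},
#'   \code{translation} (length-2), \code{distance} and \code{B_aligned}
#'   (B mapped onto the pre-shape of A).
#' @export
alignPair <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B)))
    stop("configurations must have the same number of landmarks")
  zA <- complex(real = A[, 1], imaginary = A[, 2])
  zB <- complex(real = B[, 1], imaginary = B[, 2])
  mA <- mean(zA); mB <- mean(zB)
  zA <- zA - mA; zB <- zB - mB
  nA <- sqrt(sum(Mod(zA)^2)); nB <- sqrt(sum(Mod(zB)^2))
  if (nA == 0 || nB == 0) stop("degenerate shape: all landmarks identical")
  uA <- zA / nA; uB <- zB / nB
  # least-squares complex regression uA ~ beta * uB: beta = <uB,uA>
  beta <- sum(Conj(uB) * uA)
  d <- sqrt(sum(Mod(uA - beta * uB)^2))   # = sqrt(1 - |beta|^2), accurate
  aligned <- beta * uB
  list(rotation = Arg(beta),
       scale = Mod(beta),
       translation = c(Re(-beta * mB / nB), Im(-beta * mB / nB)),
       distance = d,
       B_aligned = cbind(Re(aligned), Im(aligned)))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of all configurations: each is centred and
#' scaled to unit centroid size, then repeatedly rotated onto the current
#' consensus; the consensus is the coordinate-wise mean, renormalized to
#' unit centroid size after each sweep. Iteration stops when the consensus
#' moves by less than \code{tol} (root-sum-of-squares) or after
#' \code{max_iter} sweeps. The result is invariant (to ~1e-8) to the input
#' ordering and to arbitrary similarity transforms applied per specimen
#' beforehand, up to a global rotation.
#'
#' @param dataset a \linkS4class{ShapeDataset} (or bare p x 2 x n array).
#' @param tol convergence tolerance on consensus movement (default 1e-10).
#' @param max_iter maximum iterations (default 500; realistic datasets
#'   converge in under 10, the cap only matters for pathologically
#'   dispersed shapes).
#' @return A \linkS4class{GPAFit}.
#' @examples
#' tri <- rbind(c(0, 0), c(1, 0), c(0.3, 0.8))
#' sh <- lapply(1:4, function(i) tri * i)   # same shape, different sizes
#' fit <- gpa(ShapeDataset(sh))
#' max(fit@procrustesToMean) < 1e-9
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 500L) {
  if (is(dataset, "ShapeDataset")) {
    coords <- dataset@coords
    labels <- dataset@labels
  } else {
    coords <- dataset
    labels <- data.frame(row.names = seq_len(dim(coords)[3]))
  }
  d <- dim(coords)
  p <- d[1]; n <- d[3]
  if (n < 2L) stop("need at least 2 specimens")
  sizes <- apply(coords, 3, centroidSize)
  aligned <- array(NA_real_, d, dimnames = dimnames(coords))
  for (i in seq_len(n)) aligned[, , i] <- .preshape(coords[, , i])

  consensus <- aligned[, , 1]           # initial reference: first specimen
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (i in seq_len(n))
      aligned[, , i] <- aligned[, , i] %*%
        .optimalRotation(aligned[, , i], consensus)
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- .preshape(new_cons)
    move <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (move < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  # final rotation pass onto the converged consensus
  for (i in seq_len(n))
    aligned[, , i] <- aligned[, , i] %*%
      .optimalRotation(aligned[, , i], consensus)
  dmean <- vapply(seq_len(n), function(i)
    .fullProcrustesDistance(aligned[, , i], consensus), 0)
  fit <- new("GPAFit", aligned = aligned, consensus = consensus,
             centroidSizes = sizes,
             procrustesToMean = dmean,
             tangent = matrix(0, n, 2 * p),
             iterations = iterations, converged = converged,
             labels = labels)
  fit@tangent <- tangentProject(fit)
  fit
}

#' Project aligned shapes into the tangent space at the consensus
#'
#' Orthogonal projection of each aligned unit pre-shape onto the tangent
#' space of shape space at the consensus: the component along the consensus
#' vector is removed, which also subtracts the consensus itself. The
#' resulting n x 2p coordinate matrix has rank at most 2p - 4 (translation,
#' scale and rotation are gone) and feeds all multivariate statistics.
#'
#' @param fit a \linkS4class{GPAFit}.
#' @return n x 2p numeric matrix.
#' @export
tangentProject <- function(fit) {
  stopifnot(is(fit, "GPAFit"))
  d <- dim(fit@aligned)
  p <- d[1]; n <- d[3]
  cvec <- as.numeric(fit@consensus)            # unit norm (CS 1)
  cvec <- cvec / sqrt(sum(cvec^2))
  X <- t(apply(fit@aligned, 3, as.numeric))    # n x 2p
  if (n == 1L) X <- matrix(X, 1L, 2L * p)
  proj <- X - outer(as.numeric(X %*% cvec), cvec)
  dimnames(proj) <- list(dimnames(fit@aligned)[[3]], NULL)
  proj
}

#' Pairwise full Procrustes distance matrix
#'
#' All-pairs full Procrustes distances between the specimens of a GPA fit
#' (computed from the closed-form planar formula, so the values do not
#' depend on the common orientation chosen by GPA).
#'
#' @param fit a \linkS4class{GPAFit}.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
procrustesDistanceMatrix <- function(fit) {
  stopifnot(is(fit, "GPAFit"))
  d3 <- dim(fit@aligned)
  p <- d3[1]; n <- d3[3]
  Z <- matrix(complex(real = fit@aligned[, 1, ],
                      imaginary = fit@aligned[, 2, ]), p, n)
  # columns are centred unit vectors already; normalize defensively
  Z <- sweep(Z, 2, sqrt(colSums(Mod(Z)^2)), "/")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1L, n)) {
    b <- sum(Conj(Z[, j]) * Z[, i])
    D[i, j] <- D[j, i] <- sqrt(sum(Mod(Z[, i] - b * Z[, j])^2))
  }
  dimnames(D) <- list(dimnames(fit@aligned)[[3]], dimnames(fit@aligned)[[3]])
  D
}
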