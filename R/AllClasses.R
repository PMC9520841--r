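#' @import methods
#' @importFrom stats dist pf rnorm runif rbinom rgeom
#' @importFrom utils write.table read.delim
NULL

#' LandmarkSpecimen: one digitized flea head
#'
#' Holds the raw digitization of a single specimen: an ordered set of fixed
#' 2-D landmarks, zero or more open curves (polylines, each later resampled
#' into semilandmarks), an optional image scale factor and reference, and
#' specimen labels (sex, cox1 species, morphology species, region).
#'
#' Coordinates are unitless image coordinates exactly as stored in the TPS
#' file; the y axis is never flipped on ingest.
#'
#' @slot specimenID character scalar identifier.
#' @slot landmarks numeric matrix (p x 2) of fixed landmarks.
#' @slot curves list of numeric matrices (>= 2 rows x 2 cols), open polylines.
#' @slot scale numeric scalar, units per pixel (NA when absent); must be > 0.
#' @slot imageRef character scalar, source image name ("" when absent).
#' @slot labels named character vector; recognised names are \code{sex}
#'   (F/M), \code{species_cox1} (canis/orientis/unknown), \code{species_morph}
#'   (canis/orientis/indeterminate) and \code{region}.
#' @export
setClass("LandmarkSpecimen",
  representation(
    specimenID = "character",
    landmarks = "matrix",
    curves = "list",
    scale = "numeric",
    imageRef = "character",
    labels = "character"
  ),
  prototype(
    specimenID = NA_character_,
    curves = list(),
    scale = NA_real_,
    imageRef = "",
    labels = character(0)
  )
)

setValidity("LandmarkSpecimen", function(object) {
  msg <- character(0)
  lm <- object@landmarks
  if (!is.numeric(lm) || ncol(lm) != 2L || nrow(lm) < 1L)
    msg <- c(msg, "landmarks must be a non-empty numeric p x 2 matrix")
  else if (!all(is.finite(lm)))
    msg <- c(msg, "landmark coordinates must be finite")
  for (i in seq_along(object@curves)) {
    cv <- object@curves[[i]]
    if (!is.matrix(cv) || !is.numeric(cv) || ncol(cv) != 2L || nrow(cv) < 2L)
      msg <- c(msg, sprintf("curve %d must be a numeric matrix with >= 2 rows and 2 columns", i))
    else if (!all(is.finite(cv)))
      msg <- c(msg, sprintf("curve %d has non-finite coordinates", i))
  }
  if (length(object@scale) != 1L)
    msg <- c(msg, "scale must be a single value (possibly NA)")
  else if (!is.na(object@scale) && object@scale <= 0)
    msg <- c(msg, "scale must be > 0 when present")
  if (length(msg)) msg else TRUE
})

#' ShapeDataset: a set of homologous landmark configurations
#'
#' An n-specimen dataset of p homologous 2-D landmarks stored as a
#' p x 2 x n array plus per-specimen labels. All downstream shape analysis
#' (GPA, Procrustes ANOVA, CVA, DFA) starts from this container.
#'
#' @slot coords numeric array, dim p x 2 x n; third dimension named by
#'   specimen id.
#' @slot labels data.frame with n rows; columns typically \code{sex},
#'   \code{species}, \code{region} (missing labels are NA).
#' @slot provenance character vector length p: \code{"fixed"} or
#'   \code{"semilandmark"} per landmark (may be empty when unknown).
#' @export
setClass("ShapeDataset",
  representation(
    coords = "array",
    labels = "data.frame",
    provenance = "character"
  ),
  prototype(provenance = character(0))
)

setValidity("ShapeDataset", function(object) {
  d <- dim(object@coords)
  msg <- character(0)
  if (length(d) != 3L || d[2] != 2L)
    msg <- c(msg, "coords must be a p x 2 x n array")
  else {
    if (d[3] < 2L) msg <- c(msg, "need at least 2 specimens")
    if (d[1] < 3L) msg <- c(msg, "need at least 3 landmarks")
    if (!all(is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
    if (nrow(object@labels) != d[3])
      msg <- c(msg, "labels must have one row per specimen")
    if (length(object@provenance) && length(object@provenance) != d[1])
      msg <- c(msg, "provenance must have one entry per landmark")
  }
  if (length(msg)) msg else TRUE
})

#' GPAFit: result of generalized Procrustes superimposition
#'
#' @slot aligned numeric array p x 2 x n of superimposed coordinates, each
#'   configuration centred at the origin with unit centroid size.
#' @slot consensus p x 2 mean shape (unit centroid size).
#' @slot centroidSizes numeric n, original centroid sizes before scaling.
#' @slot procrustesToMean numeric n, full Procrustes distance of each
#'   specimen to the consensus.
#' @slot tangent numeric n x 2p matrix of tangent-space coordinates.
#' @slot iterations integer, GPA iterations performed.
#' @slot converged logical.
#' @slot labels data.frame carried over from the input dataset.
#' @export
setClass("GPAFit",
  representation(
    aligned = "array",
    consensus = "matrix",
    centroidSizes = "numeric",
    procrustesToMean = "numeric",
    tangent = "matrix",
    iterations = "integer",
    converged = "logical",
    labels = "data.frame"
  )
)

setValidity("GPAFit", function(object) {
  d <- dim(object@aligned)
  msg <- character(0)
  if (length(d) != 3L || d[2] != 2L)
    msg <- c(msg, "aligned must be p x 2 x n")
  else {
    if (!identical(dim(object@consensus), c(d[1], 2L)))
      msg <- c(msg, "consensus must be p x 2")
    if (length(object@centroidSizes) != d[3])
      msg <- c(msg, "centroidSizes length must equal n")
    if (!identical(dim(object@tangent), c(d[3], 2L * d[1])))
      msg <- c(msg, "tangent must be n x 2p")
  }
  if (length(msg)) msg else TRUE
})

#' CvaFit: canonical variate analysis of tangent coordinates
#'
#' @slot axes canonical vectors (columns), expressed in the original 2p
#'   tangent coordinates.
#' @slot eigenvalues numeric, canonical roots (non-increasing).
#' @slot percentVar numeric, percent of among-group variance per CV.
#' @slot scores n x k matrix of specimen scores.
#' @slot groupMeans g x k matrix of group means in canonical space.
#' @slot mahalanobis g x g matrix of pairwise Mahalanobis distances.
#' @slot procrustes g x g matrix of pairwise distances between group mean
#'   shapes (Euclidean in tangent space, i.e. Procrustes distance to first
#'   order).
#' @slot pValues list with elements \code{mahalanobis} and \code{procrustes},
#'   each a g x g permutation p-value matrix (NA until tested).
#' @slot groups factor of group membership.
#' @slot nPerm integer, permutation rounds used.
#' @slot seed integer seed recorded for reproducibility.
#' @export
setClass("CvaFit",
  representation(
    axes = "matrix",
    eigenvalues = "numeric",
    percentVar = "numeric",
    scores = "matrix",
    groupMeans = "matrix",
    mahalanobis = "matrix",
    procrustes = "matrix",
    pValues = "list",
    groups = "factor",
    nPerm = "integer",
    seed = "integer"
  )
)

#' DfaFit: two-group discriminant function analysis
#'
#' @slot axis discriminant vector in the original 2p tangent coordinates.
#' @slot scores numeric n, discriminant scores.
#' @slot cutoff numeric, midpoint of the two group mean scores.
#' @slot resubstitution 2 x 2 contingency table (rows = true group).
#' @slot loo 2 x 2 leave-one-out contingency table (empty until run).
#' @slot looRates per-group LOO misclassification rates.
#' @slot permutationP numeric, permutation p-value for the group-mean
#'   Mahalanobis distance.
#' @slot groups factor with two levels.
#' @slot nPerm integer.
#' @slot seed integer.
#' @export
setClass("DfaFit",
  representation(
    axis = "numeric",
    scores = "numeric",
    cutoff = "numeric",
    resubstitution = "matrix",
    loo = "matrix",
    looRates = "numeric",
    permutationP = "numeric",
    groups = "factor",
    nPerm = "integer",
    seed = "integer"
  )
)

setMethod("show", "LandmarkSpecimen", function(object) {
  cat("LandmarkSpecimen", sQuote(object@specimenID), "\n")
  cat("  ", nrow(object@landmarks), " fixed landmarks; ",
      length(object@curves), " curve(s)",
      if (length(object@curves))
        paste0(" with ", paste(vapply(object@curves, nrow, 0L), collapse = ", "),
               " points"),
      "\n", sep = "")
  if (!is.na(object@scale)) cat("  scale:", object@scale, "\n")
  if (length(object@labels))
    cat("  labels:", paste(names(object@labels), object@labels,
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ShapeDataset", function(object) {
  d <- dim(object@coords)
  cat("ShapeDataset:", d[3], "specimens x", d[1], "landmarks (2-D)\n")
  if (ncol(object@labels))
    cat("  labels:", paste(colnames(object@labels), collapse = ", "), "\n")
})

setMethod("show", "GPAFit", function(object) {
  d <- dim(object@aligned)
  cat("GPAFit:", d[3], "specimens x", d[1], "landmarks\n")
  cat("  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  mean Procrustes distance to consensus:",
      format(mean(object@procrustesToMean), digits = 4), "\n")
})

setMethod("show", "CvaFit", function(object) {
  cat("CvaFit:", nlevels(object@groups), "groups,",
      length(object@eigenvalues), "canonical variates\n")
  cat("  % variance:", paste(format(object@percentVar, digits = 3),
                             collapse = ", "), "\n")
  if (!all(is.na(object@pValues$mahalanobis)))
    cat("  permutation tests:", object@nPerm, "rounds (seed",
        object@seed, ")\n")
})

setMethod("show", "DfaFit", function(object) {
  cat("DfaFit:", paste(levels(object@groups), collapse = " vs "), "\n")
  cat("  resubstitution errors:",
      sum(object@resubstitution) - sum(diag(object@resubstitution)),
      "/", sum(object@resubstitution), "\n")
  if (length(object@loo) && sum(object@loo) > 0)
    cat("  LOO errors:", sum(object@loo) - sum(diag(object@loo)),
        "/", sum(object@loo), "\n")
  if (!is.na(object@permutationP))
    cat("  permutation p:", format(object@permutationP, digits = 3), "\n")
})

#' Construct a LandmarkSpecimen
#'
#' @param specimenID character identifier.
#' @param landmarks p x 2 numeric matrix.
#' @param curves list of polyline matrices (each >= 2 x 2).
#' @param scale optional positive scale factor (units per pixel).
#' @param imageRef optional image file name.
#' @param labels named character vector of specimen labels.
#' @return A \linkS4class{LandmarkSpecimen}.
#' @examples
#' sp <- LandmarkSpecimen("f1", cbind(c(0, 1), c(0, 1)))
#' @export
LandmarkSpecimen <- function(specimenID, landmarks, curves = list(),
                             scale = NA_real_, imageRef = "",
                             labels = character(0)) {
  landmarks <- as.matrix(landmarks)
  storage.mode(landmarks) <- "double"
  curves <- lapply(curves, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  new("LandmarkSpecimen", specimenID = as.character(specimenID),
      landmarks = landmarks, curves = curves, scale = as.numeric(scale),
      imageRef = as.character(imageRef), labels = labels)
}

#' Construct a ShapeDataset
#'
#' @param coords p x 2 x n array, or a list of n p x 2 matrices.
#' @param labels data.frame of per-specimen labels (n rows), or NULL.
#' @param provenance optional character vector, "fixed"/"semilandmark" per
#'   landmark.
#' @return A \linkS4class{ShapeDataset}.
#' @export
ShapeDataset <- function(coords, labels = NULL, provenance = character(0)) {
  if (is.list(coords)) {
    p <- nrow(coords[[1]])
    if (any(vapply(coords, nrow, 0L) != p))
      stop("all configurations must have the same number of landmarks")
    coords <- array(unlist(lapply(coords, as.numeric)),
                    dim = c(p, 2L, length(coords)),
                    dimnames = list(NULL, c("x", "y"), names(coords)))
  }
  n <- dim(coords)[3]
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(n))
  new("ShapeDataset", coords = coords, labels = labels,
      provenance = provenance)
}
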