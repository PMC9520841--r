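#' Accessors for shape objects
#'
#' Small accessor family: \code{specimenLabels} returns the per-specimen
#' label table, \code{alignedCoords} the superimposed p x 2 x n array,
#' \code{consensusShape} the GPA mean shape, \code{tangentCoords} the
#' n x 2p tangent-space coordinate matrix, \code{centroidSizes} the
#' original centroid sizes, \code{cvScores} specimen scores on canonical
#' or discriminant axes, and \code{percentVariance} the percent variance
#' accounted for per canonical variate.
#'
#' @param object a \linkS4class{ShapeDataset}, \linkS4class{GPAFit},
#'   \linkS4class{CvaFit} or \linkS4class{DfaFit}.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("specimenLabels", function(object) standardGeneric("specimenLabels"))
#' @rdname accessors
#' @export
setGeneric("alignedCoords", function(object) standardGeneric("alignedCoords"))
#' @rdname accessors
#' @export
setGeneric("consensusShape", function(object) standardGeneric("consensusShape"))
#' @rdname accessors
#' @export
setGeneric("tangentCoords", function(object) standardGeneric("tangentCoords"))
#' @rdname accessors
#' @export
setGeneric("centroidSizes", function(object) standardGeneric("centroidSizes"))
#' @rdname accessors
#' @export
setGeneric("cvScores", function(object) standardGeneric("cvScores"))
#' @rdname accessors
#' @export
setGeneric("percentVariance", function(object) standardGeneric("percentVariance"))

#' @rdname accessors
setMethod("specimenLabels", "ShapeDataset", function(object) object@labels)
#' @rdname accessors
setMethod("specimenLabels", "GPAFit", function(object) object@labels)
#' @rdname accessors
setMethod("alignedCoords", "GPAFit", function(object) object@aligned)
#' @rdname accessors
setMethod("consensusShape", "GPAFit", function(object) object@consensus)
#' @rdname accessors
setMethod("tangentCoords", "GPAFit", function(object) object@tangent)
#' @rdname accessors
setMethod("centroidSizes", "GPAFit", function(object) object@centroidSizes)
#' @rdname accessors
setMethod("cvScores", "CvaFit", function(object) object@scores)
#' @rdname accessors
setMethod("cvScores", "DfaFit", function(object) object@scores)
#' @rdname accessors
setMethod("percentVariance", "CvaFit", function(object) object@percentVar)

#' @rdname accessors
#' @export
setGeneric("mahalanobisDistances", function(object) standardGeneric("mahalanobisDistances"))
#' @rdname accessors
setMethod("mahalanobisDistances", "CvaFit", function(object) object@mahalanobis)

#' @rdname accessors
#' @export
setGeneric("permutationP", function(object) standardGeneric("permutationP"))
#' @rdname accessors
setMethod("permutationP", "CvaFit", function(object) object@pValues)
#' @rdname accessors
setMethod("permutationP", "DfaFit", function(object) object@permutationP)

#' Number of specimens / landmarks
#'
#' @param object a \linkS4class{ShapeDataset} or \linkS4class{GPAFit}.
#' @return integer count.
#' @export
setGeneric("nSpecimens", function(object) standardGeneric("nSpecimens"))
#' @rdname nSpecimens
#' @export
setGeneric("nLandmarks", function(object) standardGeneric("nLandmarks"))
#' @rdname nSpecimens
setMethod("nSpecimens", "ShapeDataset", function(object) dim(object@coords)[3])
#' @rdname nSpecimens
setMethod("nSpecimens", "GPAFit", function(object) dim(object@aligned)[3])
#' @rdname nSpecimens
setMethod("nLandmarks", "ShapeDataset", function(object) dim(object@coords)[1])
#' @rdname nSpecimens
setMethod("nLandmarks", "GPAFit", function(object) dim(object@aligned)[1])
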