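#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("gramValues", function(object) standardGeneric("gramValues"))
#' @rdname accessors
#' @export
setGeneric("blocks", function(object) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setGeneric("dualCoef", function(object) standardGeneric("dualCoef"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("varianceShare", function(object) standardGeneric("varianceShare"))
#' @rdname accessors
#' @export
setGeneric("tangentVectors", function(object) standardGeneric("tangentVectors"))
#' @rdname accessors
#' @export
setGeneric("tangentNorms", function(object) standardGeneric("tangentNorms"))
#' @rdname accessors
#' @export
setGeneric("rankingTable", function(object) standardGeneric("rankingTable"))

#' Accessors for kpcaInterp objects
#'
#' Small accessor functions so user code never reaches into slots:
#' \code{sampleIds} (ids of samples/points), \code{gramValues} (the kernel
#' matrix), \code{blocks} (list of data matrices), \code{dualCoef} (dual
#' coefficient matrix of a fitted model), \code{eigenvalues} (covariance
#' eigenvalues), \code{scores} (training embedding), \code{coords}
#' (embedding coordinates), \code{varianceShare} (per-component share of
#' feature-space variance), \code{tangentVectors}/\code{tangentNorms}
#' (tangent field content) and \code{rankingTable} (ranking data.frame).
#'
#' @param object the object to access.
#' @name accessors
#' @returns the corresponding slot content, copied.
NULL

#' @rdname accessors
#' @export
setMethod("sampleIds", "MultiBlockData", function(object) object@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "GramMatrix", function(object) object@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "KPCAModel", function(object) object@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "Embedding", function(object) object@pointIds)
#' @rdname accessors
#' @export
setMethod("gramValues", "GramMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("gramValues", "CenteredGram", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("blocks", "MultiBlockData", function(object) object@blocks)
#' @rdname accessors
#' @export
setMethod("dualCoef", "KPCAModel", function(object) object@A)
#' @rdname accessors
#' @export
setMethod("eigenvalues", "KPCAModel", function(object) object@lambdas)
#' @rdname accessors
#' @export
setMethod("scores", "KPCAModel", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("coords", "Embedding", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("varianceShare", "KPCAModel",
    function(object) object@lambdas / sum(object@evals))
#' @rdname accessors
#' @export
setMethod("varianceShare", "Embedding", function(object) object@varianceShare)
#' @rdname accessors
#' @export
setMethod("tangentVectors", "TangentField", function(object) object@vectors)
#' @rdname accessors
#' @export
setMethod("tangentNorms", "TangentField", function(object) object@norms)
#' @rdname accessors
#' @export
setMethod("rankingTable", "DirectionRanking", function(object) object@table)
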