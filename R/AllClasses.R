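#' @import methods
NULL

## tolerances shared across validity checks
.SYM_TOL <- 1e-10
.PSD_TOL <- 1e-8
.CENTER_TOL <- 1e-9
.DEGENERATE_NORM <- 1e-12

#' Kernel specification
#'
#' Describes a kernel family and its hyperparameters. The RBF kernel is
#' \eqn{k(x, z) = \exp(-c \|x - z\|^2)} with width parameter \eqn{c > 0};
#' when \code{c} is \code{NA} it is resolved per block at fit time by the
#' median heuristic (see \code{\link{rbfBandwidth}}). The polynomial kernel
#' is \eqn{(x^\top z + \mathrm{offset})^{\mathrm{degree}}}. A
#' \code{"precomputed"} spec carries no hyperparameters and supports no
#' pointwise evaluation or gradient.
#'
#' @slot family character; one of \code{"rbf"}, \code{"linear"},
#'   \code{"polynomial"}, \code{"precomputed"}.
#' @slot c numeric; RBF width, \code{NA} for automatic bandwidth.
#' @slot degree numeric; polynomial degree (>= 1).
#' @slot offset numeric; polynomial offset.
#' @export
setClass("KernelSpec",
    representation(family = "character", c = "numeric",
                   degree = "numeric", offset = "numeric"),
    prototype(family = "rbf", c = NA_real_, degree = 2, offset = 1))

setValidity("KernelSpec", function(object) {
    fams <- c("rbf", "linear", "polynomial", "precomputed")
    if (length(object@family) != 1L || !object@family %in% fams)
        return(sprintf("family must be one of %s", paste(fams, collapse = ", ")))
    if (object@family == "rbf" && !is.na(object@c) && object@c <= 0)
        return("rbf width c must be > 0")
    if (object@family == "polynomial" &&
        (length(object@degree) != 1L || object@degree < 1))
        return("polynomial degree must be >= 1")
    TRUE
})

#' @param family kernel family.
#' @param c RBF width; \code{NA} requests the median heuristic at fit time.
#' @param degree,offset polynomial parameters.
#' @rdname KernelSpec-class
#' @examples
#' kernelSpec("rbf", c = 0.5)
#' kernelSpec("linear")
#' @export
kernelSpec <- function(family = c("rbf", "linear", "polynomial", "precomputed"),
                       c = NA_real_, degree = 2, offset = 1) {
    family <- match.arg(family)
    new("KernelSpec", family = family, c = as.numeric(c),
        degree = as.numeric(degree), offset = as.numeric(offset))
}

setMethod("show", "KernelSpec", function(object) {
    extra <- switch(object@family,
        rbf = sprintf(" (c = %s)",
            if (is.na(object@c)) "auto" else format(object@c)),
        polynomial = sprintf(" (degree = %g, offset = %g)",
            object@degree, object@offset),
        "")
    cat(sprintf("KernelSpec: %s%s\n", object@family, extra))
})

#' Multi-block sample-by-variable data
#'
#' Holds one or more numeric blocks measured on the same samples, in a
#' shared sample order, together with the per-variable location/scale used
#' if the blocks were standardized. Blocks may have different variables
#' (e.g. gene expression and fatty-acid concentrations) but must share
#' samples.
#'
#' @slot blocks named list of numeric matrices (samples x variables),
#'   identical row order across blocks.
#' @slot sampleIds character vector of sample identifiers.
#' @slot standardized logical; whether per-variable standardization was
#'   applied.
#' @slot centers,scales lists (one numeric vector per block) recording the
#'   location/scale removed from each variable; scales are 1 when
#'   \code{standardized} is \code{FALSE}.
#' @export
setClass("MultiBlockData",
    representation(blocks = "list", sampleIds = "character",
                   standardized = "logical", centers = "list",
                   scales = "list"))

setValidity("MultiBlockData", function(object) {
    if (length(object@blocks) < 1L) return("at least one block required")
    m <- length(object@sampleIds)
    for (b in seq_along(object@blocks)) {
        X <- object@blocks[[b]]
        if (!is.matrix(X) || !is.numeric(X)) return("blocks must be numeric matrices")
        if (nrow(X) != m) return("all blocks must have the same sample count")
        if (!identical(rownames(X), object@sampleIds))
            return("block rows must follow the shared sample order")
        if (anyDuplicated(colnames(X)))
            return("variable names must be unique within a block")
        if (any(object@scales[[b]] <= 0)) return("scales must be strictly positive")
    }
    if (anyDuplicated(object@sampleIds)) return("duplicate sample ids")
    TRUE
})

#' @param blocks a numeric matrix/data.frame or a (preferably named) list of
#'   them; rows are samples, columns variables. Row names are used as sample
#'   ids (generated when absent).
#' @param standardize logical; centre each variable and divide by its
#'   standard deviation before kernel evaluation. Constant variables are
#'   centred but left unscaled, with a message.
#' @rdname MultiBlockData-class
#' @examples
#' X <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), paste0("v", 1:4)))
#' multiBlockData(X)
#' @export
multiBlockData <- function(blocks, standardize = TRUE) {
    if (!is.list(blocks) || is.data.frame(blocks)) blocks <- list(blocks)
    blocks <- lapply(blocks, function(X) {
        X <- as.matrix(X)
        storage.mode(X) <- "double"
        X
    })
    if (is.null(names(blocks)))
        names(blocks) <- paste0("block", seq_along(blocks))
    if (any(vapply(blocks, function(X) any(!is.finite(X)), logical(1))))
        stop("blocks contain non-finite values; missing data are not supported")
    ids <- rownames(blocks[[1L]])
    if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(blocks[[1L]])))
    blocks <- lapply(blocks, function(X) {
        if (is.null(rownames(X))) rownames(X) <- ids
        if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
        X[ids, , drop = FALSE]
    })
    centers <- lapply(blocks, function(X) colMeans(X))
    scales <- lapply(blocks, function(X) {
        s <- apply(X, 2L, stats::sd)
        if (standardize && any(s == 0)) {
            message("constant variable(s) left unscaled: ",
                    paste(colnames(X)[s == 0], collapse = ", "))
        }
        s[s == 0] <- 1
        s
    })
    if (standardize) {
        blocks <- Map(function(X, ce, sc) {
            scale(X, center = ce, scale = sc)[, , drop = FALSE]
        }, blocks, centers, scales)
        blocks <- lapply(blocks, function(X) {
            attr(X, "scaled:center") <- NULL
            attr(X, "scaled:scale") <- NULL
            X
        })
    } else {
        centers <- lapply(centers, function(ce) ce * 0)
        scales <- lapply(scales, function(sc) sc * 0 + 1)
    }
    new("MultiBlockData", blocks = blocks, sampleIds = ids,
        standardized = standardize, centers = centers, scales = scales)
}

setMethod("show", "MultiBlockData", function(object) {
    cat(sprintf("MultiBlockData: %d samples, %d block(s)%s\n",
        length(object@sampleIds), length(object@blocks),
        if (object@standardized) " (standardized)" else ""))
    for (nm in names(object@blocks))
        cat(sprintf("  %s: %d variables\n", nm, ncol(object@blocks[[nm]])))
})

#' Gram (kernel) matrix
#'
#' The m x m matrix of pairwise kernel evaluations over training samples.
#' Validity enforces symmetry (within 1e-10) and positive semidefiniteness
#' up to roundoff (minimum eigenvalue >= -1e-8 times the maximum).
#'
#' @slot values numeric m x m matrix.
#' @slot sampleIds character vector of sample ids.
#' @export
setClass("GramMatrix",
    representation(values = "matrix", sampleIds = "character"))

setValidity("GramMatrix", function(object) {
    K <- object@values
    if (nrow(K) != ncol(K)) return("Gram matrix must be square")
    if (nrow(K) != length(object@sampleIds))
        return("sampleIds length must match the matrix")
    if (max(abs(K - t(K))) > .SYM_TOL * max(1, max(abs(K))))
        return("Gram matrix is not symmetric")
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -.PSD_TOL * max(abs(ev), 1e-300))
        return("Gram matrix is not positive semidefinite within tolerance")
    TRUE
})

#' @param values square numeric matrix.
#' @param sampleIds sample identifiers; defaults to row names.
#' @rdname GramMatrix-class
#' @export
gramMatrix <- function(values, sampleIds = rownames(values)) {
    values <- as.matrix(values)
    if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(values)))
    dimnames(values) <- list(sampleIds, sampleIds)
    new("GramMatrix", values = values, sampleIds = as.character(sampleIds))
}

setMethod("show", "GramMatrix", function(object) {
    cat(sprintf("GramMatrix: %d x %d\n", nrow(object@values), ncol(object@values)))
})

#' Doubly centered Gram matrix
#'
#' The Gram matrix of implicitly mean-centred feature images, computed from
#' its non-centred counterpart as
#' \deqn{\tilde K = K - \tfrac1m K 1 1^\top - \tfrac1m 1 1^\top K
#'   + \tfrac1{m^2} (1^\top K 1) 1 1^\top.}
#' The column means of K and the grand mean are retained so that new points
#' can be projected later.
#'
#' @slot values the centred matrix.
#' @slot colMeansK column means of the original K.
#' @slot grandMean grand mean of the original K.
#' @slot m sample count.
#' @slot sampleIds sample ids.
#' @export
setClass("CenteredGram",
    representation(values = "matrix", colMeansK = "numeric",
                   grandMean = "numeric", m = "integer",
                   sampleIds = "character"))

setValidity("CenteredGram", function(object) {
    Kt <- object@values
    m <- object@m
    tol <- .CENTER_TOL * m * max(abs(Kt), 1e-300)
    if (max(abs(rowSums(Kt))) > tol || max(abs(colSums(Kt))) > tol)
        return("row/column sums of the centred Gram must vanish")
    if (max(abs(Kt - t(Kt))) > .SYM_TOL * max(1, max(abs(Kt))))
        return("centred Gram is not symmetric")
    TRUE
})

setMethod("show", "CenteredGram", function(object) {
    cat(sprintf("CenteredGram: %d x %d (grand mean of K = %.4g)\n",
        object@m, object@m, object@grandMean))
})

#' Fitted kernel PCA model
#'
#' Result of solving the dual eigenproblem \eqn{\tilde K \tilde\alpha = m
#' \tilde\lambda \tilde\alpha}. Dual coefficients are scaled so the
#' feature-space eigenvectors have unit norm, i.e. \eqn{(m
#' \tilde\lambda_k)\|\tilde\alpha^k\|^2 = 1}; under the linear kernel the
#' resulting scores coincide with classical PCA scores.
#'
#' @slot A m x r matrix of dual coefficients (one column per component).
#' @slot lambdas eigenvalues of the feature-space covariance operator
#'   (eigenvalues of the centred Gram divided by m), descending.
#' @slot evals all retained-and-discarded positive covariance eigenvalues,
#'   used for variance shares.
#' @slot scores m x r training embedding.
#' @slot colMeansK,grandMean centering statistics of the training Gram.
#' @slot m,r sample count and retained components.
#' @slot specs list of resolved \linkS4class{KernelSpec}, one per block.
#' @slot training the \linkS4class{MultiBlockData} used to fit, or an empty
#'   list slot content when fitted from a precomputed Gram.
#' @slot sampleIds training sample ids.
#' @export
setClass("KPCAModel",
    representation(A = "matrix", lambdas = "numeric", evals = "numeric",
                   scores = "matrix", colMeansK = "numeric",
                   grandMean = "numeric", m = "integer", r = "integer",
                   specs = "list", training = "ANY", sampleIds = "character"))

setValidity("KPCAModel", function(object) {
    r <- object@r; m <- object@m
    if (r > m - 1L) return("retained components must be <= m - 1")
    if (length(object@lambdas) != r) return("lambdas length must equal r")
    if (any(object@lambdas <= 0)) return("retained eigenvalues must be positive")
    if (is.unsorted(rev(object@lambdas))) return("eigenvalues must be descending")
    nrm <- m * object@lambdas * colSums(object@A^2)
    if (max(abs(nrm - 1)) > 1e-9)
        return("dual coefficients violate the unit-norm eigenvector convention")
    TRUE
})

setMethod("show", "KPCAModel", function(object) {
    cat(sprintf("KPCAModel: %d samples, %d component(s)\n", object@m, object@r))
    vs <- object@lambdas / sum(object@evals)
    cat("  variance shares:", paste(sprintf("%.3f", vs), collapse = " "), "\n")
    for (s in object@specs) show(s)
})

#' Low-dimensional embedding
#'
#' Coordinates of points (training samples or projected test points) in the
#' kernel PCA subspace, with the share of feature-space variance carried by
#' each retained component.
#'
#' @slot coords n x r coordinate matrix.
#' @slot pointIds point identifiers.
#' @slot varianceShare per-component variance shares (sum <= 1).
#' @export
setClass("Embedding",
    representation(coords = "matrix", pointIds = "character",
                   varianceShare = "numeric"))

setValidity("Embedding", function(object) {
    if (nrow(object@coords) != length(object@pointIds))
        return("pointIds must match coords rows")
    if (any(!is.finite(object@coords))) return("coordinates must be finite")
    if (sum(object@varianceShare) > 1 + 1e-8)
        return("variance shares must sum to at most 1")
    TRUE
})

setMethod("show", "Embedding", function(object) {
    cat(sprintf("Embedding: %d points x %d components\n",
        nrow(object@coords), ncol(object@coords)))
})

#' Direction specification
#'
#' A single input variable or a linear combination of variables within one
#' block, e.g. the sum of the expression of a gene module. Used both to
#' trace induced curves and to attach tangent fields.
#'
#' @slot block block id (name or index, stored as character).
#' @slot variables variable names or indices within the block.
#' @slot weights combination weights, one per variable.
#' @export
setClass("DirectionSpec",
    representation(block = "character", variables = "ANY",
                   weights = "numeric"))

setValidity("DirectionSpec", function(object) {
    if (length(object@variables) < 1L) return("at least one variable required")
    if (length(object@weights) != length(object@variables))
        return("one weight per variable required")
    if (all(object@weights == 0)) return("weights must not all be zero")
    if (anyDuplicated(object@variables)) return("variables must be distinct")
    TRUE
})

#' @param variables variable names (character) or column indices (numeric).
#' @param block which block the variables live in (name or index).
#' @param weights combination weights, recycled to length of
#'   \code{variables}; default all 1 (a plain sum).
#' @rdname DirectionSpec-class
#' @examples
#' directionSpec("X1")
#' directionSpec(c("X1", "X2"), weights = c(1, -1))
#' @export
directionSpec <- function(variables, block = 1L, weights = 1) {
    weights <- rep_len(as.numeric(weights), length(variables))
    new("DirectionSpec", block = as.character(block), variables = variables,
        weights = weights)
}

setMethod("show", "DirectionSpec", function(object) {
    terms <- paste(sprintf("%g*%s", object@weights, object@variables),
                   collapse = " + ")
    cat(sprintf("DirectionSpec (block %s): %s\n", object@block, terms))
})

#' Tangent field of a variable over the embedding
#'
#' For one variable (or linear combination) the collection of tangent
#' vectors of the induced curves at s = 0, one per anchor point: the local
#' direction of maximum growth of that variable in the embedding.
#'
#' @slot vectors n_anchor x r matrix of tangent vectors.
#' @slot anchors n_anchor x r embedding coordinates the vectors attach to.
#' @slot norms Euclidean norms of the tangent vectors.
#' @slot spec the \linkS4class{DirectionSpec} represented.
#' @slot anchorIds anchor identifiers.
#' @export
setClass("TangentField",
    representation(vectors = "matrix", anchors = "matrix", norms = "numeric",
                   spec = "DirectionSpec", anchorIds = "character"))

setValidity("TangentField", function(object) {
    if (!all(dim(object@vectors) == dim(object@anchors)))
        return("vectors and anchors must have matching dimensions")
    if (length(object@norms) != nrow(object@vectors))
        return("one norm per tangent vector required")
    if (max(abs(object@norms - sqrt(rowSums(object@vectors^2)))) > 1e-8)
        return("norms must be the row Euclidean norms")
    TRUE
})

setMethod("show", "TangentField", function(object) {
    cat(sprintf("TangentField: %d anchors x %d components, median norm %.4g\n",
        nrow(object@vectors), ncol(object@vectors),
        stats::median(object@norms)))
})

#' Variable ranking against a reference direction
#'
#' For every variable the mean (the R statistic) and standard deviation of
#' the per-sample cosines between the variable's tangent field and a
#' reference direction, sorted by mean cosine, descending.
#'
#' @slot reference description of the reference used.
#' @slot table data.frame with columns variable, block, mean, sd, n_used,
#'   n_skipped.
#' @export
setClass("DirectionRanking",
    representation(reference = "character", table = "data.frame"))

setValidity("DirectionRanking", function(object) {
    tb <- object@table
    need <- c("variable", "block", "mean", "sd", "n_used", "n_skipped")
    if (!all(need %in% names(tb)))
        return("table must have variable/block/mean/sd/n_used/n_skipped")
    ok <- is.finite(tb$mean)
    if (any(tb$mean[ok] < -1 - 1e-12 | tb$mean[ok] > 1 + 1e-12))
        return("mean cosines must lie in [-1, 1]")
    if (is.unsorted(rev(tb$mean[ok]))) return("table must be sorted by mean, descending")
    TRUE
})

setMethod("show", "DirectionRanking", function(object) {
    cat(sprintf("DirectionRanking (%d variables) against %s\n",
        nrow(object@table), object@reference))
    print(utils::head(object@table, 10L), row.names = FALSE)
    if (nrow(object@table) > 10L) cat("  ...\n")
})
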