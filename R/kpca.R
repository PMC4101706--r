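## Centered dual eigenproblem, score computation, out-of-sample projection.

#' Fit kernel PCA on single-block, multi-block or precomputed input
#'
#' Builds the (direct-sum) Gram matrix, double-centers it, and solves the
#' dual eigenproblem \eqn{\tilde K \tilde\alpha = m \tilde\lambda
#' \tilde\alpha}. Dual coefficient columns are scaled so the implicit
#' feature-space eigenvectors have unit norm
#' (\eqn{m\tilde\lambda_k \|\tilde\alpha^k\|^2 = 1}); with a linear kernel
#' the training scores then coincide with classical PCA scores. Component
#' signs are fixed by making the largest-magnitude dual coefficient
#' positive (first such index on ties).
#'
#' @param x a \linkS4class{MultiBlockData}, a numeric matrix/data.frame
#'   (single block; standardized according to \code{standardize}), a
#'   \linkS4class{GramMatrix} (precomputed), or a list of
#'   \linkS4class{GramMatrix} objects (fused by direct sum).
#' @param specs a \linkS4class{KernelSpec} or list of them, one per block;
#'   RBF widths left \code{NA} are resolved per block by the median
#'   heuristic. Ignored for precomputed input.
#' @param r number of components to retain (default 2, matching
#'   two-dimensional displays).
#' @param eigTol relative eigenvalue cutoff: eigenvalues below
#'   \code{eigTol * max} are discarded (centering always produces at least
#'   one null eigenvalue).
#' @param standardize used when \code{x} is a bare matrix/list of matrices;
#'   see \code{\link{multiBlockData}}.
#' @returns a \linkS4class{KPCAModel}.
#' @examples
#' toy <- makeToyData(seed = 1)
#' fit <- fitKPCA(toy$data, kernelSpec("rbf"))
#' head(scores(fit))
#' @export
fitKPCA <- function(x, specs = kernelSpec("rbf"), r = 2L, eigTol = 1e-10,
                    standardize = TRUE) {
    if (r < 1L) stop("r must be >= 1")
    precomputed <- FALSE
    if (is(x, "GramMatrix")) {
        gram <- x
        specs <- list(kernelSpec("precomputed"))
        training <- NULL
        precomputed <- TRUE
    } else if (is.list(x) && !is.data.frame(x) &&
               all(vapply(x, is, logical(1), "GramMatrix"))) {
        gram <- directSum(x)
        specs <- replicate(length(x), kernelSpec("precomputed"),
                           simplify = FALSE)
        training <- NULL
        precomputed <- TRUE
    } else {
        if (!is(x, "MultiBlockData")) x <- multiBlockData(x, standardize = standardize)
        training <- x
        if (is(specs, "KernelSpec")) specs <- list(specs)
        if (length(specs) == 1L && length(x@blocks) > 1L)
            specs <- rep(specs, length(x@blocks))
        if (length(specs) != length(x@blocks))
            stop("need one kernel spec per block")
        specs <- Map(.resolveSpec, specs, x@blocks)
        grams <- Map(computeGram, specs, x@blocks)
        gram <- directSum(grams)
    }
    m <- nrow(gram@values)
    if (m < 2L) stop("need at least two samples")
    cg <- centerGram(gram)
    eig <- eigen(cg@values, symmetric = TRUE)
    evals <- eig$values
    maxev <- max(evals)
    if (maxev <= 0) stop("degenerate data: the centred Gram matrix is zero")
    keep <- which(evals > eigTol * maxev)
    if (length(keep) == 0L) stop("degenerate data: no eigenvalue above tolerance")
    if (r > length(keep)) {
        warning(sprintf("r = %d exceeds the retainable rank %d; truncating",
                        r, length(keep)))
        r <- length(keep)
    }
    e <- evals[seq_len(r)]
    U <- eig$vectors[, seq_len(r), drop = FALSE]
    ## unit-norm feature-space eigenvectors: alpha = u / sqrt(e)
    A <- sweep(U, 2L, sqrt(e), "/")
    ## deterministic signs: largest |coefficient| positive
    for (k in seq_len(r)) {
        j <- which.max(abs(A[, k]))
        if (A[j, k] < 0) A[, k] <- -A[, k]
    }
    gaps <- diff(evals[keep]) / maxev
    if (any(abs(gaps) < 1e-8))
        warning("near-degenerate eigenvalues: the subspace is stable but ",
                "individual axes are not")
    S <- cg@values %*% A
    dimnames(S) <- list(cg@sampleIds, paste0("comp_", seq_len(r)))
    dimnames(A) <- dimnames(S)
    new("KPCAModel", A = A, lambdas = e / m, evals = evals[keep] / m,
        scores = S, colMeansK = cg@colMeansK, grandMean = cg@grandMean,
        m = as.integer(m), r = as.integer(r), specs = specs,
        training = if (precomputed) NULL else training,
        sampleIds = cg@sampleIds)
}

## project already-standardized per-block coordinates (list of matrices,
## test points in rows) -- the internal workhorse
.projectStd <- function(model, blocksList) {
    Z <- 0
    for (l in seq_along(blocksList)) {
        spec <- model@specs[[l]]
        Xl <- model@training@blocks[[l]]
        Yl <- blocksList[[l]]
        if (ncol(Yl) != ncol(Xl))
            stop("test point dimension does not match block ", l)
        Z <- Z + t(apply(Yl, 1L, function(y) .kernelRow(spec, Xl, y)))
    }
    .projectZ(model, Z)
}

## project test-kernel vectors Z (n_test x m): coordinates are
## (Z^T - (1/m) 1^T K)(I - (1/m) 1 1^T) applied in dual coordinates
.projectZ <- function(model, Z) {
    Z <- matrix(Z, ncol = model@m)
    Zt <- sweep(Z, 2L, model@colMeansK) - rowMeans(Z) + model@grandMean
    Zt %*% model@A
}

#' Project new points into a fitted kernel PCA embedding
#'
#' Computes the test-kernel vector \eqn{Z_i = k(y, x_i)} (summed over
#' blocks for a fused model) and the centred projection onto the retained
#' eigenvectors. Projecting the training samples reproduces the stored
#' scores.
#'
#' @param model a fitted \linkS4class{KPCAModel}.
#' @param newdata a numeric matrix/vector on the original data scale
#'   (single block), a list of such matrices (one per block, fused model),
#'   or, for a model fitted from a precomputed Gram, a matrix of kernel
#'   evaluations against the training samples (n_test x m).
#' @returns an \linkS4class{Embedding}.
#' @export
projectPoints <- function(model, newdata) {
    if (is.null(model@training)) {
        Z <- matrix(as.matrix(newdata), ncol = model@m)
        if (is.null(rownames(Z))) rownames(Z) <- paste0("new", seq_len(nrow(Z)))
        co <- .projectZ(model, Z)
        ids <- rownames(Z)
    } else {
        if (!is.list(newdata) || is.data.frame(newdata))
            newdata <- list(newdata)
        if (length(newdata) != length(model@training@blocks))
            stop("newdata must supply one table per block (",
                 length(model@training@blocks), " expected)")
        newdata <- lapply(newdata, function(Y) {
            Y <- if (is.null(dim(Y))) matrix(Y, nrow = 1L) else as.matrix(Y)
            storage.mode(Y) <- "double"
            Y
        })
        std <- Map(function(Y, ce, sc) {
            sweep(sweep(Y, 2L, ce), 2L, sc, "/")
        }, newdata, model@training@centers, model@training@scales)
        co <- .projectStd(model, std)
        ids <- rownames(newdata[[1L]]) %||% paste0("new", seq_len(nrow(co)))
    }
    dimnames(co) <- list(ids, paste0("comp_", seq_len(model@r)))
    new("Embedding", coords = co, pointIds = as.character(ids),
        varianceShare = varianceShare(model))
}

#' Training embedding of a fitted model
#'
#' @param model a fitted \linkS4class{KPCAModel}.
#' @returns an \linkS4class{Embedding} holding the training scores.
#' @export
trainingEmbedding <- function(model) {
    new("Embedding", coords = model@scores, pointIds = model@sampleIds,
        varianceShare = varianceShare(model))
}
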