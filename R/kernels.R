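## Kernel evaluation, Gram construction, double centering, direct-sum
## fusion, and analytic/numeric kernel gradients.

.checkDifferentiable <- function(spec) {
    if (spec@family == "precomputed")
        stop("a precomputed kernel has no kernel function: pointwise ",
             "evaluation and gradients (hence variable representation) ",
             "are unavailable")
    invisible(TRUE)
}

## fill c for rbf specs from the data when requested (NA)
.resolveSpec <- function(spec, X) {
    if (spec@family == "rbf" && is.na(spec@c)) spec@c <- rbfBandwidth(X)
    spec
}

#' Evaluate a kernel on a pair of points
#'
#' @param spec a \linkS4class{KernelSpec}; must not be precomputed.
#' @param x,y numeric vectors of equal length.
#' @returns the similarity k(x, y); for the RBF kernel a value in (0, 1].
#' @examples
#' evalKernel(kernelSpec("rbf", c = 0.5), c(0, 0), c(1, 0))  # exp(-0.5)
#' @export
evalKernel <- function(spec, x, y) {
    .checkDifferentiable(spec)
    if (length(x) != length(y))
        stop("x and y must have the same dimension (", length(x),
             " vs ", length(y), ")")
    switch(spec@family,
        rbf = {
            if (is.na(spec@c)) stop("rbf width c is unresolved; set it or fit from data")
            exp(-spec@c * sum((x - y)^2))
        },
        linear = sum(x * y),
        polynomial = (sum(x * y) + spec@offset)^spec@degree)
}

## k(y, x_i) for all rows x_i of X -- the test-kernel vector Z
.kernelRow <- function(spec, X, y) {
    switch(spec@family,
        rbf = {
            d2 <- rowSums(sweep(X, 2L, y)^2)
            exp(-spec@c * d2)
        },
        linear = drop(X %*% y),
        polynomial = (drop(X %*% y) + spec@offset)^spec@degree,
        stop("precomputed kernels cannot evaluate new points from coordinates"))
}

#' Median-heuristic RBF bandwidth
#'
#' Returns \eqn{c = 1 / (2 \cdot \mathrm{median})} of the nonzero pairwise
#' squared Euclidean distances, a scale-free default for the RBF width.
#'
#' @param X numeric matrix, samples in rows (>= 2 distinct samples).
#' @returns a positive scalar.
#' @export
rbfBandwidth <- function(X) {
    X <- as.matrix(X)
    if (nrow(X) < 2L) stop("need at least two samples")
    d2 <- stats::dist(X)^2
    d2 <- d2[d2 > 0]
    if (length(d2) == 0L)
        stop("all samples are identical: median pairwise distance is zero")
    1 / (2 * stats::median(d2))
}

#' Compute the Gram matrix of a kernel over a data block
#'
#' @param spec a \linkS4class{KernelSpec}; an RBF spec with \code{c = NA}
#'   gets the median-heuristic bandwidth of \code{X}.
#' @param X numeric samples x variables matrix with finite entries.
#' @returns a \linkS4class{GramMatrix}.
#' @examples
#' X <- matrix(rnorm(20), 5, 4)
#' computeGram(kernelSpec("linear"), X)
#' @export
computeGram <- function(spec, X) {
    .checkDifferentiable(spec)
    X <- as.matrix(X)
    if (nrow(X) < 2L) stop("need at least two samples")
    if (any(!is.finite(X))) stop("input contains non-finite values")
    spec <- .resolveSpec(spec, X)
    ## rbf columns are built with the same kernel-row primitive used for
    ## test points, so projecting a training sample reproduces its Gram
    ## column bit-for-bit
    K <- switch(spec@family,
        rbf = vapply(seq_len(nrow(X)),
                     function(j) .kernelRow(spec, X, X[j, ]),
                     numeric(nrow(X))),
        linear = tcrossprod(X),
        polynomial = (tcrossprod(X) + spec@offset)^spec@degree)
    gramMatrix(K, sampleIds = if (is.null(rownames(X)))
        paste0("sample", seq_len(nrow(X))) else rownames(X))
}

#' Double-center a Gram matrix
#'
#' Computes the Gram matrix of implicitly mean-centred feature images from
#' its non-centred counterpart, retaining the column means and grand mean
#' of K so that test points can be projected later. Centering is
#' idempotent.
#'
#' @param K a \linkS4class{GramMatrix} or symmetric matrix.
#' @returns a \linkS4class{CenteredGram}.
#' @export
centerGram <- function(K) {
    ids <- if (is(K, "GramMatrix")) K@sampleIds else
        (rownames(K) %||% paste0("sample", seq_len(nrow(K))))
    K <- if (is(K, "GramMatrix")) K@values else as.matrix(K)
    m <- nrow(K)
    cm <- colMeans(K)
    g <- mean(K)
    ## same arithmetic (and order) as the test-point projection, so the
    ## centred training rows match projected training points bit-for-bit
    Kt <- K - matrix(cm, m, m, byrow = TRUE) - matrix(cm, m, m) + g
    new("CenteredGram", values = Kt, colMeansK = cm, grandMean = g,
        m = m, sampleIds = as.character(ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direct sum of Gram matrices
#'
#' Fuses blocks through the direct-sum kernel
#' \eqn{(k_1 \oplus k_2)((x_1, x_2), (x'_1, x'_2)) = k_1(x_1, x'_1) +
#' k_2(x_2, x'_2)}: elementwise addition of the per-block Gram matrices,
#' which preserves symmetry and positive semidefiniteness.
#'
#' @param grams list of \linkS4class{GramMatrix} objects sharing sample ids
#'   and order.
#' @returns a \linkS4class{GramMatrix}.
#' @export
directSum <- function(grams) {
    stopifnot(length(grams) >= 1L)
    ids <- grams[[1L]]@sampleIds
    for (g in grams[-1L])
        if (!identical(g@sampleIds, ids))
            stop("all Gram matrices must share sample ids and ordering")
    K <- Reduce(`+`, lapply(grams, gramValues))
    gramMatrix(K, sampleIds = ids)
}

.resolveVariables <- function(vars, X) {
    if (is.character(vars)) {
        idx <- match(vars, colnames(X))
        if (anyNA(idx))
            stop("unknown variable(s): ", paste(vars[is.na(idx)], collapse = ", "))
        idx
    } else {
        idx <- as.integer(vars)
        if (any(idx < 1L | idx > ncol(X))) stop("variable index out of range")
        idx
    }
}

#' Analytic kernel gradient along a variable direction
#'
#' Component i of the returned vector is
#' \eqn{\sum_t c_t \, \partial k(y, x_i) / \partial y_{k_t}} at \eqn{y = a}:
#' the derivative of the test-kernel vector Z along the input-space line
#' \eqn{a + s \sum_t c_t e_{k_t}} at s = 0. For the RBF kernel and a single
#' variable k this is \eqn{-2c\,k(a, x_i)(a_k - x_{ik})}; for the linear
#' kernel it is \eqn{\sum_t c_t x_{i,k_t}}.
#'
#' @param spec a differentiable \linkS4class{KernelSpec}.
#' @param X the block's samples x variables matrix (on the scale the model
#'   was fitted on).
#' @param variables variable names or indices forming the direction.
#' @param a anchor point in the block's input space.
#' @param weights combination weights (default 1 each).
#' @returns numeric vector of length \code{nrow(X)}.
#' @export
kernelGradient <- function(spec, X, variables, a, weights = 1) {
    .checkDifferentiable(spec)
    X <- as.matrix(X)
    idx <- .resolveVariables(variables, X)
    w <- rep_len(as.numeric(weights), length(idx))
    a <- as.numeric(a)
    if (length(a) != ncol(X)) stop("anchor dimension does not match the block")
    unname(switch(spec@family,
        rbf = {
            Ka <- .kernelRow(spec, X, a)
            diffs <- matrix(a[idx], nrow(X), length(idx), byrow = TRUE) -
                X[, idx, drop = FALSE]
            -2 * spec@c * Ka * drop(diffs %*% w)
        },
        linear = drop(X[, idx, drop = FALSE] %*% w),
        polynomial = {
            s <- drop(X %*% a)
            spec@degree * (s + spec@offset)^(spec@degree - 1) *
                drop(X[, idx, drop = FALSE] %*% w)
        }))
}

## gradient vectors for ALL training anchors at once: row beta holds
## dZ_i/ds at a = x_beta. K is the block's uncentered Gram (rbf only).
.gradientMatrix <- function(spec, X, idx, w, K = NULL) {
    m <- nrow(X)
    switch(spec@family,
        rbf = {
            if (is.null(K)) K <- gramValues(computeGram(spec, X))
            v <- drop(X[, idx, drop = FALSE] %*% w)
            ## Diff[beta, i] = sum_t w_t (x_{beta,k_t} - x_{i,k_t})
            Diff <- matrix(v, m, m) - matrix(v, m, m, byrow = TRUE)
            -2 * spec@c * K * Diff
        },
        linear = {
            g <- drop(X[, idx, drop = FALSE] %*% w)
            matrix(g, m, m, byrow = TRUE)
        },
        polynomial = {
            S <- tcrossprod(X)
            g <- drop(X[, idx, drop = FALSE] %*% w)
            spec@degree * (S + spec@offset)^(spec@degree - 1) *
                matrix(g, m, m, byrow = TRUE)
        },
        stop("precomputed kernels have no gradient"))
}

#' Central-difference kernel gradient (numeric oracle)
#'
#' Finite-difference counterpart of \code{\link{kernelGradient}}:
#' \eqn{(Z(a + h d) - Z(a - h d)) / (2h)} with d the direction's weight
#' vector embedded in the block's input space. Exact for the linear kernel
#' at any step size.
#'
#' @inheritParams kernelGradient
#' @param h positive step size on the block's data scale.
#' @returns numeric vector of length \code{nrow(X)}.
#' @export
numericGradient <- function(spec, X, variables, a, weights = 1, h = 1e-5) {
    .checkDifferentiable(spec)
    stopifnot(h > 0)
    X <- as.matrix(X)
    idx <- .resolveVariables(variables, X)
    w <- rep_len(as.numeric(weights), length(idx))
    d <- numeric(ncol(X))
    d[idx] <- w
    unname(.kernelRow(spec, X, as.numeric(a) + h * d) -
        .kernelRow(spec, X, as.numeric(a) - h * d)) / (2 * h)
}
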