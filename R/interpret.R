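## Variable curves and tangent fields on the embedding, centroid reference
## directions, the cosine-averaging correlation statistic, variable
## ranking, and group-median profiles.

.resolveBlock <- function(model, block) {
    if (is.null(model@training))
        stop("variable representation needs an explicit kernel function; ",
             "this model was fitted from a precomputed Gram matrix")
    nms <- names(model@training@blocks)
    idx <- if (suppressWarnings(!is.na(as.integer(block))))
        as.integer(block) else match(block, nms)
    if (is.na(idx) || idx < 1L || idx > length(nms))
        stop("unknown block: ", block)
    idx
}

.resolveAnchors <- function(model, anchors) {
    if (is.null(anchors)) return(seq_len(model@m))
    if (is.character(anchors)) {
        idx <- match(anchors, model@sampleIds)
        if (anyNA(idx))
            stop("unknown sample id(s): ",
                 paste(anchors[is.na(idx)], collapse = ", "))
        idx
    } else {
        idx <- as.integer(anchors)
        if (any(idx < 1L | idx > model@m)) stop("anchor index out of range")
        idx
    }
}

#' Induced curve of a variable through the embedding
#'
#' Traces the image of the input-space line \eqn{y(s) = a + s d}, where d
#' embeds the direction's weights into the block holding its variables and
#' a is a training sample, through the fitted kernel PCA projection. At
#' s = 0 the curve passes through the anchor's embedding; its tangent there
#' is the local direction of maximum growth of the variable (see
#' \code{\link{tangentField}}). For fused models the other blocks stay at
#' the anchor's coordinates. The line moves on the scale the model was
#' fitted on (standardized coordinates when standardization is on).
#'
#' @param model a fitted \linkS4class{KPCAModel} with a differentiable
#'   kernel.
#' @param spec a \linkS4class{DirectionSpec}.
#' @param anchor a training sample id or index.
#' @param s numeric vector of curve parameters.
#' @returns a length(s) x r matrix of embedding coordinates.
#' @export
variableCurve <- function(model, spec, anchor, s) {
    l <- .resolveBlock(model, spec@block)
    .checkDifferentiable(model@specs[[l]])
    i <- .resolveAnchors(model, anchor)
    if (length(i) != 1L) stop("exactly one anchor required")
    Xl <- model@training@blocks[[l]]
    idx <- .resolveVariables(spec@variables, Xl)
    d <- numeric(ncol(Xl))
    d[idx] <- spec@weights
    blocksList <- lapply(model@training@blocks, function(X)
        X[rep(i, length(s)), , drop = FALSE])
    blocksList[[l]] <- blocksList[[l]] + outer(s, d)
    co <- .projectStd(model, blocksList)
    dimnames(co) <- list(format(s), paste0("comp_", seq_len(model@r)))
    co
}

#' Tangent field of a variable or linear combination
#'
#' For each anchor (by default every training sample) computes the tangent
#' at s = 0 of the induced curve of the direction: in matrix form
#' \eqn{(dZ^\top/ds)(I - \tfrac1m 1 1^\top)\tilde V}, with the gradient of
#' the test-kernel vector taken analytically through the chain rule. In a
#' fused model the gradient involves only the kernel of the block the
#' variables belong to. The resulting arrows, attached at the sample
#' embeddings, point towards samples with higher values of the variable.
#'
#' @param model a fitted \linkS4class{KPCAModel} with a differentiable
#'   kernel for the direction's block.
#' @param spec a \linkS4class{DirectionSpec} (or a variable name/index,
#'   promoted to one on block 1).
#' @param anchors training sample ids or indices; default all.
#' @returns a \linkS4class{TangentField}.
#' @examples
#' toy <- makeToyData(seed = 1)
#' fit <- fitKPCA(toy$data, kernelSpec("rbf"))
#' tf <- tangentField(fit, directionSpec("X1"))
#' head(tangentVectors(tf))
#' @export
tangentField <- function(model, spec, anchors = NULL) {
    if (!is(spec, "DirectionSpec")) spec <- directionSpec(spec)
    l <- .resolveBlock(model, spec@block)
    sp <- model@specs[[l]]
    .checkDifferentiable(sp)
    Xl <- model@training@blocks[[l]]
    idx <- .resolveVariables(spec@variables, Xl)
    ai <- .resolveAnchors(model, anchors)
    Kl <- gramValues(computeGram(sp, Xl))
    G <- .gradientMatrix(sp, Xl, idx, spec@weights, K = Kl)[ai, , drop = FALSE]
    V <- (G - rowMeans(G)) %*% model@A
    dimnames(V) <- list(model@sampleIds[ai], colnames(model@scores))
    new("TangentField", vectors = V,
        anchors = model@scores[ai, , drop = FALSE],
        norms = sqrt(rowSums(V^2)), spec = spec,
        anchorIds = model@sampleIds[ai])
}

#' Reference direction between two group centroids
#'
#' Returns the vector from the centroid of \code{from} to the centroid of
#' \code{to} in the embedding (unnormalized); with \code{from = NULL} the
#' grand centroid of all points is used as the base. Swapping the groups
#' negates the direction.
#'
#' @param x an \linkS4class{Embedding}, \linkS4class{KPCAModel} (training
#'   scores) or coordinate matrix.
#' @param labels group label per point.
#' @param to,from group labels selecting the tip and base centroids.
#' @returns a numeric r-vector.
#' @export
centroidDirection <- function(x, labels, to, from = NULL) {
    co <- if (is(x, "Embedding")) x@coords else if (is(x, "KPCAModel"))
        x@scores else as.matrix(x)
    labels <- as.character(labels)
    if (length(labels) != nrow(co))
        stop("one label per point required")
    pick <- function(g) {
        sel <- labels == g
        if (!any(sel)) stop("label not found or group empty: ", g)
        colMeans(co[sel, , drop = FALSE])
    }
    base <- if (is.null(from)) colMeans(co) else pick(from)
    w <- pick(to) - base
    if (sqrt(sum(w^2)) < .DEGENERATE_NORM)
        warning("centroid direction is (numerically) the zero vector")
    w
}

#' Cosine correlation of a tangent field with a reference direction
#'
#' Attaches a parallel copy of the reference vector w at every anchor and
#' averages the cosine of the angle between w and the field's tangent
#' vector there:
#' \deqn{R = \frac1m \sum_i \cos\angle(w_i, (d\sigma/ds|_0)_{x_i}).}
#' Anchors whose tangent (or per-sample reference) has norm below 1e-12
#' are excluded from the mean and standard deviation and counted in
#' \code{n_skipped}: the cosine is undefined there, and zeroing it would
#' bias R towards 0.
#'
#' @param field a \linkS4class{TangentField}.
#' @param w a nonzero r-vector, or an n_anchor x r matrix giving one
#'   reference vector per anchor (used when a variable's own tangent field
#'   serves as the reference).
#' @returns a list with elements \code{R} (mean cosine), \code{sd} (sample
#'   standard deviation of the per-anchor cosines), \code{cosines},
#'   \code{nUsed} and \code{nSkipped}.
#' @export
directionCorrelation <- function(field, w) {
    V <- field@vectors
    n <- nrow(V)
    if (is.matrix(w)) {
        if (!all(dim(w) == dim(V)))
            stop("per-anchor reference must match the field's dimensions")
        W <- w
    } else {
        if (length(w) != ncol(V)) stop("reference dimension must equal r")
        if (sqrt(sum(w^2)) < .DEGENERATE_NORM)
            stop("reference direction must be nonzero")
        W <- matrix(w, n, length(w), byrow = TRUE)
    }
    nv <- sqrt(rowSums(V^2))
    nw <- sqrt(rowSums(W^2))
    ok <- nv >= .DEGENERATE_NORM & nw >= .DEGENERATE_NORM
    if (!any(ok)) stop("all tangent vectors are degenerate")
    cosines <- rep(NA_real_, n)
    cosines[ok] <- rowSums(V[ok, , drop = FALSE] * W[ok, , drop = FALSE]) /
        (nv[ok] * nw[ok])
    cosines <- pmin(1, pmax(-1, cosines))
    list(R = mean(cosines[ok]),
         sd = if (sum(ok) > 1L) stats::sd(cosines[ok]) else NA_real_,
         cosines = cosines, nUsed = sum(ok), nSkipped = sum(!ok))
}

#' Rank all variables against a reference direction
#'
#' Computes the tangent field of every variable in every (requested) block
#' and its mean/sd cosine statistic against a reference direction, then
#' orders variables by mean cosine, descending — variables at the top grow
#' towards the reference's tip, variables at the bottom away from it.
#'
#' The reference may be (i) an explicit r-vector, (ii) a pair of group
#' labels (with \code{labels}), resolved to the centroid-to-centroid
#' direction, or (iii) a \linkS4class{DirectionSpec} naming a variable:
#' then each variable is compared with that variable's own tangent at the
#' same sample (per-sample pairing; set \code{refMode = "mean"} to compare
#' against the single mean tangent vector instead).
#'
#' @param model a fitted \linkS4class{KPCAModel} with differentiable
#'   kernels.
#' @param reference numeric r-vector, character vector
#'   \code{c(from, to)} of two group labels, or a
#'   \linkS4class{DirectionSpec}.
#' @param labels group labels (required for a group-pair reference).
#' @param whichBlocks blocks to rank (names or indices); default all.
#' @param refMode how a variable-as-reference is paired; see Details.
#' @returns a \linkS4class{DirectionRanking}.
#' @examples
#' toy <- makeToyData(seed = 1)
#' fit <- fitKPCA(toy$data, kernelSpec("rbf"))
#' w <- centroidDirection(trainingEmbedding(fit), toy$groups, to = "g1")
#' rankVariables(fit, w)
#' @export
rankVariables <- function(model, reference, labels = NULL,
                          whichBlocks = NULL,
                          refMode = c("per-sample", "mean")) {
    refMode <- match.arg(refMode)
    if (is.null(model@training))
        stop("ranking needs an explicit kernel function; this model was ",
             "fitted from a precomputed Gram matrix")
    for (sp in model@specs) .checkDifferentiable(sp)
    W <- NULL
    if (is(reference, "DirectionSpec")) {
        refField <- tangentField(model, reference)
        W <- if (refMode == "per-sample") refField@vectors else
            colMeans(refField@vectors)
        refDesc <- sprintf("variable %s (block %s, %s pairing)",
            paste(reference@variables, collapse = "+"), reference@block,
            refMode)
    } else if (is.character(reference)) {
        if (length(reference) != 2L)
            stop("a group reference must be c(from, to)")
        if (is.null(labels)) stop("labels are required for a group reference")
        W <- centroidDirection(model@scores, labels, to = reference[2L],
                               from = reference[1L])
        refDesc <- sprintf("centroid direction %s -> %s",
                           reference[1L], reference[2L])
    } else {
        W <- as.numeric(reference)
        refDesc <- sprintf("vector (%s)",
                           paste(signif(W, 3), collapse = ", "))
    }
    if (!is.matrix(W) && sqrt(sum(W^2)) < .DEGENERATE_NORM)
        stop("reference direction resolves to the zero vector")
    blockIdx <- if (is.null(whichBlocks)) seq_along(model@training@blocks)
        else vapply(whichBlocks, function(b) .resolveBlock(model, b), 0L)
    rows <- list()
    for (l in blockIdx) {
        sp <- model@specs[[l]]
        Xl <- model@training@blocks[[l]]
        Kl <- gramValues(computeGram(sp, Xl))
        bname <- names(model@training@blocks)[l]
        for (k in seq_len(ncol(Xl))) {
            G <- .gradientMatrix(sp, Xl, k, 1, K = Kl)
            V <- (G - rowMeans(G)) %*% model@A
            fld <- new("TangentField", vectors = V, anchors = model@scores,
                       norms = sqrt(rowSums(V^2)),
                       spec = directionSpec(k, block = bname),
                       anchorIds = model@sampleIds)
            dc <- directionCorrelation(fld, W)
            rows[[length(rows) + 1L]] <- data.frame(
                variable = colnames(Xl)[k], block = bname,
                mean = dc$R, sd = dc$sd, n_used = dc$nUsed,
                n_skipped = dc$nSkipped, stringsAsFactors = FALSE)
        }
    }
    tb <- do.call(rbind, rows)
    tb <- tb[order(-tb$mean), , drop = FALSE]
    rownames(tb) <- NULL
    new("DirectionRanking", reference = refDesc, table = tb)
}

#' Per-group medians of a variable
#'
#' @param values numeric vector, one value per sample.
#' @param groups group label per sample; the output follows the given
#'   group order (factor levels, or first appearance otherwise).
#' @returns a named numeric vector of group medians.
#' @examples
#' groupMedianProfile(c(1, 2, 3, 100), c("a", "a", "b", "b"))
#' @export
groupMedianProfile <- function(values, groups) {
    if (length(values) != length(groups))
        stop("labels must cover all samples")
    lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
    groups <- as.character(groups)
    out <- vapply(lv, function(g) {
        sel <- groups == g
        if (!any(sel)) stop("empty group: ", g)
        stats::median(values[sel])
    }, numeric(1))
    names(out) <- lv
    out
}
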