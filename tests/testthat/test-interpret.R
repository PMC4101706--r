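toyFit <- local({
    toy <- makeToyData(seed = 1)
    list(toy = toy, fit = fitKPCA(toy$data, kernelSpec("rbf")))
})

test_that("variable curves pass through the anchor image and have tangent slope", {
    fit <- toyFit$fit
    spec <- directionSpec("X1")
    co <- variableCurve(fit, spec, anchor = 3, s = 0)
    expect_equal(drop(co), scores(fit)[3, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
    # slope at 0 matches the analytic tangent
    tf <- tangentField(fit, spec, anchors = 3)
    expect_lt(relErr(curveSlope(fit, spec, 3), drop(tangentVectors(tf))),
              1e-5)
})

test_that("linear-kernel variable curves are affine in the curve parameter", {
    X <- randData(10, 4, seed = 31)
    fit <- fitKPCA(X, kernelSpec("linear"), standardize = FALSE)
    co <- variableCurve(fit, directionSpec(2), anchor = 1,
                        s = c(-2, -1, 0, 1, 2, 5))
    d1 <- diff(co)
    steps <- diff(c(-2, -1, 0, 1, 2, 5))
    slopes <- d1 / steps
    for (j in seq_len(ncol(co)))
        expect_lt(max(abs(slopes[, j] - slopes[1, j])), 1e-9)
})

test_that("tangent fields are linear in direction coefficients", {
    fit <- toyFit$fit
    t1 <- tangentVectors(tangentField(fit, directionSpec("X1")))
    t3 <- tangentVectors(tangentField(fit, directionSpec("X3")))
    t13 <- tangentVectors(tangentField(
        fit, directionSpec(c("X1", "X3"), weights = c(2, -0.5))))
    expect_equal(t13, 2 * t1 - 0.5 * t3, tolerance = 1e-12)
})

test_that("every tangent vector matches the projected central difference of its curve", {
    fit <- toyFit$fit
    for (v in c("X1", "X4", "X6")) {
        spec <- directionSpec(v)
        V <- tangentVectors(tangentField(fit, spec))
        for (i in seq_len(nrow(V)))
            expect_lt(relErr(curveSlope(fit, spec, i), V[i, ]), 1e-5)
    }
})

test_that("toy X1/X2 tangent fields point towards the group-1 centroid", {
    fit <- toyFit$fit
    toy <- toyFit$toy
    w <- centroidDirection(trainingEmbedding(fit), toy$groups, to = "g1")
    for (v in c("X1", "X2")) {
        dc <- directionCorrelation(tangentField(fit, directionSpec(v)), w)
        expect_gt(dc$R, 0)
    }
})

test_that("centroid directions behave like centroid differences", {
    co <- rbind(c(-1, 0), c(1, 0))
    w <- centroidDirection(co, c("a", "b"), to = "b", from = "a")
    expect_equal(w, c(2, 0), ignore_attr = TRUE)
    expect_equal(centroidDirection(co, c("a", "b"), to = "a", from = "b"),
                 -w, ignore_attr = TRUE)
    expect_warning(centroidDirection(co, c("a", "b"), to = "a", from = "a"),
                   "zero")
    expect_error(centroidDirection(co, c("a", "b"), to = "missing"),
                 "not found")
    # toy g1 -> g3 direction points predominantly along the PC1 axis
    wg <- centroidDirection(trainingEmbedding(toyFit$fit), toyFit$toy$groups,
                            to = "g3", from = "g1")
    expect_gt(abs(wg[1]), 2 * abs(wg[2]))
})

test_that("cosine correlation handles parallel, antiparallel, orthogonal and degenerate fields", {
    mkField <- function(V) {
        new("TangentField", vectors = V, anchors = V * 0,
            norms = sqrt(rowSums(V^2)), spec = directionSpec(1),
            anchorIds = paste0("s", seq_len(nrow(V))))
    }
    w <- c(1, 2)
    Vpar <- matrix(w, 5, 2, byrow = TRUE) * c(1, 2, 3, 4, 5)
    expect_equal(directionCorrelation(mkField(Vpar), w)$R, 1)
    expect_equal(directionCorrelation(mkField(Vpar), w)$sd, 0)
    expect_equal(directionCorrelation(mkField(-Vpar), w)$R, -1)
    Vorth <- matrix(c(-2, 1), 5, 2, byrow = TRUE)
    expect_equal(directionCorrelation(mkField(Vorth), w)$R, 0)
    # degenerate rows are skipped, not zeroed
    Vdeg <- rbind(w, c(0, 0), w)
    dc <- directionCorrelation(mkField(Vdeg), w)
    expect_equal(dc$R, 1)
    expect_equal(dc$nUsed, 2L)
    expect_equal(dc$nSkipped, 1L)
    expect_error(directionCorrelation(mkField(Vpar), c(0, 0)), "nonzero")
    expect_error(directionCorrelation(mkField(matrix(0, 3, 2)), w),
                 "degenerate")
})

test_that("cosine correlation is antisymmetric and scale invariant", {
    fit <- toyFit$fit
    tf <- tangentField(fit, directionSpec("X2"))
    w <- c(0.3, -0.8)
    dc <- directionCorrelation(tf, w)
    expect_equal(directionCorrelation(tf, -w)$R, -dc$R)
    expect_equal(directionCorrelation(tf, 7.3 * w)$R, dc$R)
    expect_true(all(abs(dc$cosines) <= 1))
    # rescaling the field rows does not change R
    tf2 <- tf
    tf2@vectors <- tf@vectors * 12.5
    tf2@norms <- tf@norms * 12.5
    expect_equal(directionCorrelation(tf2, w)$R, dc$R)
})

test_that("variable ranking is sorted, complete, and exact for self-reference", {
    fit <- toyFit$fit
    toy <- toyFit$toy
    rk <- rankVariables(fit, c("g3", "g1"), labels = toy$groups)
    tb <- rankingTable(rk)
    expect_setequal(tb$variable, paste0("X", 1:6))
    expect_false(is.unsorted(rev(tb$mean)))
    expect_true(all(tb$n_used + tb$n_skipped == 18))
    # a variable referenced against itself has mean cosine 1
    rkSelf <- rankVariables(fit, directionSpec("X5"))
    tbS <- rankingTable(rkSelf)
    expect_equal(tbS$mean[tbS$variable == "X5"], 1)
    # group-pair and explicit-vector references agree
    w <- centroidDirection(trainingEmbedding(fit), toy$groups,
                           to = "g1", from = "g3")
    rkW <- rankVariables(fit, w)
    expect_equal(rankingTable(rkW)$mean,
                 rankingTable(rankVariables(fit, c("g3", "g1"),
                                            labels = toy$groups))$mean)
})

test_that("tangent fields in a fused model use only their block's kernel", {
    sim <- makeMultiBlockSim(seed = 5, m = 20, p1 = 10, p2 = 6)
    mbd <- multiBlockData(sim$blocks, standardize = FALSE)
    fit <- fitKPCA(mbd, kernelSpec("rbf", c = 0.05))
    # replace block 2 by a surrogate with the bit-identical Gram (negation)
    mbd2 <- multiBlockData(list(expression = sim$blocks[[1]],
                                lipids = -sim$blocks[[2]]),
                           standardize = FALSE)
    fit2 <- fitKPCA(mbd2, kernelSpec("rbf", c = 0.05))
    f1 <- tangentField(fit, directionSpec(3, block = "expression"))
    f2 <- tangentField(fit2, directionSpec(3, block = "expression"))
    expect_identical(tangentVectors(f1), tangentVectors(f2))
})

test_that("group medians match a sort-based oracle and preserve group order", {
    expect_equal(groupMedianProfile(c(1, 2, 3, 100), c("a", "a", "b", "b")),
                 c(a = 1.5, b = 51.5))
    expect_equal(groupMedianProfile(rep(4.2, 9), rep(c("x", "y", "z"), 3)),
                 c(x = 4.2, y = 4.2, z = 4.2))
    sortMedian <- function(v) {
        v <- sort(v)
        n <- length(v)
        if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    }
    set.seed(17)
    values <- rnorm(1000)
    groups <- sample(letters[1:6], 1000, replace = TRUE)
    got <- groupMedianProfile(values, groups)
    for (g in unique(groups))
        expect_equal(unname(got[g]), sortMedian(values[groups == g]))
    # order follows first appearance / factor levels
    expect_identical(names(groupMedianProfile(1:4, c("b", "a", "b", "a"))),
                     c("b", "a"))
    expect_identical(
        names(groupMedianProfile(1:4, factor(c("b", "a", "b", "a"),
                                             levels = c("a", "b")))),
        c("a", "b"))
    expect_error(groupMedianProfile(1:3, factor(c("a", "a", "a"),
                                                levels = c("a", "b"))),
                 "empty group")
})
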