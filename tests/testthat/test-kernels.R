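test_that("pointwise kernel evaluation matches closed forms and is symmetric", {
    rbf <- kernelSpec("rbf", c = 0.5)
    expect_equal(evalKernel(rbf, c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(evalKernel(kernelSpec("linear"), c(1, 2), c(3, 4)), 11)
    # closed form exp(-c ||x-z||^2) at c = 0.5, distance 1
    expect_equal(evalKernel(rbf, c(0, 0), c(1, 0)), 0.606530659712633,
                 tolerance = 1e-12)
    set.seed(42)
    for (i in 1:20) {
        x <- rnorm(4); y <- rnorm(4)
        spec <- list(rbf, kernelSpec("linear"),
                     kernelSpec("polynomial", degree = 3))[[1 + i %% 3]]
        expect_identical(evalKernel(spec, x, y), evalKernel(spec, y, x))
    }
    expect_true(evalKernel(rbf, rnorm(3), rnorm(3)) <= 1)
    expect_error(evalKernel(rbf, 1:2, 1:3), "dimension")
    expect_error(evalKernel(kernelSpec("precomputed"), 1, 1), "precomputed")
})

test_that("Gram construction matches a double-loop oracle", {
    X <- randData(8, 3, seed = 7)
    expect_equal(gramValues(computeGram(kernelSpec("linear"),
                                        rbind(c(1, 0), c(0, 1)))),
                 diag(2), ignore_attr = TRUE)
    for (spec in list(kernelSpec("rbf", c = 0.3), kernelSpec("linear"),
                      kernelSpec("polynomial", degree = 2, offset = 1))) {
        K <- gramValues(computeGram(spec, X))
        expect_equal(K, naiveGram(spec, X), ignore_attr = TRUE,
                     tolerance = 1e-12)
    }
    expect_equal(diag(gramValues(computeGram(kernelSpec("rbf", c = 2), X))),
                 rep(1, 8), ignore_attr = TRUE)
    Xbad <- X; Xbad[2, 2] <- NA
    expect_error(computeGram(kernelSpec("rbf", c = 1), Xbad), "non-finite")
})

test_that("median-heuristic bandwidth matches brute-force pair enumeration", {
    expect_equal(rbfBandwidth(rbind(c(0, 0), c(1, 0))), 0.5)
    X <- randData(10, 4, seed = 3)
    d2 <- numeric(0)
    for (i in 1:9) for (j in (i + 1):10)
        d2 <- c(d2, sum((X[i, ] - X[j, ])^2))
    expect_length(d2, 45)
    expect_equal(rbfBandwidth(X), 1 / (2 * median(d2)))
    # homogeneity: scaling data by t scales c by 1/t^2
    expect_equal(rbfBandwidth(3 * X), rbfBandwidth(X) / 9)
    expect_error(rbfBandwidth(rbind(c(1, 2), c(1, 2))), "identical")
})

test_that("double centering zeroes margins, is idempotent, and matches explicit centering", {
    K <- diag(2)
    expect_equal(gramValues(centerGram(K)),
                 matrix(c(0.5, -0.5, -0.5, 0.5), 2), ignore_attr = TRUE)
    expect_equal(gramValues(centerGram(matrix(3.7, 4, 4))),
                 matrix(0, 4, 4), ignore_attr = TRUE)
    # a linear-kernel Gram centred in kernel space equals the Gram of
    # explicitly mean-centred features
    X <- randData(20, 6, seed = 11)
    Kt <- gramValues(centerGram(computeGram(kernelSpec("linear"), X)))
    Xc <- scale(X, scale = FALSE)
    expect_equal(Kt, tcrossprod(Xc), ignore_attr = TRUE, tolerance = 1e-9)
    expect_lt(max(abs(rowSums(Kt))), 1e-9 * 20 * max(abs(Kt)))
    # idempotence
    expect_equal(gramValues(centerGram(Kt)), Kt, tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("direct-sum fusion adds Gram matrices and preserves PSD structure", {
    X1 <- randData(6, 3, seed = 1); X2 <- randData(6, 4, seed = 2)
    K1 <- computeGram(kernelSpec("linear"), X1)
    K2 <- computeGram(kernelSpec("linear"), X2)
    zero <- gramMatrix(matrix(0, 6, 6), sampleIds = sampleIds(K1))
    expect_equal(gramValues(directSum(list(K1, zero))), gramValues(K1))
    # concatenation oracle for linear kernels
    expect_equal(gramValues(directSum(list(K1, K2))),
                 tcrossprod(cbind(X1, X2)), ignore_attr = TRUE,
                 tolerance = 1e-12)
    R1 <- computeGram(kernelSpec("rbf", c = 1), X1)
    R2 <- computeGram(kernelSpec("rbf", c = 2), X2)
    S <- directSum(list(R1, R2))
    expect_equal(diag(gramValues(S)), rep(2, 6), ignore_attr = TRUE)
    V <- gramValues(S)
    expect_lt(max(abs(V - t(V))), 1e-12)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    K3 <- gramMatrix(gramValues(K2), sampleIds = rev(sampleIds(K2)))
    expect_error(directSum(list(K1, K3)), "ordering")
})

test_that("analytic kernel gradients agree with central differences", {
    X <- randData(12, 5, seed = 5)
    # anchor at a training point: its own component vanishes for rbf
    g <- kernelGradient(kernelSpec("rbf", c = 0.7), X, 2, X[4, ])
    expect_equal(g[4], 0)
    # closed-form check at c = 0.5
    g2 <- kernelGradient(kernelSpec("rbf", c = 0.5), rbind(c(1, 0), c(2, 2)),
                         1, a = c(0, 0))
    expect_equal(g2[1], exp(-0.5), tolerance = 1e-12)
    # singleton combination equals the single-variable gradient
    expect_equal(kernelGradient(kernelSpec("rbf", c = 0.7), X, 3, X[1, ],
                                weights = 1),
                 kernelGradient(kernelSpec("rbf", c = 0.7), X,
                                variables = c(3), X[1, ]))
    # sweep: analytic vs numeric over random anchors/directions/kernels
    set.seed(99)
    for (spec in list(kernelSpec("rbf", c = 0.4), kernelSpec("linear"),
                      kernelSpec("polynomial", degree = 3, offset = 1))) {
        for (i in 1:35) {
            a <- rnorm(5)
            vars <- sample(5, sample(1:3, 1))
            w <- rnorm(length(vars))
            ana <- kernelGradient(spec, X, vars, a, weights = w)
            num <- numericGradient(spec, X, vars, a, weights = w, h = 1e-5)
            expect_lt(relErr(ana, num), 1e-5)
        }
    }
    # additivity in direction coefficients
    gA <- kernelGradient(kernelSpec("rbf", c = 0.4), X, 1, X[2, ])
    gB <- kernelGradient(kernelSpec("rbf", c = 0.4), X, 4, X[2, ])
    gAB <- kernelGradient(kernelSpec("rbf", c = 0.4), X, c(1, 4), X[2, ],
                          weights = c(2, -3))
    expect_equal(gAB, 2 * gA - 3 * gB, tolerance = 1e-12)
    expect_error(kernelGradient(kernelSpec("precomputed"), X, 1, X[1, ]),
                 "precomputed")
})

test_that("numeric gradient is exact for linear kernels and vanishes for zero weights", {
    X <- randData(9, 4, seed = 6)
    a <- rnorm(4)
    for (h in c(1e-3, 1e-5, 0.1))
        expect_equal(numericGradient(kernelSpec("linear"), X, 2, a, h = h),
                     unname(X[, 2]), tolerance = 1e-9)
    expect_equal(numericGradient(kernelSpec("rbf", c = 1), X, 2, a,
                                 weights = 0),
                 rep(0, 9))
})
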