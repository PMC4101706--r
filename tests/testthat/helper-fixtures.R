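# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# random samples x variables matrix with ids
randData <- function(m, p, seed = 1, sd = 1) {
    set.seed(seed)
    matrix(rnorm(m * p, sd = sd), m, p,
           dimnames = list(paste0("s", seq_len(m)), paste0("v", seq_len(p))))
}

# random PSD Gram matrix via a linear kernel on random features
randPSDGram <- function(m, p = max(3L, m %/% 3L), seed = 1) {
    X <- randData(m, p, seed = seed)
    gramMatrix(tcrossprod(X))
}

# double-loop Gram oracle, deliberately naive
naiveGram <- function(spec, X) {
    m <- nrow(X)
    K <- matrix(NA_real_, m, m)
    for (i in seq_len(m))
        for (j in seq_len(m))
            K[i, j] <- evalKernel(spec, X[i, ], X[j, ])
    K
}

# relative-error helper with an absolute floor for near-zero references
relErr <- function(got, want, floor = 1e-8) {
    sqrt(sum((got - want)^2)) / max(sqrt(sum(want^2)), floor)
}

# central-difference slope of a variable curve, projected: the independent
# oracle for tangent vectors
curveSlope <- function(model, spec, anchor, h = 1e-5) {
    co <- variableCurve(model, spec, anchor, c(-h, h))
    (co[2L, ] - co[1L, ]) / (2 * h)
}
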