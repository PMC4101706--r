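## Seeded generators: the 18-point, 6-variable, 3-group toy configuration
## and a balanced two-factor, two-block study design with planted signal.

## run code with a private RNG state so generator calls never share or
## disturb global generator statefulness
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Three-group toy configuration in six dimensions
#'
#' Generates 18 points in 6-dimensional space arranged in three groups of
#' six, defined by sum constraints on the coordinates:
#' \itemize{
#'   \item group 1: \eqn{X_1 + X_2 = 15} for all six points;
#'     \eqn{X_3 + X_4 + X_5 = 0} for three of them and 6 for the other
#'     three;
#'   \item group 2: \eqn{X_3 + X_4 + X_5 = 0} for all six;
#'     \eqn{X_1 + X_2 = 0} for three and -4 for the other three;
#'   \item group 3: \eqn{X_1 + X_2 = 0} for all six;
#'     \eqn{X_3 + X_4 + X_5 = 15} for three and 24 for the other three.
#' }
#' Each sum target is split equally across its coordinates (group 1:
#' \eqn{X_1 = X_2 = 7.5}, and so on); \code{split = "random"} draws a
#' random split of each target instead. Coordinates \eqn{X_1 \ldots X_5}
#' are then perturbed with independent Gaussian noise of standard
#' deviation \code{coordNoiseSd}, and \eqn{X_6} is drawn independently
#' from a Gaussian with mean zero and standard deviation \code{x6Sd} —
#' a pure-noise variable no direction in the embedding should favour.
#'
#' @param seed integer seed; same seed, bit-identical output.
#' @param coordNoiseSd noise standard deviation on X1..X5 (default 0.1,
#'   small against the smallest inter-group sum gap of 4).
#' @param x6Sd standard deviation of the X6 draw (default 0.5).
#' @param split how sum targets are distributed over their coordinates.
#' @returns a list with \code{data} (18 x 6 matrix), \code{groups} (factor
#'   g1/g2/g3), and \code{construction} (the noiseless 18 x 6 matrix).
#' @examples
#' toy <- makeToyData(seed = 1)
#' rowSums(toy$construction[1:6, 1:2])  # all 15
#' @export
makeToyData <- function(seed = 1L, coordNoiseSd = 0.1, x6Sd = 0.5,
                        split = c("equal", "random")) {
    split <- match.arg(split)
    if (coordNoiseSd <= 0 || x6Sd <= 0) stop("noise sds must be positive")
    splitSum <- function(target, ncoord) {
        if (split == "equal" || target == 0) rep(target / ncoord, ncoord)
        else { p <- stats::runif(ncoord); target * p / sum(p) }
    }
    .withSeed(seed, {
        C <- matrix(0, 18L, 6L,
                    dimnames = list(paste0("s", 1:18), paste0("X", 1:6)))
        fill <- function(rows, pairTarget, tripleTarget) {
            for (i in rows) {
                C[i, 1:2] <<- splitSum(pairTarget, 2L)
                C[i, 3:5] <<- splitSum(tripleTarget, 3L)
            }
        }
        fill(1:3, 15, 0); fill(4:6, 15, 6)      # group 1
        fill(7:9, 0, 0); fill(10:12, -4, 0)     # group 2
        fill(13:15, 0, 15); fill(16:18, 0, 24)  # group 3
        data <- C
        data[, 1:5] <- data[, 1:5] +
            matrix(stats::rnorm(18L * 5L, sd = coordNoiseSd), 18L, 5L)
        data[, 6] <- stats::rnorm(18L, mean = 0, sd = x6Sd)
        list(data = data,
             groups = factor(rep(c("g1", "g2", "g3"), each = 6L)),
             construction = C)
    })
}

#' Balanced two-factor, two-block simulated study
#'
#' Emulates the shape of a nutrigenomic-style design: m samples
#' cross-classified by genotype (two levels, WT / PPAR) and diet
#' (\code{nDiets} levels), with a large expression-like block and a small
#' concentration-like block measured on the same samples. All variables
#' are Gaussian noise of standard deviation \code{noiseSd}; a planted
#' subset per block receives additive group shifts — genotype-informative
#' variables are shifted by \code{genotypeEffect} in the second genotype,
#' diet-informative variables by \code{dietEffect} in one assigned diet —
#' and the planted identities are returned for recovery experiments.
#'
#' @param seed integer seed.
#' @param m samples (default 40); must be divisible by \code{2 * nDiets}.
#' @param p1,p2 variables in blocks 1 and 2 (defaults 120 and 21).
#' @param nDiets diet levels (default 5).
#' @param genotypeEffect,dietEffect additive shift sizes (defaults 2 and 1).
#' @param nInformative planted variables per factor in each block
#'   (recycled; default c(4, 2)).
#' @param noiseSd background noise standard deviation (default 1).
#' @returns a list with \code{blocks} (named list of two matrices),
#'   \code{genotype} and \code{diet} factors, and \code{planted} (per
#'   block, the genotype- and diet-informative column indices).
#' @export
makeMultiBlockSim <- function(seed = 1L, m = 40L, p1 = 120L, p2 = 21L,
                              nDiets = 5L, genotypeEffect = 2,
                              dietEffect = 1, nInformative = c(4L, 2L),
                              noiseSd = 1) {
    if (m %% (2L * nDiets) != 0L)
        stop("m must be divisible by 2 * nDiets for a balanced cross")
    if (noiseSd <= 0) stop("noiseSd must be positive")
    nInformative <- rep_len(as.integer(nInformative), 2L)
    ps <- c(p1, p2)
    if (any(2L * nInformative > ps))
        stop("informative counts exceed block sizes")
    perCell <- m %/% (2L * nDiets)
    design <- expand.grid(rep = seq_len(perCell),
                          diet = paste0("diet", seq_len(nDiets)),
                          genotype = c("WT", "PPAR"))
    genotype <- factor(design$genotype, levels = c("WT", "PPAR"))
    diet <- factor(design$diet)
    ids <- paste0("m", seq_len(m))
    .withSeed(seed, {
        prefixes <- c("G", "FA")
        blocks <- list()
        planted <- list()
        for (b in 1:2) {
            p <- ps[b]
            X <- matrix(stats::rnorm(m * p, sd = noiseSd), m, p,
                        dimnames = list(ids,
                            sprintf("%s%03d", prefixes[b], seq_len(p))))
            pos <- sample.int(p, 2L * nInformative[b])
            gIdx <- pos[seq_len(nInformative[b])]
            dIdx <- pos[nInformative[b] + seq_len(nInformative[b])]
            for (j in gIdx)
                X[genotype == "PPAR", j] <- X[genotype == "PPAR", j] +
                    genotypeEffect
            targets <- rep_len(levels(diet), length(dIdx))
            for (t in seq_along(dIdx))
                X[diet == targets[t], dIdx[t]] <-
                    X[diet == targets[t], dIdx[t]] + dietEffect
            blocks[[b]] <- X
            planted[[b]] <- list(genotype = sort(gIdx), diet = sort(dIdx))
        }
        names(blocks) <- c("expression", "lipids")
        names(planted) <- names(blocks)
        list(blocks = blocks, genotype = genotype, diet = diet,
             planted = planted)
    })
}
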