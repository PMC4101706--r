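## Feature-table readers/writers, block alignment, result export.

#' Read a samples-by-variables feature table
#'
#' Expects a delimited text file with a header row of variable names, a
#' first column of sample ids, and a numeric body. Missing values,
#' duplicate ids and non-numeric cells are hard errors reported with
#' row/column context — the methods here have no missing-data mechanism.
#'
#' @param path file path.
#' @param delim field delimiter; default comma, use \code{"\t"} for TSV.
#' @returns a numeric matrix with sample ids as row names.
#' @export
readFeatureTable <- function(path, delim = ",") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = delim,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L) stop("expected a sample-id column plus >= 1 variable")
    ids <- df[[1L]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
    body <- df[, -1L, drop = FALSE]
    X <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
    for (j in seq_len(ncol(body))) {
        v <- suppressWarnings(as.numeric(body[[j]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop(sprintf(
                "non-numeric or missing value in column '%s' (e.g. row '%s')",
                colnames(body)[j], ids[bad[1L]]))
        X[, j] <- v
    }
    X
}

#' Write a feature table as CSV
#'
#' @param x numeric matrix with sample ids as row names.
#' @param path output path.
#' @param idColumn name of the sample-id column.
#' @export
writeFeatureTable <- function(x, path, idColumn = "sample_id") {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a precomputed Gram matrix
#'
#' A square CSV whose header and first column carry matching sample ids.
#'
#' @param path file path.
#' @returns a \linkS4class{GramMatrix}.
#' @export
readGramMatrix <- function(path) {
    X <- readFeatureTable(path)
    if (nrow(X) != ncol(X) || !identical(rownames(X), colnames(X)))
        stop("a precomputed Gram matrix must be square with matching ",
             "row/column ids")
    gramMatrix(X)
}

#' Align feature tables on shared sample ids
#'
#' Reorders every table to the first table's sample order (alignment is by
#' id, not by row position) and bundles them into a
#' \linkS4class{MultiBlockData}. Tables whose id sets differ are rejected,
#' reporting the ids on each side of the symmetric difference.
#'
#' @param tables a list of numeric matrices with sample-id row names.
#' @param standardize see \code{\link{multiBlockData}}.
#' @returns a \linkS4class{MultiBlockData}.
#' @export
alignBlocks <- function(tables, standardize = TRUE) {
    if (!is.list(tables) || is.data.frame(tables)) tables <- list(tables)
    tables <- lapply(tables, as.matrix)
    ids <- rownames(tables[[1L]])
    if (is.null(ids)) stop("tables must carry sample ids as row names")
    for (i in seq_along(tables)[-1L]) {
        other <- rownames(tables[[i]])
        extra <- setdiff(other, ids)
        missing <- setdiff(ids, other)
        if (length(extra) || length(missing))
            stop(sprintf(
                "sample id mismatch in table %d: only there [%s]; only in table 1 [%s]",
                i, paste(extra, collapse = ", "),
                paste(missing, collapse = ", ")))
        tables[[i]] <- tables[[i]][ids, , drop = FALSE]
    }
    multiBlockData(tables, standardize = standardize)
}

#' Write an embedding as CSV
#'
#' Columns: sample id, then comp_1 ... comp_r.
#'
#' @param embedding an \linkS4class{Embedding}.
#' @param path output path.
#' @export
writeEmbedding <- function(embedding, path) {
    writeFeatureTable(embedding@coords, path)
}

#' Write a variable ranking as CSV
#'
#' Columns: variable, block, mean, sd, n_used, n_skipped.
#'
#' @param ranking a \linkS4class{DirectionRanking}.
#' @param path output path.
#' @export
writeRanking <- function(ranking, path) {
    utils::write.csv(ranking@table, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
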