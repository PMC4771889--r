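#' Read time-series expression data from tab-separated text
#'
#' Two dialects are accepted: (a) several files, one replicate series per
#' file, each with a header row of gene names and one row per time point;
#' (b) a single file whose first column is named \code{series} and labels
#' the replicate each row belongs to. Gene names must agree across files.
#'
#' @param paths character vector of one or more TSV paths.
#' @return An [ExpressionTimeSeries-class] object.
#' @examples
#' d <- generateDataset(benchmarkNetwork30(), 2, 5, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeExpression(d, f)
#' d2 <- readExpression(f)
#' @export
readExpression <- function(paths) {
    stopifnot(length(paths) >= 1L, all(file.exists(paths)))
    parseOne <- function(path) {
        df <- read.delim(path, check.names = FALSE,
                         colClasses = "character")
        if (ncol(df) < 1L || nrow(df) < 1L)
            stop(sprintf("%s: empty expression table", path))
        hasSeries <- identical(colnames(df)[1L], "series")
        seriesCol <- if (hasSeries) df[[1L]] else rep("1", nrow(df))
        vals <- df[, (1L + hasSeries):ncol(df), drop = FALSE]
        num <- suppressWarnings(
            vapply(vals, as.numeric, numeric(nrow(vals))))
        num <- matrix(num, nrow = nrow(vals),
                      dimnames = list(NULL, colnames(vals)))
        bad <- which(is.na(num) & !(vals == "NA"), arr.ind = TRUE)
        if (nrow(bad) > 0L)
            stop(sprintf(
                "%s: non-numeric value '%s' at data row %d, column '%s'",
                path, as.character(vals[bad[1L, 1L], bad[1L, 2L]]),
                bad[1L, 1L], colnames(vals)[bad[1L, 2L]]))
        if (anyNA(num))
            stop(sprintf("%s: missing values are not supported", path))
        split.data.frame(num, factor(seriesCol, levels = unique(seriesCol)))
    }
    mats <- unlist(lapply(paths, parseOne), recursive = FALSE)
    genes <- lapply(mats, colnames)
    if (length(unique(genes)) != 1L)
        stop("inconsistent gene names across series")
    dims <- vapply(mats, nrow, integer(1))
    if (length(unique(dims)) != 1L)
        stop("all series must have the same number of time points")
    ExpressionTimeSeries(mats)
}

#' Write time-series expression data as tab-separated text
#'
#' Writes either one file containing all series, with a leading
#' \code{series} column (the single-path form), or one file per series
#' with plain gene-name headers (when \code{paths} has one entry per
#' series). Output is readable by [readExpression()].
#'
#' @param dataset an [ExpressionTimeSeries-class] object.
#' @param paths a single path, or one path per series.
#' @param digits significant digits written (default 6; use 15 or more
#'   when exact round trips matter).
#' @return Invisibly, the paths written.
#' @export
writeExpression <- function(dataset, paths, digits = 6) {
    stopifnot(is(dataset, "ExpressionTimeSeries"))
    mats <- seriesMatrices(dataset)
    fmt <- function(m) {
        out <- matrix(formatC(m, digits = digits, format = "g"),
                      nrow(m), dimnames = dimnames(m))
        as.data.frame(out, check.names = FALSE)
    }
    if (length(paths) == 1L) {
        dfs <- lapply(seq_along(mats), function(k)
            cbind(series = k, fmt(mats[[k]])))
        write.table(do.call(rbind, dfs), paths, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    } else {
        stopifnot(length(paths) == length(mats))
        for (k in seq_along(mats))
            write.table(fmt(mats[[k]]), paths[k], sep = "\t",
                        quote = FALSE, row.names = FALSE)
    }
    invisible(paths)
}

#' Write a signed network
#'
#' Either as a signed adjacency matrix TSV (gene names as row and column
#' headers; entry (i, j) is the sign of the effect of gene j on gene i) or
#' as a three-column edge list \code{regulator, target, sign} with signs
#' \code{+}/\code{-} and 1-based indices.
#'
#' @param network a [SignedNetwork-class] object.
#' @param path output path.
#' @param format \code{"adjacency"} (default) or \code{"edges"}.
#' @return Invisibly, \code{path}.
#' @export
writeSignedNetwork <- function(network, path,
                               format = c("adjacency", "edges")) {
    stopifnot(is(network, "SignedNetwork"))
    format <- match.arg(format)
    if (format == "adjacency") {
        df <- as.data.frame(network@sign)
        write.table(cbind(gene = rownames(network@sign), df), path,
                    sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        write.table(edgeList(network), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}

#' Read a signed network
#'
#' Auto-detects the two formats written by [writeSignedNetwork()]: an
#' adjacency TSV (first column \code{gene}) or an edge list (columns
#' \code{regulator}, \code{target}, \code{sign}).
#'
#' @param path input path.
#' @param nGenes required for edge lists when the gene count cannot be
#'   inferred from the largest index present.
#' @return A [SignedNetwork-class] object.
#' @export
readSignedNetwork <- function(path, nGenes = NULL) {
    df <- read.delim(path, check.names = FALSE)
    if (all(c("regulator", "target", "sign") %in% colnames(df))) {
        n <- if (is.null(nGenes)) max(df$regulator, df$target) else nGenes
        s <- matrix(0, n, n)
        s[cbind(df$target, df$regulator)] <-
            ifelse(df$sign %in% c("+", "1"), 1, -1)
        return(SignedNetwork(s))
    }
    stopifnot(identical(colnames(df)[1L], "gene"))
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene
    SignedNetwork(m, geneNames = df$gene)
}

#' Preprocess raw stress-response time courses
#'
#' The standard preprocessing for the E. coli SOS DNA-repair expression
#' series (and similar raw time courses): the first time point of every
#' series -- an all-zero baseline in that experiment -- is dropped, then
#' every gene is min--max rescaled to \eqn{[0, 1]} within each series. A
#' gene that is constant after dropping (zero range) is set to 0.5 with a
#' warning.
#'
#' @param raw an [ExpressionTimeSeries-class] object with at least 3 time
#'   points.
#' @return A preprocessed [ExpressionTimeSeries-class] with one fewer time
#'   point and all values in \eqn{[0, 1]}.
#' @export
preprocessSOS <- function(raw) {
    stopifnot(is(raw, "ExpressionTimeSeries"), nTimepoints(raw) >= 3L)
    mats <- lapply(seriesMatrices(raw), function(m) {
        m <- m[-1L, , drop = FALSE]
        for (j in seq_len(ncol(m))) {
            r <- range(m[, j])
            if (diff(r) == 0) {
                warning(sprintf(
                    "gene %d constant after dropping first time point; set to 0.5",
                    j))
                m[, j] <- 0.5
            } else {
                m[, j] <- (m[, j] - r[1L]) / diff(r)
            }
        }
        m
    })
    ExpressionTimeSeries(mats, geneNames = geneNames(raw))
}

#' Write an inferred network and its artifacts
#'
#' Writes three files into \code{dir}: \code{weights.tsv} (fitted weight
#' matrix), \code{parameters.tsv} (per-gene regulators, weights, bias,
#' time constant, fitness, stop reason) and \code{edges.tsv} (called
#' signed edge list).
#'
#' @param inferred an [InferredNetwork-class] object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeInferredNetwork <- function(inferred, dir) {
    stopifnot(is(inferred, "InferredNetwork"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gn <- geneNames(inferred)
    if (is.null(gn)) gn <- paste0("G", seq_len(nGenes(inferred)))
    wPath <- file.path(dir, "weights.tsv")
    w <- as.data.frame(inferred@weights)
    colnames(w) <- gn
    write.table(cbind(gene = gn, w), wPath,
                sep = "\t", quote = FALSE, row.names = FALSE)
    pPath <- file.path(dir, "parameters.tsv")
    ptab <- data.frame(
        gene = seq_len(nGenes(inferred)),
        regulators = vapply(inferred@regulators, paste,
                            character(1), collapse = ","),
        weights = vapply(seq_len(nGenes(inferred)), function(i)
            paste(formatC(inferred@weights[i, inferred@regulators[[i]]],
                          digits = 6, format = "g"), collapse = ","),
            character(1)),
        bias = inferred@bias, tau = inferred@tau,
        fitness = inferred@fitness, stopReason = inferred@stopReason)
    write.table(ptab, pPath, sep = "\t", quote = FALSE, row.names = FALSE)
    ePath <- file.path(dir, "edges.tsv")
    writeSignedNetwork(callEdges(inferred), ePath, format = "edges")
    invisible(c(wPath, pPath, ePath))
}
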