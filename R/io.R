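#' Read and write mutation count matrices as TSV
#'
#' The on-disk layout has a header row of channel labels, a first column
#' "Sample" of sample identifiers and integer count cells. `readCatalog` and
#' `writeCatalog` are inverses: write followed by read reproduces the
#' catalog exactly, channel order included. Channel sets other than the
#' built-in ones are accepted as "custom".
#'
#' @param path TSV file path.
#' @return `readCatalog`: a [MutationCatalog-class].
#' @examples
#' m <- matrix(0L, 1, 96, dimnames = list("s1", sbs96Channels()))
#' f <- tempfile(fileext = ".tsv")
#' writeCatalog(MutationCatalog(m), f)
#' readCatalog(f)
#' @export
readCatalog <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
        stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("catalog TSV needs a Sample column and channels")
    samples <- as.character(df[[1]])
    if (anyDuplicated(samples))
        stop("duplicate sample id: ",
             samples[duplicated(samples)][1])
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf(
            "invalid count at row %d (sample %s), column %s: %s",
            bad[1, 1], samples[bad[1, 1]],
            colnames(m)[bad[1, 2]], format(m[bad[1, 1], bad[1, 2]])))
    storage.mode(m) <- "integer"
    rownames(m) <- samples
    MutationCatalog(m)
}

#' @rdname readCatalog
#' @param x a [MutationCatalog-class].
#' @export
writeCatalog <- function(x, path) {
    m <- catalogCounts(x)
    df <- data.frame(Sample = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(NULL)
}

#' Read and write signature panels as TSV
#'
#' Two layouts are understood and auto-detected: the COSMIC-style layout
#' (rows are channels, columns are signatures, the first column holding
#' channel labels) and its transpose (rows are signatures, first column
#' "Signature"). Detection looks for substitution-style channel labels
#' (`"A[C>A]A"`) in the first data column; panels are stored internally as
#' signatures x channels. `writeSignaturePanel` writes the transposed
#' (signatures-in-rows) layout by default, or COSMIC layout with
#' `layout = "cosmic"`.
#'
#' @param path TSV file path.
#' @return `readSignaturePanel`: a [SignaturePanel-class].
#' @export
readSignaturePanel <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
        stringsAsFactors = FALSE)
    first <- as.character(df[[1]])
    channelsInRows <- mean(grepl("\\[.>.\\]", first)) > 0.5 ||
        all(first %in% sbs96Channels())
    if (channelsInRows) {
        probs <- t(as.matrix(df[, -1, drop = FALSE]))
        colnames(probs) <- first
    } else {
        probs <- as.matrix(df[, -1, drop = FALSE])
        rownames(probs) <- first
    }
    SignaturePanel(probs)
}

#' @rdname readSignaturePanel
#' @param x a [SignaturePanel-class].
#' @param layout "signatures" (signatures in rows) or "cosmic" (channels in
#'   rows).
#' @export
writeSignaturePanel <- function(x, path, layout = c("signatures", "cosmic")) {
    layout <- match.arg(layout)
    p <- signatureProbs(x)
    df <- if (layout == "signatures")
        data.frame(Signature = rownames(p), p, check.names = FALSE)
    else
        data.frame(`Mutation Type` = colnames(p), t(p),
            check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(NULL)
}

#' Write a JSON run manifest
#'
#' Records a command, its parameters, seeds and the MD5 digests of its input
#' files, so a run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param command the (sub)command name.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param extra optional named list of extra diagnostics (convergence,
#'   skip/clamp tallies, ...).
#' @return the manifest list, invisibly.
#' @export
writeRunManifest <- function(path, command, params = list(),
                             inputs = character(0), extra = list()) {
    manifest <- c(list(
        command = command,
        version = as.character(utils::packageVersion("signovo")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        params = params,
        inputs = as.list(tools::md5sum(inputs))), extra)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(manifest)
}
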