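#' Construct a SignaturePanel
#'
#' @param probs matrix of signature probabilities, signatures in rows
#'   (rownames required), channels in columns (colnames required); each row
#'   must sum to 1 within 1e-6 (rows are renormalised to sum exactly 1).
#' @param channelSet channel-set identifier; inferred from the labels when
#'   `NULL` (as for [MutationCatalog()]).
#' @param novel logical flag(s) marking de novo signatures; recycled.
#' @return a [SignaturePanel-class].
#' @examples
#' p <- matrix(1 / 96, 2, 96,
#'     dimnames = list(c("Flat.1", "Flat.2"), sbs96Channels()))
#' SignaturePanel(p)
#' @export
SignaturePanel <- function(probs, channelSet = NULL, novel = FALSE) {
    probs <- as.matrix(probs)
    rs <- rowSums(probs)
    if (nrow(probs) > 0 && any(abs(rs - 1) > 1e-6))
        stop("signature rows must sum to 1 (tolerance 1e-6)")
    if (nrow(probs) > 0) probs <- probs / rs
    if (is.null(channelSet))
        channelSet <- .inferChannelSet(colnames(probs))
    if (identical(channelSet, "SBS96"))
        probs <- probs[, sbs96Channels(), drop = FALSE]
    new("SignaturePanel", probs = probs, channelSet = channelSet,
        novel = rep_len(novel, nrow(probs)))
}

#' @describeIn SignaturePanel the signatures-by-channels probability matrix.
#' @param x,object a SignaturePanel.
#' @export
signatureProbs <- function(x) x@probs

#' @describeIn SignaturePanel the signature names.
#' @export
signatureNames <- function(x) rownames(x@probs)

#' @describeIn SignaturePanel logical de novo flags, one per signature.
#' @export
isNovelSignature <- function(x) x@novel

#' @describeIn SignaturePanel subset by signature name or index.
#' @param i signature names or indices.
#' @param j,drop,... ignored (channel subsetting is not supported: rows
#'   would no longer be distributions).
#' @export
setMethod("[", "SignaturePanel", function(x, i, j, ..., drop = FALSE) {
    if (!missing(j)) stop("channel subsetting of a SignaturePanel is not supported")
    new("SignaturePanel", probs = x@probs[i, , drop = FALSE],
        channelSet = x@channelSet,
        novel = setNames(x@novel, rownames(x@probs))[i])
})

setMethod("show", "SignaturePanel", function(object) {
    cat("SignaturePanel (", object@channelSet, "): ",
        nrow(object@probs), " signatures x ", ncol(object@probs),
        " channels; ", sum(object@novel), " de novo\n", sep = "")
    cat("  ", paste(utils::head(rownames(object@probs), 8), collapse = ", "),
        if (nrow(object@probs) > 8) ", ..." else "", "\n", sep = "")
})

#' @describeIn SignaturePanel number of signatures.
#' @export
setMethod("nrow", "SignaturePanel", function(x) nrow(x@probs))

# Align a panel's channel columns to a catalog's channel labels.
# Mismatched label sets are an error, never silently intersected.
.alignPanel <- function(panel, labels) {
    pl <- colnames(panel@probs)
    if (!setequal(pl, labels)) {
        miss <- c(setdiff(labels, pl), setdiff(pl, labels))
        stop("channel labels do not match between catalog and panel; ",
             "unmatched: ", paste(utils::head(miss, 10), collapse = ", "))
    }
    panel@probs <- panel@probs[, labels, drop = FALSE]
    panel
}

.asCounts <- function(A) {
    if (is(A, "MutationCatalog")) A@counts else as.matrix(A)
}
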