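#' @useDynLib signovo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom ggplot2 .data
#' @importFrom stats setNames
#' @import methods
NULL

#' MutationCatalog: a samples-by-channels mutation count matrix
#'
#' Holds the matrix of somatic mutation counts A: one row per sample, one
#' column per mutation-type channel (for single-base substitutions, the 96
#' trinucleotide channels under strand symmetry). Counts are non-negative;
#' a sample's row sum is its total number of classified mutations.
#'
#' @slot counts non-negative numeric matrix with sample rownames and channel
#'   colnames.
#' @slot channelSet channel-set identifier: "SBS96", "DBS78", "ID83" or
#'   "custom".
#'
#' @seealso [MutationCatalog()], [readCatalog()], [buildCatalogFromVCF()]
#' @exportClass MutationCatalog
setClass("MutationCatalog",
    representation(counts = "matrix", channelSet = "character"))

setValidity("MutationCatalog", function(object) {
    m <- object@counts
    msg <- character(0)
    if (!is.numeric(m))
        msg <- c(msg, "counts must be a numeric matrix")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "samples must have unique identifiers (rownames)")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "channels must have unique labels (colnames)")
    if (is.numeric(m) && any(m < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(object@channelSet) != 1L ||
        !object@channelSet %in% c("SBS96", "DBS78", "ID83", "custom"))
        msg <- c(msg, "channelSet must be one of SBS96, DBS78, ID83, custom")
    if (identical(object@channelSet, "SBS96") &&
        !identical(colnames(m), sbs96Channels()))
        msg <- c(msg, "SBS96 catalogs must use the 96 canonical channel labels in canonical order")
    if (length(msg)) msg else TRUE
})

#' SignaturePanel: signatures as probability distributions over channels
#'
#' A set of mutational signatures, stored as a signatures-by-channels matrix
#' H in which every row is a probability distribution (sums to one) over the
#' mutation-type channels. Rows flagged as novel are de novo signatures
#' extracted from data rather than reference signatures.
#'
#' @slot probs numeric matrix, signatures in rows, channels in columns; each
#'   row sums to 1 (tolerance 1e-6).
#' @slot channelSet channel-set identifier (see [MutationCatalog-class]).
#' @slot novel logical vector, one flag per signature row.
#'
#' @seealso [SignaturePanel()], [readSignaturePanel()],
#'   [syntheticSignaturePanel()]
#' @exportClass SignaturePanel
setClass("SignaturePanel",
    representation(probs = "matrix", channelSet = "character",
                   novel = "logical"))

setValidity("SignaturePanel", function(object) {
    p <- object@probs
    msg <- character(0)
    if (!is.numeric(p))
        msg <- c(msg, "probs must be a numeric matrix")
    if (nrow(p) > 0 && (is.null(rownames(p)) || anyDuplicated(rownames(p))))
        msg <- c(msg, "signatures must have unique names (rownames)")
    if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
        msg <- c(msg, "channels must have unique labels (colnames)")
    if (is.numeric(p) && any(p < 0))
        msg <- c(msg, "signature probabilities must be non-negative")
    if (is.numeric(p) && nrow(p) > 0 && any(abs(rowSums(p) - 1) > 1e-6))
        msg <- c(msg, "each signature row must sum to 1 (tolerance 1e-6)")
    if (length(object@novel) != nrow(p))
        msg <- c(msg, "novel flags must have one entry per signature")
    if (length(msg)) msg else TRUE
})

#' CostCurve: the record of a stepwise signature-selection run
#'
#' Ordered record of forward or backward stepwise selection: at each step one
#' signature is added (forward) or removed (backward) and the model cost C
#' (the sample-size-normalised Frobenius norm of the reconstruction error)
#' after the step is recorded, together with the model membership.
#'
#' @slot direction "forward" or "backward".
#' @slot steps data.frame with columns step, signature, cost.
#' @slot membership list of character vectors: model membership after each
#'   step.
#' @slot panelNames the full panel's signature names, in panel order.
#'
#' @seealso [forwardSelect()], [backwardSelect()], [truncateModel()],
#'   [suggestElbow()]
#' @exportClass CostCurve
setClass("CostCurve",
    representation(direction = "character", steps = "data.frame",
                   membership = "list", panelNames = "character"))

setValidity("CostCurve", function(object) {
    msg <- character(0)
    if (!object@direction %in% c("forward", "backward"))
        msg <- c(msg, "direction must be forward or backward")
    st <- object@steps
    if (!all(c("step", "signature", "cost") %in% names(st)))
        msg <- c(msg, "steps needs columns step, signature, cost")
    else {
        if (!identical(as.integer(st$step), seq_len(nrow(st))))
            msg <- c(msg, "step indices must run 1..n_k")
        if (anyDuplicated(st$signature) ||
            !setequal(st$signature, object@panelNames))
            msg <- c(msg, "every panel signature must appear exactly once")
    }
    if (length(object@membership) != nrow(st))
        msg <- c(msg, "membership must have one entry per step")
    if (length(msg)) msg else TRUE
})

#' CVResult: leave-k-out cross-validation over candidate de novo ranks
#'
#' Train and test reconstruction costs for each candidate number of de novo
#' signatures, from leave-k-out cross-validation of the partially-fixed NMF
#' on the residual matrix.
#'
#' @slot summary data.frame with columns nNew, trainCost, testCost (fold
#'   means).
#' @slot perFold data.frame with columns nNew, fold, trainCost, testCost.
#' @slot folds list of integer vectors: sample indices left out per fold.
#' @slot k samples left out per fold.
#' @slot seed base seed used for the NMF restarts.
#'
#' @seealso [crossValidateDenovo()], [cvElbow()]
#' @exportClass CVResult
setClass("CVResult",
    representation(summary = "data.frame", perFold = "data.frame",
                   folds = "list", k = "integer", seed = "integer"))

#' NMFResult: a fitted partially-fixed NMF model
#'
#' Result of factorising a residual matrix as W' H' where a designated block
#' of H' rows (the reference signatures) is held fixed and only the novel
#' rows and all of W' are optimised.
#'
#' @slot panel [SignaturePanel-class] of fixed reference rows plus novel
#'   rows (flagged via the novel slot).
#' @slot exposures samples-by-signatures matrix W' of attributed mutations.
#' @slot objective per-iteration Frobenius objective of the best restart.
#' @slot converged whether the relative-change stopping rule fired before
#'   the iteration cap.
#' @slot seed seed of the best restart.
#' @slot restart index of the best restart.
#'
#' @seealso [nmfPartialFixed()]
#' @exportClass NMFResult
setClass("NMFResult",
    representation(panel = "SignaturePanel", exposures = "matrix",
                   objective = "numeric", converged = "logical",
                   seed = "integer", restart = "integer"))

#' SimulationSpec: parameters of a multinomial catalog simulation
#'
#' @slot panel the [SignaturePanel-class] whose signatures generate the
#'   mutations.
#' @slot fractions per-signature exposure fractions summing to 1 (one row:
#'   cohort-level; or one row per sample).
#' @slot nSamples number of samples to simulate.
#' @slot nMutations mutations per sample (scalar or one per sample).
#' @slot seed RNG seed.
#'
#' @seealso [simulateCatalog()], [scenarioPreset()]
#' @exportClass SimulationSpec
setClass("SimulationSpec",
    representation(panel = "SignaturePanel", fractions = "matrix",
                   nSamples = "integer", nMutations = "integer",
                   seed = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character(0)
    f <- object@fractions
    if (ncol(f) != nrow(object@panel@probs))
        msg <- c(msg, "fractions must have one column per panel signature")
    if (any(f < 0)) msg <- c(msg, "fractions must be non-negative")
    if (any(abs(rowSums(f) - 1) > 1e-9))
        msg <- c(msg, "fractions must sum to 1 (tolerance 1e-9)")
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (any(object@nMutations < 1L)) msg <- c(msg, "nMutations must be >= 1")
    if (!nrow(f) %in% c(1L, object@nSamples))
        msg <- c(msg, "fractions must have 1 row or nSamples rows")
    if (length(msg)) msg else TRUE
})
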