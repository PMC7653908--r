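#' Fit signature exposures by non-negative least squares
#'
#' Infers the emission matrix W from the counts A and a fixed signature
#' matrix H by solving, independently for every sample row a, the
#' constrained problem min ||a - w H||_2 subject to w >= 0 (Lawson-Hanson
#' active set). Because rows are independent the fit decomposes into n_g
#' small NNLS problems sharing the basis t(H).
#'
#' @param A a [MutationCatalog-class] (or samples-by-channels matrix with
#'   dimnames).
#' @param H a [SignaturePanel-class]; channel labels must match A's (they
#'   are aligned by label, with explicit reordering; a mismatch is an
#'   error).
#' @return samples-by-signatures matrix W of non-negative exposures
#'   (mutations attributed to each signature).
#' @examples
#' p <- syntheticSignaturePanel()
#' sim <- simulateCatalog(scenarioPreset("A", panel = p, seed = 1))
#' W <- nnlsExposures(sim$catalog, p[c("Signature.1", "Signature.3")])
#' @export
nnlsExposures <- function(A, H) {
    counts <- .asCounts(A)
    H <- .alignPanel(H, colnames(counts))
    if (nrow(H@probs) < 1) stop("panel must contain at least one signature")
    W <- .nnlsMulti(t(H@probs), counts)
    dimnames(W) <- list(rownames(counts), rownames(H@probs))
    W
}

#' Sample-size-normalised Frobenius reconstruction cost
#'
#' The model cost C = ||A - W H||_F / n_g, the Frobenius norm of the
#' reconstruction error divided by the number of samples.
#'
#' @inheritParams nnlsExposures
#' @param W samples-by-signatures exposure matrix.
#' @return a non-negative scalar.
#' @export
modelCost <- function(A, W, H) {
    counts <- .asCounts(A)
    if (nrow(counts) == 0) stop("empty catalog")
    H <- .alignPanel(H, colnames(counts))
    R <- counts - W %*% H@probs
    norm(R, "F") / nrow(counts)
}

.frobCost <- function(counts, probs) {
    # cost of the NNLS-optimal fit of `probs` to `counts`
    if (nrow(probs) == 0) return(norm(counts, "F") / nrow(counts))
    W <- .nnlsMulti(t(probs), counts)
    norm(counts - W %*% probs, "F") / nrow(counts)
}

# first index attaining the minimum within relative tolerance (panel-order
# tie break, tolerance 1e-12 relative)
.whichBest <- function(costs) {
    best <- min(costs)
    which(costs <= best + abs(best) * 1e-12)[1]
}

#' Stepwise signature selection over a reference panel
#'
#' `forwardSelect` starts from the empty model and at each step trials every
#' not-yet-included signature by refitting the enlarged model with
#' [nnlsExposures()], adding the signature that yields the lowest model cost
#' C; it runs until all panel signatures are included. `backwardSelect`
#' starts from the full model and iteratively discards the signature whose
#' removal increases the cost least, down to the empty model; the implied
#' importance ranking is the reverse of the removal order. Both return the
#' full cost curve; truncating the model is the user's decision (see
#' [truncateModel()] and [suggestElbow()]).
#'
#' Ties in candidate cost (within 1e-12 relative) are broken by panel
#' order, so runs are deterministic.
#'
#' @inheritParams nnlsExposures
#' @param panel the [SignaturePanel-class] of candidate reference
#'   signatures.
#' @return a [CostCurve-class].
#' @examples
#' p <- syntheticSignaturePanel()[1:6]
#' sim <- simulateCatalog(scenarioPreset("A", panel = p, seed = 7,
#'     nSamples = 10, nMutations = 1000))
#' forwardSelect(sim$catalog, p)
#' @export
forwardSelect <- function(A, panel) {
    counts <- .asCounts(A)
    panel <- .alignPanel(panel, colnames(counts))
    nms <- rownames(panel@probs)
    if (length(nms) < 1) stop("panel must contain at least one signature")
    members <- character(0)
    steps <- data.frame(step = integer(0), signature = character(0),
        cost = numeric(0))
    membership <- list()
    for (s in seq_along(nms)) {
        cand <- setdiff(nms, members)
        costs <- vapply(cand, function(cn)
            .frobCost(counts, panel@probs[c(members, cn), , drop = FALSE]),
            numeric(1))
        pick <- cand[.whichBest(costs)]
        members <- c(members, pick)
        steps <- rbind(steps, data.frame(step = s, signature = pick,
            cost = costs[[.whichBest(costs)]]))
        membership[[s]] <- members
    }
    new("CostCurve", direction = "forward", steps = steps,
        membership = membership, panelNames = nms)
}

#' @rdname forwardSelect
#' @export
backwardSelect <- function(A, panel) {
    counts <- .asCounts(A)
    panel <- .alignPanel(panel, colnames(counts))
    nms <- rownames(panel@probs)
    if (length(nms) < 1) stop("panel must contain at least one signature")
    members <- nms
    steps <- data.frame(step = integer(0), signature = character(0),
        cost = numeric(0))
    membership <- list()
    for (s in seq_along(nms)) {
        costs <- vapply(members, function(cn)
            .frobCost(counts,
                panel@probs[setdiff(members, cn), , drop = FALSE]),
            numeric(1))
        drop <- members[.whichBest(costs)]
        members <- setdiff(members, drop)
        steps <- rbind(steps, data.frame(step = s, signature = drop,
            cost = costs[[.whichBest(costs)]]))
        membership[[s]] <- members
    }
    new("CostCurve", direction = "backward", steps = steps,
        membership = membership, panelNames = nms)
}

#' @describeIn forwardSelect the per-step record as a data.frame (columns
#'   step, signature, cost).
#' @param curve a [CostCurve-class].
#' @export
costSteps <- function(curve) curve@steps

#' Importance-ranked signature names of a cost curve
#'
#' Forward curves rank by addition order; backward curves by reverse removal
#' order (the last-removed signature matters most).
#'
#' @param curve a [CostCurve-class].
#' @return character vector of signature names, most important first.
#' @export
rankedSignatures <- function(curve) {
    if (curve@direction == "forward") curve@steps$signature
    else rev(curve@steps$signature)
}

setMethod("show", "CostCurve", function(object) {
    cat("CostCurve (", object@direction, "): ",
        nrow(object@steps), " steps\n", sep = "")
    print(utils::head(object@steps, 8), row.names = FALSE)
    if (nrow(object@steps) > 8) cat("  ...\n")
})

#' Truncate a selection curve to its most important signatures
#'
#' Keeps the `nKeep` most important signatures of the curve (see
#' [rankedSignatures()]) and refits the exposures by NNLS on exactly that
#' subset. The choice of `nKeep` is deliberately left to the user; an
#' automatic elbow suggestion is available from [suggestElbow()] and is
#' advisory only, never applied silently.
#'
#' @inheritParams nnlsExposures
#' @param curve the [CostCurve-class] from [forwardSelect()] or
#'   [backwardSelect()] on the same catalog and panel.
#' @param panel the full [SignaturePanel-class] the curve was computed from.
#' @param nKeep number of signatures to keep (1..n_k).
#' @return list with elements `panel` (the kept [SignaturePanel-class]),
#'   `exposures` (the refit W) and `cost` (the model cost of the truncated
#'   model).
#' @export
truncateModel <- function(A, curve, panel, nKeep) {
    nk <- length(curve@panelNames)
    if (nKeep < 1 || nKeep > nk)
        stop("nKeep must be between 1 and ", nk)
    keep <- rankedSignatures(curve)[seq_len(nKeep)]
    sub <- panel[keep]
    W <- nnlsExposures(A, sub)
    list(panel = sub, exposures = W, cost = modelCost(A, W, sub))
}

# max perpendicular distance to the chord joining the curve endpoints
.elbowIndex <- function(x, y) {
    n <- length(x)
    if (n < 3) return(if (n > 0) n else NA_integer_)
    dx <- x[n] - x[1]; dy <- y[n] - y[1]
    d <- abs(dy * (x - x[1]) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
    which.max(d)
}

#' Suggest an elbow on a cost curve or cross-validation curve
#'
#' Computes the point of maximum perpendicular distance from the chord
#' joining the curve endpoints, a standard geometric elbow heuristic.
#' Signatures selected beyond the elbow no longer notably reduce the cost.
#' The suggestion is advisory: model truncation always requires an explicit
#' `nKeep` (or `nNew`) from the user.
#'
#' @param x a [CostCurve-class] or [CVResult-class].
#' @return for a cost curve, the suggested model size (number of signatures
#'   kept); for a CV result, the suggested number of de novo signatures.
#' @export
suggestElbow <- function(x) {
    if (is(x, "CostCurve")) {
        st <- x@steps
        size <- if (x@direction == "forward") st$step
            else length(x@panelNames) - st$step
        o <- order(size)
        size[o][.elbowIndex(size[o], st$cost[o])]
    } else if (is(x, "CVResult")) {
        cvElbow(x)
    } else stop("need a CostCurve or CVResult")
}
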