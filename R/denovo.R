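#' Residual counts left unexplained by a fitted reference panel
#'
#' Computes A' = A - W H entrywise. Negative entries (where the
#' reconstruction overshoots the observed counts) are clamped to zero so
#' the residual can be factorised by NMF; the clamped mass is reported in
#' the `"clampedMass"` attribute and via `message()`.
#'
#' @inheritParams modelCost
#' @return non-negative samples-by-channels matrix with attribute
#'   `"clampedMass"`.
#' @export
residualMatrix <- function(A, W, H) {
    counts <- .asCounts(A)
    H <- .alignPanel(H, colnames(counts))
    R <- counts - W %*% H@probs
    clamped <- -sum(R[R < 0])
    R[R < 0] <- 0
    if (clamped > 0)
        message(sprintf("clamped %.4g negative residual counts to zero",
            clamped))
    attr(R, "clampedMass") <- clamped
    R
}

# one multiplicative-update run; free rows of H are updated, fixed rows are
# left untouched; returns list(W, H, objective)
.nmfRun <- function(A, H0, freeRows, maxIter, tol, tolWindow, eps = 1e-12) {
    ng <- nrow(A); nk <- nrow(H0)
    H <- H0
    W <- matrix(stats::runif(ng * nk, 0, max(A)), ng, nk)
    obj <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        # W update: W <- W * (A H^T) / (W H H^T)
        HHt <- H %*% t(H)
        W <- W * (A %*% t(H)) / (W %*% HHt + eps)
        if (length(freeRows)) {
            # H update on free rows only: H <- H * (W^T A) / (W^T W H)
            num <- crossprod(W, A)
            den <- crossprod(W) %*% H + eps
            H[freeRows, ] <- H[freeRows, , drop = FALSE] *
                num[freeRows, , drop = FALSE] / den[freeRows, , drop = FALSE]
        }
        obj[it] <- norm(A - W %*% H, "F")
        if (it > tolWindow) {
            prev <- obj[it - tolWindow]
            if (prev > 0 && (prev - obj[it]) / prev < tol) {
                converged <- TRUE
                break
            }
        }
    }
    list(W = W, H = H, objective = obj, converged = converged)
}

#' Partially-fixed non-negative matrix factorisation
#'
#' Factorises the residual matrix as A' ~ W' H', where H' stacks the fixed
#' reference signatures (never modified) on top of `nNew` free de novo
#' rows. Only the free rows of H' and all of W' are optimised, by
#' Frobenius-objective multiplicative updates. The best of `nRestarts`
#' random initialisations is returned; free rows are renormalised to sum to
#' one at the end, with the compensating scale folded into the matching W'
#' columns (the objective is invariant to this rescaling).
#'
#' With `nNew = 0` no NMF is run: W' is the exact per-row NNLS fit to the
#' fixed panel.
#'
#' @param Ares non-negative residual matrix (samples x channels), e.g. from
#'   [residualMatrix()]; a [MutationCatalog-class] is also accepted (pure de
#'   novo extraction on raw counts).
#' @param Href [SignaturePanel-class] of fixed reference signatures, or
#'   `NULL` for pure de novo extraction.
#' @param nNew number of free (de novo) signature rows.
#' @param seed integer seed; restart r uses seed + r - 1.
#' @param nRestarts random restarts (default 10).
#' @param maxIter iteration cap per restart (default 10000).
#' @param tol relative objective decrease over `tolWindow` iterations below
#'   which a run stops (default 1e-8 over 10 iterations).
#' @param tolWindow see `tol`.
#' @return an [NMFResult-class]. De novo rows are named Denovo_1, Denovo_2,
#'   ... in decreasing order of total attributed mutations.
#' @export
nmfPartialFixed <- function(Ares, Href = NULL, nNew, seed = 1L,
                            nRestarts = 10L, maxIter = 10000L, tol = 1e-8,
                            tolWindow = 10L) {
    A <- .asCounts(Ares)
    nRef <- if (is.null(Href)) 0L else nrow(Href@probs)
    if (nNew < 0) stop("nNew must be >= 0")
    if (nNew + nRef < 1) stop("nothing to fit: no fixed and no free signatures")
    if (nRef > 0) Href <- .alignPanel(Href, colnames(A))

    if (nNew == 0) {
        W <- .nnlsMulti(t(Href@probs), A)
        dimnames(W) <- list(rownames(A), rownames(Href@probs))
        return(new("NMFResult", panel = Href, exposures = W,
            objective = norm(A - W %*% Href@probs, "F"),
            converged = TRUE, seed = as.integer(seed), restart = 0L))
    }

    refProbs <- if (nRef > 0) Href@probs else
        matrix(0, 0, ncol(A), dimnames = list(NULL, colnames(A)))
    freeRows <- nRef + seq_len(nNew)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        rseed <- as.integer(seed) + r - 1L
        set.seed(rseed)
        Hfree <- matrix(stats::runif(nNew * ncol(A)), nNew, ncol(A))
        Hfree <- Hfree / rowSums(Hfree)
        H0 <- rbind(refProbs, Hfree)
        run <- .nmfRun(A, H0, freeRows, maxIter, tol, tolWindow)
        run$seed <- rseed; run$restart <- r
        if (is.null(best) ||
            run$objective[length(run$objective)] <
            best$objective[length(best$objective)])
            best <- run
    }

    # renormalise free rows, folding scale into W columns
    H <- best$H; W <- best$W
    s <- rowSums(H[freeRows, , drop = FALSE])
    degen <- s <= 0
    if (any(degen)) {
        H[freeRows[degen], ] <- 1 / ncol(A)
        W[, freeRows[degen]] <- 0
        s[degen] <- 1
    }
    H[freeRows, ] <- H[freeRows, , drop = FALSE] / s
    W[, freeRows] <- sweep(W[, freeRows, drop = FALSE], 2, s, `*`)

    # de novo naming by decreasing total attributed mutations
    tot <- colSums(W[, freeRows, drop = FALSE])
    ord <- order(tot, decreasing = TRUE)
    H[freeRows, ] <- H[freeRows, , drop = FALSE][ord, , drop = FALSE]
    W[, freeRows] <- W[, freeRows, drop = FALSE][, ord, drop = FALSE]
    rn <- c(rownames(refProbs), paste0("Denovo_", seq_len(nNew)))
    rownames(H) <- rn
    dimnames(W) <- list(rownames(A), rn)

    panel <- new("SignaturePanel", probs = H,
        channelSet = if (nRef > 0) Href@channelSet else
            .inferChannelSet(colnames(A)),
        novel = c(rep(FALSE, nRef), rep(TRUE, nNew)))
    new("NMFResult", panel = panel, exposures = W,
        objective = best$objective, converged = best$converged,
        seed = best$seed, restart = as.integer(best$restart))
}

#' @describeIn nmfPartialFixed the fitted signature panel (fixed + de novo
#'   rows).
#' @param object,x an [NMFResult-class].
#' @export
fittedPanel <- function(x) x@panel

#' @describeIn nmfPartialFixed the fitted exposure matrix W'.
#' @export
fittedExposures <- function(x) x@exposures

#' @describeIn nmfPartialFixed the per-iteration Frobenius objective trace.
#' @export
objectiveTrace <- function(x) x@objective

setMethod("show", "NMFResult", function(object) {
    cat("NMFResult: ", sum(!object@panel@novel), " fixed + ",
        sum(object@panel@novel), " de novo signatures, ",
        length(object@objective), " iterations (restart ", object@restart,
        ", seed ", object@seed, ", ",
        if (object@converged) "converged" else "iteration cap", ")\n",
        sep = "")
    cat("  final objective ",
        format(object@objective[length(object@objective)]), "\n", sep = "")
})

#' Project residual rows onto a fixed signature model
#'
#' Infers the exposures of (held-out) samples against an already-learned
#' signature matrix by per-row non-negative least squares: the same contract
#' as [nnlsExposures()], applied to residuals.
#'
#' @param Ares residual matrix rows (samples x channels).
#' @param Hmodel [SignaturePanel-class] to project onto.
#' @return samples-by-signatures exposure matrix.
#' @export
projectExposures <- function(Ares, Hmodel) {
    nnlsExposures(Ares, Hmodel)
}

#' Leave-k-out cross-validation for the number of de novo signatures
#'
#' For each candidate number of de novo signatures, ceiling(n_g / k) models
#' are trained with [nmfPartialFixed()] on the samples not in the fold; the
#' exposures of the k left-out samples are then inferred by projecting their
#' residuals onto the learned signature matrix ([projectExposures()]), and
#' the test cost is the sample-size-normalised Frobenius error of the
#' left-out reconstruction, averaged over folds. The training cost is the
#' analogous error on the retained samples. A rising (or flattening) test
#' cost past a candidate indicates overfitting; the elbow of the test curve
#' ([cvElbow()]) suggests the number of de novo signatures to add.
#'
#' Folds are assigned deterministically in sample order; when n_g is not
#' divisible by k the final fold holds the remainder. With
#' `includeZero = TRUE` an nNew = 0 baseline (projection onto the fixed
#' panel only, no NMF) is also recorded; it is reported but excluded from
#' the elbow, which is defined over the candidates 1..maxNew.
#'
#' @inheritParams nmfPartialFixed
#' @param maxNew largest candidate number of de novo signatures (>= 1).
#' @param k samples left out per fold (default 1, leave-one-out).
#' @param includeZero also record the projection-only baseline.
#' @return a [CVResult-class].
#' @export
crossValidateDenovo <- function(Ares, Href = NULL, maxNew, k = 1L,
                                seed = 1L, nRestarts = 10L,
                                maxIter = 10000L, tol = 1e-8,
                                includeZero = FALSE) {
    A <- .asCounts(Ares)
    ng <- nrow(A)
    if (ng < 2) stop("cross-validation needs at least 2 samples")
    if (k >= ng) stop("k must be smaller than the number of samples")
    if (maxNew < 1) stop("maxNew must be >= 1")
    nFolds <- ceiling(ng / k)
    folds <- split(seq_len(ng), rep(seq_len(nFolds), each = k)[seq_len(ng)])

    cands <- if (includeZero) 0:maxNew else 1:maxNew
    perFold <- expand.grid(fold = seq_len(nFolds), nNew = cands)
    perFold <- perFold[, c("nNew", "fold")]
    perFold$trainCost <- NA_real_
    perFold$testCost <- NA_real_
    for (i in seq_len(nrow(perFold))) {
        nNew <- perFold$nNew[i]; f <- perFold$fold[i]
        test <- folds[[f]]
        train <- setdiff(seq_len(ng), test)
        fseed <- (as.integer(seed) + 131L * nNew + 17L * f) %%
            .Machine$integer.max
        fit <- nmfPartialFixed(A[train, , drop = FALSE], Href, nNew,
            seed = fseed, nRestarts = nRestarts, maxIter = maxIter,
            tol = tol)
        Hm <- fit@panel
        Wtest <- projectExposures(A[test, , drop = FALSE], Hm)
        perFold$testCost[i] <-
            norm(A[test, , drop = FALSE] - Wtest %*% Hm@probs, "F") /
            length(test)
        perFold$trainCost[i] <-
            norm(A[train, , drop = FALSE] - fit@exposures %*% Hm@probs,
                "F") / length(train)
    }
    summ <- do.call(rbind, lapply(split(perFold, perFold$nNew), function(d)
        data.frame(nNew = d$nNew[1], trainCost = mean(d$trainCost),
            testCost = mean(d$testCost))))
    rownames(summ) <- NULL
    new("CVResult", summary = summ, perFold = perFold, folds = folds,
        k = as.integer(k), seed = as.integer(seed))
}

#' @describeIn crossValidateDenovo fold-mean train/test costs per candidate
#'   (data.frame nNew, trainCost, testCost).
#' @param cv a [CVResult-class].
#' @export
cvSummary <- function(cv) cv@summary

#' @describeIn crossValidateDenovo the elbow of the mean test-cost curve
#'   (max distance to the chord), as a suggested number of de novo
#'   signatures. Advisory only.
#' @export
cvElbow <- function(cv) {
    s <- cv@summary[cv@summary$nNew >= 1, , drop = FALSE]
    s$nNew[.elbowIndex(s$nNew, s$testCost)]
}

setMethod("show", "CVResult", function(object) {
    cat("CVResult: leave-", object@k, "-out, ",
        length(object@folds), " folds\n", sep = "")
    print(object@summary, row.names = FALSE)
    cat("  test-cost elbow at nNew = ", cvElbow(object), "\n", sep = "")
})

#' Combine fitting-stage and residual-stage exposures
#'
#' The final reported emission of a reference signature is its stage-1
#' refit exposure plus its stage-2 residual-stage exposure; de novo columns
#' come from stage 2 alone. Both addends are retained in attributes
#' `"stage1"` and `"stage2"` so either interpretation of the reference
#' columns stays recoverable.
#'
#' @param Wfit stage-1 exposures from [nnlsExposures()] (possibly truncated
#'   model).
#' @param Wprime stage-2 exposures from [nmfPartialFixed()].
#' @return combined samples-by-signatures matrix.
#' @export
combineExposures <- function(Wfit, Wprime) {
    if (!identical(rownames(Wfit), rownames(Wprime)))
        stop("sample mismatch between exposure matrices")
    sigs <- union(colnames(Wfit), colnames(Wprime))
    out <- matrix(0, nrow(Wfit), length(sigs),
        dimnames = list(rownames(Wfit), sigs))
    out[, colnames(Wfit)] <- out[, colnames(Wfit)] + Wfit
    out[, colnames(Wprime)] <- out[, colnames(Wprime)] + Wprime
    attr(out, "stage1") <- Wfit
    attr(out, "stage2") <- Wprime
    out
}
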