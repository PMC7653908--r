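test_that("residual matrix is A - WH with clamped negatives accounted", {
    panel <- makeCustomPanel(2, 6, seed = 91)
    H <- signatureProbs(panel)
    set.seed(92)
    W <- matrix(rexp(6, 1 / 30), 3, 2, dimnames = list(paste0("g", 1:3),
        rownames(H)))
    A <- asCatalog(W %*% H, channels = channelLabels(panel))
    R0 <- residualMatrix(A, W, panel)
    expect_true(all(abs(R0) < 1e-9))
    expect_equal(attr(R0, "clampedMass"), 0)

    # push the reconstruction 2 counts above A in one cell
    Araw <- W %*% H
    Araw[2, 3] <- Araw[2, 3] - 2
    A2 <- asCatalog(Araw, channels = channelLabels(panel))
    R2 <- suppressMessages(residualMatrix(A2, W, panel))
    expect_equal(R2[2, 3], 0)
    expect_equal(attr(R2, "clampedMass"), 2)

    # random instance: equals direct arithmetic on non-negative cells
    set.seed(93)
    A3raw <- matrix(rpois(18, 20), 3, 6)
    A3 <- asCatalog(A3raw, channels = channelLabels(panel))
    R3 <- suppressMessages(residualMatrix(A3, W, panel))
    direct <- A3raw - W %*% H
    expect_equal(unname(R3[direct >= 0]), unname(direct[direct >= 0]))
    expect_true(all(R3[direct < 0] == 0))
})

test_that("nNew = 0 reduces to the NNLS fit against the fixed panel", {
    panel <- makeCustomPanel(3, 10, seed = 101)
    set.seed(102)
    A <- asCatalog(matrix(rpois(40, 15), 4, 10),
        channels = channelLabels(panel))
    fit <- nmfPartialFixed(A, panel, nNew = 0)
    expect_identical(signatureProbs(fittedPanel(fit)),
        signatureProbs(panel))
    expect_equal(fittedExposures(fit), nnlsExposures(A, panel))
    expect_error(nmfPartialFixed(A, NULL, nNew = 0), "nothing to fit")
})

test_that("multiplicative updates keep fixed rows and never raise the objective", {
    panel <- makeCustomPanel(3, 20, seed = 111, conc = 0.6)
    set.seed(112)
    W0 <- matrix(rexp(5 * 3, 1 / 200), 5, 3)
    A <- asCatalog(W0 %*% signatureProbs(panel) +
        matrix(rexp(100, 2), 5, 20), channels = channelLabels(panel))
    ref <- panel[c("S1", "S2")]
    fit <- nmfPartialFixed(catalogCounts(A), ref, nNew = 2, seed = 5,
        nRestarts = 3, maxIter = 800, tol = 1e-9)
    # fixed rows bit-identical to the input reference rows
    expect_identical(signatureProbs(fittedPanel(fit))[1:2, ],
        signatureProbs(ref))
    expect_identical(unname(isNovelSignature(fittedPanel(fit))),
        c(FALSE, FALSE, TRUE, TRUE))
    tr <- objectiveTrace(fit)
    expect_true(all(diff(tr) <= 1e-8 * pmax(tr[-length(tr)], 1)))
    # free rows sum to one
    expect_equal(unname(rowSums(signatureProbs(fittedPanel(fit)))),
        rep(1, 4), tolerance = 1e-6)
    # de novo naming follows attributed mass
    W <- fittedExposures(fit)
    expect_gte(sum(W[, "Denovo_1"]), sum(W[, "Denovo_2"]))
})

test_that("a hidden signature is recovered from the residual", {
    core <- syntheticSignaturePanel()[1:6]
    ref <- core[c("Signature.1", "Signature.11", "Signature.18",
        "Signature.22")]
    # generating mixture = the four references plus hidden Signature.5
    fr <- c(Signature.1 = 0.36, Signature.11 = 0.18, Signature.18 = 0.18,
        Signature.22 = 0.18, Signature.5 = 0.1)
    sim <- simulateCatalog(SimulationSpec(core[names(fr)], fr,
        nSamples = 25, nMutations = 35000, seed = 131))
    W <- nnlsExposures(sim$catalog, ref)
    Ares <- suppressMessages(residualMatrix(sim$catalog, W, ref))
    fit <- nmfPartialFixed(Ares, ref, nNew = 1, seed = 7, nRestarts = 5,
        maxIter = 5000, tol = 1e-8)
    novel <- fittedPanel(fit)[isNovelSignature(fittedPanel(fit))]
    hit <- bestMatch(novel, core)
    expect_identical(hit$reference, "Signature.5")
    expect_lt(hit$hds, 0.35)
})

test_that("projection onto a fixed model matches the NNLS contract", {
    panel <- makeCustomPanel(2, 8, seed = 141)
    zero <- matrix(0, 2, 8, dimnames = list(c("a", "b"),
        channelLabels(panel)))
    expect_true(all(projectExposures(zero, panel) == 0))
    r <- 100 * signatureProbs(panel)["S2", , drop = FALSE]
    rownames(r) <- "x"
    W <- projectExposures(r, panel)
    expect_equal(unname(W), matrix(c(0, 100), 1), tolerance = 1e-6)
    set.seed(142)
    R <- matrix(rexp(16, 1 / 10), 2, 8,
        dimnames = list(c("a", "b"), channelLabels(panel)))
    W2 <- projectExposures(R, panel)
    basis <- t(signatureProbs(panel))
    for (g in 1:2)
        expect_equal(unname(W2[g, ]), nnlsOracle(basis, R[g, ]),
            tolerance = 1e-6)
})

test_that("cross-validation is reproducible and validates its inputs", {
    panel <- makeCustomPanel(2, 12, seed = 151, conc = 0.6)
    set.seed(152)
    A <- matrix(rpois(6 * 12, 40), 6, 12,
        dimnames = list(paste0("g", 1:6), channelLabels(panel)))
    cv1 <- crossValidateDenovo(A, panel, maxNew = 2, k = 2, seed = 9,
        nRestarts = 2, maxIter = 300, tol = 1e-7)
    cv2 <- crossValidateDenovo(A, panel, maxNew = 2, k = 2, seed = 9,
        nRestarts = 2, maxIter = 300, tol = 1e-7)
    expect_identical(cvSummary(cv1), cvSummary(cv2))  # bit-identical
    expect_identical(length(cv1@folds), 3L)
    expect_identical(sort(unname(unlist(cv1@folds))), 1:6)
    # remainder fold when n_g is not divisible by k
    cv3 <- crossValidateDenovo(A[1:5, ], panel, maxNew = 1, k = 2,
        seed = 9, nRestarts = 1, maxIter = 100)
    expect_identical(lengths(cv3@folds) |> unname(), c(2L, 2L, 1L))
    expect_error(crossValidateDenovo(A, panel, maxNew = 2, k = 6),
        "smaller")
    expect_error(crossValidateDenovo(A[1, , drop = FALSE], panel,
        maxNew = 1, k = 1), "2 samples")
})

test_that("spurious candidates cut the test cost far less than a real signature", {
    core <- syntheticSignaturePanel()[1:6]
    ref <- core[c("Signature.1", "Signature.18", "Signature.22")]
    cvDrops <- function(gen, fr) {
        sim <- simulateCatalog(SimulationSpec(gen, fr, nSamples = 25,
            nMutations = 10000, seed = 162))
        W <- nnlsExposures(sim$catalog, ref)
        Ares <- suppressMessages(residualMatrix(sim$catalog, W, ref))
        s <- cvSummary(crossValidateDenovo(Ares, ref, maxNew = 3, k = 5,
            seed = 3, nRestarts = 2, maxIter = 1500, tol = 1e-7,
            includeZero = TRUE))
        -diff(s$testCost) / s$testCost[-nrow(s)]
    }
    # null: data generated exactly from the fixed panel
    null <- cvDrops(ref, c(Signature.1 = 0.5, Signature.18 = 0.3,
        Signature.22 = 0.2))
    # signal: the same cohort with hidden Signature.5 mixed in
    sig <- cvDrops(core[c(signatureNames(ref), "Signature.5")],
        c(Signature.1 = 0.4, Signature.18 = 0.25, Signature.22 = 0.15,
          Signature.5 = 0.2))
    # spurious candidates never cut the null test cost notably ...
    expect_true(all(null[-1] < 0.05))
    expect_lt(null[1], 0.10)
    # ... while a genuine hidden signature does, exactly at its rank
    expect_gt(sig[1], 5 * null[1])
    expect_true(all(sig[-1] < 0.02))
})

test_that("the CV elbow and recovered signatures identify two hidden processes", {
    p <- syntheticSignaturePanel()
    core <- p[1:6]
    ref <- core[c("Signature.1", "Signature.11", "Signature.18",
        "Signature.22")]
    elbows <- integer(0)
    hds <- numeric(0)
    overfitGap <- logical(0)
    for (seed in 1:10) {
        set.seed(700 + seed)
        nm <- sample(c(20000, 25000, 30000, 35000), 1)
        sim <- simulateCatalog(scenarioPreset(
            sample(c("A", "B", "C"), 1), panel = core,
            nSamples = 25, nMutations = nm, seed = 1000 + seed))
        W <- nnlsExposures(sim$catalog, ref)
        Ares <- suppressMessages(residualMatrix(sim$catalog, W, ref))
        cv <- crossValidateDenovo(Ares, ref, maxNew = 3, k = 5,
            seed = seed, nRestarts = 2, maxIter = 2000, tol = 1e-6)
        elbows <- c(elbows, cvElbow(cv))
        s <- cvSummary(cv)
        overfitGap <- c(overfitGap,
            all(s$testCost[s$nNew > 2] >= s$trainCost[s$nNew > 2]))
        fit <- nmfPartialFixed(Ares, ref, nNew = 2, seed = seed,
            nRestarts = 3, maxIter = 4000, tol = 1e-7)
        novel <- fittedPanel(fit)[isNovelSignature(fittedPanel(fit))]
        bm <- bestMatch(novel, core[c("Signature.3", "Signature.5")])
        # both hidden signatures matched, each by a different de novo row
        if (length(unique(bm$reference)) == 2)
            hds <- c(hds, bm$hds)
        else hds <- c(hds, 1, 1)
    }
    expect_gte(sum(elbows == 2), 8)
    expect_true(all(overfitGap))
    expect_gte(sum(hds <= 0.35), 16)    # >= 8/10 runs recover both
})

test_that("exposures from the two stages combine additively with provenance", {
    W1 <- matrix(c(5, 3, 2, 1), 2, 2,
        dimnames = list(c("a", "b"), c("S1", "S2")))
    Wz <- matrix(0, 2, 2, dimnames = dimnames(W1))
    expect_equal(combineExposures(W1, Wz)[, c("S1", "S2")], W1)
    W2 <- matrix(c(1, 1, 4, 2), 2, 2,
        dimnames = list(c("a", "b"), c("S2", "Denovo_1")))
    comb <- combineExposures(W1, W2)
    expect_equal(comb[, "S2"], W1[, "S2"] + W2[, "S2"])
    expect_equal(comb[, "Denovo_1"], W2[, "Denovo_1"])
    expect_equal(attr(comb, "stage1"), W1)
    expect_equal(attr(comb, "stage2"), W2)
    # pure de novo: no reference columns, output is stage 2 alone
    Wnone <- matrix(0, 2, 0, dimnames = list(c("a", "b"), NULL))
    pure <- combineExposures(Wnone, W2 * 0 + 7)
    expect_equal(pure[, colnames(W2)], W2 * 0 + 7)
    rownames(W2) <- c("a", "c")
    expect_error(combineExposures(W1, W2), "mismatch")
})
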