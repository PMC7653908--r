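test_that("NNLS recovers exact non-negative factorisations and zeros", {
    panel <- makeCustomPanel(3, 8, seed = 21)
    set.seed(22)
    W0 <- matrix(rexp(4 * 3, 1 / 50), 4, 3)
    A <- asCatalog(W0 %*% signatureProbs(panel), channels = channelLabels(panel))
    W <- nnlsExposures(A, panel)
    expect_equal(unname(W), unname(W0), tolerance = 1e-8)
    expect_lt(modelCost(A, W, panel), 1e-8)

    A0 <- asCatalog(matrix(0, 2, 8), channels = channelLabels(panel))
    expect_true(all(nnlsExposures(A0, panel) == 0))
})

test_that("NNLS agrees with the exhaustive active-set oracle", {
    for (seed in 1:25) {
        set.seed(seed)
        nk <- sample(1:3, 1); nc <- sample(3:6, 1)
        panel <- makeCustomPanel(nk, nc, seed = 100 + seed)
        A <- matrix(rpois(4 * nc, 20) - rpois(4 * nc, 8), 4, nc)
        A <- asCatalog(pmax(A, 0), channels = channelLabels(panel))
        W <- nnlsExposures(A, panel)
        basis <- t(signatureProbs(panel))
        for (g in 1:4) {
            expect_equal(unname(W[g, ]),
                nnlsOracle(basis, catalogCounts(A)[g, ]),
                tolerance = 1e-6)
        }
    }
})

test_that("NNLS agrees with an independent Lawson-Hanson implementation", {
    skip_if_not_installed("pracma")
    panel <- makeCustomPanel(6, 20, seed = 31)
    set.seed(32)
    A <- asCatalog(matrix(rpois(5 * 20, 30), 5, 20),
        channels = channelLabels(panel))
    W <- nnlsExposures(A, panel)
    basis <- t(signatureProbs(panel))
    for (g in 1:5)
        expect_equal(unname(W[g, ]),
            pracma::lsqnonneg(basis, catalogCounts(A)[g, ])$x,
            tolerance = 1e-6)
})

test_that("model cost is the sample-size-normalised Frobenius norm", {
    panel <- makeCustomPanel(1, 6, seed = 41)
    # one sample, residual (3, 4, 0, ...): cost 5
    H <- signatureProbs(panel)
    W <- matrix(10, 1, 1, dimnames = list("g1", "S1"))
    A1 <- asCatalog(10 * H + matrix(c(3, 4, rep(0, 4)), 1),
        channels = channelLabels(panel))
    expect_equal(modelCost(A1, W, panel), 5)
    # two samples with the same residual: sqrt(50) / 2
    W2 <- matrix(10, 2, 1)
    A2 <- asCatalog(rbind(10 * H + c(3, 4, rep(0, 4)),
        10 * H + c(3, 4, rep(0, 4))), channels = channelLabels(panel))
    expect_equal(modelCost(A2, W2, panel), sqrt(50) / 2)
    empty <- matrix(0, 0, 6, dimnames = list(NULL, channelLabels(panel)))
    expect_error(modelCost(empty, W, panel), "empty")
})

test_that("catalog/panel channel mismatches are an error, never intersected", {
    panel <- makeCustomPanel(2, 6, seed = 51)
    A <- asCatalog(matrix(1, 2, 6), channels = paste0("other", 1:6))
    expect_error(nnlsExposures(A, panel), "unmatched")
})

test_that("forward selection finds a single generating signature first", {
    panel <- makeCustomPanel(5, 30, seed = 61, conc = 0.4)
    set.seed(62)
    # catalog simulated from signature S3 alone
    A <- asCatalog(t(stats::rmultinom(25, 5000, signatureProbs(panel)["S3", ])),
        channels = channelLabels(panel))
    fwd <- forwardSelect(A, panel)
    expect_identical(costSteps(fwd)$signature[1], "S3")
    # one signature explains the data: step-1 cost within 5% of full cost
    costs <- costSteps(fwd)$cost
    expect_lt(costs[1], costs[5] * 1.05)
    # backward selection keeps the generating signature until last
    bwd <- backwardSelect(A, panel)
    expect_identical(costSteps(bwd)$signature[5], "S3")
    expect_identical(rankedSignatures(bwd)[1], "S3")
})

test_that("duplicate-signature ties break by panel order", {
    panel <- makeCustomPanel(3, 10, seed = 71)
    p <- signatureProbs(panel)
    p <- rbind(p, p["S2", , drop = FALSE])
    rownames(p) <- c("S1", "S2", "S3", "S2copy")
    dup <- SignaturePanel(p)
    set.seed(72)
    A <- asCatalog(t(stats::rmultinom(10, 2000, p["S2", ])),
        channels = channelLabels(panel))
    fwd <- forwardSelect(A, dup)
    expect_identical(costSteps(fwd)$signature[1], "S2")
})

test_that("selection curves are monotone and truncation reproduces costs", {
    for (seed in 1:5) {
        panel <- makeCustomPanel(6, 25, seed = 200 + seed, conc = 0.5)
        set.seed(seed)
        f <- rprob(6)
        A <- asCatalog(t(stats::rmultinom(8, 3000,
            as.vector(f %*% signatureProbs(panel)))),
            channels = channelLabels(panel))
        fwd <- forwardSelect(A, panel)
        bwd <- backwardSelect(A, panel)
        expect_true(all(diff(costSteps(fwd)$cost) <= 1e-9))
        expect_true(all(diff(costSteps(bwd)$cost) >= -1e-9))
        # keeping everything reproduces the full-model cost
        trF <- truncateModel(A, fwd, panel, 6)
        expect_equal(trF$cost, costSteps(fwd)$cost[6], tolerance = 1e-10)
        # backward final step is the empty model: cost ||A||_F / n_g
        expect_equal(costSteps(bwd)$cost[6],
            norm(catalogCounts(A), "F") / nrow(catalogCounts(A)))
    }
    panel1 <- makeCustomPanel(1, 5, seed = 299)
    A1 <- asCatalog(matrix(1, 2, 5), channels = channelLabels(panel1))
    expect_identical(nrow(costSteps(backwardSelect(A1, panel1))), 1L)
})

test_that("forward and backward agree on a dominant signature", {
    agree <- 0L
    for (seed in 1:20) {
        panel <- makeCustomPanel(4, 20, seed = 300 + seed, conc = 0.5)
        set.seed(seed)
        f <- c(0.97, rep(0.01, 3))  # one signature explains >= 95%
        A <- asCatalog(t(stats::rmultinom(10, 2000,
            as.vector(f %*% signatureProbs(panel)))),
            channels = channelLabels(panel))
        top <- costSteps(forwardSelect(A, panel))$signature[1]
        bot <- rankedSignatures(backwardSelect(A, panel))[1]
        agree <- agree + (top == "S1" && bot == "S1")
    }
    expect_identical(agree, 20L)
})

test_that("truncation subsets by curve importance and validates nKeep", {
    panel <- makeCustomPanel(4, 15, seed = 81)
    set.seed(82)
    A <- asCatalog(t(stats::rmultinom(6, 1500,
        as.vector(rprob(4) %*% signatureProbs(panel)))),
        channels = channelLabels(panel))
    bwd <- backwardSelect(A, panel)
    tr <- truncateModel(A, bwd, panel, 2)
    expect_identical(signatureNames(tr$panel), rankedSignatures(bwd)[1:2])
    expect_identical(colnames(tr$exposures), signatureNames(tr$panel))
    expect_error(truncateModel(A, bwd, panel, 0), "between")
    expect_error(truncateModel(A, bwd, panel, 5), "between")
})

test_that("the elbow suggestion finds a sharp kink", {
    # monotone synthetic forward curve with a single kink at step 3:
    # chord from (1, 100) to (6, 0); max perpendicular distance at step 3
    curve <- new("CostCurve", direction = "forward",
        steps = data.frame(step = 1:6,
            signature = paste0("S", 1:6),
            cost = c(100, 55, 12, 8, 4, 0)),
        membership = lapply(1:6, function(i) paste0("S", 1:i)),
        panelNames = paste0("S", 1:6))
    expect_identical(suggestElbow(curve), 3L)
})
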