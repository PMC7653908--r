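#' Construct a SimulationSpec
#'
#' Parameters of a multinomial catalog simulation: mutations of every sample
#' are drawn from a single multinomial whose channel probabilities are the
#' exposure-fraction-weighted mixture of the panel's signatures.
#'
#' @param panel a [SignaturePanel-class].
#' @param fractions per-signature exposure fractions summing to 1: a named
#'   numeric vector (cohort-level, applied to every sample) or a
#'   samples-by-signatures matrix for per-sample fractions.
#' @param nSamples number of samples.
#' @param nMutations mutations per sample (scalar, or one value per sample).
#' @param seed RNG seed.
#' @return a [SimulationSpec-class].
#' @export
SimulationSpec <- function(panel, fractions, nSamples, nMutations, seed) {
    f <- if (is.matrix(fractions)) fractions else
        matrix(fractions, 1, length(fractions),
            dimnames = list(NULL, names(fractions)))
    if (!is.null(colnames(f))) {
        if (!setequal(colnames(f), signatureNames(panel)))
            stop("fraction names must match panel signatures")
        f <- f[, signatureNames(panel), drop = FALSE]
    } else colnames(f) <- signatureNames(panel)
    new("SimulationSpec", panel = panel, fractions = f,
        nSamples = as.integer(nSamples),
        nMutations = as.integer(nMutations), seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec: ", object@nSamples, " samples, ",
        paste(unique(object@nMutations), collapse = "/"),
        " mutations/sample, seed ", object@seed, "\n", sep = "")
    cat("  fractions: ", paste(sprintf("%s=%.4g",
        colnames(object@fractions),
        colMeans(object@fractions)), collapse = ", "), "\n", sep = "")
})

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws each sample's counts from a single multinomial of size
#' `nMutations` with channel success probabilities proportional to the
#' exposure-weighted mixture of the signature emissions,
#' p = fractions' H. With `perSignature = TRUE` the per-sample mutation
#' total is first split across signatures (one multinomial over
#' signatures), then each signature's share is drawn from its own channel
#' distribution — equivalent in distribution, but the per-signature
#' ground-truth counts are then integer-valued.
#'
#' @param spec a [SimulationSpec-class] (see [SimulationSpec()] and
#'   [scenarioPreset()]).
#' @param perSignature draw one multinomial per signature instead of one
#'   per sample.
#' @return list with `catalog` (a [MutationCatalog-class]), `exposures`
#'   (ground-truth samples-by-signatures exposure matrix: expected
#'   fraction x nMutations, or the realised integer split when
#'   `perSignature`), and `spec`.
#' @examples
#' p <- syntheticSignaturePanel()[1:6]
#' sim <- simulateCatalog(scenarioPreset("C", panel = p, seed = 42))
#' sim$catalog
#' @export
simulateCatalog <- function(spec, perSignature = FALSE) {
    stopifnot(is(spec, "SimulationSpec"))
    H <- signatureProbs(spec@panel)
    ng <- spec@nSamples
    nm <- rep_len(spec@nMutations, ng)
    f <- spec@fractions
    if (nrow(f) == 1) f <- f[rep(1, ng), , drop = FALSE]
    if (any(rowSums(f) <= 0)) stop("zero total signature weight")
    samples <- sprintf("Sample_%02d", seq_len(ng))
    counts <- matrix(0L, ng, ncol(H),
        dimnames = list(samples, colnames(H)))
    truth <- matrix(0, ng, nrow(H), dimnames = list(samples, rownames(H)))
    set.seed(spec@seed)
    for (i in seq_len(ng)) {
        if (perSignature) {
            nsig <- stats::rmultinom(1, nm[i], f[i, ])[, 1]
            for (s in which(nsig > 0))
                counts[i, ] <- counts[i, ] +
                    stats::rmultinom(1, nsig[s], H[s, ])[, 1]
            truth[i, ] <- nsig
        } else {
            p <- as.vector(f[i, , drop = FALSE] %*% H)
            counts[i, ] <- stats::rmultinom(1, nm[i], p)[, 1]
            truth[i, ] <- f[i, ] * nm[i]
        }
    }
    list(catalog = MutationCatalog(counts, channelSet = spec@panel@channelSet),
         exposures = truth, spec = spec)
}

#' Scenario presets for benchmark simulations
#'
#' Three cohort structures over the six signatures Signature.1, Signature.3,
#' Signature.5, Signature.11, Signature.18 and Signature.22:
#' \describe{
#'   \item{A}{one dominant process: Signature.1 at 0.75, the other five at
#'     0.05 each;}
#'   \item{B}{two dominant processes: Signature.1 and Signature.3 at 0.375
#'     each, the other four at 0.0625 each;}
#'   \item{C}{all six contributing equally (1/6 each).}
#' }
#'
#' Samples within a cohort do not carry identical signature loads: each
#' sample's fraction vector is drawn from a Dirichlet distribution centred
#' on the scenario fractions (concentration `concentration`, higher =
#' tighter around the scenario structure). This per-sample variation is what
#' makes the hidden signatures of a cohort separable by factorisation; with
#' `concentration = Inf` every sample uses exactly the scenario fractions.
#' The draw is deterministic given `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param scenario "A", "B" or "C".
#' @param panel a [SignaturePanel-class] containing the six named
#'   signatures (e.g. a COSMIC v2-format table, or
#'   [syntheticSignaturePanel()]); other signatures in the panel are
#'   ignored.
#' @param nSamples cohort size; the benchmark grid uses 15, 25 or 50.
#' @param nMutations mutations per sample; the benchmark grid uses 500,
#'   1000, 2500 and 5000 for signature fitting and 20000 or 35000 for de
#'   novo inference.
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration of the per-sample fraction
#'   draw (default 25); `Inf` disables per-sample variation.
#' @return a [SimulationSpec-class] over exactly the six signatures.
#' @export
scenarioPreset <- function(scenario = c("A", "B", "C"), panel,
                           nSamples = 25L, nMutations = 5000L, seed = 1L,
                           concentration = 25) {
    scenario <- match.arg(scenario)
    core <- c("Signature.1", "Signature.3", "Signature.5",
              "Signature.11", "Signature.18", "Signature.22")
    miss <- setdiff(core, signatureNames(panel))
    if (length(miss))
        stop("panel is missing required signatures: ",
             paste(miss, collapse = ", "))
    f <- switch(scenario,
        A = c(0.75, rep(0.05, 5)),
        B = c(0.375, 0.375, rep(0.0625, 4)),
        C = rep(1 / 6, 6))
    names(f) <- core
    if (is.finite(concentration)) {
        oldSeed <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (is.null(oldSeed)) {
                if (exists(".Random.seed", globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", oldSeed, envir = globalenv())
        })
        set.seed((as.integer(seed) + 423779L) %% .Machine$integer.max)
        g <- matrix(stats::rgamma(nSamples * 6, shape = rep(
            concentration * f, each = nSamples)), nSamples, 6)
        f <- g / rowSums(g)
        colnames(f) <- core
    }
    SimulationSpec(panel[core], f, nSamples, nMutations, seed)
}

#' A deterministic synthetic reference signature panel
#'
#' Constructs a synthetic stand-in for a COSMIC v2-style SBS-96 reference
#' panel. It is NOT the published reference panel: the published probability
#' tables are not redistributed here. The six core signatures reuse the
#' COSMIC v2 names that the scenario presets require and emulate the
#' qualitative character of the corresponding processes — Signature.1 spiky
#' C>T at CpG (spontaneous deamination), Signature.3 and Signature.5 flat
#' ("noisy") profiles (double-strand-break repair deficiency; unknown
#' clock-like), Signature.11 broad non-CpG C>T (alkylating exposure),
#' Signature.18 peaked C>A (reactive oxygen damage), Signature.22 peaked
#' T>A (aristolochic acid) — plus `nDecoys` structured decoy signatures.
#' Construction is deterministic: the same panel is returned on every call
#' and the caller's RNG state is untouched.
#'
#' @param nDecoys number of decoy signatures appended after the six core
#'   ones (default 9, giving a 15-signature panel).
#' @return a [SignaturePanel-class] over the SBS-96 channels.
#' @export
syntheticSignaturePanel <- function(nDecoys = 9L) {
    labels <- sbs96Channels()
    oldSeed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(oldSeed)) {
            if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", oldSeed, envir = globalenv())
    })
    set.seed(902716L)

    spiky <- function(peaks, peakMass, conc = 0.5) {
        # Dirichlet-like background plus concentrated peak mass
        bg <- stats::rgamma(96, conc)
        bg <- bg / sum(bg) * (1 - peakMass)
        bg[match(peaks, labels)] <- bg[match(peaks, labels)] +
            peakMass / length(peaks)
        bg
    }
    flat <- function(conc = 60) {
        x <- stats::rgamma(96, conc)
        x / sum(x)
    }
    classChannels <- function(cls) labels[grepl(cls, labels, fixed = TRUE)]

    tilt <- function(x, cls, by) {
        i <- match(classChannels(cls), labels)
        x[i] <- x[i] * by
        x / sum(x)
    }
    probs <- rbind(
        Signature.1 = spiky(paste0(c("A", "C", "G", "T"), "[C>T]G"), 0.65),
        Signature.3 = tilt(tilt(tilt(flat(8), "C>A", 2.2), "C>G", 1.8),
            "T>A", 0.5),
        Signature.5 = tilt(tilt(flat(12), "T>C", 3.2), "C>T", 1.4),
        Signature.11 = {
            x <- spiky(setdiff(classChannels("C>T"),
                paste0(c("A", "C", "G", "T"), "[C>T]G")), 0.75, conc = 0.4)
            x
        },
        Signature.18 = spiky(c("A[C>A]A", "T[C>A]T", "G[C>A]A",
            "A[C>A]T"), 0.6),
        Signature.22 = spiky(c("C[T>A]G", "A[T>A]G", "C[T>A]T"), 0.65))

    if (nDecoys > 0) {
        # alternate spiky and broad decoys: reference panels contain both,
        # and the broad ones are what makes greedy selection fallible
        classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
        decoys <- t(vapply(seq_len(nDecoys), function(i) {
            if (i %% 2 == 1) {
                x <- stats::rgamma(96, 0.35)
                x / sum(x)
            } else {
                x <- stats::rgamma(96, 25)
                x <- x / sum(x)
                tilt(x, classes[1 + (i %/% 2) %% 6],
                    1.5 + stats::runif(1))
            }
        }, numeric(96)))
        rownames(decoys) <- paste0("Decoy.", seq_len(nDecoys))
        probs <- rbind(probs, decoys)
    }
    colnames(probs) <- labels
    SignaturePanel(probs, "SBS96")
}
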