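# Independent oracles and fixture builders used across the suite.

# Exhaustive active-set NNLS oracle: enumerate every support set, solve the
# unconstrained least squares on it, keep the feasible minimum. Independent
# of the package's compiled solver.
nnlsOracle <- function(basis, y) {
    k <- ncol(basis)
    best <- list(x = rep(0, k), rss = sum(y^2))
    for (code in seq_len(2^k) - 1L) {
        sup <- which(bitwAnd(code, bitwShiftL(1L, 0:(k - 1))) > 0)
        if (!length(sup)) next
        B <- basis[, sup, drop = FALSE]
        z <- tryCatch(qr.solve(crossprod(B), crossprod(B, y)),
            error = function(e) NULL)
        if (is.null(z) || any(z < 0)) next
        rss <- sum((y - B %*% z)^2)
        if (rss < best$rss - 1e-12) {
            x <- rep(0, k); x[sup] <- z
            best <- list(x = x, rss = rss)
        }
    }
    best$x
}

# random probability vector
rprob <- function(n, conc = 1) {
    x <- rgamma(n, conc)
    x / sum(x)
}

# small custom-channel panel for fitting tests
makeCustomPanel <- function(nSig, nCh, seed = 1, conc = 1,
                            names = paste0("S", seq_len(nSig))) {
    set.seed(seed)
    p <- t(vapply(seq_len(nSig), function(i) rprob(nCh, conc),
        numeric(nCh)))
    dimnames(p) <- list(names, paste0("ch", seq_len(nCh)))
    SignaturePanel(p)
}

asCatalog <- function(m, samples = sprintf("g%d", seq_len(nrow(m))),
                      channels = paste0("ch", seq_len(ncol(m)))) {
    dimnames(m) <- list(samples, channels)
    MutationCatalog(m)
}

# independent SBS-96 classifier built on string ops only (test-local)
oracleChannel <- function(ref, alt, left, right) {
    rc <- function(b) chartr("ACGT", "TGCA", b)
    if (ref %in% c("A", "G")) {
        tmp <- left
        left <- rc(right); right <- rc(tmp)
        ref <- rc(ref); alt <- rc(alt)
    }
    paste0(left, "[", ref, ">", alt, "]", right)
}

# ---- tiny genome + VCF fixtures (plain text, written at test time) ----

writeTinyFasta <- function(path, seqs) {
    lines <- unlist(mapply(function(nm, s) c(paste0(">", nm), s),
        names(seqs), seqs, SIMPLIFY = FALSE))
    writeLines(lines, path)
    path
}

writeTinyVcf <- function(path, records,
                         contigs = NULL) {
    # records: data.frame chrom, pos, ref, alt
    hdr <- c("##fileformat=VCFv4.2",
        if (!is.null(contigs))
            paste0("##contig=<ID=", contigs, ">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
        records$chrom, records$pos, records$ref, records$alt)
    writeLines(c(hdr, body), path)
    path
}
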