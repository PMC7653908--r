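#' The canonical SBS-96 channel labels
#'
#' Single-base substitutions are collapsed onto a pyrimidine reference base
#' (strand symmetry), giving six substitution classes (C>A, C>G, C>T, T>A,
#' T>C, T>G); each class is split by the 5' and 3' flanking bases into 16
#' trinucleotide contexts, for 96 channels. Ordering is substitution-class
#' major, then alphabetical 5' and 3' context, e.g. "A[C>A]A", "A[C>A]C",
#' ..., "T[T>G]T".
#'
#' @return character vector of 96 channel labels.
#' @examples
#' head(sbs96Channels())
#' @export
sbs96Channels <- function() {
    subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    bases <- c("A", "C", "G", "T")
    unlist(lapply(subs, function(s)
        as.vector(t(outer(bases, bases, function(l, r)
            paste0(l, "[", s, "]", r))))))
}

.inferChannelSet <- function(labels) {
    if (setequal(labels, sbs96Channels())) "SBS96"
    else if (length(labels) == 78L) "DBS78"
    else if (length(labels) == 83L) "ID83"
    else "custom"
}

#' Construct a MutationCatalog
#'
#' @param counts non-negative matrix of mutation counts, samples in rows
#'   (rownames required), channels in columns (colnames required).
#' @param channelSet channel-set identifier; if `NULL` it is inferred from
#'   the column labels: the canonical 96 SBS labels give "SBS96", 78 columns
#'   give "DBS78", 83 give "ID83", anything else "custom". SBS96 catalogs
#'   are reordered to canonical channel order.
#' @return a [MutationCatalog-class].
#' @examples
#' m <- matrix(0L, 2, 96, dimnames = list(c("s1", "s2"), sbs96Channels()))
#' m[1, "A[C>T]G"] <- 5L
#' MutationCatalog(m)
#' @export
MutationCatalog <- function(counts, channelSet = NULL) {
    counts <- as.matrix(counts)
    if (is.null(channelSet))
        channelSet <- .inferChannelSet(colnames(counts))
    if (identical(channelSet, "SBS96"))
        counts <- counts[, sbs96Channels(), drop = FALSE]
    new("MutationCatalog", counts = counts, channelSet = channelSet)
}

#' @describeIn MutationCatalog the counts matrix.
#' @param object,x a MutationCatalog.
#' @export
catalogCounts <- function(x) x@counts

#' @describeIn MutationCatalog the channel-set identifier.
#' @export
channelSet <- function(x) {
    if (is(x, "MutationCatalog") || is(x, "SignaturePanel")) x@channelSet
    else stop("no channel set for this object")
}

#' @describeIn MutationCatalog the ordered channel labels.
#' @export
channelLabels <- function(x) {
    if (is(x, "MutationCatalog")) colnames(x@counts)
    else if (is(x, "SignaturePanel")) colnames(x@probs)
    else stop("no channel labels for this object")
}

#' @describeIn MutationCatalog the sample identifiers.
#' @export
catalogSamples <- function(x) rownames(x@counts)

setMethod("show", "MutationCatalog", function(object) {
    m <- object@counts
    cat("MutationCatalog (", object@channelSet, "): ",
        nrow(m), " samples x ", ncol(m), " channels\n", sep = "")
    cat("  total mutations per sample: ",
        paste(utils::head(rowSums(m), 5), collapse = ", "),
        if (nrow(m) > 5) ", ..." else "", "\n", sep = "")
})

#' @describeIn MutationCatalog number of samples.
#' @export
setMethod("nrow", "MutationCatalog", function(x) nrow(x@counts))

#' @describeIn MutationCatalog number of channels.
#' @export
setMethod("ncol", "MutationCatalog", function(x) ncol(x@counts))

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify single-base substitutions into SBS-96 channels
#'
#' Maps a substitution and its immediate 5'/3' context to one of the 96
#' channels. Purine reference bases (A, G) are collapsed by taking the
#' reverse complement of the mutated trinucleotide, so the reported
#' reference base is always a pyrimidine (C or T). Vectorised over records.
#'
#' @param ref,alt reference and alternate base (single characters, A/C/G/T).
#' @param left,right the 5' and 3' neighbouring bases on the reference
#'   strand.
#' @return integer vector of channel indices into [sbs96Channels()], named
#'   by channel label; `NA` where any base is not A/C/G/T (unclassifiable,
#'   e.g. an N in the context).
#' @examples
#' sbs96Channels()[classifySNV("C", "T", "A", "G")]  # "A[C>T]G"
#' sbs96Channels()[classifySNV("G", "T", "A", "C")]  # "G[C>A]T"
#' @export
classifySNV <- function(ref, alt, left, right) {
    n <- length(ref)
    stopifnot(length(alt) == n, length(left) == n, length(right) == n)
    if (any(ref == alt, na.rm = TRUE))
        stop("invalid record: ref == alt")
    ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
        left %in% c("A", "C", "G", "T") & right %in% c("A", "C", "G", "T")
    idx <- rep(NA_integer_, n)
    if (any(ok)) {
        r <- ref[ok]; a <- alt[ok]; l <- left[ok]; rt <- right[ok]
        pur <- r %in% c("A", "G")
        # reverse complement the trinucleotide for purine references
        if (any(pur)) {
            l2 <- .complement[rt[pur]]
            rt2 <- .complement[l[pur]]
            a2 <- .complement[a[pur]]
            r2 <- .complement[r[pur]]
            r[pur] <- r2; a[pur] <- a2; l[pur] <- l2; rt[pur] <- rt2
        }
        lab <- paste0(l, "[", r, ">", a, "]", rt)
        idx[ok] <- match(lab, sbs96Channels())
    }
    names(idx) <- ifelse(is.na(idx), NA_character_, sbs96Channels()[idx])
    idx
}

.normalizeChrom <- function(chrom, genomeNames) {
    # resolve "chr1" vs "1" style differences against the FASTA index
    out <- chrom
    miss <- !(out %in% genomeNames)
    if (any(miss)) {
        alt <- ifelse(grepl("^chr", out[miss]),
            sub("^chr", "", out[miss]), paste0("chr", out[miss]))
        hit <- alt %in% genomeNames
        out[miss][hit] <- alt[hit]
    }
    out
}

#' Build an SBS-96 catalog from VCF files and a reference genome
#'
#' Reads somatic SNV calls from one VCF per sample, extracts the
#' trinucleotide context of every variant from an indexed FASTA, classifies
#' each substitution into its SBS-96 channel and tallies per-sample counts.
#' Multi-allelic records are split into one candidate SNV per ALT allele.
#' Non-SNV records (indels, MNVs, symbolic alleles), records with an
#' ambiguous context (N) and records whose VCF REF disagrees with the genome
#' base are skipped; the skip tallies are returned in the log attribute and
#' reported via `message()`.
#'
#' @param vcfFiles character vector of VCF paths; `names(vcfFiles)` are the
#'   sample identifiers (file basenames if unnamed).
#' @param genomeFasta path to the reference FASTA; a `.fai` sidecar index is
#'   created with [Rsamtools::indexFa()] if absent.
#' @return a [MutationCatalog-class] with attribute `"log"`: a data.frame of
#'   per-sample record tallies (records after ALT splitting, classified,
#'   skipped by reason).
#' @export
buildCatalogFromVCF <- function(vcfFiles, genomeFasta) {
    samples <- names(vcfFiles)
    if (is.null(samples))
        samples <- sub("\\.vcf(\\.gz)?$", "", basename(vcfFiles))
    if (anyDuplicated(samples)) stop("duplicate sample identifiers")
    if (!file.exists(paste0(genomeFasta, ".fai")))
        Rsamtools::indexFa(genomeFasta)
    fa <- Rsamtools::FaFile(genomeFasta)
    genomeNames <- as.character(GenomicRanges::seqnames(
        Rsamtools::scanFaIndex(fa)))
    genomeLens <- GenomicRanges::width(Rsamtools::scanFaIndex(fa))
    names(genomeLens) <- genomeNames

    labels <- sbs96Channels()
    counts <- matrix(0L, length(samples), 96,
        dimnames = list(samples, labels))
    log <- data.frame(sample = samples, records = 0L, classified = 0L,
        skippedNonSNV = 0L, skippedRefMismatch = 0L, skippedContext = 0L)

    for (i in seq_along(vcfFiles)) {
        vcf <- VariantAnnotation::readVcf(vcfFiles[i])
        if (length(vcf) == 0) {
            warning("empty VCF for sample ", samples[i])
            next
        }
        vcf <- VariantAnnotation::expand(vcf)   # split multi-allelic records
        rr <- SummarizedExperiment::rowRanges(vcf)
        ref <- as.character(VariantAnnotation::ref(vcf))
        alt <- as.character(VariantAnnotation::alt(vcf))
        log$records[i] <- length(ref)

        isSnv <- nchar(ref) == 1 & nchar(alt) == 1 &
            ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
        log$skippedNonSNV[i] <- sum(!isSnv)
        if (!any(isSnv)) next
        rr <- rr[isSnv]; ref <- ref[isSnv]; alt <- alt[isSnv]

        chrom <- .normalizeChrom(as.character(GenomicRanges::seqnames(rr)),
            genomeNames)
        if (any(!(chrom %in% genomeNames)))
            stop("chromosome not found in genome: ",
                 paste(unique(chrom[!(chrom %in% genomeNames)]),
                       collapse = ", "))
        pos <- GenomicRanges::start(rr)
        if (any(pos < 1 | pos > genomeLens[chrom]))
            stop("variant position outside chromosome bounds")
        # context window clipped at chromosome ends; edge variants lack
        # a full trinucleotide and are unclassifiable
        gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
            pmax(pos - 1, 1), pmin(pos + 1, genomeLens[chrom])))
        ctx <- toupper(as.character(Biostrings::getSeq(fa, gr)))
        full <- nchar(ctx) == 3 & pos > 1
        gbase <- ifelse(full, substr(ctx, 2, 2), NA_character_)

        refOk <- !is.na(gbase) & gbase == ref
        log$skippedRefMismatch[i] <- sum(full & gbase != ref, na.rm = TRUE)
        keep <- refOk
        if (any(keep)) {
            idx <- classifySNV(ref[keep], alt[keep],
                substr(ctx[keep], 1, 1), substr(ctx[keep], 3, 3))
            log$skippedContext[i] <- sum(!full) + sum(is.na(idx))
            tab <- tabulate(idx[!is.na(idx)], nbins = 96)
            counts[i, ] <- counts[i, ] + as.integer(tab)
            log$classified[i] <- sum(!is.na(idx))
        } else {
            log$skippedContext[i] <- sum(!full)
        }
    }
    message("classified ", sum(log$classified), " SNVs; skipped ",
        sum(log$skippedNonSNV), " non-SNV, ",
        sum(log$skippedRefMismatch), " REF-mismatch, ",
        sum(log$skippedContext), " ambiguous-context records")
    out <- MutationCatalog(counts, "SBS96")
    attr(out, "log") <- log
    out
}
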