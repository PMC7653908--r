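#' Plot signature profiles as 96-channel bar charts
#'
#' One bar per channel, faceted by signature, bars grouped and coloured by
#' the six substitution classes, channels in canonical order. For non-SBS96
#' channel sets a generic single-colour bar layout is drawn.
#'
#' @param panel a [SignaturePanel-class].
#' @param file optional output path (written with [ggplot2::ggsave()]).
#' @return the ggplot object, invisibly when `file` is given.
#' @export
plotSignatureProfile <- function(panel, file = NULL) {
    p <- signatureProbs(panel)
    df <- data.frame(
        signature = factor(rep(rownames(p), each = ncol(p)),
            levels = rownames(p)),
        channel = factor(rep(colnames(p), nrow(p)), levels = colnames(p)),
        prob = as.vector(t(p)))
    if (identical(panel@channelSet, "SBS96")) {
        df$class <- sub("^.\\[(.>.)\\].$", "\\1", as.character(df$channel))
        g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$channel,
                y = .data$prob, fill = .data$class)) +
            ggplot2::scale_fill_manual(values = c(
                "C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
                "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4"))
    } else {
        g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$channel,
            y = .data$prob))
    }
    g <- g + ggplot2::geom_col() +
        ggplot2::facet_wrap(~signature, ncol = 1, scales = "free_y") +
        ggplot2::labs(x = NULL, y = "mutation probability") +
        ggplot2::theme_minimal(base_size = 8) +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
            vjust = 0.5, size = 4), legend.position = "none")
    if (!is.null(file)) {
        ggplot2::ggsave(file, g, width = 10,
            height = 1.2 * nrow(p) + 1, limitsize = FALSE)
        return(invisible(g))
    }
    g
}

#' Plot per-sample signature contributions as stacked bars
#'
#' Stacked bar of attributed mutations per sample; stack heights equal the
#' row sums of W. With `clustered = TRUE`, samples are ordered by
#' average-linkage hierarchical clustering of the Euclidean distances
#' between row-normalised exposure fractions.
#'
#' @param W samples-by-signatures exposure matrix.
#' @param clustered reorder samples by hierarchical clustering.
#' @param file optional output path.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
plotContributions <- function(W, clustered = FALSE, file = NULL) {
    ord <- seq_len(nrow(W))
    if (clustered && nrow(W) > 1) {
        fr <- W / pmax(rowSums(W), 1e-12)
        ord <- stats::hclust(stats::dist(fr), method = "average")$order
    }
    df <- data.frame(
        sample = factor(rep(rownames(W), ncol(W)),
            levels = rownames(W)[ord]),
        signature = rep(colnames(W), each = nrow(W)),
        exposure = as.vector(W))
    g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample,
            y = .data$exposure, fill = .data$signature)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "attributed mutations",
            caption = if (clustered)
                "sample order: average-linkage clustering, Euclidean distance of exposure fractions"
            else NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
            vjust = 0.5))
    if (!is.null(file)) {
        ggplot2::ggsave(file, g, width = 8, height = 5)
        return(invisible(g))
    }
    g
}

#' Plot a stepwise cost curve or a cross-validation curve
#'
#' For a [CostCurve-class], cost against model size with the
#' added/removed signature labelled at each point; backward curves are
#' drawn against the number of signatures remaining in the model, so the
#' curve appears decreasing like a forward curve. For a [CVResult-class],
#' overlaid train and test series against the candidate number of de novo
#' signatures.
#'
#' @param x a [CostCurve-class] or [CVResult-class].
#' @param file optional output path.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
plotCostCurve <- function(x, file = NULL) {
    if (is(x, "CostCurve")) {
        st <- x@steps
        size <- if (x@direction == "forward") st$step
            else length(x@panelNames) - st$step
        df <- data.frame(size = size, cost = st$cost,
            signature = st$signature)
        g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size,
                y = .data$cost)) +
            ggplot2::geom_line(colour = "grey50") +
            ggplot2::geom_point() +
            ggplot2::geom_text(ggplot2::aes(label = .data$signature),
                hjust = -0.1, vjust = -0.4, size = 2.6) +
            ggplot2::labs(x = "signatures in model", y = "cost C",
                title = paste0(x@direction, " selection"))
    } else if (is(x, "CVResult")) {
        s <- x@summary
        df <- data.frame(
            nNew = rep(s$nNew, 2),
            cost = c(s$trainCost, s$testCost),
            set = rep(c("train", "test"), each = nrow(s)))
        g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nNew,
                y = .data$cost, colour = .data$set)) +
            ggplot2::geom_line() + ggplot2::geom_point() +
            ggplot2::labs(x = "de novo signatures", y = "cost C")
    } else stop("need a CostCurve or CVResult")
    g <- g + ggplot2::theme_minimal()
    if (!is.null(file)) {
        ggplot2::ggsave(file, g, width = 6, height = 4)
        return(invisible(g))
    }
    g
}
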