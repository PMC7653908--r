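#' Hellinger distance between two probability distributions
#'
#' Mutational signatures are probability distributions over mutation-type
#' channels, so their similarity is scored with a metric built for
#' distributions: the Hellinger distance
#' \deqn{H(p, q) = \frac{1}{\sqrt{2}} \sqrt{\sum_i (\sqrt{p_i} - \sqrt{q_i})^2},}
#' which lies in [0, 1], is 0 exactly for identical distributions and 1 for
#' distributions with disjoint support.
#'
#' Inputs whose sums deviate from 1 by at most 1e-6 are renormalised;
#' larger deviations are an input error, never silently normalised.
#'
#' @param p,q non-negative numeric vectors of equal length, each summing
#'   to 1.
#' @return the distance, a scalar in [0, 1].
#' @examples
#' hellinger(c(1, 0), c(0, 1))        # 1
#' hellinger(c(1, 0), c(0.5, 0.5))    # ~0.5412
#' @export
hellinger <- function(p, q) {
    if (length(p) != length(q)) stop("length mismatch")
    if (any(p < 0) || any(q < 0)) stop("negative entry in distribution")
    sp <- sum(p); sq <- sum(q)
    if (abs(sp - 1) > 1e-6 || abs(sq - 1) > 1e-6)
        stop("input does not sum to 1 (tolerance 1e-6)")
    p <- p / sp; q <- q / sq
    min(1, sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2))
}

#' Hellinger distance matrix between two signature panels
#'
#' @param Q,R [SignaturePanel-class] objects over the same channel set
#'   (aligned by channel label; a label mismatch is an error).
#' @return matrix of distances, Q signatures in rows, R signatures in
#'   columns, entries in [0, 1].
#' @export
hellingerMatrix <- function(Q, R) {
    R <- .alignPanel(R, colnames(Q@probs))
    qs <- sqrt(Q@probs / rowSums(Q@probs))
    rs <- sqrt(R@probs / rowSums(R@probs))
    # ||sqrt(p)-sqrt(q)||^2 = 2 - 2 <sqrt(p), sqrt(q)>
    d2 <- pmax(2 - 2 * tcrossprod(qs, rs), 0)
    d <- pmin(sqrt(d2) / sqrt(2), 1)
    dimnames(d) <- list(rownames(Q@probs), rownames(R@probs))
    d
}

#' Best-matching reference signature per query signature
#'
#' For every query signature, the reference signature at the smallest
#' Hellinger distance (HDS). Ties are broken by reference panel order.
#'
#' @inheritParams hellingerMatrix
#' @return data.frame with columns query, reference, hds.
#' @export
bestMatch <- function(Q, R) {
    if (nrow(R@probs) < 1) stop("empty reference panel")
    d <- hellingerMatrix(Q, R)
    j <- apply(d, 1, which.min)
    data.frame(query = rownames(d), reference = colnames(d)[j],
        hds = d[cbind(seq_len(nrow(d)), j)], row.names = NULL)
}
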