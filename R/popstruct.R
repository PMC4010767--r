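## Kinship estimation, least-related subset selection, and PCA.

#' Pairwise kinship/relatedness matrix
#'
#' Two estimators over non-missing shared sites:
#' \describe{
#'   \item{ibs}{allele-sharing proportion, mean of (2 - |g_i - g_j|)/2;
#'     entries in [0, 1], diagonal 1.}
#'   \item{grm}{VanRaden centered/scaled genomic relationship,
#'     Z Z' / m with Z = (g - 2p)/sqrt(2 p (1-p)); missing calls are
#'     mean-imputed (0 after centering); diagonal is about 1 + inbreeding.}
#' }
#'
#' @param gm [GenotypeData].
#' @param mode "ibs" or "grm".
#' @return symmetric n x n matrix with sample-id dimnames.
#' @export
kinshipMatrix <- function(gm, mode = c("ibs", "grm")) {
    mode <- match.arg(mode)
    g <- t(genotypeCalls(gm))          # samples x variants
    if (any(rowSums(!is.na(g)) == 0L))
        stop("sample(s) with no non-missing calls: ",
             paste(rownames(g)[rowSums(!is.na(g)) == 0L], collapse = ", "))
    if (mode == "ibs") {
        ## sum over sites of |g_i - g_j| decomposes over dosage indicators
        A <- list(`0` = (!is.na(g)) & g == 0L,
                  `1` = (!is.na(g)) & g == 1L,
                  `2` = (!is.na(g)) & g == 2L)
        A <- lapply(A, function(x) {x[is.na(x)] <- FALSE; x * 1})
        absdiff <- matrix(0, nrow(g), nrow(g))
        for (a in 0:2) for (b in 0:2)
            if (a != b)
                absdiff <- absdiff +
                    abs(a - b) * tcrossprod(A[[as.character(a)]],
                                            A[[as.character(b)]])
        M <- tcrossprod((!is.na(g)) * 1)  # shared non-missing counts
        if (any(M == 0))
            stop("pair(s) with zero overlapping non-missing sites: ",
                 paste(apply(which(M == 0, arr.ind = TRUE)[1, , drop = FALSE],
                             1, function(ij)
                                 paste(rownames(g)[ij], collapse = "/")),
                       collapse = ", "))
        K <- 1 - absdiff / (2 * M)
    } else {
        p <- colMeans(g, na.rm = TRUE) / 2
        keep <- p > 0 & p < 1
        gk <- g[, keep, drop = FALSE]
        p <- p[keep]
        Z <- sweep(gk, 2L, 2 * p)
        Z[is.na(Z)] <- 0
        Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
        K <- tcrossprod(Z) / ncol(Z)
    }
    dimnames(K) <- list(rownames(g), rownames(g))
    K
}

#' Greedy least-related subset selection
#'
#' While any off-diagonal kinship exceeds \code{max_kin}, drops the sample
#' involved in the most violating pairs; ties broken by largest mean
#' kinship, then lexicographic sample id. The retained set has no pair
#' above the threshold.
#'
#' @param K symmetric kinship matrix with sample-id dimnames.
#' @param max_kin exclusion threshold on pairwise kinship.
#' @return character vector of retained sample ids.
#' @export
selectLeastRelated <- function(K, max_kin = 0.9) {
    if (max_kin >= min(diag(K)))
        stop("max_kin must be below the diagonal (self-kinship) values")
    keep <- rownames(K)
    repeat {
        Ks <- K[keep, keep, drop = FALSE]
        viol <- Ks > max_kin
        diag(viol) <- FALSE
        counts <- rowSums(viol)
        if (all(counts == 0L)) break
        worst <- which(counts == max(counts))
        if (length(worst) > 1L) {
            mk <- rowMeans(Ks)[worst]
            worst <- worst[mk == max(mk)]
            if (length(worst) > 1L)
                worst <- worst[order(names(worst))][1L]
        }
        keep <- setdiff(keep, names(worst)[1L])
    }
    keep
}

#' Principal component analysis of genotypes
#'
#' EIGENSTRAT-style: each variant is centered by its mean dosage (2 p-hat)
#' and scaled by sqrt(p-hat (1 - p-hat)); missing calls are imputed to the
#' column mean before scaling; monomorphic variants are removed. Scores
#' are the eigenvectors of the sample covariance Z Z' / m.
#'
#' @param gm [GenotypeData].
#' @param n_components number of components to return.
#' @return list with \code{scores} (n x k, orthonormal columns),
#'   \code{eigenvalues} (non-increasing), \code{n_variants_used}.
#' @export
pcaGenotypes <- function(gm, n_components = 10L) {
    g <- t(genotypeCalls(gm))
    if (nrow(g) < 2L) stop("need at least two samples")
    p <- colMeans(g, na.rm = TRUE) / 2
    keep <- !is.na(p) & p > 0 & p < 1
    if (sum(keep) < 2L) stop("fewer than two polymorphic variants")
    g <- g[, keep, drop = FALSE]
    p <- p[keep]
    Z <- sweep(g, 2L, 2 * p)
    Z[is.na(Z)] <- 0
    Z <- sweep(Z, 2L, sqrt(p * (1 - p)), "/")
    C <- tcrossprod(Z) / ncol(Z)
    eig <- eigen(C, symmetric = TRUE)
    k <- min(n_components, nrow(g))
    scores <- eig$vectors[, seq_len(k), drop = FALSE]
    rownames(scores) <- rownames(g)
    colnames(scores) <- paste0("PC", seq_len(k))
    list(scores = scores, eigenvalues = eig$values[seq_len(k)],
         n_variants_used = ncol(Z), scaling = "eigenstrat")
}

#' Write a kinship matrix (or PCA scores) as TSV
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTsv <- function(x, path) {
    utils::write.table(data.frame(id = rownames(x), x, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
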