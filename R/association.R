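## Kinship-corrected association, adaptive permutation, EM linkage
## disequilibrium, Gabriel-rule haplotype blocks, and per-pattern
## haplotype association.

.alignKinship <- function(K, ids) {
    if (is.null(rownames(K))) {
        if (nrow(K) != length(ids)) stop("kinship matrix not aligned to samples")
        dimnames(K) <- list(ids, ids)
    }
    if (!all(ids %in% rownames(K))) stop("kinship matrix missing sample(s)")
    K[ids, ids]
}

## REML profile log-likelihood in the eigenbasis of K, intercept-only null
.remlNull <- function(yt, at, lambda) {
    n <- length(yt)
    ll <- function(logdelta) {
        d <- lambda + exp(logdelta)
        w <- 1 / d
        beta0 <- sum(w * at * yt) / sum(w * at^2)
        r <- yt - at * beta0
        s2 <- sum(w * r^2) / (n - 1)
        -0.5 * ((n - 1) * log(2 * pi * s2) + sum(log(d)) +
                log(sum(w * at^2)) + (n - 1))
    }
    grid <- seq(-10, 10, length.out = 81)
    vals <- vapply(grid, ll, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE)
    delta <- exp(opt$maximum)
    d <- lambda + delta
    w <- 1 / d
    beta0 <- sum(w * at * yt) / sum(w * at^2)
    s2g <- sum(w * (yt - at * beta0)^2) / (n - 1)
    list(delta = delta, sigma2_g = s2g, sigma2_e = delta * s2g,
         logREML = opt$objective)
}

## Vectorized per-SNP GLS t-tests with fixed weights w in the rotated basis.
## Gt: n x m rotated (mean-imputed) genotypes; returns beta, t, p (df n-2).
.glsScan <- function(yt, at, Gt, w) {
    n <- length(yt)
    wa <- w * at; wy <- w * yt
    Saa <- sum(wa * at); Say <- sum(wa * yt); Syy <- sum(wy * yt)
    Sax <- colSums(Gt * wa)
    Sxy <- colSums(Gt * wy)
    Sxx <- colSums(Gt * Gt * w)
    det <- Saa * Sxx - Sax^2
    ok <- det > 1e-10 * Saa * pmax(Sxx, 1e-300)
    beta <- (Saa * Sxy - Sax * Say) / det
    beta0 <- (Say * Sxx - Sxy * Sax) / det
    rss <- Syy - beta0 * Say - beta * Sxy
    rss <- pmax(rss, 0)
    s2 <- rss / (n - 2)
    se <- suppressWarnings(sqrt(s2 * Saa / det))
    tstat <- beta / se
    tstat[!ok] <- NA_real_
    beta[!ok] <- NA_real_
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    list(beta = beta, stat = tstat, p = p)
}

.meanImpute <- function(G) {   # samples x variants
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    if (nrow(idx)) G[idx] <- mu[idx[, 2L]]
    G
}

#' Mixed-model case/control association
#'
#' Single-SNP association under the model y = mu + g + e with
#' g ~ N(0, sigma2_g K) and e ~ N(0, sigma2_e I). The variance ratio
#' delta = sigma2_e / sigma2_g is estimated once by REML on the null model
#' via the eigendecomposition of K and one-dimensional likelihood
#' optimization; every SNP is then tested by generalized least squares
#' with those fixed variance components (the EMMAX approximation).
#' Case/control status is coded 0/1 and analysed as a quantitative trait.
#' Missing genotypes are mean-imputed per SNP for testing; constant SNPs
#' get NA statistics.
#'
#' @param gm [GenotypeData].
#' @param phenotype numeric 0/1 vector aligned to samples (1 = case), or
#'   NULL to derive it from \code{sampleInfo(gm)$role}.
#' @param K kinship matrix (see [kinshipMatrix()], mode "grm" recommended);
#'   identity if NULL.
#' @return list with \code{table} (per-variant data.frame: id, chrom, pos,
#'   beta, stat, p, plus NA \code{p_perm}/\code{n_perm} columns filled by
#'   [adaptivePermutation()]), \code{sigma2_g}, \code{sigma2_e},
#'   \code{delta}, and the eigen-rotation reused for permutation.
#' @export
mixedModelAssoc <- function(gm, phenotype = NULL, K = NULL) {
    s <- sampleInfo(gm)
    if (is.null(phenotype))
        phenotype <- as.numeric(s$role == "case")
    y <- as.numeric(phenotype)
    if (length(unique(y)) < 2L) stop("phenotype is constant")
    n <- length(y)
    if (is.null(K)) K <- diag(n)
    K <- .alignKinship(K, s$sample_id)
    eig <- eigen(K + diag(1e-8, n), symmetric = TRUE)
    if (min(eig$values) < -1e-6)
        stop("kinship matrix is not positive semi-definite")
    lambda <- pmax(eig$values, 0)
    U <- eig$vectors
    yt <- drop(crossprod(U, y))
    at <- drop(crossprod(U, rep(1, n)))
    null <- .remlNull(yt, at, lambda)
    w <- 1 / (lambda + null$delta)
    G <- .meanImpute(t(genotypeCalls(gm)))
    Gt <- crossprod(U, G)
    sc <- .glsScan(yt, at, Gt, w)
    v <- variantInfo(gm)
    tab <- data.frame(variant_id = names(v),
                      chrom = as.character(GenomicRanges::seqnames(v)),
                      pos_bp = GenomicRanges::start(v),
                      beta = sc$beta, stat = sc$stat, p = sc$p,
                      p_perm = NA_real_, n_perm = 0L,
                      stringsAsFactors = FALSE, row.names = NULL)
    list(table = tab, sigma2_g = null$sigma2_g, sigma2_e = null$sigma2_e,
         delta = null$delta, logREML = null$logREML,
         rotation = list(U = U, lambda = lambda, w = w, y = y))
}

#' Adaptive permutation p-values for the association scan
#'
#' Permutes phenotype labels at the sample level and counts permuted |t|
#' statistics at least as large as the observed one (ties count, add-one
#' smoothing): p = (1 + count) / (1 + n_performed). SNPs are dropped from
#' the active set once their exceedance count reaches \code{drop_count}
#' (their p-value is then already resolved as clearly non-significant),
#' which is what makes the procedure adaptive. The permuted statistic uses
#' the same fixed variance components as the observed scan.
#'
#' @param assoc result of [mixedModelAssoc()].
#' @param gm the same [GenotypeData].
#' @param max_perm maximum permutations per SNP.
#' @param drop_count early-termination exceedance count.
#' @param seed optional RNG seed for reproducible permutations.
#' @return \code{assoc} with \code{table$p_perm} and \code{table$n_perm}
#'   filled in.
#' @export
adaptivePermutation <- function(assoc, gm, max_perm = 1000L,
                                drop_count = 10L, seed = NULL) {
    if (max_perm < 1L) stop("max_perm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    rot <- assoc$rotation
    y <- rot$y
    if (length(unique(y)) < 2L) stop("phenotype is constant")
    G <- .meanImpute(t(genotypeCalls(gm)))
    Gt <- crossprod(rot$U, G)
    at <- drop(crossprod(rot$U, rep(1, length(y))))
    obs <- abs(assoc$table$stat)
    m <- length(obs)
    count <- integer(m); nperf <- integer(m)
    active <- which(!is.na(obs))
    for (b in seq_len(max_perm)) {
        if (length(active) == 0L) break
        yp <- y[sample.int(length(y))]
        ypt <- drop(crossprod(rot$U, yp))
        st <- abs(.glsScan(ypt, at, Gt[, active, drop = FALSE], rot$w)$stat)
        hit <- !is.na(st) & st >= obs[active]
        count[active] <- count[active] + hit
        nperf[active] <- nperf[active] + 1L
        active <- active[count[active] < drop_count]
    }
    p <- (1 + count) / (1 + nperf)
    p[nperf == 0L] <- NA_real_
    assoc$table$p_perm <- p
    assoc$table$n_perm <- nperf
    assoc
}

## ---- EM linkage disequilibrium ----

.twoLocusCounts <- function(g1, g2) {
    ok <- !is.na(g1) & !is.na(g2)
    table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
}

## genotype-pair log-likelihood given haplotype frequencies
## p4 = c(p00, p01, p10, p11), alleles (locus1, locus2);
## .glMap[g, ab] maps the 16 ordered haplotype pairs onto the 9 genotype
## cells (row-major g1 then g2), precomputed once
.glMap <- local({
    hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    M <- matrix(0, 9, 16)
    k <- 0
    for (a in 1:4) for (b in 1:4) {
        k <- k + 1
        g1 <- hap[a, 1] + hap[b, 1]
        g2 <- hap[a, 2] + hap[b, 2]
        M[g1 * 3 + g2 + 1, k] <- 1
    }
    M
})

.twoLocusLogLik <- function(counts, p4) {
    p <- pmax(p4, 1e-12)
    gp <- .glMap %*% as.vector(outer(p, p, `*`))
    ## counts is indexed [g1, g2]; gp rows are g1-major
    cnt <- as.vector(t(counts))
    sum(cnt * log(pmax(gp, 1e-300)))
}

#' EM estimate of two-locus linkage disequilibrium
#'
#' Maximum-likelihood haplotype frequencies from unphased diploid
#' genotypes: only the double heterozygote is phase-ambiguous and is split
#' between cis and trans configurations in the E step. Convergence when
#' the largest frequency change is below 1e-8 (at most 1000 iterations).
#'
#' @param g1,g2 genotype dosage vectors (0/1/2, NA allowed).
#' @return list: \code{r2}, \code{dprime} (signed), \code{hap_freq}
#'   (p00, p01, p10, p11), \code{loglik}, \code{iterations},
#'   \code{converged}.
#' @export
ldR2EM <- function(g1, g2) {
    n <- .twoLocusCounts(g1, g2)
    nn <- sum(n)
    if (nn == 0L) stop("no complete genotype pairs")
    pA <- sum(n * matrix(0:2, 3, 3)) / (2 * nn)       # alt freq locus 1
    pB <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * nn)
    if (pA <= 0 || pA >= 1) stop("locus 1 is monomorphic")
    if (pB <= 0 || pB >= 1) stop("locus 2 is monomorphic")
    ## haplotype counts fixed by genotype except the double het
    ## base counts of (00,01,10,11) from unambiguous configurations
    fixed <- c(
        `00` = 2 * n[1, 1] + n[1, 2] + n[2, 1],
        `01` = 2 * n[1, 3] + n[1, 2] + n[2, 3],
        `10` = 2 * n[3, 1] + n[3, 2] + n[2, 1],
        `11` = 2 * n[3, 3] + n[3, 2] + n[2, 3])
    ndh <- n[2, 2]
    p <- c((1 - pA) * (1 - pB), (1 - pA) * pB, pA * (1 - pB), pA * pB)
    it <- 0L; converged <- FALSE
    while (it < 1000L) {
        it <- it + 1L
        cis <- p[1] * p[4]
        trans <- p[2] * p[3]
        pc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
        h <- fixed + ndh * c(pc, 1 - pc, 1 - pc, pc)
        pnew <- h / (2 * nn)
        if (max(abs(pnew - p)) < 1e-8) { p <- pnew; converged <- TRUE; break }
        p <- pnew
    }
    D <- p[4] - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    list(r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))),
         dprime = unname(if (dmax > 0) D / dmax else 0),
         hap_freq = stats::setNames(p, c("p00", "p01", "p10", "p11")),
         loglik = .twoLocusLogLik(n, p),
         iterations = it, converged = converged)
}

## 90% confidence interval for |D'| by likelihood profiling on a
## 101-point grid with allele frequencies fixed at their MLEs.
.dprimeCI <- function(g1, g2) {
    n <- .twoLocusCounts(g1, g2)
    nn <- sum(n)
    pA <- sum(n * matrix(0:2, 3, 3)) / (2 * nn)
    pB <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * nn)
    if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NULL)
    em <- ldR2EM(g1, g2)
    sgn <- if (em$dprime >= 0) 1 else -1
    dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    grid <- seq(0, 1, length.out = 101L)
    D <- sgn * grid * dmax
    P <- rbind((1 - pA) * (1 - pB) + D, (1 - pA) * pB - D,
               pA * (1 - pB) - D, pA * pB + D)          # 4 x 101
    bad <- colSums(P < -1e-9) > 0
    P <- pmax(P, 1e-12)
    PP <- P[rep(1:4, times = 4), , drop = FALSE] *
          P[rep(1:4, each = 4), , drop = FALSE]         # 16 x 101
    gp <- pmax(.glMap %*% PP, 1e-300)                   # 9 x 101
    ll <- colSums(as.vector(t(n)) * log(gp))
    ll[bad] <- -Inf
    L <- exp(ll - max(ll))
    cum <- cumsum(L) / sum(L)
    low <- if (any(cum < 0.05)) grid[max(which(cum < 0.05)) + 1L] else 0
    high <- if (any(cum <= 0.95)) grid[min(101L, max(which(cum <= 0.95)) + 1L)]
            else grid[1L]
    c(lower = low, upper = high)
}

#' Detect haplotype blocks by the Gabriel confidence-interval rule
#'
#' For each close marker pair a 90% confidence interval of |D'| is
#' profiled on a 101-point grid; a pair is "strong LD" when the CI lower
#' bound is at least \code{strong_lower} and the upper at least
#' \code{strong_upper}, and "strong recombination" (informative but not
#' strong) when the upper bound is below \code{recomb_upper}. A contiguous
#' candidate region is a block when at least \code{frac_strong} of its
#' informative pairs are strong LD; candidates are accepted greedily
#' largest-first without overlap. Pairs farther apart than
#' \code{max_pair_dist_kb} are ignored.
#'
#' @param gm [GenotypeData] (or [HaplotypeSet], collapsed internally).
#' @param max_pair_dist_kb maximum pair distance considered, kb.
#' @param max_block_snps cap on block size in SNPs (bounds the pair scan).
#' @param strong_lower,strong_upper,recomb_upper,frac_strong Gabriel rule
#'   constants (Haploview defaults).
#' @return data.frame: block_id, start_index, end_index, chrom, start_bp,
#'   end_bp, n_snps.
#' @export
detectBlocks <- function(gm, max_pair_dist_kb = 1000,
                         max_block_snps = 50L,
                         strong_lower = 0.70, strong_upper = 0.98,
                         recomb_upper = 0.90, frac_strong = 0.95) {
    if (is(gm, "HaplotypeSet")) gm <- haplotypesToGenotypes(gm)
    G <- t(genotypeCalls(gm))
    v <- variantInfo(gm)
    pos <- GenomicRanges::start(v)
    chrom <- as.character(GenomicRanges::seqnames(v))
    if (length(unique(chrom)) != 1L)
        stop("detectBlocks expects a single chromosome")
    m <- ncol(G)
    if (m < 2L) stop("need at least two variants")
    ## pair classification: 1 strong, -1 recomb, 0 uninformative
    cls <- matrix(0L, m, m)
    for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):min(m, i + max_block_snps - 1L)) {
            if (pos[j] - pos[i] > max_pair_dist_kb * 1000) break
            ci <- tryCatch(.dprimeCI(G[, i], G[, j]), error = function(e) NULL)
            if (is.null(ci)) next
            if (ci["lower"] >= strong_lower && ci["upper"] >= strong_upper)
                cls[i, j] <- 1L
            else if (ci["upper"] < recomb_upper)
                cls[i, j] <- -1L
        }
    }
    cand <- list()
    for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):min(m, i + max_block_snps - 1L)) {
            if (pos[j] - pos[i] > max_pair_dist_kb * 1000) break
            sub <- cls[i:j, i:j]
            ns <- sum(sub == 1L); nr <- sum(sub == -1L)
            if (ns + nr == 0L) next
            if (ns / (ns + nr) >= frac_strong && ns >= 1L)
                cand[[length(cand) + 1L]] <- c(i, j)
        }
    }
    if (length(cand) == 0L)
        return(data.frame(block_id = integer(), start_index = integer(),
                          end_index = integer(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer()))
    cand <- do.call(rbind, cand)
    ord <- order(-(cand[, 2L] - cand[, 1L]), cand[, 1L])
    cand <- cand[ord, , drop = FALSE]
    taken <- rep(FALSE, m)
    keep <- list()
    for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (!any(taken[i:j])) {
            taken[i:j] <- TRUE
            keep[[length(keep) + 1L]] <- c(i, j)
        }
    }
    keep <- do.call(rbind, keep)
    keep <- keep[order(keep[, 1L]), , drop = FALSE]
    data.frame(block_id = seq_len(nrow(keep)),
               start_index = keep[, 1L], end_index = keep[, 2L],
               chrom = chrom[1L],
               start_bp = pos[keep[, 1L]], end_bp = pos[keep[, 2L]],
               n_snps = keep[, 2L] - keep[, 1L] + 1L,
               stringsAsFactors = FALSE)
}

#' Per-pattern haplotype association with a permutation null
#'
#' Within each block, chromosomes are grouped by their exact allele
#' string; every pattern is tested pattern-vs-rest with a 2x2 chi-square
#' on case/control chromosome counts. The permutation null permutes
#' sample-level labels (both chromosomes of a sample move together) and
#' counts permuted chi-squares at least as large as the observed one
#' (add-one smoothing). Chromosomes with a missing call inside the block
#' are excluded from that block.
#'
#' @param hs [HaplotypeSet].
#' @param blocks data.frame from [detectBlocks()] (needs start_index,
#'   end_index; block_id optional).
#' @param phenotype 0/1 vector aligned to the samples of \code{hs}
#'   (1 = case/affected).
#' @param n_perm permutations for the corrected p-value (0 = skip).
#' @param min_pattern_freq patterns rarer than this overall are not tested.
#' @param report_threshold_perm_p only rows with permuted p below this are
#'   returned (set to 1 to keep everything; also 1 when n_perm = 0).
#' @param seed optional RNG seed.
#' @return data.frame mirroring the block-pattern table schema: block_id,
#'   start_bp, end_bp, block_distance_bp, haplotype (letter string),
#'   freq_total, freq_slick, freq_nonslick, chi2, p_value, p_perm.
#' @export
patternAssoc <- function(hs, blocks, phenotype, n_perm = 100000L,
                         min_pattern_freq = 0.01,
                         report_threshold_perm_p = 0.001, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (n_perm == 0L) report_threshold_perm_p <- 1
    a <- hapAlleles(hs)
    v <- variantInfo(hs)
    pos <- GenomicRanges::start(v)
    ref <- S4Vectors::mcols(v)$ref; alt <- S4Vectors::mcols(v)$alt
    ids <- unique(hapSampleOf(hs))
    sample_idx <- match(hapSampleOf(hs), ids)
    stopifnot(length(phenotype) == length(ids))
    case <- as.numeric(phenotype) == 1
    out <- list()
    chi2 <- function(a1, b1, c1, d1) {
        tot <- (a1 + b1 + c1 + d1)
        den <- (a1 + b1) * (c1 + d1) * (a1 + c1) * (b1 + d1)
        ifelse(den > 0, tot * (a1 * d1 - b1 * c1)^2 / den, NA_real_)
    }
    for (b in seq_len(nrow(blocks))) {
        i <- blocks$start_index[b]; j <- blocks$end_index[b]
        sub <- a[, i:j, drop = FALSE]
        ok <- rowSums(is.na(sub)) == 0L
        if (!any(ok)) { warning("block ", b, " all-missing; skipped"); next }
        strs <- apply(matrix(ifelse(sub[ok, , drop = FALSE] == 1L,
                                    rep(alt[i:j], each = sum(ok)),
                                    rep(ref[i:j], each = sum(ok))),
                             nrow = sum(ok)),
                      1L, paste, collapse = "")
        pats <- names(which(table(strs) / length(strs) >= min_pattern_freq))
        if (length(pats) == 0L) next
        ## per-sample pattern dosage (0/1/2 chromosomes matching)
        sidx <- sample_idx[ok]
        D <- vapply(pats, function(pt)
            as.vector(tabulate(sidx[strs == pt], nbins = length(ids))),
            numeric(length(ids)))
        chrom_per_sample <- tabulate(sidx, nbins = length(ids))
        n_case_chr <- sum(chrom_per_sample[case])
        n_ctrl_chr <- sum(chrom_per_sample[!case])
        cnt_case <- colSums(D[case, , drop = FALSE])
        cnt_ctrl <- colSums(D[!case, , drop = FALSE])
        obs <- chi2(cnt_case, n_case_chr - cnt_case,
                    cnt_ctrl, n_ctrl_chr - cnt_ctrl)
        pperm <- rep(NA_real_, length(pats))
        if (n_perm > 0L) {
            exceed <- numeric(length(pats))
            done <- 0L
            while (done < n_perm) {
                nb <- min(5000L, n_perm - done)
                C <- vapply(seq_len(nb), function(z)
                    as.numeric(sample(case)), numeric(length(ids)))
                ncc <- drop(crossprod(C, chrom_per_sample))
                cc <- crossprod(D, C)            # patterns x perms
                other <- matrix(ncc, nrow = length(pats),
                                ncol = nb, byrow = TRUE) - cc
                tc <- crossprod(D, 1 - C)
                no <- matrix(sum(chrom_per_sample) - ncc,
                             nrow = length(pats), ncol = nb,
                             byrow = TRUE) - tc
                st <- chi2(cc, other, tc, no)
                exceed <- exceed +
                    rowSums(!is.na(st) & st >= obs - 1e-12, na.rm = TRUE)
                done <- done + nb
            }
            pperm <- (1 + exceed) / (1 + n_perm)
        }
        out[[length(out) + 1L]] <- data.frame(
            block_id = if (!is.null(blocks$block_id)) blocks$block_id[b] else b,
            start_bp = pos[i], end_bp = pos[j],
            block_distance_bp = pos[j] - pos[i],
            haplotype = pats,
            freq_total = (cnt_case + cnt_ctrl) / (n_case_chr + n_ctrl_chr),
            freq_slick = cnt_case / n_case_chr,
            freq_nonslick = cnt_ctrl / n_ctrl_chr,
            chi2 = obs,
            p_value = stats::pchisq(obs, df = 1, lower.tail = FALSE),
            p_perm = pperm,
            stringsAsFactors = FALSE, row.names = NULL)
    }
    if (length(out) == 0L)
        return(data.frame())
    res <- do.call(rbind, out)
    if (report_threshold_perm_p < 1 && n_perm > 0L)
        res <- res[!is.na(res$p_perm) &
                   res$p_perm < report_threshold_perm_p, , drop = FALSE]
    rownames(res) <- NULL
    res
}
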