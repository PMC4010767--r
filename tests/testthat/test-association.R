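test_that("mixed model with identity kinship reduces to ordinary regression", {
    set.seed(11)
    n <- 40; m <- 25
    calls <- matrix(rbinom(n * m, 2, 0.4), nrow = m)
    y <- rbinom(n, 1, 0.5); y[1] <- 1; y[2] <- 0     # ensure non-constant
    gm <- toyGm(calls)
    a <- mixedModelAssoc(gm, y, K = NULL)
    for (j in c(1, 7, 20)) {
        fit <- summary(stats::lm(y ~ calls[j, ]))
        expect_lt(abs(a$table$p[j] - fit$coefficients[2, 4]), 1e-6)
        expect_lt(abs(a$table$beta[j] - fit$coefficients[2, 1]), 1e-8)
    }
    ## constant SNP: NA statistic, not an error
    calls2 <- calls; calls2[3, ] <- 1L
    a2 <- mixedModelAssoc(toyGm(calls2), y, NULL)
    expect_true(is.na(a2$table$p[3]))
    expect_error(mixedModelAssoc(gm, rep(1, n), NULL), "constant")
})

test_that("variance components are sensible and invariant to reordering", {
    co <- simulateCohort(smallConfig(seed = 3))
    gm <- co$genotypes
    y <- as.numeric(sampleInfo(gm)$role == "case")
    K <- kinshipMatrix(gm, "grm")
    a <- mixedModelAssoc(gm, y, K)
    expect_gt(a$sigma2_g, 0)
    expect_gt(a$sigma2_e, 0)
    expect_equal(a$delta, a$sigma2_e / a$sigma2_g, tolerance = 1e-10)
    ## joint sample permutation leaves per-SNP p-values unchanged
    perm <- sample(seq_along(y))
    a2 <- mixedModelAssoc(as(gm[, perm], "GenotypeData"), y[perm],
                          K[perm, perm])
    expect_equal(a2$table$p, a$table$p, tolerance = 1e-6)
})

test_that("the causal SNP tops the kinship-corrected scan", {
    hits <- 0L
    for (sd in 1:3) {
        co <- simulateCohort(cohortConfig(seed = 400 + sd))
        gm <- co$genotypes
        K <- kinshipMatrix(gm, "grm")
        a <- mixedModelAssoc(gm, NULL, K)
        top <- a$table$pos_bp[which.min(a$table$p)]
        hits <- hits + (abs(top - co$truth$causal_pos) <= 5e5)
    }
    expect_gte(hits, 2L)
})

test_that("adaptive permutation p-values obey the add-one rule", {
    set.seed(15)
    n <- 30
    y <- rep(c(1, 0), each = 15)
    calls <- matrix(rbinom(n * 10, 2, 0.5), nrow = 10)
    calls[1, ] <- ifelse(y == 1, 2L, 0L)   # perfect association
    gm <- toyGm(calls)
    a <- mixedModelAssoc(gm, y, NULL)
    a <- adaptivePermutation(a, gm, max_perm = 999, drop_count = 10000L,
                             seed = 77)
    ## no permutation can beat a perfect split at n = 30
    expect_equal(a$table$p_perm[1], 1 / 1000)
    expect_equal(a$table$n_perm[1], 999L)
    expect_true(all(a$table$p_perm >= 1 / 1000, na.rm = TRUE))
    ## dropped SNPs performed fewer permutations but keep valid p
    expect_true(all(a$table$p_perm <= 1, na.rm = TRUE))
    expect_error(adaptivePermutation(a, gm, max_perm = 0), "max_perm")
})

test_that("adaptive permutation agrees with exhaustive enumeration at n=6", {
    set.seed(19)
    y <- c(1, 1, 1, 0, 0, 0)
    calls <- matrix(c(2, 2, 1, 1, 0, 0,
                      0, 2, 1, 0, 2, 1), nrow = 2, byrow = TRUE)
    gm <- toyGm(calls)
    a <- mixedModelAssoc(gm, y, NULL)
    ## exact permutation p by full enumeration of the 20 distinct labelings
    tstat <- function(yy, x) {
        f <- stats::lm(yy ~ x)
        abs(summary(f)$coefficients[2, 3])
    }
    combs <- utils::combn(6, 3)
    for (j in 1:2) {
        obs <- abs(a$table$stat[j])
        perm_stats <- apply(combs, 2, function(ix) {
            yy <- rep(0, 6); yy[ix] <- 1
            tstat(yy, calls[j, ])
        })
        p_exact <- mean(perm_stats >= obs - 1e-12)
        ap <- adaptivePermutation(a, gm, max_perm = 20000,
                                  drop_count = 1e6, seed = 5)
        expect_lt(abs(ap$table$p_perm[j] - p_exact), 0.02)
    }
})

test_that("EM linkage disequilibrium recovers known LD structure", {
    ## identical columns with all three genotype classes: perfect LD
    g <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
    r <- ldR2EM(g, g)
    expect_equal(r$r2, 1, tolerance = 1e-6)
    expect_equal(abs(r$dprime), 1, tolerance = 1e-6)
    expect_true(r$converged)
    ## independent columns: near-zero r2
    set.seed(23)
    g1 <- rbinom(500, 2, 0.5); g2 <- rbinom(500, 2, 0.4)
    expect_lt(ldR2EM(g1, g2)$r2, 0.02)
    expect_error(ldR2EM(rep(0, 10), g1[1:10]), "monomorphic")
})

test_that("EM haplotype frequencies maximize the likelihood (grid oracle)", {
    set.seed(29)
    for (rep in 1:50) {
        p <- runif(4); p <- p / sum(p)     # random true haplotype freqs
        n <- 60
        h1 <- sample(4, 2 * n, TRUE, prob = p)
        hapA <- c(0, 0, 1, 1)[h1]; hapB <- c(0, 1, 0, 1)[h1]
        g1 <- hapA[1:n] + hapA[(n + 1):(2 * n)]
        g2 <- hapB[1:n] + hapB[(n + 1):(2 * n)]
        if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
        em <- ldR2EM(g1, g2)
        counts <- table(factor(g1, 0:2), factor(g2, 0:2))
        grid_best <- max(vapply(1:200, function(i) {
            q <- runif(4); q <- q / sum(q)
            slickmap:::.twoLocusLogLik(counts, q)
        }, numeric(1)))
        expect_gte(em$loglik + 1e-6, grid_best)
    }
})

test_that("EM r2 matches the phased-count r2 when phase is unambiguous", {
    set.seed(31)
    for (rep in 1:10) {
        p <- c(0.45, 0.05, 0.05, 0.45)    # strong LD, rare recombinants
        n <- 200
        h <- sample(4, 2 * n, TRUE, prob = p)
        hapA <- c(0, 0, 1, 1)[h]; hapB <- c(0, 1, 0, 1)[h]
        g1 <- hapA[1:n] + hapA[(n + 1):(2 * n)]
        g2 <- hapB[1:n] + hapB[(n + 1):(2 * n)]
        ## drop double heterozygotes: on the remaining individuals the
        ## haplotype counts are fully determined, so EM must match the
        ## phased-count r2 exactly
        keep <- !(g1 == 1 & g2 == 1)
        keep_h <- rep(keep, 2)
        g1 <- g1[keep]; g2 <- g2[keep]
        hA <- hapA[keep_h]; hB <- hapB[keep_h]
        if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
        pA <- mean(hA == 1); pB <- mean(hB == 1)
        D <- mean(hA == 1 & hB == 1) - pA * pB
        r2_phased <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
        expect_lt(abs(ldR2EM(g1, g2)$r2 - r2_phased), 1e-6)
    }
})

test_that("block detection follows the confidence-interval rule", {
    ## five SNPs in complete LD: one block of five
    set.seed(37)
    col <- rbinom(60, 2, 0.5)
    while (length(unique(col)) < 3) col <- rbinom(60, 2, 0.5)
    gm <- toyGm(matrix(rep(col, 5), nrow = 5, byrow = TRUE))
    bl <- detectBlocks(gm)
    expect_equal(nrow(bl), 1L)
    expect_equal(bl$n_snps, 5L)
    ## independent SNPs: no blocks
    set.seed(41)
    gm2 <- toyGm(matrix(rbinom(8 * 80, 2, 0.5), nrow = 8))
    bl2 <- detectBlocks(gm2)
    expect_true(nrow(bl2) == 0L || all(bl2$n_snps == 1L))
    ## hand-checked 3-SNP case: SNPs 1-2 in perfect LD, SNP 3 independent
    set.seed(43)
    c3 <- rbinom(60, 2, 0.5)
    gm3 <- toyGm(rbind(col, col, c3))
    ci12 <- slickmap:::.dprimeCI(col, col)
    ci13 <- slickmap:::.dprimeCI(col, c3)
    expect_true(ci12["lower"] >= 0.70 && ci12["upper"] >= 0.98)
    expect_false(ci13["lower"] >= 0.70 && ci13["upper"] >= 0.98)
    bl3 <- detectBlocks(gm3)
    expect_equal(bl3$start_index, 1L)
    expect_equal(bl3$end_index, 2L)
})

test_that("pattern association reproduces the closed-form chi-square", {
    ## 5 case samples homozygous for one pattern, 5 controls for another:
    ## case chromosomes (10, 0), control (0, 10) -> chi2 = 20
    al <- rbind(matrix(0L, 10, 2), matrix(1L, 10, 2))
    hs <- toyHaps(al)
    y <- rep(c(0, 1), each = 5)            # samples 6-10 are cases
    blocks <- data.frame(block_id = 1, start_index = 1, end_index = 2)
    pa <- patternAssoc(hs, blocks, y, n_perm = 0)
    expect_equal(nrow(pa), 2L)
    expect_equal(pa$chi2, c(20, 20))
    expect_equal(pa$p_value, rep(7.744216e-06, 2), tolerance = 1e-6)
    ## pattern only in cases: control frequency 0
    case_pat <- pa[pa$freq_slick == 1, ]
    expect_equal(case_pat$freq_nonslick, 0)
    expect_equal(case_pat$haplotype, "GG")   # alt letters
    ## frequencies over observed patterns sum to 1
    expect_equal(sum(pa$freq_total), 1)
    expect_equal(pa$block_distance_bp, rep(10000, 2))
})

test_that("pattern permutation p-values are valid and bounded", {
    set.seed(47)
    al <- matrix(rbinom(20 * 4, 1, 0.5), nrow = 20)
    hs <- toyHaps(al)
    y <- rep(c(0, 1), 5)
    blocks <- data.frame(block_id = 1, start_index = 1, end_index = 4)
    pa <- patternAssoc(hs, blocks, y, n_perm = 500, min_pattern_freq = 0,
                       report_threshold_perm_p = 1, seed = 3)
    expect_true(all(pa$p_perm >= 1 / 501))
    expect_true(all(pa$p_perm <= 1))
    ## chromosomes with missing calls are excluded from the block
    al2 <- al; al2[1, 2] <- NA
    pa2 <- patternAssoc(toyHaps(al2), blocks, y, n_perm = 0,
                        min_pattern_freq = 0)
    expect_equal(sum(pa2$freq_total), 1)
})
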