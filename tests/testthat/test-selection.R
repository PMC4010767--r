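test_that("EHH equals the pair-counting definition", {
    ## 4 carrier chromosomes splitting 2/2 one SNP out: EHH = (1+1)/6
    al <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1),
                c(0, 0, 0), c(0, 0, 0))
    hs <- toyHaps(al)
    e <- ehh(hs, core = 1, allele = 1, direction = "right")
    expect_equal(e$right$ehh[1], 1)                       # at the core
    expect_equal(e$right$ehh[2], 2 / 6)                   # 2/2 split
    ## after the second SNP all four differ except two identical pairs?
    ## groups: (0,0), (0,1), (1,0), (1,1) -> all singletons -> EHH 0
    expect_equal(e$right$ehh[3], 0)
    ## identical carriers: EHH stays 1 all the way
    al2 <- rbind(matrix(rep(c(1, 0, 1, 1, 0), 4), nrow = 4, byrow = TRUE),
                 c(0, 1, 1, 0, 1), c(0, 0, 0, 0, 0))
    e2 <- ehh(toyHaps(al2), core = 1, allele = 1, direction = "both")
    expect_true(all(e2$right$ehh == 1))
    expect_true(all(e2$left$ehh == 1))
    one_carrier <- toyHaps(rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 0)))
    expect_error(ehh(one_carrier, core = 1, allele = 1, direction = "right"),
                 "fewer than 2")
})

test_that("EHH curves are monotone non-increasing without missing calls", {
    set.seed(61)
    for (rep in 1:10) {
        al <- matrix(rbinom(20 * 40, 1, 0.5), nrow = 20)
        al[, 20] <- rep(c(0, 1), 10)
        e <- ehh(toyHaps(al), core = 20, allele = 1, direction = "both")
        expect_true(all(diff(e$right$ehh) <= 1e-12))
        expect_true(all(diff(e$left$ehh) <= 1e-12))
    }
})

test_that("iHH integration matches a hand-computed trapezoid sum", {
    ## 6 chromosomes, derived allele (1) at the core (SNP 3 of 5)
    al <- rbind(c(0, 0, 1, 0, 0),
                c(0, 0, 1, 0, 0),
                c(1, 0, 1, 0, 1),
                c(0, 1, 0, 1, 0),
                c(1, 1, 0, 1, 1),
                c(0, 1, 0, 0, 1))
    variants <- toyVariants(5, spacing = 10000L)
    hs <- toyHaps(al, variants)
    pos <- GenomicRanges::start(variants)
    ## pair-counting oracle for one allele and direction
    oracleIhh <- function(rows, dirs) {
        tot <- 0
        for (dir in dirs) {
            idx <- if (dir > 0) 4:5 else 2:1
            prev <- 1; prev_pos <- pos[3]
            for (j in idx) {
                strs <- apply(al[rows, (min(3, j)):(max(3, j)), drop = FALSE],
                              1, paste, collapse = "")
                cnt <- table(strs)
                eh <- sum(cnt * (cnt - 1)) / (length(rows) * (length(rows) - 1))
                tot <- tot + abs(pos[j] - prev_pos) * (prev + eh) / 2
                prev <- eh; prev_pos <- pos[j]
                if (eh < 0.05) break
            }
        }
        tot
    }
    r <- ihsUnstandardized(hs, core = 3, ancestral = 0)
    expect_equal(r$ihh_der, oracleIhh(which(al[, 3] == 1), c(-1, 1)),
                 tolerance = 1e-9)
    expect_equal(r$ihh_anc, oracleIhh(which(al[, 3] == 0), c(-1, 1)),
                 tolerance = 1e-9)
    expect_equal(r$ihs, log(r$ihh_anc / r$ihh_der), tolerance = 1e-12)
    ## antisymmetry: swapping the ancestral label flips the sign
    r2 <- ihsUnstandardized(hs, core = 3, ancestral = 1)
    expect_equal(r2$ihs, -r$ihs, tolerance = 1e-12)
    ## identical structure for both alleles: iHS = 0
    al3 <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 1, 0))
    r3 <- ihsUnstandardized(toyHaps(al3), core = 2, ancestral = 0)
    expect_equal(r3$ihs, 0, tolerance = 1e-12)
})

test_that("the compiled scan matches the reference implementation", {
    set.seed(67)
    al <- matrix(rbinom(30 * 120, 1, 0.5), nrow = 30)
    ## plant some structure + missing calls
    al[1:10, 40:80] <- al[rep(1, 10), 40:80]
    al[5, 90] <- NA
    hs <- toyHaps(al)
    anc <- ancestralByGroupFreq(hs, 1:10)
    sc_r <- ihsScan(hs, anc, cores = c(10, 60, 100), engine = "r")
    sc_c <- ihsScan(hs, anc, cores = c(10, 60, 100), engine = "cpp")
    expect_equal(sc_c, sc_r, tolerance = 1e-12)
})

test_that("the 5 Mb boundary and EHH cutoff truncate the integral", {
    set.seed(71)
    ## all carriers identical: EHH never decays, so iHH is truncated at
    ## the boundary and equals its length exactly
    al <- rbind(matrix(rep(rbinom(1200, 1, 0.5), 6), nrow = 6, byrow = TRUE),
                matrix(rbinom(2 * 1200, 1, 0.5), nrow = 2))
    al[, 600] <- c(rep(1L, 6), 0L, 0L)
    hs <- toyHaps(al, toyVariants(1200, spacing = 10000L))
    r <- ihsUnstandardized(hs, core = 600, ancestral = 0,
                           max_extend_bp = 2e6)
    expect_equal(r$ihh_der, 4e6, tolerance = 1)   # 2 Mb each side, EHH = 1
    expect_identical(unname(r$truncation_der), c("boundary", "boundary"))
})

test_that("ancestral alleles follow the group-frequency rule", {
    al <- rbind(c(1, 1, 0, 1), c(1, 0, 0, 1), c(1, 0, 1, 0),
                c(0, 0, 1, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
    hs <- toyHaps(al)
    ## slick group = rows 1:3; allele with higher frequency there is
    ## ancestral; ties break toward the panel major allele
    anc <- ancestralByGroupFreq(hs, 1:3)
    expect_equal(anc[1], 1L)      # freq 1 in group
    expect_equal(anc[2], 0L)      # freq 2/3 for 0
    ## SNP 4: group is 2/3 for allele 1 -> ancestral 1
    expect_equal(anc[4], 1L)
    ## tie in group (SNP 3 would be 1/3)... construct explicit tie:
    al2 <- rbind(c(1), c(0), c(1), c(0), c(0), c(0))
    anc2 <- ancestralByGroupFreq(toyHaps(al2), 1:4)   # group tied 2/2
    expect_equal(anc2[1], 0L)     # panel major allele is 0 (4/6)
    ## counting oracle on random data
    set.seed(73)
    al3 <- matrix(rbinom(40 * 30, 1, 0.5), nrow = 40)
    grp <- 1:15
    anc3 <- ancestralByGroupFreq(toyHaps(al3), grp)
    f <- colMeans(al3[grp, ])
    expected <- ifelse(f > 0.5, 1L,
                ifelse(f < 0.5, 0L,
                       as.integer(colMeans(al3) > 0.5)))
    expect_equal(anc3, expected)
    expect_error(ancestralByGroupFreq(toyHaps(al3), integer(0)), "empty")
})

test_that("frequency-bin standardization has unit moments by construction", {
    set.seed(79)
    n <- 2000
    scan <- data.frame(ihs = rnorm(n, 1, 2), freq_der = runif(n))
    std <- standardizeIHS(scan, n_bins = 20)
    for (b in unique(std$bin)) {
        z <- std$ihs_std[std$bin == b]
        expect_lt(abs(mean(z)), 1e-9)
        expect_lt(abs(stats::sd(z) - 1), 1e-9)
    }
    expect_equal(std$abs_ihs_std, abs(std$ihs_std))
    ## single-bin mode equals global z-scoring
    std1 <- standardizeIHS(scan, n_bins = 1)
    expect_equal(std1$ihs_std,
                 (scan$ihs - mean(scan$ihs)) / stats::sd(scan$ihs),
                 tolerance = 1e-12)
    ## sparse bins are merged: no bin below 5 members
    scan2 <- data.frame(ihs = rnorm(40), freq_der = c(runif(38), 0.999, 1))
    std2 <- standardizeIHS(scan2, n_bins = 20)
    expect_true(all(table(std2$bin) >= 2))
    expect_error(standardizeIHS(data.frame(ihs = NA_real_,
                                           freq_der = 0.5)), "no defined")
})

test_that("window averaging matches the loop oracle and edge rules", {
    x <- rep(5, 100)
    expect_equal(windowAverage(x, 30), x)
    ## spike of 30 in zeros: plateau of ~1 across the window
    sp <- rep(0, 200); sp[100] <- 30
    wa <- windowAverage(sp, 30)
    expect_equal(max(wa), 1)
    expect_equal(sum(wa > 0.99), 30)
    ## NA-gapped track against a direct loop
    set.seed(83)
    y <- rnorm(150); y[sample(150, 25)] <- NA
    wa2 <- windowAverage(y, 7)
    oracle <- vapply(1:150, function(i) {
        lo <- max(1, i - 3); hi <- min(150, i + 3)
        v <- y[lo:hi]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    expect_equal(wa2, oracle)
    expect_error(windowAverage(1:5, 10), "window")
})

test_that("planted sweeps rank near the top of the standardized scan", {
    ## scan the affected (consanguine) chromosome panel, as the pipeline
    ## does; the causal core should sit in the upper tail of |iHS|
    hits <- 0L
    for (sd in 1:3) {
        co <- simulateCohort(cohortConfig(seed = 500 + sd))
        hs <- co$haplotypes
        s <- sampleInfo(co$genotypes)
        case_rows <- which(hapSampleOf(hs) %in%
                           s$sample_id[s$phenotype == "slick"])
        anc <- ancestralByGroupFreq(hs, case_rows)
        hss <- HaplotypeSet(hapAlleles(hs)[case_rows, ],
                            hapSampleOf(hs)[case_rows], variantInfo(hs))
        ci <- co$truth$causal_index
        sc <- ihsScan(hss, anc,
                      cores = sort(unique(c(seq(1, 4000, by = 4), ci))))
        sc <- standardizeIHS(sc)
        at <- sc$abs_ihs_std[sc$index == ci]
        hits <- hits + (at >= stats::quantile(sc$abs_ihs_std, 0.90,
                                              na.rm = TRUE))
    }
    expect_gte(hits, 2L)
})
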