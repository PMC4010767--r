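test_that("simulation is fully seed-deterministic", {
    co1 <- simulateCohort(smallConfig(seed = 5))
    co2 <- simulateCohort(smallConfig(seed = 5))
    expect_identical(genotypeCalls(co1$genotypes), genotypeCalls(co2$genotypes))
    expect_identical(hapAlleles(co1$haplotypes), hapAlleles(co2$haplotypes))
    co3 <- simulateCohort(smallConfig(seed = 6))
    expect_false(identical(genotypeCalls(co1$genotypes),
                           genotypeCalls(co3$genotypes)))
    ## dimensions depend on config, not seed
    expect_identical(dim(genotypeCalls(co1$genotypes)),
                     dim(genotypeCalls(co3$genotypes)))
    f1 <- simulateFounders(smallConfig(seed = 9))
    f2 <- simulateFounders(smallConfig(seed = 9))
    expect_identical(f1, f2)
})

test_that("Balding-Nichols divergence has the right mean and FST", {
    ## small F: per-breed frequencies are centred on the ancestral ones
    diffs <- replicate(50, {
        f <- simulateFounders(smallConfig(seed = sample.int(1e6, 1)))
        ## compare one breed's drawn frequencies to the ancestral vector
        mean(f$pools[["SE"]]$freq - f$p_anc)
    })
    ## with F = 0.15 the deviations are mean-zero
    expect_lt(abs(mean(diffs)), 0.02)

    ## Hudson-style FST between two breeds at F = 0.2 from the model
    ## frequencies: mean (p1-p2)^2 / mean (p1(1-p2) + p2(1-p1))
    br <- function(name) list(name = name, n_founder_haplotypes = 10L,
                              n_samples = 2L, divergence_F = 0.2,
                              carrier = FALSE)
    cfg <- cohortConfig(seed = 31, n_snps = 4000L, causal_index = 1L,
                        breeds = list(br("P1"), br("P2")),
                        cross_designs = list())
    f <- simulateFounders(cfg)
    p1 <- f$pools[["P1"]]$freq; p2 <- f$pools[["P2"]]$freq
    fst <- mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
    expect_lt(abs(fst - 0.2), 0.05)

    expect_error(cohortConfig(breeds = list(list(
        name = "B", n_founder_haplotypes = 10L, n_samples = 2L,
        divergence_F = 1.2, carrier = FALSE))), "divergence_F")
})

test_that("the planted causal haplotype is shared and absent in controls", {
    cfg <- smallConfig(seed = 2)
    f <- plantCausalHaplotype(simulateFounders(cfg), cfg)
    ci <- cfg$causal_index
    ## carrier pools: the planted rows are identical over the whole
    ## chromosome (IBS segment = full span)
    k <- max(1L, round(30 * cfg$plant_freq))
    planted <- f$pools[["SE"]]$haps[seq_len(k), , drop = FALSE]
    expect_true(all(apply(planted, 2, function(x) length(unique(x)) == 1)))
    expect_identical(unname(planted[1, ]), unname(f$founder_haps[[1]]))
    ## single-origin mode: both carrier breeds carry the same haplotype
    expect_identical(f$pools[["SE"]]$haps[1, ], f$pools[["CR"]]$haps[1, ])
    ## control pools never carry the derived allele
    expect_equal(sum(f$pools[["AN"]]$haps[, ci]), 0)
    expect_equal(sum(f$pools[["HO"]]$haps[, ci]), 0)
    ## independent origins differ away from the causal site
    cfg2 <- smallConfig(seed = 2, causal_origin = "independent")
    f2 <- plantCausalHaplotype(simulateFounders(cfg2), cfg2)
    expect_length(f2$founder_haps, 2L)
    expect_true(f2$pools[["SE"]]$haps[1, ci] == 1 &&
                f2$pools[["CR"]]$haps[1, ci] == 1)
})

test_that("shared carrier segments shrink with generations", {
    cfg <- smallConfig(seed = 4)
    f <- plantCausalHaplotype(simulateFounders(cfg), cfg)
    ci <- cfg$causal_index
    pos <- seq_len(cfg$n_snps) * cfg$chrom_length_bp / cfg$n_snps
    founder <- f$founder_haps[[1]]
    seg_len <- function(gens) {
        ## high map density so decay is visible on the short test
        ## chromosome; segment lengths pooled over replicates
        lens <- unlist(lapply(1:4, function(rep) {
            set.seed(990 + rep)
            pool <- breedForward(f$pools[["SE"]]$haps, gens, 60, pos,
                                 cfg$chrom_length_bp, rate_cM_Mb = 25,
                                 keep_freq_at = list(index = ci, freq = 0.5))
            carr <- pool[pool[, ci] == 1L, , drop = FALSE]
            ## shared founder segment around the causal site per chromosome
            apply(carr, 1, function(h) {
                same <- h == founder
                l <- ci; r <- ci
                while (l > 1 && same[l - 1]) l <- l - 1
                while (r < length(same) && same[r + 1]) r <- r + 1
                r - l + 1
            })
        }))
        stats::median(lens)
    }
    l2 <- seg_len(2); l6 <- seg_len(6); l18 <- seg_len(18)
    expect_gt(l2, l6)
    expect_gt(l6, l18)
})

test_that("meiosis follows the Haldane model and Mendelian inheritance", {
    pos <- seq_len(4000) * 1e4
    h1 <- rep(0L, 4000); h2 <- rep(1L, 4000)
    ## zero recombination rate: gametes are whole-chromosome copies
    set.seed(1)
    g0 <- meiosis(h1, h2, pos, 4e7, rate_cM_Mb = 0)
    expect_true(all(g0$alleles == 0L) || all(g0$alleles == 1L))
    ## 40 Mb at 1 cM/Mb: mean crossovers 0.4 (Poisson), within 3 SE
    set.seed(2)
    nx <- replicate(2000, sum(diff(meiosis(h1, h2, pos, 4e7, 1)$from1) != 0))
    expect_lt(abs(mean(nx) - 0.4), 3 * sqrt(0.4 / 2000))
    ## gamete alleles always come from one of the two parents
    set.seed(3)
    p1 <- rbinom(4000, 1L, 0.5); p2 <- rbinom(4000, 1L, 0.5)
    g <- meiosis(p1, p2, pos, 4e7, 1)
    expect_true(all(g$alleles == p1 | g$alleles == p2))
    expect_identical(g$alleles, ifelse(g$from1, p1, p2))
})

test_that("backcross lineages dilute donor ancestry as 2^-g", {
    cfg <- smallConfig(seed = 12)
    f <- plantCausalHaplotype(simulateFounders(cfg), cfg)
    pools <- lapply(f$pools, `[[`, "haps")
    ## F1: donor fraction exactly 0.5
    set.seed(7)
    cr1 <- makeCross(pools, list(dam_breed = "SE", sire_breed = "HO",
                                 n_backcross_generations = 1L,
                                 n_samples = 50L), cfg)
    expect_equal(cr1$expected_frac, 0.5)
    expect_true(all(cr1$donor_frac == 0.5))
    ## g = 4 without carrier selection: mean donor fraction near 1/16
    set.seed(8)
    cr4 <- makeCross(pools, list(dam_breed = "SE", sire_breed = "HO",
                                 n_backcross_generations = 4L,
                                 n_samples = 200L, select_carrier = FALSE),
                     cfg)
    expect_equal(cr4$expected_frac, 0.0625)
    expect_lt(abs(mean(cr4$donor_frac) - 0.0625), 0.05)
    ## with carrier selection every sample carries the causal allele
    set.seed(9)
    cr <- makeCross(pools, list(dam_breed = "SE", sire_breed = "HO",
                                n_backcross_generations = 4L,
                                n_samples = 20L), cfg)
    ci <- cfg$causal_index
    dos <- cr$alleles[seq(1, 39, 2), ci] + cr$alleles[seq(2, 40, 2), ci]
    expect_true(all(dos >= 1))
    expect_error(makeCross(pools, list(dam_breed = "XX", sire_breed = "HO",
                                       n_backcross_generations = 1L,
                                       n_samples = 1L), cfg),
                 "unknown breed")
})

test_that("phenotypes follow dominant inheritance at given penetrance", {
    set.seed(21)
    expect_identical(assignPhenotypes(c(0L, 1L, 2L), 1.0),
                     c("nonslick", "slick", "slick"))
    ## full penetrance: phenotype equals the carrier indicator exactly
    dos <- sample(0:2, 500, replace = TRUE)
    expect_identical(assignPhenotypes(dos, 1.0) == "slick", dos >= 1L)
    ## penetrance 0.8 among 1000 carriers: binomial check
    ph <- assignPhenotypes(rep(1L, 1000), 0.8)
    expect_lt(abs(mean(ph == "slick") - 0.8), 3 * sqrt(0.8 * 0.2 / 1000))
    ## dominance: het and hom carriers have the same affection rate
    ph1 <- assignPhenotypes(rep(1L, 4000), 0.7)
    ph2 <- assignPhenotypes(rep(2L, 4000), 0.7)
    expect_lt(abs(mean(ph1 == "slick") - mean(ph2 == "slick")),
              3 * sqrt(2 * 0.7 * 0.3 / 4000))
    ## non-carriers are never affected
    expect_true(all(assignPhenotypes(rep(0L, 100), 0.5) == "nonslick"))
})

test_that("cohorts round-trip through the on-disk bundle and YAML config", {
    dir <- withr::local_tempdir()
    writeLines(c("seed: 5", "n_snps: 200", "chrom_length_bp: 2.0e6",
                 "causal_index: 100", "generations: 2"),
               file.path(dir, "cfg.yaml"))
    cfg <- cohortConfigFromYaml(file.path(dir, "cfg.yaml"))
    expect_equal(cfg$n_snps, 200L)
    expect_equal(cfg$seed, 5L)
    expect_equal(cfg$penetrance, 1.0)       # default preserved
    co <- simulateCohort(smallConfig(seed = 31))
    writeCohort(co, dir)
    hs2 <- readHaplotypes(file.path(dir, "cohort.vcf"))
    expect_identical(unname(hapAlleles(hs2)),
                     unname(hapAlleles(co$haplotypes)))
    gm2 <- readGenotypes(file.path(dir, "cohort.ped"), "ped_map")
    g_in <- genotypeCalls(co$genotypes)
    g_out <- genotypeCalls(gm2)[rownames(g_in), colnames(g_in)]
    ## PED letters carry no ref/alt orientation, so dosages may flip
    flip_ok <- vapply(seq_len(nrow(g_in)), function(j)
        all(g_out[j, ] == g_in[j, ]) || all(g_out[j, ] == 2L - g_in[j, ]),
        logical(1))
    expect_true(all(flip_ok))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"))
    expect_equal(truth$causal_index, co$truth$causal_index)
})

test_that("carrier heterozygosity at defaults falls in the expected range", {
    ## fraction of heterozygous carriers among affected individuals in the
    ## carrier breeds, averaged over seeds (soft range)
    hets <- vapply(1:20, function(sd) {
        co <- simulateCohort(smallConfig(seed = 100 + sd))
        s <- sampleInfo(co$genotypes)
        dos <- co$truth$carrier_dosage
        carrier_breed <- s$breed %in% c("SE", "CR")
        sum(dos == 1 & carrier_breed) / sum(dos >= 1 & carrier_breed)
    }, numeric(1))
    expect_gt(mean(hets), 0.5)
    expect_lt(mean(hets), 0.8)
})
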