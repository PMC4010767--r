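## Small in-code fixtures shared across the suite.

toyVariants <- function(m, chrom = "20", spacing = 10000L, ref = "A",
                        alt = "G") {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(seq_len(m) * spacing, width = 1L),
        ref = rep_len(ref, m), alt = rep_len(alt, m))
    names(gr) <- sprintf("snp%03d", seq_len(m))
    gr
}

toyGm <- function(calls, phenotype = NULL, breed = "XX") {
    calls <- as.matrix(calls)
    m <- nrow(calls); n <- ncol(calls)
    ids <- sprintf("S%02d", seq_len(n))
    if (is.null(phenotype)) phenotype <- rep("unknown", n)
    samples <- data.frame(sample_id = ids, breed = rep_len(breed, n),
                          phenotype = phenotype,
                          role = ifelse(phenotype == "slick", "case",
                                 ifelse(phenotype == "nonslick", "control",
                                        "excluded")),
                          stringsAsFactors = FALSE)
    colnames(calls) <- ids
    GenotypeData(calls, toyVariants(m), samples)
}

toyHaps <- function(alleles, variants = NULL) {
    alleles <- as.matrix(alleles)
    n2 <- nrow(alleles)
    stopifnot(n2 %% 2 == 0)
    ids <- rep(sprintf("S%02d", seq_len(n2 / 2)), each = 2)
    if (is.null(variants)) variants <- toyVariants(ncol(alleles))
    HaplotypeSet(alleles, ids, variants)
}

## genotypes with exact control over homozygosity layout
randomHomGm <- function(n_samples, m, p_hom = 0.9, seed = 1) {
    set.seed(seed)
    states <- sample(c(0L, 1L, 2L), n_samples * m, replace = TRUE,
                     prob = c(p_hom / 2, 1 - p_hom, p_hom / 2))
    toyGm(matrix(states, nrow = m, ncol = n_samples))
}

naiveRoh <- function(gi, L) {
    ## simple reference scan: every maximal all-homozygous stretch
    hom <- !is.na(gi) & gi != 1L
    runs <- list()
    i <- 1L
    while (i <= length(gi)) {
        if (hom[i]) {
            j <- i
            while (j < length(gi) && hom[j + 1L]) j <- j + 1L
            if (j - i + 1L >= L) runs[[length(runs) + 1L]] <- c(i, j)
            i <- j + 1L
        } else i <- i + 1L
    }
    runs
}

## a small cohort config for cheap end-to-end tests
smallConfig <- function(seed = 1, ...) {
    br <- function(name, n, carrier)
        list(name = name, n_founder_haplotypes = 30L, n_samples = n,
             divergence_F = 0.15, carrier = carrier)
    cohortConfig(seed = seed, n_snps = 600L, chrom_length_bp = 6e6,
                 causal_index = 300L, generations = 4L,
                 breeds = list(br("SE", 12L, TRUE), br("CR", 8L, TRUE),
                               br("AN", 8L, FALSE), br("HO", 8L, FALSE)),
                 cross_designs = list(list(dam_breed = "SE",
                                           sire_breed = "HO",
                                           n_backcross_generations = 2L,
                                           n_samples = 4L)),
                 ...)
}
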