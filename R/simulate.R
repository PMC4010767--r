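## Forward-in-time multi-breed cohort simulator with a planted dominant
## causal haplotype. Breeds diverge under a Balding-Nichols model; LD is
## induced by mosaic copying from a small founder pool; recombination is
## Haldane (Poisson crossovers, no interference) on a uniform cM/Mb map.

#' Simulation configuration for a multi-breed cohort
#'
#' Defaults emulate a tropical-cattle study design: three carrier breeds
#' segregating one shared dominant causal haplotype, four non-carrier
#' ancestral control breeds, and one backcross lineage bred back to a
#' recipient breed with selection on carrier status.
#'
#' @param seed integer; fully determines the cohort.
#' @param n_snps number of SNPs on the single simulated chromosome.
#' @param chrom_length_bp chromosome length (uniform SNP spacing).
#' @param chrom chromosome name.
#' @param recomb_rate recombination rate, cM per Mb.
#' @param breeds list of breed descriptors:
#'   \code{list(name, n_founder_haplotypes, n_samples, divergence_F, carrier)}.
#' @param causal_index variant index of the planted causal allele.
#' @param causal_freq target frequency of the causal allele in carrier
#'   breeds at the end of forward breeding (reached by a linear selection
#'   ramp, emulating a selective sweep during breed formation).
#' @param plant_freq initial frequency of the planted founder haplotype in
#'   each carrier breed's founder pool; kept small so that only the
#'   region hitch-hiking with the causal allele rises in frequency.
#' @param causal_origin "single" (one founder haplotype shared by all
#'   carrier breeds) or "independent" (one origin per carrier breed).
#' @param generations forward generations bred within each breed.
#' @param cross_designs list of
#'   \code{list(dam_breed, sire_breed, n_backcross_generations, n_samples)};
#'   \code{n_backcross_generations = 1} is an F1.
#' @param penetrance probability a carrier is phenotyped affected ("slick").
#' @param founder_pool size of the small per-breed pool copied from when
#'   laying down founder haplotypes (controls baseline LD).
#' @param switch_rate per-SNP probability of switching copy template in a
#'   founder haplotype mosaic (smaller = longer LD blocks).
#' @param missing_rate post-hoc missing-call injection rate.
#' @return A validated list of class \code{cohort_config}.
#' @export
cohortConfig <- function(seed = 1L,
                         n_snps = 4000L,
                         chrom_length_bp = 40e6,
                         chrom = "20",
                         recomb_rate = 1.0,
                         breeds = NULL,
                         causal_index = 2000L,
                         causal_freq = 0.55,
                         plant_freq = 0.05,
                         causal_origin = c("single", "independent"),
                         generations = 8L,
                         cross_designs = NULL,
                         penetrance = 1.0,
                         founder_pool = 8L,
                         switch_rate = 0.02,
                         missing_rate = 0) {
    causal_origin <- match.arg(causal_origin)
    if (is.null(breeds)) {
        br <- function(name, n, carrier)
            list(name = name, n_founder_haplotypes = 60L, n_samples = n,
                 divergence_F = 0.15, carrier = carrier)
        breeds <- list(br("SE", 30L, TRUE), br("CR", 15L, TRUE),
                       br("RS", 10L, TRUE), br("AN", 12L, FALSE),
                       br("RP", 12L, FALSE), br("ND", 12L, FALSE),
                       br("HO", 12L, FALSE))
    }
    if (is.null(cross_designs))
        cross_designs <- list(list(dam_breed = "SE", sire_breed = "HO",
                                   n_backcross_generations = 4L,
                                   n_samples = 12L))
    cfg <- list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                chrom_length_bp = chrom_length_bp, chrom = chrom,
                recomb_rate = recomb_rate, breeds = breeds,
                causal_index = as.integer(causal_index),
                causal_freq = causal_freq, plant_freq = plant_freq,
                causal_origin = causal_origin,
                generations = as.integer(generations),
                cross_designs = cross_designs, penetrance = penetrance,
                founder_pool = as.integer(founder_pool),
                switch_rate = switch_rate, missing_rate = missing_rate)
    for (b in cfg$breeds)
        if (b$divergence_F <= 0 || b$divergence_F >= 1)
            stop("divergence_F must lie strictly in (0, 1)")
    if (cfg$causal_index < 1L || cfg$causal_index > cfg$n_snps)
        stop("causal_index out of range")
    if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
    class(cfg) <- "cohort_config"
    cfg
}

.simPositions <- function(config) {
    m <- config$n_snps
    as.integer(round(seq_len(m) * config$chrom_length_bp / m))
}

#' Draw per-breed founder haplotype pools
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each breed's
#' frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) (Balding-Nichols). Founder
#' haplotypes are mosaics copied from a small site-wise pool so that
#' neighbouring SNPs are in LD. The causal site is forced to the ancestral
#' allele (0) in every pool; the derived allele enters only via
#' [plantCausalHaplotype()].
#'
#' @param config a [cohortConfig()]; \code{config$seed} is set before
#'   drawing, so equal configs give byte-identical pools.
#' @return list with \code{p_anc}, per-breed \code{pools} (each
#'   \code{list(haps, freq, carrier)}), and \code{pos_bp}.
#' @export
simulateFounders <- function(config) {
    set.seed(config$seed)
    m <- config$n_snps
    p_anc <- stats::runif(m, 0.05, 0.95)
    pools <- list()
    for (b in config$breeds) {
        F <- b$divergence_F
        pb <- stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
        pb <- pmin(pmax(pb, 1e-6), 1 - 1e-6)
        small <- matrix(stats::rbinom(config$founder_pool * m, 1L, rep(pb, each = config$founder_pool)),
                        nrow = config$founder_pool, ncol = m)
        H <- b$n_founder_haplotypes
        haps <- matrix(0L, nrow = H, ncol = m)
        for (h in seq_len(H)) {
            if (config$switch_rate >= 1) {
                seg <- seq_len(m)
            } else {
                sw <- stats::runif(m) < config$switch_rate
                sw[1L] <- TRUE
                seg <- cumsum(sw)
            }
            donors <- sample.int(config$founder_pool, max(seg), replace = TRUE)
            haps[h, ] <- small[cbind(donors[seg], seq_len(m))]
        }
        haps[, config$causal_index] <- 0L
        pools[[b$name]] <- list(haps = haps, freq = pb, carrier = b$carrier)
    }
    list(p_anc = p_anc, pools = pools, pos_bp = .simPositions(config))
}

#' Plant the dominant causal haplotype into carrier founder pools
#'
#' One designated founder haplotype receives the derived allele at the
#' causal site and is copied into every carrier breed's pool at frequency
#' \code{config$causal_freq} ("single" origin), so all carrier chromosomes
#' descend from one founder segment. With \code{causal_origin =
#' "independent"} each carrier breed gets its own origin haplotype.
#'
#' @param founders result of [simulateFounders()].
#' @param config the same [cohortConfig()].
#' @return \code{founders} with carrier pools modified and a
#'   \code{founder_haps} element (one allele vector per origin).
#' @export
plantCausalHaplotype <- function(founders, config) {
    ci <- config$causal_index
    carrier_names <- names(Filter(function(p) p$carrier, founders$pools))
    if (length(carrier_names) == 0L) stop("no carrier breeds in config")
    for (nm in names(founders$pools)) {
        if (!founders$pools[[nm]]$carrier &&
            any(founders$pools[[nm]]$haps[, ci] == 1L))
            stop("causal allele already segregating in control pool ", nm)
    }
    founder_haps <- list()
    shared <- NULL
    for (nm in carrier_names) {
        pool <- founders$pools[[nm]]
        if (config$causal_origin == "single") {
            if (is.null(shared)) {
                shared <- pool$haps[1L, ]
                shared[ci] <- 1L
            }
            fh <- shared
        } else {
            fh <- pool$haps[1L, ]
            fh[ci] <- 1L
        }
        k <- max(1L, round(nrow(pool$haps) *
                           (if (is.null(config$plant_freq)) config$causal_freq
                            else config$plant_freq)))
        pool$haps[seq_len(k), ] <- matrix(fh, nrow = k, ncol = length(fh),
                                          byrow = TRUE)
        founders$pools[[nm]] <- pool
        founder_haps[[nm]] <- fh
    }
    if (config$causal_origin == "single")
        founder_haps <- founder_haps[1L]
    founders$founder_haps <- founder_haps
    founders
}

## selector: TRUE where the gamete copies parent haplotype 1
.meiosisSelector <- function(pos_bp, length_bp, rate_cM_Mb) {
    morgans <- length_bp / 1e6 * rate_cM_Mb / 100
    n_x <- stats::rpois(1L, morgans)
    breaks <- sort(stats::runif(n_x, 0, length_bp))
    phase <- sample.int(2L, 1L)
    (phase + findInterval(pos_bp, breaks)) %% 2L == 0L
}

#' One meiosis under the Haldane model
#'
#' Crossover count is Poisson with mean equal to the map length in
#' Morgans (physical length x cM/Mb / 100); breakpoints are uniform on the
#' chromosome (uniform genetic map). No interference.
#'
#' @param h1,h2 parental haplotype allele vectors.
#' @param pos_bp SNP positions.
#' @param length_bp chromosome length.
#' @param rate_cM_Mb recombination rate.
#' @return list with \code{alleles} (the gamete) and \code{from1}
#'   (logical: which sites came from \code{h1}).
#' @export
meiosis <- function(h1, h2, pos_bp, length_bp, rate_cM_Mb = 1.0) {
    sel <- .meiosisSelector(pos_bp, length_bp, rate_cM_Mb)
    list(alleles = ifelse(sel, h1, h2), from1 = sel)
}

#' Breed a haplotype pool forward in time
#'
#' Each generation replaces the pool with gametes of randomly paired pool
#' haplotypes. When \code{keep_freq_at} is supplied (carrier selection),
#' offspring are drawn until the allele at the given index is restored to
#' the target pool frequency, mimicking sustained selection on a trait.
#'
#' @param haps founder haplotype matrix (rows = haplotypes).
#' @param generations number of generations.
#' @param n_out number of haplotypes to return from the final pool.
#' @param pos_bp,length_bp,rate_cM_Mb map parameters (see [meiosis()]).
#' @param keep_freq_at optional \code{list(index =, freq =)}; \code{freq}
#'   may be a vector with one target per generation (a selection ramp).
#' @return haplotype matrix with \code{n_out} rows.
#' @export
breedForward <- function(haps, generations, n_out, pos_bp, length_bp,
                         rate_cM_Mb = 1.0, keep_freq_at = NULL) {
    if (nrow(haps) < 2L) stop("pool must contain at least two haplotypes")
    H <- nrow(haps)
    pool <- haps
    for (g in seq_len(generations)) {
        nxt <- matrix(0L, nrow = H, ncol = ncol(pool))
        if (is.null(keep_freq_at)) {
            for (i in seq_len(H)) {
                pr <- sample.int(nrow(pool), 2L)
                nxt[i, ] <- meiosis(pool[pr[1L], ], pool[pr[2L], ],
                                    pos_bp, length_bp, rate_cM_Mb)$alleles
            }
        } else {
            fr <- keep_freq_at$freq
            k_target <- round(H * fr[min(g, length(fr))])
            n_car <- 0L; n_non <- 0L; i <- 0L; tries <- 0L
            while (i < H && tries < 50L * H) {
                tries <- tries + 1L
                pr <- sample.int(nrow(pool), 2L)
                gam <- meiosis(pool[pr[1L], ], pool[pr[2L], ],
                               pos_bp, length_bp, rate_cM_Mb)$alleles
                carrier <- gam[keep_freq_at$index] == 1L
                if (carrier && n_car < k_target) {
                    n_car <- n_car + 1L
                } else if (!carrier && n_non < H - k_target) {
                    n_non <- n_non + 1L
                } else next
                i <- i + 1L
                nxt[i, ] <- gam
            }
            if (i < H)  # allele lost or fixed; fall back to what we have
                nxt <- nxt[seq_len(max(i, 1L)), , drop = FALSE]
        }
        pool <- nxt
    }
    pool[sample.int(nrow(pool), n_out, replace = n_out > nrow(pool)), ,
         drop = FALSE]
}

#' Simulate a backcross lineage
#'
#' Starting from a carrier chromosome of the donor breed paired with a
#' recipient chromosome (the F1, \code{n_backcross_generations = 1}), each
#' further generation crosses a carrier offspring back to the recipient
#' breed, selecting a causal-allele-carrying gamete every time. Expected
#' donor-genome fraction after g generations is 2^-g.
#'
#' @param pools named list of evolved breed haplotype pools.
#' @param design one cross design (see [cohortConfig()]).
#' @param config the [cohortConfig()].
#' @return list with \code{alleles} (2 rows per sample), \code{donor_frac}
#'   (realized per sample), \code{expected_frac}, \code{sample_ids}.
#' @export
makeCross <- function(pools, design, config) {
    if (!design$dam_breed %in% names(pools))
        stop("unknown breed in cross design: ", design$dam_breed)
    if (!design$sire_breed %in% names(pools))
        stop("unknown breed in cross design: ", design$sire_breed)
    donor <- pools[[design$dam_breed]]
    recip <- pools[[design$sire_breed]]
    ci <- config$causal_index
    pos <- .simPositions(config)
    carriers <- which(donor[, ci] == 1L)
    if (length(carriers) == 0L &&
        !identical(design$select_carrier, FALSE))
        stop("donor breed carries no causal allele; cannot select carriers")
    g <- design$n_backcross_generations
    n <- design$n_samples
    select_carrier <- if (is.null(design$select_carrier)) TRUE
                      else isTRUE(design$select_carrier)
    alleles <- matrix(0L, nrow = 2L * n, ncol = config$n_snps)
    origin <- matrix(0L, nrow = 2L * n, ncol = config$n_snps)
    donor_frac <- numeric(n)
    for (s in seq_len(n)) {
        start_row <- if (select_carrier)
            carriers[sample.int(length(carriers), 1L)]
        else sample.int(nrow(donor), 1L)
        hap_c <- donor[start_row, ]
        org_c <- rep(1L, config$n_snps)               # 1 = donor ancestry
        for (gen in seq_len(g)) {
            if (gen > 1L) {
                ## gamete from the current individual; with carrier
                ## selection on, retain only causal-allele-carrying
                ## gametes (half of them: the individual is heterozygous)
                repeat {
                    sel <- .meiosisSelector(pos, config$chrom_length_bp,
                                            config$recomb_rate)
                    gam <- ifelse(sel, hap_c, hap_r)
                    if (!select_carrier || gam[ci] == 1L) break
                }
                hap_c <- gam
                org_c <- ifelse(sel, org_c, org_r)
            }
            hap_r <- recip[sample.int(nrow(recip), 1L), ]
            org_r <- rep(0L, config$n_snps)
        }
        i <- 2L * s - 1L
        alleles[i, ] <- hap_c;  origin[i, ] <- org_c
        alleles[i + 1L, ] <- hap_r; origin[i + 1L, ] <- org_r
        donor_frac[s] <- mean(origin[c(i, i + 1L), ])
    }
    list(alleles = alleles, donor_frac = donor_frac,
         expected_frac = 2^-g,
         sample_ids = sprintf("%s%s_%02d", design$dam_breed,
                              design$sire_breed, seq_len(n)))
}

#' Assign phenotypes from carrier status under dominance
#'
#' P(affected | >= 1 causal allele) = penetrance; non-carriers are never
#' affected. Homozygous and heterozygous carriers are treated identically.
#'
#' @param carrier_dosage integer vector of causal-allele counts (0/1/2).
#' @param penetrance penetrance of the dominant allele.
#' @return character vector "slick"/"nonslick".
#' @export
assignPhenotypes <- function(carrier_dosage, penetrance = 1.0) {
    carrier <- carrier_dosage >= 1L
    affected <- carrier & (stats::runif(length(carrier_dosage)) < penetrance)
    ifelse(affected, "slick", "nonslick")
}

#' Read a simulation configuration from a flat YAML file
#'
#' Scalar keys map directly onto [cohortConfig()] arguments; breeds and
#' cross designs are lists of named entries. Keys not present fall back
#' to the package defaults.
#'
#' @param path YAML file path.
#' @return A \code{cohort_config}.
#' @export
cohortConfigFromYaml <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y[intersect(names(y), names(formals(cohortConfig)))]
    do.call(cohortConfig, args)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard file bundle: phased VCF, PLINK PED/MAP, a sample
#' TSV, and a truth JSON (causal index/position, carrier dosages, seed).
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeVcf(cohort$haplotypes, file.path(dir, "cohort.vcf"))
    writePedMap(cohort$genotypes, file.path(dir, "cohort"))
    utils::write.table(sampleInfo(cohort$genotypes),
                       file.path(dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tr <- cohort$truth
    jsonlite::write_json(
        list(causal_index = tr$causal_index, causal_pos = tr$causal_pos,
             carrier_dosage = as.list(tr$carrier_dosage),
             seed = tr$config$seed,
             config_hash = sum(utils::head(utf8ToInt(paste(
                 deparse(tr$config[order(names(tr$config))]),
                 collapse = "")), 1e4))),
        file.path(dir, "truth.json"), auto_unbox = TRUE)
    invisible(dir)
}

#' Simulate a complete multi-breed cohort
#'
#' Runs founders -> planting -> forward breeding -> crosses -> phenotyping
#' and returns genotypes, true phase, the sample table and the truth
#' record. Fully deterministic given \code{config$seed}.
#'
#' @param config a [cohortConfig()].
#' @return list with \code{genotypes} ([GenotypeData]), \code{haplotypes}
#'   ([HaplotypeSet]), \code{truth} (causal index/position, founder
#'   haplotype(s), per-sample carrier dosage and donor fractions).
#' @export
simulateCohort <- function(config) {
    founders <- simulateFounders(config)       # sets the seed
    if (any(vapply(config$breeds, `[[`, logical(1), "carrier")))
        founders <- plantCausalHaplotype(founders, config)
    pos <- founders$pos_bp
    ci <- config$causal_index
    hap_rows <- list(); hap_ids <- character(); breed_of <- character()
    pools_out <- list()
    for (b in config$breeds) {
        ## carrier breeds sweep the causal allele up along a linear ramp
        ## from the planting frequency to the final target
        keep <- if (b$carrier)
            list(index = ci,
                 freq = seq(config$plant_freq, config$causal_freq,
                            length.out = config$generations + 1L)[-1L])
        else NULL
        pool <- breedForward(founders$pools[[b$name]]$haps,
                             config$generations,
                             n_out = max(2L * b$n_samples,
                                         b$n_founder_haplotypes),
                             pos, config$chrom_length_bp,
                             config$recomb_rate, keep_freq_at = keep)
        pools_out[[b$name]] <- pool
        take <- sample.int(nrow(pool), 2L * b$n_samples,
                           replace = 2L * b$n_samples > nrow(pool))
        hap_rows[[b$name]] <- pool[take, , drop = FALSE]
        ids <- sprintf("%s_%02d", b$name, seq_len(b$n_samples))
        hap_ids <- c(hap_ids, rep(ids, each = 2L))
        breed_of <- c(breed_of, rep(b$name, b$n_samples))
    }
    donor_frac <- list()
    for (d in config$cross_designs) {
        cr <- makeCross(pools_out, d, config)
        nm <- paste0(d$dam_breed, d$sire_breed)
        hap_rows[[nm]] <- cr$alleles
        hap_ids <- c(hap_ids, rep(cr$sample_ids, each = 2L))
        breed_of <- c(breed_of, rep(nm, length(cr$sample_ids)))
        donor_frac[[nm]] <- cr$donor_frac
    }
    alleles <- do.call(rbind, hap_rows)
    if (config$missing_rate > 0) {
        drop <- stats::runif(length(alleles)) < config$missing_rate
        alleles[drop] <- NA_integer_
    }
    base4 <- c("A", "C", "G", "T")
    ref <- sample(base4, config$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(base4, r), 1L), character(1))
    gr <- GenomicRanges::GRanges(config$chrom,
                                 IRanges::IRanges(pos, width = 1L),
                                 ref = ref, alt = alt)
    names(gr) <- sprintf("snp%04d", seq_len(config$n_snps))
    hs <- HaplotypeSet(alleles, hap_ids, gr)
    ids <- unique(hap_ids)
    dosage <- vapply(split(seq_along(hap_ids), factor(hap_ids, levels = ids)),
                     function(i) sum(alleles[i, ci] == 1L, na.rm = TRUE),
                     integer(1))
    phen <- assignPhenotypes(dosage, config$penetrance)
    samples <- data.frame(
        sample_id = ids, breed = breed_of, phenotype = phen,
        role = ifelse(phen == "slick", "case", "control"),
        stringsAsFactors = FALSE)
    gm <- haplotypesToGenotypes(hs, samples)
    list(genotypes = gm, haplotypes = hs,
         truth = list(causal_index = ci, causal_pos = pos[ci],
                      founder_haps = founders$founder_haps,
                      carrier_dosage = dosage, donor_frac = donor_frac,
                      config = config))
}
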