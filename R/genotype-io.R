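## Genotype/haplotype I/O, QC filtering, and interval utilities.

#' Read diploid SNP genotypes
#'
#' Reads biallelic SNP genotypes from a VCF (GT field) or a PLINK text
#' PED/MAP pair into a [GenotypeData]. Calls are coded as alt-allele
#' dosage 0/1/2 with NA for missing ("./." in VCF, "0 0" in PED).
#' Variants are sorted by (chromosome, position). If every VCF genotype is
#' phased ("|"), the phase can be recovered with [readHaplotypes()].
#'
#' @param path path to the .vcf file, or the .ped file (the .map file is
#'   found by swapping the extension) when \code{format = "ped_map"}.
#' @param format "vcf" or "ped_map".
#' @param samples optional sample table merged by \code{sample_id}.
#' @param multiallelic "error" (default) rejects records with >1 ALT
#'   allele; "drop" silently removes them.
#' @return A [GenotypeData].
#' @export
readGenotypes <- function(path, format = c("vcf", "ped_map"),
                          samples = NULL,
                          multiallelic = c("error", "drop")) {
    format <- match.arg(format)
    multiallelic <- match.arg(multiallelic)
    parsed <- switch(format,
                     vcf = .readVcf(path, multiallelic),
                     ped_map = .readPedMap(path))
    calls <- parsed$calls
    variants <- parsed$variants
    if (anyDuplicated(variants$variant_id))
        stop("duplicate variant id(s): ",
             paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
                   collapse = ", "))
    ord <- order(variants$chrom, variants$pos_bp)
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
    if (!is.null(samples)) {
        samples <- samples[match(colnames(calls), samples$sample_id), ,
                           drop = FALSE]
    }
    rownames(calls) <- variants$variant_id
    GenotypeData(calls, variants, samples)
}

.readVcf <- function(path, multiallelic) {
    if (!file.exists(path)) stop("file not found: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    given_ids <- fix[, "ID"]
    given_ids <- given_ids[!is.na(given_ids) & given_ids != "."]
    if (anyDuplicated(given_ids))
        stop("duplicate variant id(s): ",
             paste(unique(given_ids[duplicated(given_ids)]), collapse = ", "))
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                       dimnames = list(fix[, "ID"], names(gt)))
    if (any(multi)) {
        if (multiallelic == "error")
            stop("multi-allelic record(s) at line(s): ",
                 paste(which(multi), collapse = ", "),
                 " (use multiallelic = \"drop\")")
        fix <- fix[!multi, , drop = FALSE]
        gt <- gt[!multi, , drop = FALSE]
    }
    allele1 <- substr(gt, 1L, 1L)
    allele2 <- substr(gt, 3L, 3L)
    dose <- function(a) {
        d <- suppressWarnings(as.integer(a))
        d[a %in% c(".", "")] <- NA_integer_
        d
    }
    calls <- dose(allele1) + dose(allele2)
    bad <- !is.na(calls) & calls > 2L
    if (any(bad))
        stop("non-biallelic genotype code in record(s): ",
             paste(unique(which(bad) %% nrow(gt)), collapse = ", "))
    calls <- matrix(calls, nrow = nrow(gt), dimnames = dimnames(gt))
    ids <- fix[, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
    pos <- suppressWarnings(as.integer(fix[, "POS"]))
    if (anyNA(pos))
        stop("malformed POS at VCF record ", which(is.na(pos))[1L])
    list(calls = calls,
         variants = data.frame(variant_id = ids,
                               chrom = fix[, "CHROM"],
                               pos_bp = pos,
                               ref = fix[, "REF"], alt = fix[, "ALT"],
                               stringsAsFactors = FALSE),
         phased = all(grepl("|", gt[!is.na(gt)], fixed = TRUE)))
}

.readPedMap <- function(path) {
    map_path <- sub("\\.ped$", ".map", path)
    if (!file.exists(path)) stop("file not found: ", path)
    if (!file.exists(map_path)) stop("file not found: ", map_path)
    map <- utils::read.table(map_path, header = FALSE,
                             col.names = c("chrom", "variant_id", "cm", "pos_bp"),
                             colClasses = c("character", "character",
                                            "numeric", "integer"))
    ped <- utils::read.table(path, header = FALSE,
                             colClasses = "character")
    m <- nrow(map)
    if (ncol(ped) != 6L + 2L * m)
        stop("PED line width ", ncol(ped), " does not match MAP (",
             6L + 2L * m, " fields expected)")
    ids <- ped[, 2L]
    al <- as.matrix(ped[, -(1:6), drop = FALSE])
    a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
    a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
    calls <- matrix(NA_integer_, nrow = m, ncol = nrow(ped))
    ref <- alt <- character(m)
    for (j in seq_len(m)) {
        obs <- c(a1[, j], a2[, j])
        lv <- sort(unique(obs[obs != "0"]))
        if (length(lv) > 2L)
            stop("variant ", map$variant_id[j], " has >2 alleles in PED")
        if (length(lv) == 0L) lv <- c("?", "??")
        ref[j] <- lv[1L]
        alt[j] <- if (length(lv) == 2L) lv[2L] else paste0(lv[1L], "'")
        d1 <- ifelse(a1[, j] == "0", NA_integer_,
                     as.integer(a1[, j] == alt[j]))
        d2 <- ifelse(a2[, j] == "0", NA_integer_,
                     as.integer(a2[, j] == alt[j]))
        miss <- a1[, j] == "0" | a2[, j] == "0"  # "0 0" or half-missing -> NA
        calls[j, ] <- ifelse(miss, NA_integer_, d1 + d2)
    }
    colnames(calls) <- ids
    list(calls = calls,
         variants = data.frame(variant_id = map$variant_id,
                               chrom = map$chrom, pos_bp = map$pos_bp,
                               ref = ref, alt = alt,
                               stringsAsFactors = FALSE),
         phased = FALSE)
}

#' Read phased haplotypes from a VCF
#'
#' Requires every genotype to use the phased separator "|"; allele order
#' within "a|b" is preserved as the two haplotype rows of each sample.
#'
#' @param path VCF path.
#' @return A [HaplotypeSet].
#' @export
readHaplotypes <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    ok <- is.na(gt) | grepl("|", gt, fixed = TRUE)
    if (!all(ok))
        stop("unphased genotype(s) present; phase externally first")
    dose <- function(a) {
        d <- suppressWarnings(as.integer(a))
        d[a %in% c(".", "")] <- NA_integer_
        d
    }
    a1 <- matrix(dose(substr(gt, 1L, 1L)), nrow = nrow(gt))
    a2 <- matrix(dose(substr(gt, 3L, 3L)), nrow = nrow(gt))
    n <- ncol(gt)
    alleles <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(gt))
    alleles[seq(1L, 2L * n, 2L), ] <- t(a1)
    alleles[seq(2L, 2L * n, 2L), ] <- t(a2)
    ids <- fix[, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
    gr <- GenomicRanges::GRanges(fix[, "CHROM"],
                                 IRanges::IRanges(as.integer(fix[, "POS"]),
                                                  width = 1L),
                                 ref = fix[, "REF"], alt = fix[, "ALT"])
    names(gr) <- ids
    HaplotypeSet(alleles, rep(colnames(gt), each = 2L), gr)
}

#' Write genotypes or phased haplotypes as VCF 4.2 text
#'
#' @param x a [GenotypeData] (written unphased, "/") or [HaplotypeSet]
#'   (written phased, "|").
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(x, path) {
    if (is(x, "HaplotypeSet")) {
        v <- variantInfo(x)
        a <- hapAlleles(x)
        ids <- unique(hapSampleOf(x))
        idx <- split(seq_len(nrow(a)), factor(hapSampleOf(x), levels = ids))
        fmt <- function(z) ifelse(is.na(z), ".", as.character(z))
        gtcols <- vapply(idx, function(i)
            paste0(fmt(a[i[1L], ]), "|", fmt(a[i[2L], ])),
            character(ncol(a)))
        if (ncol(a) == 1L) gtcols <- matrix(gtcols, nrow = 1L)
    } else {
        v <- variantInfo(x)
        g <- genotypeCalls(x)
        ids <- colnames(g)
        code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
        gtcols <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
        ok <- !is.na(g)
        gtcols[ok] <- code[as.character(g[ok])]
    }
    lines <- c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t"))
    body <- paste(as.character(GenomicRanges::seqnames(v)),
                  GenomicRanges::start(v), names(v),
                  S4Vectors::mcols(v)$ref, S4Vectors::mcols(v)$alt,
                  ".", ".", ".", "GT",
                  apply(gtcols, 1L, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(c(lines, body), path)
    invisible(path)
}

#' Write genotypes as PLINK text PED/MAP
#'
#' @param gm [GenotypeData].
#' @param prefix output prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @return \code{prefix}, invisibly.
#' @export
writePedMap <- function(gm, prefix) {
    v <- variantInfo(gm)
    g <- genotypeCalls(gm)
    s <- sampleInfo(gm)
    map <- data.frame(chrom = as.character(GenomicRanges::seqnames(v)),
                      id = names(v), cm = 0, pos = GenomicRanges::start(v))
    utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    ref <- S4Vectors::mcols(v)$ref
    alt <- S4Vectors::mcols(v)$alt
    pheno <- ifelse(s$phenotype == "slick", 2L,
                    ifelse(s$phenotype == "nonslick", 1L, 0L))
    con <- file(paste0(prefix, ".ped"), "w")
    on.exit(close(con))
    for (i in seq_len(ncol(g))) {
        gi <- g[, i]
        a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, alt, ref))
        a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, alt, ref))
        al <- character(2L * length(gi))
        al[c(TRUE, FALSE)] <- a1
        al[c(FALSE, TRUE)] <- a2
        writeLines(paste(c(s$breed[i], s$sample_id[i], "0", "0", "0",
                           pheno[i], al), collapse = " "), con)
    }
    invisible(prefix)
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies the standard array-QC rules with strict ("greater than")
#' thresholds: samples below the sample call-rate threshold are dropped
#' first, then variants below the variant call-rate threshold, then minor
#' allele frequency is recomputed on the surviving samples and variants at
#' or below the MAF threshold are dropped. MAF is computed over non-missing
#' calls only.
#'
#' @param gm [GenotypeData].
#' @param min_variant_call variant call-rate threshold (keep if strictly
#'   greater); default 0.90.
#' @param min_maf minor-allele-frequency threshold (keep if strictly
#'   greater); default 0.05.
#' @param min_sample_call sample call-rate threshold (keep if strictly
#'   greater); default 0.95.
#' @return The filtered [GenotypeData]; the QC report (counts and the
#'   filtering order) is attached as \code{metadata(x)$qc_report}.
#' @export
qcFilter <- function(gm, min_variant_call = 0.90, min_maf = 0.05,
                     min_sample_call = 0.95) {
    g <- genotypeCalls(gm)
    if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")
    sample_cr <- colMeans(!is.na(g))
    keep_s <- sample_cr > min_sample_call
    g2 <- g[, keep_s, drop = FALSE]
    if (ncol(g2) == 0L) stop("QC removed all samples")
    variant_cr <- rowMeans(!is.na(g2))
    keep_v1 <- variant_cr > min_variant_call
    g3 <- g2[keep_v1, , drop = FALSE]
    af <- rowMeans(g3, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    maf[is.nan(maf)] <- 0
    keep_v2 <- maf > min_maf
    if (!any(keep_v1) || !any(keep_v2))
        stop("QC removed all variants")
    out <- gm[which(keep_v1)[keep_v2], keep_s]
    out <- as(out, "GenotypeData")
    report <- list(
        order = c("samples by call rate", "variants by call rate",
                  "variants by recomputed MAF"),
        thresholds = c(min_sample_call = min_sample_call,
                       min_variant_call = min_variant_call,
                       min_maf = min_maf),
        n_samples_removed = sum(!keep_s),
        n_variants_removed_callrate = sum(!keep_v1),
        n_variants_removed_maf = sum(!keep_v2),
        n_samples_kept = ncol(out), n_variants_kept = nrow(out))
    S4Vectors::metadata(out)$qc_report <- report
    out
}

## ---- interval utilities (1-based, both ends inclusive) ----

#' Construct a 1-based inclusive genomic interval
#'
#' @param chrom chromosome name.
#' @param start_bp,end_bp inclusive 1-based endpoints, start <= end.
#' @return A length-1 GRanges.
#' @export
genomicInterval <- function(chrom, start_bp, end_bp) {
    if (any(end_bp < start_bp)) stop("end_bp must be >= start_bp")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start_bp, end_bp))
}

#' Interval span in bp
#'
#' The span convention is \code{end - start} (the printed "block distance"
#' convention: the first base is excluded), not the inclusive width.
#'
#' @param iv GRanges.
#' @return integer vector of spans.
#' @export
intervalSpan <- function(iv) {
    GenomicRanges::end(iv) - GenomicRanges::start(iv)
}

#' Intersect intervals on one chromosome
#'
#' @param ivs GRanges (each range one piece of evidence) or list of
#'   GRanges; all must be on the same chromosome.
#' @return A GRanges of length 1 (max of starts .. min of ends), or
#'   length 0 when the intersection is empty.
#' @export
intervalIntersect <- function(ivs) {
    if (is.list(ivs)) ivs <- do.call(c, ivs)
    if (length(ivs) == 0L) return(GenomicRanges::GRanges())
    chr <- unique(as.character(GenomicRanges::seqnames(ivs)))
    if (length(chr) != 1L)
        stop("cannot intersect intervals across chromosomes: ",
             paste(chr, collapse = ", "))
    s <- max(GenomicRanges::start(ivs))
    e <- min(GenomicRanges::end(ivs))
    if (s > e) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chr, IRanges::IRanges(s, e))
}

#' Merge overlapping intervals
#'
#' Thin wrapper over \code{GenomicRanges::reduce}; abutting or overlapping
#' ranges on the same chromosome are merged.
#'
#' @param ivs GRanges or list of GRanges.
#' @return A reduced GRanges.
#' @export
mergeIntervals <- function(ivs) {
    if (is.list(ivs)) ivs <- do.call(c, ivs)
    GenomicRanges::reduce(ivs)
}

#' Write intervals as BED (0-based half-open) text
#'
#' Converts from the package's 1-based inclusive convention explicitly:
#' BED start = start - 1, BED end = end.
#'
#' @param iv GRanges; a metadata column \code{name} or \code{score} is
#'   carried through when present.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(iv, path) {
    mc <- S4Vectors::mcols(iv)
    nm <- if ("name" %in% colnames(mc)) as.character(mc$name) else
        paste0("region", seq_along(iv))
    sc <- if ("score" %in% colnames(mc)) mc$score else rep(0, length(iv))
    writeLines(paste(as.character(GenomicRanges::seqnames(iv)),
                     GenomicRanges::start(iv) - 1L, GenomicRanges::end(iv),
                     nm, sc, sep = "\t"), path)
    invisible(path)
}
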