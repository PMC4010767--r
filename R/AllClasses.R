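#' @import methods
#' @importFrom stats setNames
NULL

#' GenotypeData: diploid SNP genotypes with variant and sample annotation
#'
#' A container for diploid biallelic SNP genotypes, stored as a
#' variants x samples integer matrix of alt-allele dosages (0, 1, 2) with
#' \code{NA} for missing calls. Extends
#' \linkS4class{RangedSummarizedExperiment}: variants live in
#' \code{rowRanges} (1-based single-base positions, with \code{ref} and
#' \code{alt} allele codes in the metadata columns) and the sample table in
#' \code{colData} (columns \code{sample_id}, \code{breed},
#' \code{phenotype} in \code{c("slick","nonslick","unknown")} and
#' \code{role} in \code{c("case","control","excluded")}).
#'
#' @slot .Data inherited SummarizedExperiment machinery; use the accessors.
#' @seealso [genotypeCalls()], [variantInfo()], [sampleInfo()],
#'   [readGenotypes()], [qcFilter()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

.validGenotypeData <- function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        g <- SummarizedExperiment::assay(object, "calls")
        bad <- !(g %in% c(0L, 1L, 2L, NA))
        if (any(bad))
            msg <- c(msg, "calls must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
        msg <- c(msg, "variant ids (rownames) must be unique and non-NULL")
    if (!all(c("ref", "alt") %in% colnames(S4Vectors::mcols(rr))))
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt' columns")
    else if (any(as.character(S4Vectors::mcols(rr)$ref) ==
                 as.character(S4Vectors::mcols(rr)$alt)))
        msg <- c(msg, "ref and alt alleles must differ at every variant")
    # positions strictly increasing within each chromosome
    if (length(rr) > 1L) {
        byc <- split(GenomicRanges::start(rr),
                     as.character(GenomicRanges::seqnames(rr)))
        if (!all(vapply(byc, function(p) all(diff(p) > 0), logical(1))))
            msg <- c(msg, "positions must be strictly increasing within a chromosome")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "breed", "phenotype", "role")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData needs columns:", paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample ids must be unique")
        if (!all(cd$phenotype %in% c("slick", "nonslick", "unknown")))
            msg <- c(msg, "phenotype must be slick/nonslick/unknown")
        if (!all(cd$role %in% c("case", "control", "excluded")))
            msg <- c(msg, "role must be case/control/excluded")
        bad <- cd$role == "case" & cd$phenotype == "nonslick"
        if (any(bad))
            msg <- c(msg, "role 'case' requires phenotype slick (or unknown)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param calls integer matrix, variants x samples, values 0/1/2/NA
#'   (alt-allele dosage; NA = missing call, never conflated with 0).
#' @param variants either a \code{GRanges} with names (variant ids) and
#'   metadata columns \code{ref}, \code{alt}, or a data.frame with columns
#'   \code{variant_id}, \code{chrom}, \code{pos_bp}, \code{ref}, \code{alt}.
#' @param samples data.frame with columns \code{sample_id}, \code{breed},
#'   \code{phenotype}, \code{role}; defaults fill \code{unknown}/\code{excluded}.
#' @return A \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(calls, variants, samples) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (is.data.frame(variants)) {
        variants <- GenomicRanges::GRanges(
            seqnames = as.character(variants$chrom),
            ranges = IRanges::IRanges(start = variants$pos_bp, width = 1L),
            ref = as.character(variants$ref),
            alt = as.character(variants$alt))
        names(variants) <- if (!is.null(variants$variant_id))
            variants$variant_id else NULL
    }
    if (is.null(names(variants)) && !is.null(rownames(calls)))
        names(variants) <- rownames(calls)
    if (missing(samples) || is.null(samples)) {
        ids <- colnames(calls)
        if (is.null(ids)) ids <- paste0("S", seq_len(ncol(calls)))
        samples <- data.frame(sample_id = ids,
                              breed = "NA",
                              phenotype = "unknown",
                              role = "excluded",
                              stringsAsFactors = FALSE)
    }
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    if (is.null(samples$breed)) samples$breed <- "NA"
    if (is.null(samples$phenotype)) samples$phenotype <- "unknown"
    if (is.null(samples$role)) samples$role <- "excluded"
    rownames(calls) <- names(variants)
    colnames(calls) <- samples$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls),
        rowRanges = variants,
        colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
    new("GenotypeData", se)
}

#' HaplotypeSet: phased chromosome-level alleles
#'
#' Phased haplotypes as a (2 * n_samples) x n_variants matrix of allele
#' codes 0/1 (NA = missing). Each sample owns exactly two consecutive rows;
#' summing a sample's two rows reproduces its alt-allele dosage wherever
#' both rows are non-missing.
#'
#' @slot alleles integer matrix, 2n x m.
#' @slot sampleOf character of length 2n mapping each row to a sample id.
#' @slot variants GRanges of variant positions with ref/alt columns.
#' @export
setClass("HaplotypeSet",
         representation(alleles = "matrix",
                        sampleOf = "character",
                        variants = "GRanges"))

setValidity("HaplotypeSet", function(object) {
    msg <- character()
    a <- object@alleles
    if (!all(a %in% c(0L, 1L, NA)))
        msg <- c(msg, "haplotype alleles must be 0, 1 or NA")
    if (nrow(a) != length(object@sampleOf))
        msg <- c(msg, "sampleOf length must equal number of haplotype rows")
    tab <- table(object@sampleOf)
    if (length(tab) && any(tab != 2L))
        msg <- c(msg, "each sample must own exactly two haplotype rows")
    if (ncol(a) != length(object@variants))
        msg <- c(msg, "allele columns must match variants")
    if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeSet
#'
#' @param alleles 2n x m matrix of 0/1/NA allele codes; consecutive row
#'   pairs belong to one sample.
#' @param sampleOf character vector of sample ids, one per row (each id
#'   appearing exactly twice).
#' @param variants GRanges of the m variants (as in [GenotypeData()]).
#' @return A \linkS4class{HaplotypeSet}.
#' @export
HaplotypeSet <- function(alleles, sampleOf, variants) {
    alleles <- as.matrix(alleles)
    storage.mode(alleles) <- "integer"
    new("HaplotypeSet", alleles = alleles,
        sampleOf = as.character(sampleOf), variants = variants)
}

#' ConsensusLocus: the integrated fine-mapping interval
#'
#' Result of [integrateConsensus()]: the intersection of all span-type
#' evidence intervals, together with the classification of support-type
#' tracks as overlapping or failing. An empty \code{interval} (length-0
#' GRanges) encodes the explicit no-consensus outcome.
#'
#' @slot interval GRanges of length 1 (or 0 for no consensus).
#' @slot spanTracks names of the span tracks intersected.
#' @slot supportsOverlapping,supportsFailing names of support tracks that
#'   do / do not overlap the consensus interval.
#' @export
setClass("ConsensusLocus",
         representation(interval = "GRanges",
                        spanTracks = "character",
                        supportsOverlapping = "character",
                        supportsFailing = "character"))

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "variants x", ncol(object), "samples\n")
    g <- SummarizedExperiment::assay(object, "calls")
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(g))))
    cd <- SummarizedExperiment::colData(object)
    cat("  phenotypes:", paste(sprintf("%s=%d", names(table(cd$phenotype)),
                                       table(cd$phenotype)), collapse = " "), "\n")
    callNextMethod()
})

setMethod("show", "HaplotypeSet", function(object) {
    cat("HaplotypeSet:", nrow(object@alleles), "haplotypes (",
        nrow(object@alleles) / 2L, "samples ) x",
        ncol(object@alleles), "variants\n")
})

setMethod("show", "ConsensusLocus", function(object) {
    if (length(object@interval) == 0L) {
        cat("ConsensusLocus: no consensus (span tracks disjoint)\n")
    } else {
        iv <- object@interval
        cat(sprintf("ConsensusLocus: %s:%d-%d (%.1f Mb span)\n",
                    as.character(GenomicRanges::seqnames(iv)),
                    GenomicRanges::start(iv), GenomicRanges::end(iv),
                    intervalSpan(iv) / 1e6))
    }
    cat("  span tracks:", paste(object@spanTracks, collapse = ", "), "\n")
    if (length(object@supportsOverlapping))
        cat("  supports overlapping:",
            paste(object@supportsOverlapping, collapse = ", "), "\n")
    if (length(object@supportsFailing))
        cat("  supports failing:",
            paste(object@supportsFailing, collapse = ", "), "\n")
})

#' @rdname GenotypeData-accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname GenotypeData-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname GenotypeData-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("hapAlleles", function(x) standardGeneric("hapAlleles"))
#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("hapSampleOf", function(x) standardGeneric("hapSampleOf"))

#' Accessors for GenotypeData
#'
#' \code{genotypeCalls} returns the variants x samples dosage matrix,
#' \code{variantInfo} the variant GRanges, \code{sampleInfo} the sample
#' table as a plain data.frame.
#'
#' @param x a GenotypeData (or HaplotypeSet for \code{variantInfo}).
#' @name GenotypeData-accessors
#' @export
setMethod("genotypeCalls", "GenotypeData", function(x)
    SummarizedExperiment::assay(x, "calls"))
#' @rdname GenotypeData-accessors
#' @export
setMethod("variantInfo", "GenotypeData", function(x)
    SummarizedExperiment::rowRanges(x))
#' @rdname GenotypeData-accessors
#' @export
setMethod("sampleInfo", "GenotypeData", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))
#' @rdname GenotypeData-accessors
#' @export
setMethod("variantInfo", "HaplotypeSet", function(x) x@variants)

#' Accessors for HaplotypeSet
#'
#' \code{hapAlleles} returns the 2n x m allele matrix, \code{hapSampleOf}
#' the row-to-sample map.
#'
#' @param x a HaplotypeSet.
#' @name HaplotypeSet-accessors
#' @export
setMethod("hapAlleles", "HaplotypeSet", function(x) x@alleles)
#' @rdname HaplotypeSet-accessors
#' @export
setMethod("hapSampleOf", "HaplotypeSet", function(x) x@sampleOf)

#' Collapse a HaplotypeSet to genotypes
#'
#' Sums each sample's two haplotype rows into an alt-allele dosage; a
#' missing allele on either row makes the genotype missing.
#'
#' @param hs HaplotypeSet.
#' @param samples optional sample table (as in [GenotypeData()]); defaults
#'   to unknown phenotype/role.
#' @return A \linkS4class{GenotypeData}.
#' @export
haplotypesToGenotypes <- function(hs, samples = NULL) {
    a <- hapAlleles(hs)
    ids <- unique(hapSampleOf(hs))
    idx <- split(seq_len(nrow(a)), factor(hapSampleOf(hs), levels = ids))
    g <- vapply(idx, function(i) a[i[1L], ] + a[i[2L], ],
                integer(ncol(a)))
    if (ncol(a) == 1L) g <- matrix(g, nrow = 1L)  # vapply drops dim at m=1
    if (is.null(samples)) {
        samples <- data.frame(sample_id = ids, breed = "NA",
                              phenotype = "unknown", role = "excluded",
                              stringsAsFactors = FALSE)
    } else {
        samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
    }
    GenotypeData(g, variantInfo(hs), samples)
}

#' Subset a HaplotypeSet by variant index
#'
#' @param hs HaplotypeSet.
#' @param j integer vector of variant (column) indices.
#' @return A HaplotypeSet restricted to those variants.
#' @export
subsetVariants <- function(hs, j) {
    HaplotypeSet(hs@alleles[, j, drop = FALSE], hs@sampleOf, hs@variants[j])
}
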