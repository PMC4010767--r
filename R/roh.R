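## Runs of homozygosity: per-sample run detection at SNP-count thresholds
## and the per-locus ROH frequency track.

#' Detect runs of homozygosity
#'
#' Maximal runs of consecutive homozygous calls per sample, with at most
#' \code{het_tolerance} heterozygous and \code{missing_tolerance} missing
#' calls inside a run. Defaults are strict (0/0): a heterozygous or
#' missing call breaks the run. Runs shorter than \code{L} SNPs are
#' discarded. Runs are defined in SNP-index space; bp extent is reported
#' but never used for calling.
#'
#' @param gm [GenotypeData], single chromosome.
#' @param L minimum run length in SNPs (>= 2).
#' @param het_tolerance,missing_tolerance allowed slippage per run.
#' @return data.frame: sample_id, start_index, end_index, n_snps, chrom,
#'   start_bp, end_bp.
#' @export
detectROH <- function(gm, L = 100L, het_tolerance = 0L,
                      missing_tolerance = 0L) {
    if (L < 2L) stop("L must be >= 2")
    v <- variantInfo(gm)
    chrom <- unique(as.character(GenomicRanges::seqnames(v)))
    if (length(chrom) != 1L) stop("detectROH expects a single chromosome")
    pos <- GenomicRanges::start(v)
    m <- length(pos)
    if (L > m) {
        warning("L exceeds the number of variants; no runs possible")
        return(data.frame(sample_id = character(), start_index = integer(),
                          end_index = integer(), n_snps = integer(),
                          chrom = character(), start_bp = integer(),
                          end_bp = integer(), stringsAsFactors = FALSE))
    }
    g <- genotypeCalls(gm)
    out <- vector("list", ncol(g))
    for (s in seq_len(ncol(g))) {
        gi <- g[, s]
        runs <- .homRuns(gi, het_tolerance, missing_tolerance)
        if (nrow(runs)) {
            runs <- runs[runs$end - runs$start + 1L >= L, , drop = FALSE]
            if (nrow(runs))
                out[[s]] <- data.frame(
                    sample_id = colnames(g)[s],
                    start_index = runs$start, end_index = runs$end,
                    n_snps = runs$end - runs$start + 1L,
                    chrom = chrom, start_bp = pos[runs$start],
                    end_bp = pos[runs$end], stringsAsFactors = FALSE)
        }
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L)
        return(data.frame(sample_id = character(), start_index = integer(),
                          end_index = integer(), n_snps = integer(),
                          chrom = character(), start_bp = integer(),
                          end_bp = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## maximal windows whose het count <= ht and missing count <= mt
.homRuns <- function(gi, ht, mt) {
    m <- length(gi)
    het <- !is.na(gi) & gi == 1L
    mis <- is.na(gi)
    if (ht == 0L && mt == 0L) {        # fast strict path
        ok <- !het & !mis
        r <- rle(ok)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values
        return(data.frame(start = starts[keep], end = ends[keep]))
    }
    ## two-pointer enumeration of maximal tolerant windows
    res <- list()
    left <- 1L; nh <- 0L; nm <- 0L
    best_right <- 0L
    for (right in seq_len(m)) {
        nh <- nh + het[right]; nm <- nm + mis[right]
        while (nh > ht || nm > mt) {
            nh <- nh - het[left]; nm <- nm - mis[left]
            left <- left + 1L
        }
        res[[right]] <- c(left, right)
    }
    ## keep windows that are maximal (not contained in the next window)
    w <- do.call(rbind, res)
    maximal <- c(w[-nrow(w), 1L] != w[-1L, 1L], TRUE)
    w <- w[maximal, , drop = FALSE]
    ## trim leading/trailing het or missing calls (a run should start and
    ## end on a homozygous call)
    keep <- logical(nrow(w))
    for (i in seq_len(nrow(w))) {
        a <- w[i, 1L]; b <- w[i, 2L]
        while (a <= b && (het[a] || mis[a])) a <- a + 1L
        while (b >= a && (het[b] || mis[b])) b <- b - 1L
        w[i, ] <- c(a, b)
        keep[i] <- b >= a
    }
    w <- unique(w[keep, , drop = FALSE])
    data.frame(start = w[, 1L], end = w[, 2L])
}

#' Per-locus ROH frequency track
#'
#' For every variant, the fraction of subset samples having a detected
#' run (of the given threshold) covering it: the sum of per-sample ROH
#' state (1 or 0) divided by the subset size.
#'
#' @param segments data.frame from [detectROH()].
#' @param subset_ids sample ids forming the denominator (e.g. all affected
#'   individuals); samples without runs contribute zeros.
#' @param variants GRanges of the scanned variants.
#' @return data.frame: variant_id, pos_bp, frequency.
#' @export
rohFrequency <- function(segments, subset_ids, variants) {
    if (length(subset_ids) == 0L) stop("empty sample subset")
    m <- length(variants)
    cov <- numeric(m)
    seg <- segments[segments$sample_id %in% subset_ids, , drop = FALSE]
    if (nrow(seg)) {
        ## merge per-sample runs so each sample contributes 0/1 per locus,
        ## then accumulate covering-sample counts with a diff array
        ir <- IRanges::reduce(S4Vectors::split(
            IRanges::IRanges(seg$start_index, seg$end_index),
            seg$sample_id))
        ir <- unlist(ir, use.names = FALSE)
        d <- numeric(m + 1L)
        for (i in seq_along(ir)) {
            d[IRanges::start(ir)[i]] <- d[IRanges::start(ir)[i]] + 1
            d[IRanges::end(ir)[i] + 1L] <- d[IRanges::end(ir)[i] + 1L] - 1
        }
        cov <- cumsum(d[seq_len(m)])
    }
    data.frame(variant_id = names(variants),
               pos_bp = GenomicRanges::start(variants),
               frequency = cov / length(subset_ids),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Peak interval of a frequency track
#'
#' Smallest interval containing every variant whose value is at least
#' \code{fraction_of_max} times the track maximum.
#'
#' @param track data.frame with \code{pos_bp} and \code{frequency} (any
#'   score column named \code{frequency}).
#' @param chrom chromosome name for the returned interval.
#' @param fraction_of_max peak inclusion rule.
#' @return length-1 GRanges.
#' @export
peakInterval <- function(track, chrom = "20", fraction_of_max = 0.9) {
    f <- track$frequency
    if (length(f) == 0L || all(is.na(f)) || max(f, na.rm = TRUE) <= 0)
        stop("flat zero track has no peak")
    thr <- fraction_of_max * max(f, na.rm = TRUE)
    idx <- which(!is.na(f) & f >= thr)
    genomicInterval(chrom, min(track$pos_bp[idx]), max(track$pos_bp[idx]))
}
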