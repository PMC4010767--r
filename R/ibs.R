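## Sliding-window identity-by-state (IBS) haplotype scanning: exact
## allele-string matching within windows, phenotype-bound consensus
## regions, between-group sharing, and homozygote consensus haplotypes.

## Pattern ids for every window of size w, for all start positions, by
## binary-lifting: ids for window length 2L at start i combine the ids of
## length L at i and i+L; a general w combines its largest power-of-two
## prefix with an overlapping suffix (equality on both halves is equality
## on the window). Ids are compacted per column; windows containing a
## missing call get NA.
.windowIds <- function(a, w) {
    n <- nrow(a); m <- ncol(a)
    if (w < 1L || w > m) stop("window size out of range")
    ## intermediate steps compact ids globally (cheap, ids may be large but
    ## pair keys stay exact in doubles); final result is per-column compact
    combine <- function(A, B, offset) {
        W <- ncol(A) - offset
        base <- max(B, na.rm = TRUE) + 1
        K <- A[, seq_len(W), drop = FALSE] * base +
             B[, offset + seq_len(W), drop = FALSE]
        .compactGlobal(K)
    }
    ids <- a + 1L                    # length-1 windows
    len <- 1L
    while (2L * len <= w) {
        ids <- combine(ids, ids, len)
        len <- 2L * len
    }
    if (len != w)
        ## overlap trick: [i, i+w-1] = [i, i+len-1] u [i+w-len, i+w-1]
        ids <- combine(ids, ids, w - len)
    .compactColumns(ids)
}

.compactGlobal <- function(M) {
    v <- as.vector(M)
    u <- unique(v[!is.na(v)])
    matrix(match(v, u), nrow = nrow(M))
}

.compactColumns <- function(M) {
    for (c in seq_len(ncol(M))) {
        u <- unique(M[, c][!is.na(M[, c])])
        M[, c] <- match(M[, c], u)
    }
    M
}

## counts of each pattern id per window column; ids are per-column
## compact in 1..nb, NAs (missing-excluded chromosomes) dropped
.windowCounts <- function(ids, nb) {
    W <- ncol(ids)
    v <- as.vector(ids)
    col <- rep(seq_len(W) - 1L, each = nrow(ids))
    ok <- !is.na(v)
    matrix(tabulate(v[ok] + col[ok] * nb, nbins = nb * W),
           nrow = nb, ncol = W)
}

#' Window haplotype pattern frequencies
#'
#' Partitions the chromosome into sliding windows of \code{w} SNPs and,
#' at each start position, groups chromosomes by their exact allele
#' string. Chromosomes with a missing call inside a window are excluded
#' from that window. Frequencies are per group over non-excluded
#' chromosomes.
#'
#' @param hs [HaplotypeSet].
#' @param groups named list of chromosome (row) index vectors.
#' @param w window size in SNPs.
#' @param step start-position stride (1 = maximal overlap).
#' @return data.frame: window_start (variant index), start_bp, end_bp,
#'   pattern (letter string), and one frequency column per group.
#' @export
windowHaplotypeFreqs <- function(hs, groups, w, step = 1L) {
    a <- hapAlleles(hs)
    v <- variantInfo(hs)
    pos <- GenomicRanges::start(v)
    ref <- S4Vectors::mcols(v)$ref; alt <- S4Vectors::mcols(v)$alt
    ids <- .windowIds(a, w)
    starts <- seq(1L, ncol(ids), by = step)
    out <- list()
    for (s in starts) {
        col <- ids[, s]
        pat <- sort(unique(col[!is.na(col)]))
        if (length(pat) == 0L) next
        freqs <- vapply(groups, function(g) {
            cg <- col[g]
            nn <- sum(!is.na(cg))
            if (nn == 0L) rep(0, length(pat))
            else vapply(pat, function(p) sum(cg == p, na.rm = TRUE) / nn,
                        numeric(1))
        }, numeric(length(pat)))
        if (length(pat) == 1L) freqs <- matrix(freqs, nrow = 1L,
                                               dimnames = list(NULL, names(groups)))
        strs <- vapply(pat, function(p) {
            row <- which(!is.na(col) & col == p)[1L]
            al <- a[row, s:(s + w - 1L)]
            paste(ifelse(al == 1L, alt[s:(s + w - 1L)],
                         ref[s:(s + w - 1L)]), collapse = "")
        }, character(1))
        out[[length(out) + 1L]] <- data.frame(
            window_start = s, start_bp = pos[s], end_bp = pos[s + w - 1L],
            pattern = strs, freqs, stringsAsFactors = FALSE,
            check.names = FALSE, row.names = NULL)
    }
    do.call(rbind, out)
}

#' Phenotype-bound IBS consensus regions
#'
#' A window supports consensus when some allele string reaches frequency
#' at least \code{f_in_min} among in-group chromosomes while staying at or
#' below \code{f_out_max} among out-group chromosomes. Passing windows
#' across every window size in \code{w_range} are merged into maximal
#' regions.
#'
#' @param hs [HaplotypeSet].
#' @param in_group,out_group disjoint chromosome (row) index vectors.
#' @param w_range window sizes scanned (SNPs).
#' @param f_in_min minimum in-group frequency (inclusive).
#' @param f_out_max maximum out-group frequency (inclusive).
#' @param step window stride.
#' @return GRanges of merged regions with metadata: supporting window
#'   sizes (comma string), best (largest) supporting w, max in-group and
#'   its out-group frequency.
#' @export
consensusRegions <- function(hs, in_group, out_group, w_range = 1:50,
                             f_in_min = 0.4, f_out_max = 0.0, step = 1L) {
    if (length(w_range) == 0L) stop("empty window-size range")
    if (length(in_group) == 0L || length(out_group) == 0L)
        stop("groups must be non-empty")
    if (length(intersect(in_group, out_group)))
        stop("groups must be disjoint")
    a <- hapAlleles(hs)
    v <- variantInfo(hs)
    pos <- GenomicRanges::start(v)
    chrom <- as.character(GenomicRanges::seqnames(v))[1L]
    hits <- list()
    nb <- nrow(a)
    for (w in w_range) {
        if (w > ncol(a)) next
        ids <- .windowIds(a, w)
        sel <- seq(1L, ncol(ids), by = step)
        Cin <- .windowCounts(ids[in_group, sel, drop = FALSE], nb)
        Cout <- .windowCounts(ids[out_group, sel, drop = FALSE], nb)
        nin <- colSums(Cin); nout <- colSums(Cout)
        Fin <- sweep(Cin, 2L, pmax(nin, 1L), "/")
        Fout <- sweep(Cout, 2L, pmax(nout, 1L), "/")
        pass_pat <- Fin >= f_in_min & Fout <= f_out_max
        pass_pat[, nin == 0L] <- FALSE
        win_pass <- which(colSums(pass_pat) > 0L)
        for (s0 in win_pass) {
            bi <- which.max(Fin[, s0] * pass_pat[, s0])
            hits[[length(hits) + 1L]] <- data.frame(
                w = w, start = sel[s0], f_in = Fin[bi, s0],
                f_out = Fout[bi, s0])
        }
    }
    if (length(hits) == 0L)
        return(GenomicRanges::GRanges())
    h <- do.call(rbind, hits)
    gr <- GenomicRanges::GRanges(chrom,
             IRanges::IRanges(pos[h$start], pos[h$start + h$w - 1L]))
    red <- GenomicRanges::reduce(gr)
    ov <- GenomicRanges::findOverlaps(gr, red)
    ann <- S4Vectors::DataFrame(
        supporting_w = vapply(seq_along(red), function(r) {
            ws <- sort(unique(h$w[S4Vectors::queryHits(ov)[
                S4Vectors::subjectHits(ov) == r]]))
            paste(ws, collapse = ",")
        }, character(1)),
        best_w = vapply(seq_along(red), function(r)
            max(h$w[S4Vectors::queryHits(ov)[
                S4Vectors::subjectHits(ov) == r]]), numeric(1)),
        max_in_freq = vapply(seq_along(red), function(r)
            max(h$f_in[S4Vectors::queryHits(ov)[
                S4Vectors::subjectHits(ov) == r]]), numeric(1)),
        max_out_freq = vapply(seq_along(red), function(r)
            max(h$f_out[S4Vectors::queryHits(ov)[
                S4Vectors::subjectHits(ov) == r]]), numeric(1)))
    S4Vectors::mcols(red) <- ann
    red
}

#' Regions where an identical pattern is shared between two groups
#'
#' For each window size in \code{w}, finds windows whose best shared
#' allele string reaches \code{min_freq_each} in both groups; passing
#' windows are merged and each region is annotated with the maximal
#' window size at which sharing persists. Sharing is monotone: a pattern
#' shared at w is shared at every smaller window inside it.
#'
#' @param hs [HaplotypeSet].
#' @param groupA,groupB chromosome row index vectors.
#' @param w window size(s) in SNPs.
#' @param min_freq_each frequency each group must reach for the same
#'   pattern.
#' @param step window stride.
#' @return GRanges with metadata column \code{w_max}.
#' @export
sharedBetweenGroups <- function(hs, groupA, groupB, w, min_freq_each = 0.4,
                                step = 1L) {
    if (length(groupA) == 0L || length(groupB) == 0L)
        stop("groups must be non-empty")
    a <- hapAlleles(hs)
    v <- variantInfo(hs)
    pos <- GenomicRanges::start(v)
    chrom <- as.character(GenomicRanges::seqnames(v))[1L]
    hits <- list()
    nb <- nrow(a)
    for (wi in sort(w)) {
        if (wi > ncol(a)) next
        ids <- .windowIds(a, wi)
        sel <- seq(1L, ncol(ids), by = step)
        Ca <- .windowCounts(ids[groupA, sel, drop = FALSE], nb)
        Cb <- .windowCounts(ids[groupB, sel, drop = FALSE], nb)
        na_ <- colSums(Ca); nb_ <- colSums(Cb)
        Fa <- sweep(Ca, 2L, pmax(na_, 1L), "/")
        Fb <- sweep(Cb, 2L, pmax(nb_, 1L), "/")
        shared <- colSums(Fa >= min_freq_each & Fb >= min_freq_each) > 0L
        shared[na_ == 0L | nb_ == 0L] <- FALSE
        for (s0 in sel[shared])
            hits[[length(hits) + 1L]] <- data.frame(w = wi, start = s0)
    }
    if (length(hits) == 0L) return(GenomicRanges::GRanges())
    h <- do.call(rbind, hits)
    gr <- GenomicRanges::GRanges(chrom,
             IRanges::IRanges(pos[h$start], pos[h$start + h$w - 1L]))
    red <- GenomicRanges::reduce(gr)
    ov <- GenomicRanges::findOverlaps(gr, red)
    S4Vectors::mcols(red)$w_max <- vapply(seq_along(red), function(r)
        max(h$w[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == r]]),
        numeric(1))
    red
}

#' Consensus homozygous haplotype across designated samples
#'
#' Verifies that every named sample is homozygous across the hint region
#' (a heterozygous call there is an error naming the sample and position)
#' and finds the maximal interval around the hint over which all named
#' samples share one identical homozygous haplotype. If samples disagree
#' (as opposite homozygotes) inside the hint, the hint is split at the
#' mismatch and the longest clean piece is returned, with all pieces
#' reported.
#'
#' @param gm [GenotypeData].
#' @param sample_ids samples expected homozygous across the region.
#' @param hint GRanges (length 1) seeding the search.
#' @return list: \code{interval} (GRanges), \code{consensus} (letter
#'   string over the interval), \code{pieces} (GRanges of all clean
#'   pieces inside the hint).
#' @export
homozygoteConsensus <- function(gm, sample_ids, hint) {
    g <- genotypeCalls(gm)[, sample_ids, drop = FALSE]
    v <- variantInfo(gm)
    pos <- GenomicRanges::start(v)
    chrom <- as.character(GenomicRanges::seqnames(v))[1L]
    in_hint <- which(pos >= GenomicRanges::start(hint) &
                     pos <= GenomicRanges::end(hint))
    if (length(in_hint) == 0L) stop("hint region contains no variants")
    het <- which(g[in_hint, , drop = FALSE] == 1L, arr.ind = TRUE)
    if (nrow(het))
        stop("sample ", sample_ids[het[1L, 2L]],
             " is heterozygous at position ",
             pos[in_hint[het[1L, 1L]]], " inside the hint region")
    ## per variant: all named samples non-missing, homozygous, same allele
    okv <- apply(g, 1L, function(r)
        !anyNA(r) && all(r %in% c(0L, 2L)) && length(unique(r)) == 1L)
    hint_ok <- okv[in_hint]
    if (all(hint_ok)) {
        lo <- min(in_hint); hi <- max(in_hint)
        while (lo > 1L && okv[lo - 1L]) lo <- lo - 1L
        while (hi < length(okv) && okv[hi + 1L]) hi <- hi + 1L
        pieces <- genomicInterval(chrom, pos[min(in_hint)], pos[max(in_hint)])
    } else {
        r <- rle(hint_ok)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        keep <- r$values
        if (!any(keep)) stop("no shared homozygous variant inside the hint")
        ps <- in_hint[starts[keep]]; pe <- in_hint[ends[keep]]
        pieces <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos[ps], pos[pe]))
        best <- which.max(pe - ps)
        lo <- ps[best]; hi <- pe[best]
        while (lo > 1L && okv[lo - 1L]) lo <- lo - 1L
        while (hi < length(okv) && okv[hi + 1L]) hi <- hi + 1L
    }
    ref <- S4Vectors::mcols(v)$ref; alt <- S4Vectors::mcols(v)$alt
    cons <- paste(ifelse(g[lo:hi, 1L] == 2L, alt[lo:hi], ref[lo:hi]),
                  collapse = "")
    list(interval = genomicInterval(chrom, pos[lo], pos[hi]),
         consensus = cons, pieces = pieces)
}
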