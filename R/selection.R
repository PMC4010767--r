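## EHH and standardized |iHS| selection scan: bp-integrated extended
## haplotype homozygosity with a hard extension boundary, a
## group-frequency ancestral-allele rule, frequency-binned
## standardization, and windowed averaging.

## One-direction EHH walk with incremental haplotype grouping.
## Chromosomes hitting a missing call are excluded from that extension on
## (cumulative: the span core..x includes every previous site).
.ehhWalk <- function(a, carriers, core, step, limit_index, stop_below = 0) {
    ids <- rep(1L, length(carriers))
    included <- rep(TRUE, length(carriers))
    n0 <- length(carriers)
    idx <- integer(0); val <- numeric(0)
    j <- core
    while ((step > 0 && j < limit_index) || (step < 0 && j > limit_index)) {
        j <- j + step
        al <- a[carriers, j]
        included <- included & !is.na(al)
        n_inc <- sum(included)
        if (n_inc < 2L) { idx <- c(idx, j); val <- c(val, 0); break }
        key <- ids[included] * 2L + al[included]
        ids[included] <- match(key, unique(key))
        cnt <- tabulate(ids[included])
        e <- sum(cnt * (cnt - 1)) / (n_inc * (n_inc - 1))
        idx <- c(idx, j); val <- c(val, e)
        if (e < stop_below) break
    }
    list(index = idx, ehh = val, n_start = n0)
}

#' Extended haplotype homozygosity around a core allele
#'
#' EHH at an extension x is the probability that two randomly drawn
#' chromosomes carrying the core allele are identical over the whole span
#' core..x: sum over distinct extended haplotypes h of C(n_h, 2) /
#' C(n, 2). EHH at the core itself is 1 and (absent missing-call
#' exclusions) is non-increasing with distance.
#'
#' @param hs [HaplotypeSet].
#' @param core core variant index.
#' @param allele core allele (0 or 1).
#' @param direction "both", "left" or "right".
#' @return list of data.frames (\code{left}, \code{right} as requested)
#'   with columns index, pos_bp, ehh; the core point (ehh = 1) is included
#'   in each.
#' @export
ehh <- function(hs, core, allele, direction = c("both", "left", "right")) {
    direction <- match.arg(direction)
    a <- hapAlleles(hs)
    pos <- GenomicRanges::start(variantInfo(hs))
    carriers <- which(!is.na(a[, core]) & a[, core] == allele)
    if (length(carriers) < 2L)
        stop("fewer than 2 chromosomes carry allele ", allele,
             " at core ", core)
    out <- list()
    mk <- function(w) data.frame(index = c(core, w$index),
                                 pos_bp = pos[c(core, w$index)],
                                 ehh = c(1, w$ehh))
    if (direction %in% c("both", "left"))
        out$left <- mk(.ehhWalk(a, carriers, core, -1L, 1L))
    if (direction %in% c("both", "right"))
        out$right <- mk(.ehhWalk(a, carriers, core, 1L, ncol(a)))
    out
}

## trapezoid integral of one EHH walk in bp, truncated at the first of:
## EHH below cutoff, max_extend_bp from the core, chromosome end.
.ihhSide <- function(a, carriers, core, step, pos, max_extend_bp, cutoff) {
    limit <- if (step > 0) length(pos) else 1L
    w <- .ehhWalk(a, carriers, core, step, limit, stop_below = cutoff)
    x <- c(pos[core], pos[w$index])
    y <- c(1, w$ehh)
    reason <- "chrom_end"
    keep <- abs(x - pos[core]) <= max_extend_bp
    if (!all(keep)) {
        x <- x[keep]; y <- y[keep]
        reason <- "boundary"
    } else if (length(y) > 1L && y[length(y)] < cutoff) {
        reason <- "cutoff"
    }
    if (length(x) < 2L) return(list(ihh = 0, reason = reason))
    ihh <- sum(abs(diff(x)) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    list(ihh = ihh, reason = reason)
}

#' Unstandardized integrated haplotype score at one core SNP
#'
#' iHH for an allele is the trapezoid integral (over physical bp, both
#' directions) of its EHH curve, truncated at the first of: EHH below
#' \code{ehh_cutoff}, \code{max_extend_bp} from the core, or the
#' chromosome end. The unstandardized score is
#' iHS = ln(iHH_ancestral / iHH_derived).
#'
#' @param hs [HaplotypeSet].
#' @param core core variant index.
#' @param ancestral ancestral allele at the core (0 or 1).
#' @param max_extend_bp extension boundary from the core position.
#' @param ehh_cutoff EHH truncation threshold.
#' @return list: ihh_anc, ihh_der, ihs (NA with \code{reason} when either
#'   allele has < 2 carriers or zero iHH), freq_der, truncation reasons.
#' @export
ihsUnstandardized <- function(hs, core, ancestral, max_extend_bp = 5e6,
                              ehh_cutoff = 0.05) {
    a <- hapAlleles(hs)
    pos <- GenomicRanges::start(variantInfo(hs))
    derived <- 1L - ancestral
    car_a <- which(!is.na(a[, core]) & a[, core] == ancestral)
    car_d <- which(!is.na(a[, core]) & a[, core] == derived)
    freq_der <- length(car_d) / (length(car_a) + length(car_d))
    if (length(car_a) < 2L || length(car_d) < 2L)
        return(list(ihh_anc = NA_real_, ihh_der = NA_real_, ihs = NA_real_,
                    freq_der = freq_der, reason = "too_few_carriers"))
    int <- function(car) {
        l <- .ihhSide(a, car, core, -1L, pos, max_extend_bp, ehh_cutoff)
        r <- .ihhSide(a, car, core, 1L, pos, max_extend_bp, ehh_cutoff)
        list(ihh = l$ihh + r$ihh, reasons = c(left = l$reason, right = r$reason))
    }
    ia <- int(car_a); id <- int(car_d)
    if (ia$ihh <= 0 || id$ihh <= 0)
        return(list(ihh_anc = ia$ihh, ihh_der = id$ihh, ihs = NA_real_,
                    freq_der = freq_der, reason = "zero_ihh"))
    list(ihh_anc = ia$ihh, ihh_der = id$ihh,
         ihs = log(ia$ihh / id$ihh), freq_der = freq_der,
         reason = "ok", truncation_anc = ia$reasons,
         truncation_der = id$reasons)
}

#' Ancestral-allele assignment by group frequency
#'
#' For every variant, the allele with the higher frequency among the
#' designated group's chromosomes (e.g. the affected/slick group) is
#' labelled ancestral. Exact ties are broken toward the whole-panel major
#' allele (and toward allele 0 if the panel is tied too).
#'
#' @param hs [HaplotypeSet].
#' @param group_rows chromosome (row) indices of the designated group.
#' @return integer vector of ancestral alleles (0/1), one per variant.
#' @export
ancestralByGroupFreq <- function(hs, group_rows) {
    if (length(group_rows) == 0L) stop("group is empty")
    a <- hapAlleles(hs)
    f_grp <- colMeans(a[group_rows, , drop = FALSE] == 1L, na.rm = TRUE)
    f_all <- colMeans(a == 1L, na.rm = TRUE)
    anc <- ifelse(f_grp > 0.5, 1L, ifelse(f_grp < 0.5, 0L,
                  ifelse(f_all > 0.5, 1L, 0L)))
    as.integer(anc)
}

#' Scan |iHS| across core SNPs
#'
#' Runs [ihsUnstandardized()] over a grid of core variants.
#'
#' @param hs [HaplotypeSet].
#' @param ancestral per-variant ancestral alleles (see
#'   [ancestralByGroupFreq()]).
#' @param cores core variant indices (default: every variant).
#' @param max_extend_bp,ehh_cutoff see [ihsUnstandardized()].
#' @param engine "cpp" (compiled scan) or "r" (reference implementation);
#'   both produce identical numbers.
#' @return data.frame: index, variant_id, pos_bp, freq_der, ihh_anc,
#'   ihh_der, ihs.
#' @export
ihsScan <- function(hs, ancestral, cores = NULL, max_extend_bp = 5e6,
                    ehh_cutoff = 0.05, engine = c("cpp", "r")) {
    engine <- match.arg(engine)
    v <- variantInfo(hs)
    if (is.null(cores)) cores <- seq_along(v)
    pos <- GenomicRanges::start(v)
    if (engine == "cpp") {
        r <- .ihsScanCpp(hapAlleles(hs), as.integer(ancestral),
                         as.integer(cores), as.numeric(pos),
                         max_extend_bp, ehh_cutoff)
        res <- data.frame(index = cores, variant_id = names(v)[cores],
                          pos_bp = pos[cores], freq_der = r$freq_der,
                          ihh_anc = r$ihh_anc, ihh_der = r$ihh_der,
                          ihs = r$ihs, stringsAsFactors = FALSE)
    } else {
        rows <- lapply(cores, function(i) {
            r <- ihsUnstandardized(hs, i, ancestral[i], max_extend_bp,
                                   ehh_cutoff)
            data.frame(index = i, variant_id = names(v)[i],
                       pos_bp = pos[i],
                       freq_der = r$freq_der, ihh_anc = r$ihh_anc,
                       ihh_der = r$ihh_der, ihs = r$ihs,
                       stringsAsFactors = FALSE)
        })
        res <- do.call(rbind, rows)
    }
    rownames(res) <- NULL
    res
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Variants are binned by derived-allele frequency into \code{n_bins}
#' equal-width bins; bins with fewer than 5 defined scores are merged with
#' their neighbour. Within each bin the signed score is centered and
#' scaled to unit variance; the headline statistic is its absolute value.
#'
#' @param scan data.frame from [ihsScan()] (needs \code{ihs} and
#'   \code{freq_der}).
#' @param n_bins number of frequency bins (1 = global z-scoring).
#' @return \code{scan} with added columns \code{bin}, \code{ihs_std}
#'   (signed) and \code{abs_ihs_std}.
#' @export
standardizeIHS <- function(scan, n_bins = 20L) {
    ok <- !is.na(scan$ihs)
    if (!any(ok)) stop("no defined iHS scores to standardize")
    edges <- seq(0, 1, length.out = n_bins + 1L)
    bin <- findInterval(scan$freq_der, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    ## merge bins with < 5 defined scores into the nearest lower neighbour
    repeat {
        tab <- table(factor(bin[ok], levels = sort(unique(bin[ok]))))
        small <- names(tab)[tab < 5]
        if (length(small) == 0L || length(tab) == 1L) break
        b <- as.integer(small[1L])
        lv <- sort(unique(bin[ok]))
        tgt <- if (any(lv < b)) max(lv[lv < b]) else min(lv[lv > b])
        bin[bin == b] <- tgt
    }
    z <- rep(NA_real_, nrow(scan))
    for (b in unique(bin[ok])) {
        sel <- ok & bin == b
        mu <- mean(scan$ihs[sel])
        sdv <- stats::sd(scan$ihs[sel])
        z[sel] <- if (is.na(sdv) || sdv == 0) 0 else (scan$ihs[sel] - mu) / sdv
    }
    scan$bin <- bin
    scan$ihs_std <- z
    scan$abs_ihs_std <- abs(z)
    scan
}

#' Centered moving average over a score track
#'
#' Mean over a centered window of \code{window} entries; windows are
#' truncated at the track edges and NAs are dropped from each window's
#' mean (all-NA windows give NA).
#'
#' @param x numeric vector.
#' @param window window size in entries (SNPs).
#' @return numeric vector of the same length.
#' @export
windowAverage <- function(x, window = 30L) {
    n <- length(x)
    if (window > n) stop("window exceeds track length")
    lo <- floor((window - 1) / 2)
    hi <- window - 1L - lo
    xs <- ifelse(is.na(x), 0, x)
    cs <- c(0, cumsum(xs))
    cn <- c(0, cumsum(!is.na(x)))
    i <- seq_len(n)
    a <- pmax(i - lo, 1L); b <- pmin(i + hi, n)
    s <- cs[b + 1L] - cs[a]
    k <- cn[b + 1L] - cn[a]
    ifelse(k > 0, s / k, NA_real_)
}
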