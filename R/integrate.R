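## Evidence integration into a consensus locus, pattern-table parsing and
## summary arithmetic, and the end-to-end pipeline driver.

#' Construct an evidence interval
#'
#' @param track track name (e.g. "gwas", "roh", "ihs", "ibs").
#' @param kind "span" (constrains the consensus by intersection) or
#'   "support" (checked for overlap only).
#' @param interval GRanges (one or more ranges).
#' @param score optional numeric score.
#' @return GRanges with metadata columns track, kind, score.
#' @export
evidenceTrack <- function(track, kind = c("span", "support"), interval,
                          score = NA_real_) {
    kind <- match.arg(kind)
    S4Vectors::mcols(interval) <- S4Vectors::DataFrame(
        track = track, kind = kind,
        score = rep_len(score, length(interval)))
    interval
}

#' Integrate evidence tracks into a consensus locus
#'
#' The consensus interval is the intersection of all span-type evidence
#' intervals; each support-type track is then classified as overlapping
#' or failing. Disjoint span tracks yield an explicit no-consensus result
#' (an empty interval), not an error.
#'
#' @param evidence GRanges built with [evidenceTrack()] (concatenate with
#'   \code{c()}), or a list of them; all on one chromosome.
#' @param all_intersect if TRUE, support tracks also constrain the
#'   intersection (strict mode).
#' @return A \linkS4class{ConsensusLocus}.
#' @export
integrateConsensus <- function(evidence, all_intersect = FALSE) {
    if (is.list(evidence)) evidence <- do.call(c, evidence)
    mc <- S4Vectors::mcols(evidence)
    if (!all(c("track", "kind") %in% colnames(mc)))
        stop("evidence must be built with evidenceTrack()")
    chr <- unique(as.character(GenomicRanges::seqnames(evidence)))
    if (length(chr) != 1L)
        stop("evidence tracks span multiple chromosomes: ",
             paste(chr, collapse = ", "))
    is_span <- mc$kind == "span" | all_intersect
    if (!any(is_span)) stop("at least one span track is required")
    spans <- evidence[is_span]
    ## a multi-range track constrains via its overall footprint
    per_track <- lapply(split(spans, S4Vectors::mcols(spans)$track),
                        function(g) range(GenomicRanges::reduce(g)))
    iv <- intervalIntersect(do.call(c, unname(per_track)))
    supp <- evidence[!is_span]
    supp_names <- unique(S4Vectors::mcols(supp)$track)
    if (length(iv) == 0L) {
        overl <- character(0)
        fail <- supp_names
    } else {
        ok <- vapply(supp_names, function(nm) {
            s <- supp[S4Vectors::mcols(supp)$track == nm]
            length(GenomicRanges::findOverlaps(s, iv)) > 0L
        }, logical(1))
        overl <- supp_names[ok]
        fail <- supp_names[!ok]
    }
    new("ConsensusLocus", interval = iv,
        spanTracks = unique(S4Vectors::mcols(spans)$track),
        supportsOverlapping = as.character(overl),
        supportsFailing = as.character(fail))
}

#' @rdname ConsensusLocus-accessors
#' @export
setGeneric("consensusInterval", function(x) standardGeneric("consensusInterval"))

#' Accessors for ConsensusLocus
#'
#' \code{consensusInterval} returns the consensus GRanges (length 0 when
#' there is no consensus).
#'
#' @param x a ConsensusLocus.
#' @name ConsensusLocus-accessors
#' @export
setMethod("consensusInterval", "ConsensusLocus", function(x) x@interval)

#' Read an evidence-interval table
#'
#' Expects a TSV with columns track, kind ("span"/"support"), chrom,
#' start_bp, end_bp; returns the concatenated evidence GRanges ready for
#' [integrateConsensus()].
#'
#' @param path TSV path.
#' @return GRanges with track/kind/score metadata.
#' @export
readEvidenceTable <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("track", "kind", "chrom", "start_bp", "end_bp")
    if (!all(need %in% colnames(tab)))
        stop("evidence table missing column(s): ",
             paste(setdiff(need, colnames(tab)), collapse = ", "))
    evs <- lapply(seq_len(nrow(tab)), function(i)
        evidenceTrack(tab$track[i], tab$kind[i],
                      genomicInterval(tab$chrom[i], tab$start_bp[i],
                                      tab$end_bp[i])))
    do.call(c, evs)
}

#' Read a haplotype-pattern association table
#'
#' Expects a TSV with columns block_id, start_bp, end_bp,
#' block_distance_bp, haplotype, freq_total, freq_slick, freq_nonslick,
#' p_value (the schema written by [patternAssoc()]).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPatternTable <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("block_id", "start_bp", "end_bp", "block_distance_bp",
              "haplotype", "freq_total", "freq_slick", "freq_nonslick",
              "p_value")
    if (!all(need %in% colnames(tab)))
        stop("pattern table missing column(s): ",
             paste(setdiff(need, colnames(tab)), collapse = ", "))
    tab
}

#' Summary arithmetic over a pattern association table
#'
#' Validates the table invariants (block distance = end - start,
#' frequencies in [0, 1]) and computes the worked-example summaries:
#' longest/shortest block (by block distance), pattern and distinct-block
#' counts, patterns absent from controls, control-associated patterns
#' (control frequency above case frequency), and the pattern with the
#' largest case-over-control frequency increase.
#'
#' @param tab data.frame as returned by [readPatternTable()] /
#'   [patternAssoc()].
#' @return list of summaries.
#' @export
patternTableStats <- function(tab) {
    if (nrow(tab) == 0L) stop("empty pattern table")
    bad <- which(tab$block_distance_bp != tab$end_bp - tab$start_bp)
    if (length(bad))
        stop("block distance != end - start at row ", bad[1L],
             " (block ", tab$block_id[bad[1L]], ")")
    fr <- c(tab$freq_total, tab$freq_slick, tab$freq_nonslick)
    if (any(fr < 0 | fr > 1)) stop("frequency outside [0, 1]")
    i_long <- which.max(tab$block_distance_bp)
    i_short <- which.min(tab$block_distance_bp)
    inc <- tab$freq_slick - tab$freq_nonslick
    i_max <- which.max(inc)
    list(n_patterns = nrow(tab),
         n_distinct_blocks = length(unique(tab$block_id)),
         longest_block_id = tab$block_id[i_long],
         longest_block_span_bp = tab$block_distance_bp[i_long],
         longest_block_pattern_length = nchar(tab$haplotype[i_long]),
         shortest_block_id = tab$block_id[i_short],
         shortest_block_span_bp = tab$block_distance_bp[i_short],
         n_zero_control_patterns = sum(tab$freq_nonslick == 0),
         n_control_associated_patterns = sum(tab$freq_nonslick > tab$freq_slick),
         max_increase_block_id = tab$block_id[i_max],
         max_increase_pattern = tab$haplotype[i_max],
         max_increase = inc[i_max],
         max_increase_freq_slick = tab$freq_slick[i_max],
         max_increase_freq_nonslick = tab$freq_nonslick[i_max])
}

#' Run the full fine-mapping pipeline on a cohort
#'
#' Executes QC, kinship + mixed-model association, ROH frequency
#' scanning, the |iHS| selection scan, and IBS consensus mapping, then
#' integrates the association span and ROH peak (span evidence) with the
#' iHS peak and IBS regions (support evidence) into a consensus locus.
#'
#' @param cohort result of [simulateCohort()], or a list with elements
#'   \code{genotypes} ([GenotypeData]) and \code{haplotypes}
#'   ([HaplotypeSet]).
#' @param assoc_alpha genome-wide significance level; the association
#'   span is the positional range of SNPs with p below
#'   \code{assoc_alpha / n_snps} (Bonferroni).
#' @param roh_L ROH run-length thresholds (SNPs); the peak uses the
#'   smallest, on a track smoothed with a centered 30-SNP window (the
#'   evidence is the elevated-autozygosity plateau, not its noisy
#'   maximum).
#' @param peak_rule fraction-of-max rule for ROH and |iHS| peak regions.
#' @param ihs_step core-SNP stride of the |iHS| scan.
#' @param ibs_w IBS window sizes (SNPs).
#' @param n_perm permutations for the haplotype-pattern stage (0 skips
#'   permutation, keeping asymptotic p-values only).
#' @param out_dir optional directory for TSV/BED outputs and a JSON run
#'   manifest.
#' @return list: \code{assoc}, \code{roh_tracks}, \code{ihs},
#'   \code{ibs_regions}, \code{blocks}, \code{patterns}, \code{evidence},
#'   \code{consensus} (a [ConsensusLocus]), \code{top_snp}.
#' @export
runPipeline <- function(cohort, assoc_alpha = 0.05,
                        roh_L = c(100L, 200L, 300L, 500L),
                        peak_rule = 0.8, ihs_step = 2L,
                        ibs_w = c(5L, 10L, 20L, 50L),
                        n_perm = 0L, out_dir = NULL) {
    gm <- qcFilter(cohort$genotypes)
    hs <- cohort$haplotypes
    keep <- match(names(variantInfo(gm)), names(variantInfo(hs)))
    hs <- subsetVariants(hs, keep)
    s <- sampleInfo(gm)
    chrom <- as.character(GenomicRanges::seqnames(variantInfo(gm)))[1L]
    pos <- GenomicRanges::start(variantInfo(gm))
    y <- as.numeric(s$role == "case")

    ## association span
    K <- kinshipMatrix(gm, mode = "grm")
    assoc <- mixedModelAssoc(gm, y, K)
    thr <- assoc_alpha / nrow(assoc$table)
    sig <- which(!is.na(assoc$table$p) & assoc$table$p < thr)
    top <- assoc$table[which.min(assoc$table$p), ]
    ev <- list()
    if (length(sig))
        ev$gwas <- evidenceTrack("gwas", "span",
            genomicInterval(chrom, min(pos[sig]), max(pos[sig])),
            score = -log10(min(assoc$table$p, na.rm = TRUE)))

    ## ROH frequency peak among affected samples
    slick_ids <- s$sample_id[s$phenotype == "slick"]
    roh_tracks <- list()
    for (L in roh_L) {
        segs <- suppressWarnings(detectROH(gm, L = L))
        roh_tracks[[as.character(L)]] <-
            rohFrequency(segs, slick_ids, variantInfo(gm))
    }
    tr <- roh_tracks[[as.character(min(roh_L))]]
    if (max(tr$frequency) > 0) {
        smoothed <- tr
        smoothed$frequency <- windowAverage(tr$frequency,
                                            min(30L, nrow(tr)))
        ev$roh <- evidenceTrack("roh", "span",
            peakInterval(smoothed, chrom, peak_rule),
            score = max(tr$frequency))
    }

    ## |iHS| selection scan (support); the scan panel is the affected
    ## (slick) chromosomes -- the consanguine group carrying the sweep --
    ## with the ancestral allele taken as the one at higher frequency
    ## among those chromosomes
    case_rows <- which(hapSampleOf(hs) %in%
                       s$sample_id[s$phenotype == "slick"])
    anc <- ancestralByGroupFreq(hs, case_rows)
    hs_slick <- HaplotypeSet(hapAlleles(hs)[case_rows, , drop = FALSE],
                             hapSampleOf(hs)[case_rows], variantInfo(hs))
    cores <- seq(1L, length(pos), by = ihs_step)
    scan <- ihsScan(hs_slick, anc, cores = cores)
    ihs <- NULL
    if (sum(!is.na(scan$ihs)) >= 40L) {
        scan <- standardizeIHS(scan, n_bins = 20L)
        scan$window_mean <- windowAverage(scan$abs_ihs_std, window = 30L)
        ihs <- scan
        wm <- scan$window_mean
        if (any(!is.na(wm)) && max(wm, na.rm = TRUE) > 0) {
            ptr <- data.frame(pos_bp = scan$pos_bp, frequency = wm)
            ev$ihs <- evidenceTrack("ihs", "support",
                peakInterval(ptr, chrom, peak_rule),
                score = max(wm, na.rm = TRUE))
        }
    }

    ## IBS consensus regions (support)
    ctrl_rows <- setdiff(seq_len(nrow(hapAlleles(hs))), case_rows)
    ibs <- consensusRegions(hs, case_rows, ctrl_rows, w_range = ibs_w,
                            f_in_min = 0.4, f_out_max = 0.0)
    if (length(ibs))
        ev$ibs <- evidenceTrack("ibs", "support", ibs,
                                score = S4Vectors::mcols(ibs)$max_in_freq)

    ## haplotype blocks + pattern association near the signal
    blocks <- NULL; patterns <- NULL
    if (length(sig)) {
        lo <- max(1L, min(sig) - 10L); hi <- min(length(pos), max(sig) + 10L)
        sub_gm <- as(gm[lo:hi, ], "GenotypeData")
        blocks <- detectBlocks(sub_gm, max_block_snps = 15L)
        if (nrow(blocks)) {
            blocks$start_index <- blocks$start_index + lo - 1L
            blocks$end_index <- blocks$end_index + lo - 1L
            blocks$block_id <- blocks$start_index
            patterns <- patternAssoc(hs, blocks, y, n_perm = n_perm,
                                     report_threshold_perm_p = 1)
        }
    }

    consensus <- if (length(ev) == 0L) NULL
                 else integrateConsensus(do.call(c, unname(ev)))
    res <- list(genotypes = gm, assoc = assoc, roh_tracks = roh_tracks,
                ihs = ihs, ibs_regions = ibs, blocks = blocks,
                patterns = patterns, evidence = ev,
                consensus = consensus, top_snp = top)
    if (!is.null(out_dir)) .writePipelineOutputs(res, out_dir)
    res
}

.writePipelineOutputs <- function(res, out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    at <- res$assoc$table
    at$neg_log10_p <- -log10(at$p)
    utils::write.table(at, file.path(out_dir, "assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (L in names(res$roh_tracks))
        utils::write.table(res$roh_tracks[[L]],
                           file.path(out_dir, paste0("roh_L", L, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$ihs))
        utils::write.table(res$ihs, file.path(out_dir, "ihs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$patterns))
        utils::write.table(res$patterns, file.path(out_dir, "patterns.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(res$evidence)) {
        ev <- do.call(c, unname(res$evidence))
        S4Vectors::mcols(ev)$name <- S4Vectors::mcols(ev)$track
        writeBed(ev, file.path(out_dir, "evidence.bed"))
    }
    if (!is.null(res$consensus) &&
        length(consensusInterval(res$consensus))) {
        iv <- consensusInterval(res$consensus)
        S4Vectors::mcols(iv)$name <- "consensus"
        writeBed(iv, file.path(out_dir, "consensus.bed"))
    }
    manifest <- list(package = "slickmap",
                     version = as.character(utils::packageVersion("slickmap")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"),
                     n_variants = nrow(res$assoc$table))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(out_dir)
}

#' Round base pairs to Mb for reporting
#'
#' One-decimal Mb presentation; raw bp should always be retained
#' alongside.
#'
#' @param bp base-pair value(s).
#' @return numeric Mb rounded to one decimal.
#' @export
bpToMb <- function(bp) round(bp / 1e6, 1L)
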