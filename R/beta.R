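#' @importFrom stats ks.test
NULL

#' Assign peaks to genes within a TSS window
#'
#' A peak is assigned to a gene when the absolute distance between the
#' peak centroid and the gene's TSS is at most `windowBp` (closed
#' boundary: a centroid exactly `windowBp` away is assigned).  One peak
#' may serve several genes.  Strand is used only to locate the TSS; the
#' distance itself is unsigned.
#'
#' @param x a [PeakSet-class] (or centroid `GRanges`).
#' @param tss TSS annotation from [readTssTable()] (width-1 `GRanges`
#'   with `gene_id`).
#' @param windowBp half-width of the assignment window in bp (default
#'   3000, i.e. "within 3 kb of the TSS").
#' @return data.frame with columns `gene_id`, `peak_id` (index into the
#'   input peaks) and `distance` (bp, `|centroid - tss|`).
#' @export
assignPeaksToGenes <- function(x, tss, windowBp = 3000) {
    stopifnot(windowBp > 0)
    if (!length(tss)) stop("empty TSS annotation")
    cen <- if (is(x, "PeakSet")) peakCentroids(x) else x
    win <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tss),
        IRanges::IRanges(pmax(1L, GenomicRanges::start(tss) - windowBp),
                         GenomicRanges::start(tss) + windowBp))
    hits <- GenomicRanges::findOverlaps(cen, win, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    d <- abs(GenomicRanges::start(cen)[qi] - GenomicRanges::start(tss)[si])
    keep <- d <= windowBp   # clamp at chromosome start can widen windows
    data.frame(gene_id = tss$gene_id[si][keep],
               peak_id = cen$peak_id[qi][keep],
               distance = d[keep], stringsAsFactors = FALSE)
}

#' Distance-decay weight of a peak
#'
#' `exp(-(0.5 + 4 * delta))` with `delta = distance / windowBp`, the
#' regulatory-potential kernel: a peak sitting on the TSS contributes
#' `exp(-0.5)` (~0.607), one at the window edge `exp(-4.5)` (~0.011).
#'
#' @param distance unsigned centroid-TSS distance(s), bp.
#' @param windowBp normalization window (default 3000 bp; 100000
#'   reproduces the original genome-wide normalization of the kernel).
#' @return numeric weight(s) in (0, exp(-0.5)].
#' @export
decayWeight <- function(distance, windowBp = 3000) {
    stopifnot(all(distance >= 0))
    exp(-(0.5 + 4 * distance / windowBp))
}

#' Per-gene regulatory potential
#'
#' Sums the distance-decay weights of all peaks assigned to each gene.
#' Genes listed in `geneIds` but receiving no peak get score 0, so the
#' result covers a full gene universe when one is supplied.
#'
#' @param assignments output of [assignPeaksToGenes()].
#' @param windowBp the same window used for assignment.
#' @param geneIds optional character vector: the full gene universe.
#' @return data.frame with `gene_id`, `score` and `n_peaks`, one row
#'   per gene.
#' @export
regulatoryPotential <- function(assignments, windowBp = 3000,
                                geneIds = NULL) {
    w <- decayWeight(assignments$distance, windowBp)
    agg <- tapply(w, assignments$gene_id, sum)
    npk <- tapply(w, assignments$gene_id, length)
    ids <- if (is.null(geneIds)) names(agg)
           else unique(as.character(geneIds))
    m <- match(ids, names(agg))
    data.frame(gene_id = ids,
               score = ifelse(is.na(m), 0, as.numeric(agg)[m]),
               n_peaks = ifelse(is.na(m), 0L, as.integer(npk)[m]),
               stringsAsFactors = FALSE)
}

#' Call direct targets by rank product
#'
#' Direct-target candidates are differentially expressed genes
#' (`fdr <= fdrCutoff`) with positive regulatory potential.  Candidates
#' are ranked by descending score (`rank_rp`) and by ascending raw
#' p-value (`rank_de`); the normalized rank product
#' `(rank_rp / n) * (rank_de / n)` in (0, 1] orders the calls (smaller
#' is stronger).  Ties are broken by gene id, lexicographically, for
#' determinism.  A gene whose log2 fold change is negative in the
#' mutant is classed `activated` (the wild-type factor promotes it);
#' positive means `repressed`.
#'
#' @param rp per-gene scores from [regulatoryPotential()].
#' @param degTable a [DegTable-class] for the factor's mutant.
#' @param fdrCutoff DEG threshold (default 0.05).
#' @param deRank `"pvalue"` (default) ranks DE significance by raw p;
#'   `"abs_log2fc"` ranks by absolute fold change instead.
#' @return data.frame sorted by ascending `rank_product` with columns
#'   `gene_id`, `score`, `log2fc`, `pvalue`, `fdr`, `rank_rp`,
#'   `rank_de`, `rank_product`, `direction`.  Empty (with a warning)
#'   when there are no candidates.
#' @export
callDirectTargets <- function(rp, degTable, fdrCutoff = 0.05,
                              deRank = c("pvalue", "abs_log2fc")) {
    deRank <- match.arg(deRank)
    r <- degRecords(degTable)
    degs <- r[!is.na(r$fdr) & r$fdr <= fdrCutoff, , drop = FALSE]
    m <- match(degs$gene_id, rp$gene_id)
    score <- ifelse(is.na(m), 0, rp$score[m])
    cand <- degs[score > 0, , drop = FALSE]
    score <- score[score > 0]
    if (!nrow(cand)) {
        warning("no direct-target candidates (no DEG has a peak in window)")
        return(data.frame(gene_id = character(), score = numeric(),
                          log2fc = numeric(), pvalue = numeric(),
                          fdr = numeric(), rank_rp = integer(),
                          rank_de = integer(), rank_product = numeric(),
                          direction = character()))
    }
    n <- nrow(cand)
    rankRp <- integer(n); rankDe <- integer(n)
    rankRp[order(-score, cand$gene_id)] <- seq_len(n)
    deKey <- if (deRank == "pvalue") cand$pvalue else -abs(cand$log2fc)
    rankDe[order(deKey, cand$gene_id)] <- seq_len(n)
    out <- data.frame(gene_id = cand$gene_id, score = score,
                      log2fc = cand$log2fc, pvalue = cand$pvalue,
                      fdr = cand$fdr, rank_rp = rankRp, rank_de = rankDe,
                      rank_product = (rankRp / n) * (rankDe / n),
                      direction = ifelse(cand$log2fc < 0, "activated",
                                         "repressed"),
                      stringsAsFactors = FALSE)
    out[order(out$rank_product, out$gene_id), , drop = FALSE]
}

#' Activator/repressor verdict by one-sided KS test
#'
#' Compares the regulatory-potential score distributions of
#' up-regulated DEGs and of down-regulated DEGs against the background
#' of non-DEG genes with defined scores, each by a one-sided
#' Kolmogorov-Smirnov test with the alternative that DEG scores are
#' stochastically larger (binding concentrates near regulated genes).
#' Verdict: `activator` when only the down-in-mutant set is significant
#' (losing the factor lowers target expression), `repressor` when only
#' the up set is, `dual` when both, `none` otherwise.  Any group with
#' fewer than 5 genes yields `none` with a warning.
#'
#' @param rp full-universe scores from [regulatoryPotential()].
#' @param degTable the factor's [DegTable-class].
#' @param alpha one-tail significance cutoff (default 0.05).
#' @param fdrCutoff DEG definition used to split the universe
#'   (default 0.05).
#' @return list with `p_up`, `p_down`, `stat_up`, `stat_down`,
#'   group sizes and `verdict`.
#' @export
ksFunctionTest <- function(rp, degTable, alpha = 0.05, fdrCutoff = 0.05) {
    r <- degRecords(degTable)
    m <- match(r$gene_id, rp$gene_id)
    score <- rp$score[m]
    ok <- !is.na(score)
    isDeg <- !is.na(r$fdr) & r$fdr <= fdrCutoff
    bg <- score[ok & !isDeg]
    up <- score[ok & isDeg & r$log2fc > 0]
    down <- score[ok & isDeg & r$log2fc < 0]
    res <- list(n_up = length(up), n_down = length(down),
                n_background = length(bg), alpha = alpha,
                stat_up = NA_real_, p_up = NA_real_,
                stat_down = NA_real_, p_down = NA_real_)
    if (length(bg) < 5L || length(up) < 5L || length(down) < 5L) {
        warning("a comparison group has fewer than 5 genes; verdict 'none'")
        res$verdict <- "none"
        return(res)
    }
    ## alternative "less": the CDF of x lies below that of y,
    ## i.e. x stochastically larger
    ku <- suppressWarnings(stats::ks.test(up, bg, alternative = "less"))
    kd <- suppressWarnings(stats::ks.test(down, bg, alternative = "less"))
    res$stat_up <- unname(ku$statistic); res$p_up <- ku$p.value
    res$stat_down <- unname(kd$statistic); res$p_down <- kd$p.value
    sigUp <- res$p_up <= alpha; sigDown <- res$p_down <= alpha
    res$verdict <- if (sigUp && sigDown) "dual"
                   else if (sigDown) "activator"
                   else if (sigUp) "repressor"
                   else "none"
    res
}
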