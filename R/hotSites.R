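#' Count co-occupying transcription factors around focal peaks
#'
#' For every focal peak, counts the distinct other transcription
#' factors in the compendium with at least one peak intersecting the
#' window `[centroid - windowBp, centroid + windowBp]`.  Multiple
#' peaks of one factor in a window count once, and a compendium entry
#' matching the focal factor's label is excluded.  Peaks whose window
#' is co-occupied by at least `hotThreshold` factors are flagged HOT
#' (high-occupancy target) sites.
#'
#' @param focal a [PeakSet-class].
#' @param compendium a [TfCompendium-class].
#' @param windowBp window half-width around each peak center
#'   (default 400 bp).
#' @param hotThreshold minimum distinct co-occupying factors for a HOT
#'   flag (default 15).
#' @param method `"intersect"` (default) counts a factor when any of
#'   its peaks intersects the window; `"center"` requires the factor
#'   peak's centroid to fall inside the window.
#' @return data.frame with `peak_id`, `tf_count`, `is_hot`, one row per
#'   focal peak.
#' @export
tfCooccupancy <- function(focal, compendium, windowBp = 400,
                          hotThreshold = 15,
                          method = c("intersect", "center")) {
    method <- match.arg(method)
    if (!length(tfNames(compendium))) stop("empty compendium")
    cen <- peakCentroids(focal)
    win <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(cen),
        IRanges::IRanges(pmax(1L, GenomicRanges::start(cen) - windowBp),
                         GenomicRanges::start(cen) + windowBp))
    sets <- tfPeakSets(compendium)
    others <- setdiff(names(sets), factorName(focal))
    counts <- integer(length(win))
    for (tf in others) {
        gr <- sets[[tf]]
        if (method == "center") gr <- peakCentroids(gr)
        hit <- unique(S4Vectors::queryHits(
            GenomicRanges::findOverlaps(win, gr)))
        counts[hit] <- counts[hit] + 1L
    }
    data.frame(peak_id = cen$peak_id, tf_count = counts,
               is_hot = counts >= hotThreshold)[order(cen$peak_id), ]
}

#' HOT-site fraction of a peak subset
#'
#' @param records output of [tfCooccupancy()].
#' @param subsetIds peak ids defining the subset (default: all).
#' @return list with `fraction` (share of subset peaks flagged HOT),
#'   `n`, and `cdf` (data.frame of `tf_count` and the cumulative
#'   fraction of peaks with at most that many co-occupying factors).
#' @export
hotFraction <- function(records, subsetIds = records$peak_id) {
    if (!length(subsetIds)) stop("empty peak subset")
    if (!all(subsetIds %in% records$peak_id))
        stop("subsetIds contains unknown peak ids")
    sub <- records[records$peak_id %in% subsetIds, , drop = FALSE]
    tc <- sort(unique(sub$tf_count))
    cdf <- data.frame(tf_count = tc,
                      cum_fraction = vapply(
                          tc, function(k) mean(sub$tf_count <= k), 0))
    list(fraction = mean(sub$is_hot), n = nrow(sub), cdf = cdf)
}
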