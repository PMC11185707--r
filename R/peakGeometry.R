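#' @importFrom stats median runif
#' @importFrom graphics hist
NULL

## Run `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Reduce peaks to centroid positions
#'
#' Each peak is reduced to a single centroid position, the midpoint of
#' its two border coordinates, `floor((start + end) / 2)`.  Centroids
#' are returned grouped by chromosome and sorted ascending; the original
#' peak row is kept in the `peak_id` metadata column.
#'
#' @param x a [PeakSet-class] or a `GRanges`.
#' @return a width-1 `GRanges` of centroids, sorted within chromosome,
#'   with metadata column `peak_id` (index into the input peaks).
#' @examples
#' ps <- PeakSet(data.frame(chrom = "chrI", start = c(100, 7),
#'                          end = c(500, 8)), "TF-A")
#' GenomicRanges::start(peakCentroids(ps))  # 7, 300
#' @export
peakCentroids <- function(x) {
    gr <- if (is(x, "PeakSet")) peaks(x) else x
    pos <- as.integer(floor((GenomicRanges::start(gr) +
                             as.numeric(GenomicRanges::end(gr))) / 2))
    cen <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(pos, width = 1L))
    cen$peak_id <- seq_along(gr)
    ord <- order(as.character(GenomicRanges::seqnames(cen)),
                 GenomicRanges::start(cen))
    cen[ord]
}

## positions: sorted numeric vector; query: numeric vector.
## Minimum |q - r| for each q via findInterval on the sorted reference.
.nnDistSorted <- function(query, ref) {
    i <- findInterval(query, ref)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(ref))
    pmin(abs(query - ref[lo]), abs(query - ref[hi]))
}

#' Nearest-neighbor inter-centroid distances
#'
#' For each query centroid, the distance to the closest reference
#' centroid on the same chromosome (the minimum over the full
#' per-chromosome distance matrix).  Query centroids on chromosomes
#' absent from the reference are skipped and counted.  The
#' distribution's `midpoint` is the 50% point of the empirical
#' cumulative distribution, i.e. the median distance.
#'
#' @param query,reference width-1 centroid `GRanges` (from
#'   [peakCentroids()]) or `PeakSet`s (centroids are computed).
#' @param direction `"A_to_B"` (query vs reference, default),
#'   `"B_to_A"` (roles swapped), or `"union"` (both directions pooled).
#' @return a list with elements `distances` (non-negative bp),
#'   `midpoint` (median, bp), `n`, and `skipped` (query centroids on
#'   chromosomes with no reference centroid).
#' @examples
#' a <- PeakSet(data.frame(chrom = "c", start = c(100, 1000),
#'                         end = c(100, 1000)), "A")
#' b <- PeakSet(data.frame(chrom = "c", start = c(120, 5000),
#'                         end = c(120, 5000)), "B")
#' nearestNeighborDistances(a, b)$distances  # 20, 880
#' @export
nearestNeighborDistances <- function(query, reference,
                                     direction = c("A_to_B", "B_to_A",
                                                   "union")) {
    direction <- match.arg(direction)
    toCen <- function(x) if (is(x, "PeakSet")) peakCentroids(x) else x
    q <- toCen(query); r <- toCen(reference)
    if (direction == "B_to_A") { tmp <- q; q <- r; r <- tmp }
    oneWay <- function(q, r) {
        qs <- split(GenomicRanges::start(q),
                    as.character(GenomicRanges::seqnames(q)))
        rs <- split(GenomicRanges::start(r),
                    as.character(GenomicRanges::seqnames(r)))
        shared <- intersect(names(qs), names(rs))
        if (!length(shared))
            stop("query and reference share no chromosomes")
        d <- unlist(lapply(shared, function(ch)
            .nnDistSorted(qs[[ch]], sort(rs[[ch]]))), use.names = FALSE)
        list(d = d, skipped = sum(lengths(qs[setdiff(names(qs), shared)])))
    }
    res <- if (direction == "union") {
        r1 <- oneWay(q, r); r2 <- oneWay(r, q)
        list(d = c(r1$d, r2$d), skipped = r1$skipped + r2$skipped)
    } else oneWay(q, r)
    list(distances = res$d, midpoint = stats::median(res$d),
         n = length(res$d), skipped = res$skipped)
}

#' Chromosome lengths of the WS245 C. elegans assembly
#'
#' Bundled constants used as the default per-chromosome position ranges
#' for [randomizeCentroids()] when analyzing worm data.
#'
#' @return named integer vector of chromosome lengths (bp).
#' @export
ws245ChromLengths <- function() {
    c(I = 15072434L, II = 15279421L, III = 13783801L,
      IV = 17493829L, V = 20924180L, X = 17718942L)
}

#' Randomize centroid positions within chromosome ranges
#'
#' Reassigns every centroid to an independent uniform position within
#' the supplied per-chromosome range, preserving per-chromosome counts.
#' This is the positional null against which the observed
#' nearest-neighbor distance distribution is compared: co-binding
#' shrinks the observed distribution's midpoint far below the null's.
#'
#' @param centroids width-1 centroid `GRanges`.
#' @param ranges either a named vector of chromosome lengths (range is
#'   then `[1, length]`) or a data.frame with columns `chrom`, `low`,
#'   `high`.
#' @param seed integer seed; the draw is deterministic given the seed
#'   and does not disturb the caller's RNG state.
#' @return a `GRanges` of randomized centroids, same per-chromosome
#'   counts, sorted within chromosome.
#' @export
randomizeCentroids <- function(centroids, ranges, seed) {
    stopifnot(!missing(seed))
    if (is.numeric(ranges) && !is.null(names(ranges)))
        ranges <- data.frame(chrom = names(ranges), low = 1,
                             high = as.numeric(ranges))
    chroms <- as.character(GenomicRanges::seqnames(centroids))
    counts <- table(chroms)
    miss <- setdiff(names(counts), ranges$chrom)
    if (length(miss))
        stop("no randomization range for chromosome(s): ",
             paste(miss, collapse = ", "))
    .withSeed(seed, {
        pieces <- lapply(names(counts), function(ch) {
            n <- counts[[ch]]
            i <- match(ch, ranges$chrom)
            lo <- ranges$low[i]; hi <- ranges$high[i]
            pos <- lo + floor(runif(n) * (hi - lo + 1))
            pos <- pmin(pos, hi)  # guard against runif() == 1
            data.frame(chrom = ch, pos = sort(as.integer(pos)))
        })
        df <- do.call(rbind, pieces)
        GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$pos, width = 1L))
    })
}

#' Observed per-chromosome coordinate ranges of a centroid set
#'
#' Alternative randomization range (minimum to maximum observed
#' position per chromosome) for [randomizeCentroids()].
#'
#' @param centroids width-1 centroid `GRanges`.
#' @return data.frame with columns `chrom`, `low`, `high`.
#' @export
observedRanges <- function(centroids) {
    pos <- split(GenomicRanges::start(centroids),
                 as.character(GenomicRanges::seqnames(centroids)))
    data.frame(chrom = names(pos),
               low = vapply(pos, min, 0),
               high = vapply(pos, max, 0), row.names = NULL)
}

#' Partition two peak sets by overlap
#'
#' Two peaks overlap iff they share at least one base pair (1-based
#' inclusive: `a.start <= b.end` and `b.start <= a.end` on the same
#' chromosome); adjacency is not overlap.  All overlapping pairs are
#' enumerated, each factor's peaks are split into overlapped and
#' exclusive, and `n_events` counts unique overlap events, defined as
#' connected components of the bipartite overlap graph, so a single
#' wide peak overlapping two partners contributes one event.
#'
#' @param a,b [PeakSet-class] objects.
#' @return a list with `n_events`, `pairs` (data.frame of `a_index`,
#'   `b_index`), per-factor overlapped/exclusive index vectors and
#'   counts, and `fractions` (overlapped share of each set).
#' @examples
#' a <- PeakSet(data.frame(chrom = "c", start = 100, end = 500), "A")
#' b <- PeakSet(data.frame(chrom = "c", start = 450, end = 700), "B")
#' overlapPartition(a, b)$n_events  # 1
#' @export
overlapPartition <- function(a, b) {
    ga <- peaks(a); gb <- peaks(b)
    hits <- GenomicRanges::findOverlaps(ga, gb)
    ai <- S4Vectors::queryHits(hits)
    bi <- S4Vectors::subjectHits(hits)
    aOv <- sort(unique(ai)); bOv <- sort(unique(bi))
    nEvents <- if (length(ai)) {
        g <- igraph::graph_from_edgelist(
            cbind(paste0("A", ai), paste0("B", bi)), directed = FALSE)
        igraph::count_components(g)
    } else 0L
    list(n_events = nEvents,
         pairs = data.frame(a_index = ai, b_index = bi),
         a_overlapped = aOv,
         a_exclusive = setdiff(seq_along(ga), aOv),
         b_overlapped = bOv,
         b_exclusive = setdiff(seq_along(gb), bOv),
         counts = c(a_overlapped = length(aOv),
                    a_exclusive = length(ga) - length(aOv),
                    b_overlapped = length(bOv),
                    b_exclusive = length(gb) - length(bOv)),
         fractions = c(a = if (length(ga)) length(aOv) / length(ga) else NA,
                       b = if (length(gb)) length(bOv) / length(gb) else NA))
}

#' Peak width distribution
#'
#' Width is `end - start + 1` (1-based inclusive).
#'
#' @param x a [PeakSet-class].
#' @param binWidth histogram bin width in bp (default 50).
#' @return list with `widths`, `mean`, `median`, and `histogram`
#'   (data.frame of bin midpoints and counts).
#' @export
peakWidthSummary <- function(x, binWidth = 50) {
    w <- GenomicRanges::width(peaks(x))
    if (!length(w)) stop("empty PeakSet: width distribution undefined")
    breaks <- seq(0, max(w) + binWidth, by = binWidth)
    h <- hist(w, breaks = breaks, plot = FALSE)
    list(widths = w, mean = mean(w), median = stats::median(w),
         histogram = data.frame(mid = h$mids, count = h$counts))
}
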