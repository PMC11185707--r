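## Shared helpers: tiny file fixtures and brute-force oracles.

writeTempTsv <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
}

randomPeakDf <- function(n, chroms = c("c1", "c2"), maxPos = 5000,
                         maxWidth = 200) {
    start <- sample.int(maxPos, n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start,
               end = start + sample.int(maxWidth, n, replace = TRUE) - 1L)
}

## O(n*m) overlap enumeration: 1-based inclusive, same chromosome
bruteOverlapPairs <- function(a, b) {
    out <- NULL
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (a$chrom[i] == b$chrom[j] &&
            a$start[i] <= b$end[j] && b$start[j] <= a$end[i])
            out <- rbind(out, c(i, j))
    }
    out
}

## exhaustive per-chromosome matrix minimum of |q - r|
bruteNearest <- function(qdf, rdf) {
    d <- numeric(0)
    for (i in seq_len(nrow(qdf))) {
        same <- rdf$pos[rdf$chrom == qdf$chrom[i]]
        if (length(same)) d <- c(d, min(abs(qdf$pos[i] - same)))
    }
    d
}

## brute-force distinct-TF count within [centroid - w, centroid + w]
bruteTfCounts <- function(centroids, tfList, w) {
    vapply(seq_len(nrow(centroids)), function(i) {
        lo <- centroids$pos[i] - w; hi <- centroids$pos[i] + w
        sum(vapply(tfList, function(d)
            any(d$chrom == centroids$chrom[i] & d$start <= hi &
                d$end >= lo), logical(1)))
    }, integer(1))
}

## small, fast synthetic study for unit tests
smallConfig <- function(seed, ...) {
    args <- list(seed = seed,
                 chromLengths = c(I = 2e6, II = 2e6, III = 2e6),
                 nPeaksA = 400, nPeaksB = 400, nGenes = 400,
                 classCounts = c(coreg_concordant = 15,
                                 coreg_antagonistic = 4,
                                 A_exclusive = 20,
                                 B_exclusive_activated = 12,
                                 B_exclusive_repressed = 14),
                 nDecoyShared = 10, nDecoyA = 10, nDecoyB = 10,
                 nTfs = 20, tfBackgroundPeaks = 40,
                 hotspotTfCount = 16)
    do.call(synthConfig, utils::modifyList(args, list(...)))
}
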