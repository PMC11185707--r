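test_that("co-occupancy counts distinct factors intersecting the window", {
    focal <- PeakSet(data.frame(chrom = "c", start = 9800, end = 10200),
                     "FOCAL")  # centroid 10000, window [9600, 10400]
    cp <- TfCompendium(list(
        TF1 = peaks(PeakSet(data.frame(chrom = "c", start = 9700,
                                       end = 9800), "x")),
        TF2 = peaks(PeakSet(data.frame(chrom = "c", start = 10500,
                                       end = 10600), "x")),
        ## two peaks of the same factor in window count once
        TF3 = peaks(PeakSet(data.frame(chrom = c("c", "c"),
                                       start = c(9650, 10300),
                                       end = c(9660, 10310)), "x")),
        FOCAL = peaks(PeakSet(data.frame(chrom = "c", start = 10000,
                                         end = 10001), "x"))))
    rec <- tfCooccupancy(focal, cp, windowBp = 400, hotThreshold = 2)
    expect_equal(rec$tf_count, 2L)   # TF1 + TF3; TF2 outside; FOCAL excluded
    expect_true(rec$is_hot)
    expect_false(tfCooccupancy(focal, cp, 400, hotThreshold = 3)$is_hot)
    expect_error(tfCooccupancy(focal, TfCompendium(list()), 400), "empty")
})

test_that("HOT flag boundary sits exactly at the threshold", {
    focal <- PeakSet(data.frame(chrom = "c", start = 1000, end = 1000), "F")
    mkCp <- function(k) TfCompendium(setNames(lapply(seq_len(k), function(i)
        peaks(PeakSet(data.frame(chrom = "c", start = 990, end = 1010),
                      "x"))), paste0("TF", seq_len(k))))
    expect_true(tfCooccupancy(focal, mkCp(15))$is_hot)
    expect_false(tfCooccupancy(focal, mkCp(14))$is_hot)
})

test_that("window counting equals brute force on random instances", {
    set.seed(23)
    for (rep in 1:3) {
        fdf <- randomPeakDf(40, maxPos = 20000)
        focal <- PeakSet(fdf, "F")
        cen <- peakCentroids(focal)
        ord <- order(cen$peak_id)   # brute force in peak-id order
        cdf <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(cen))[ord],
            pos = GenomicRanges::start(cen)[ord])
        tfs <- lapply(1:8, function(i) randomPeakDf(25, maxPos = 20000))
        names(tfs) <- paste0("TF", 1:8)
        cp <- TfCompendium(lapply(tfs, function(d)
            peaks(PeakSet(d, "x"))))
        rec <- tfCooccupancy(focal, cp, windowBp = 300, hotThreshold = 4)
        brute <- bruteTfCounts(cdf, tfs, 300)
        expect_equal(rec$tf_count, brute)
        expect_true(all(rec$tf_count <= length(tfs)))
    }
})

test_that("HOT fraction is monotone in the threshold and matches counts", {
    rec <- data.frame(peak_id = 1:10, tf_count = c(0:8, 20),
                      is_hot = c(0:8, 20) >= 5)
    hf <- hotFraction(rec)
    expect_equal(hf$fraction, 0.5)
    fr <- vapply(1:15, function(th)
        mean(rec$tf_count >= th), 0)
    expect_true(all(diff(fr) <= 0))
    expect_equal(hotFraction(rec, subsetIds = 1:4)$fraction, 0)
    expect_error(hotFraction(rec, subsetIds = integer()), "empty")
    expect_error(hotFraction(rec, subsetIds = 99), "unknown")
})

test_that("planted hotspot coverage is recovered", {
    cfg <- smallConfig(seed = 61)
    sim <- simulateStudy(cfg, phenotypes = FALSE)
    rec <- tfCooccupancy(sim$peaksA, sim$compendium,
                         windowBp = 400, hotThreshold = 15)
    hf <- hotFraction(rec)
    h <- cfg$hotspotFraction
    se <- sqrt(h * (1 - h) / peakCount(sim$peaksA))
    expect_lt(abs(hf$fraction - h), 4 * se + 0.01)
    ## planted hotspot peaks are the flagged ones
    expect_gte(mean(rec$is_hot[rec$peak_id %in% sim$hotPeakIds]), 0.99)
})
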