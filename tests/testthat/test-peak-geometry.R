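test_that("centroids are the floored interval midpoint, sorted by position", {
    ps <- PeakSet(data.frame(chrom = c("c1", "c1", "c2"),
                             start = c(100, 7, 42),
                             end = c(500, 8, 42)), "A")
    cen <- peakCentroids(ps)
    expect_equal(GenomicRanges::start(cen), c(7L, 300L, 42L))
    expect_equal(cen$peak_id, c(2L, 1L, 3L))
})

test_that("nearest-neighbor distances match the hand-worked example", {
    a <- PeakSet(data.frame(chrom = "c", start = c(100, 1000),
                            end = c(100, 1000)), "A")
    b <- PeakSet(data.frame(chrom = "c", start = c(120, 5000),
                            end = c(120, 5000)), "B")
    nn <- nearestNeighborDistances(a, b, "A_to_B")
    expect_equal(sort(nn$distances), c(20, 880))
    expect_equal(nn$midpoint, 450)

    self <- nearestNeighborDistances(
        PeakSet(data.frame(chrom = "c", start = 42, end = 42), "A"),
        PeakSet(data.frame(chrom = "c", start = 42, end = 42), "B"))
    expect_equal(self$distances, 0)
    expect_equal(self$midpoint, 0)
})

test_that("query centroids on reference-free chromosomes are skipped", {
    a <- PeakSet(data.frame(chrom = c("c1", "c2"), start = c(10, 10),
                            end = c(10, 10)), "A")
    b <- PeakSet(data.frame(chrom = "c1", start = 15, end = 15), "B")
    nn <- nearestNeighborDistances(a, b)
    expect_equal(nn$n, 1L)
    expect_equal(nn$skipped, 1L)
    c2only <- PeakSet(data.frame(chrom = "c3", start = 1, end = 1), "B")
    expect_error(nearestNeighborDistances(a, c2only), "chromosome")
})

test_that("nearest-neighbor search equals the exhaustive matrix minimum", {
    set.seed(11)
    for (rep in 1:5) {
        qdf <- data.frame(chrom = sample(c("c1", "c2"), 80, TRUE),
                          pos = sample.int(1e5, 80))
        rdf <- data.frame(chrom = sample(c("c1", "c2"), 60, TRUE),
                          pos = sample.int(1e5, 60))
        q <- PeakSet(data.frame(chrom = qdf$chrom, start = qdf$pos,
                                end = qdf$pos), "A")
        r <- PeakSet(data.frame(chrom = rdf$chrom, start = rdf$pos,
                                end = rdf$pos), "B")
        nn <- nearestNeighborDistances(q, r)
        expect_equal(sort(nn$distances), sort(bruteNearest(qdf, rdf)))
    }
})

test_that("randomized centroids respect bounds, seeds and uniformity", {
    cen <- peakCentroids(PeakSet(data.frame(chrom = "c1", start = 500,
                                            end = 500), "A"))
    rng <- data.frame(chrom = "c1", low = 1, high = 1000)
    r1 <- randomizeCentroids(cen, rng, seed = 3)
    expect_true(GenomicRanges::start(r1) >= 1 &&
                GenomicRanges::start(r1) <= 1000)
    r2 <- randomizeCentroids(cen, rng, seed = 3)
    expect_identical(GenomicRanges::start(r1), GenomicRanges::start(r2))
    expect_error(randomizeCentroids(cen, data.frame(chrom = "cX", low = 1,
                                                    high = 10), seed = 1),
                 "c1")

    ## uniformity over the range (Kolmogorov-Smirnov, alpha = 0.001)
    many <- PeakSet(data.frame(chrom = "c1", start = rep(5, 10000),
                               end = rep(5, 10000)), "A")
    rmany <- randomizeCentroids(peakCentroids(many),
                                data.frame(chrom = "c1", low = 1,
                                           high = 1e6), seed = 9)
    pos <- GenomicRanges::start(rmany)
    ks <- suppressWarnings(ks.test(pos, "punif", 1, 1e6))
    expect_gt(ks$p.value, 0.001)
})

test_that("overlap partitioning counts shared-bp pairs, not adjacency", {
    a <- PeakSet(data.frame(chrom = "c", start = 100, end = 500), "A")
    b <- PeakSet(data.frame(chrom = "c", start = 450, end = 700), "B")
    ov <- overlapPartition(a, b)
    expect_equal(nrow(ov$pairs), 1L)
    expect_equal(ov$n_events, 1L)
    expect_equal(unname(ov$counts["a_overlapped"]), 1L)

    adj <- overlapPartition(
        PeakSet(data.frame(chrom = "c", start = 100, end = 200), "A"),
        PeakSet(data.frame(chrom = "c", start = 201, end = 300), "B"))
    expect_equal(nrow(adj$pairs), 0L)
    expect_equal(adj$n_events, 0L)
})

test_that("overlap partitioning equals brute force and is symmetric", {
    set.seed(5)
    for (rep in 1:4) {
        adf <- randomPeakDf(100); bdf <- randomPeakDf(100)
        a <- PeakSet(adf, "A"); b <- PeakSet(bdf, "B")
        ov <- overlapPartition(a, b)
        brute <- bruteOverlapPairs(adf, bdf)
        got <- ov$pairs[order(ov$pairs$a_index, ov$pairs$b_index), ]
        if (is.null(brute)) {
            expect_equal(nrow(got), 0L)
        } else {
            brute <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
            expect_equal(unname(as.matrix(got)), unname(brute))
        }
        ## per-factor counts partition each set
        expect_equal(unname(ov$counts["a_overlapped"] +
                            ov$counts["a_exclusive"]), nrow(adf))
        ## event counting is symmetric
        expect_equal(ov$n_events, overlapPartition(b, a)$n_events)
    }
})

test_that("one peak overlapping several partners is a single event", {
    a <- PeakSet(data.frame(chrom = "c", start = 100, end = 1000), "A")
    b <- PeakSet(data.frame(chrom = "c", start = c(150, 900),
                            end = c(250, 1100)), "B")
    ov <- overlapPartition(a, b)
    expect_equal(nrow(ov$pairs), 2L)
    expect_equal(ov$n_events, 1L)
})

test_that("peak widths use the inclusive convention", {
    ps <- PeakSet(data.frame(chrom = "c", start = 100, end = 499), "A")
    expect_equal(peakWidthSummary(ps)$widths, 400L)
    expect_error(peakWidthSummary(PeakSet(GenomicRanges::GRanges(), "A")),
                 "empty")
})

test_that("planted co-binding pulls the observed midpoint below the null", {
    cfg <- smallConfig(seed = 21)
    sim <- simulateStudy(cfg, compendium = FALSE, phenotypes = FALSE)
    cenA <- peakCentroids(sim$peaksA); cenB <- peakCentroids(sim$peaksB)
    obs <- nearestNeighborDistances(cenA, cenB)$midpoint
    rng <- data.frame(chrom = names(cfg$chromLengths), low = 1,
                      high = as.numeric(cfg$chromLengths))
    nullMids <- vapply(1:20, function(i) {
        ra <- randomizeCentroids(cenA, rng, seed = 100 + 2 * i)
        rb <- randomizeCentroids(cenB, rng, seed = 101 + 2 * i)
        nearestNeighborDistances(ra, rb)$midpoint
    }, 0)
    expect_true(all(nullMids > obs))
})
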