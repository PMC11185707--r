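mkTss <- function(gene_id, chrom, pos, strand = "+") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                 strand = strand)
    gr$gene_id <- gene_id
    gr
}

test_that("peak-to-gene assignment uses a closed centroid window", {
    tss <- mkTss("g1", "c", 10000)
    near <- PeakSet(data.frame(chrom = "c", start = 8000, end = 8000), "A")
    far <- PeakSet(data.frame(chrom = "c", start = 14000, end = 14000), "A")
    edge <- PeakSet(data.frame(chrom = "c", start = 13000, end = 13000), "A")
    expect_equal(assignPeaksToGenes(near, tss, 3000)$distance, 2000L)
    expect_equal(nrow(assignPeaksToGenes(far, tss, 3000)), 0L)
    expect_equal(assignPeaksToGenes(edge, tss, 3000)$distance, 3000L)
    expect_error(assignPeaksToGenes(near, tss[0], 3000), "empty")
})

test_that("decay weights match closed forms to 1e-12 and decrease", {
    expect_equal(decayWeight(0), exp(-0.5), tolerance = 1e-12)
    expect_equal(decayWeight(3000, 3000), exp(-4.5), tolerance = 1e-12)
    expect_equal(decayWeight(0) + decayWeight(1500, 3000),
                 exp(-0.5) + exp(-2.5), tolerance = 1e-12)
    d <- decayWeight(seq(0, 3000, by = 10))
    expect_true(all(diff(d) < 0))
})

test_that("regulatory potential sums weights over assigned peaks", {
    tss <- mkTss(c("g1", "g2"), "c", c(10000, 100000))
    pk <- PeakSet(data.frame(chrom = "c", start = c(10000, 11500, 100000),
                             end = c(10000, 11500, 100000)), "A")
    rp <- regulatoryPotential(assignPeaksToGenes(pk, tss, 3000), 3000,
                              geneIds = c("g1", "g2", "g3"))
    expect_equal(rp$score[rp$gene_id == "g1"], exp(-0.5) + exp(-2.5),
                 tolerance = 1e-12)
    expect_equal(rp$score[rp$gene_id == "g3"], 0)
    expect_equal(rp$n_peaks[rp$gene_id == "g1"], 2L)
})

test_that("rank products match the hand computation with lexicographic ties", {
    rp <- data.frame(gene_id = c("ga", "gb", "gc"), score = c(10, 5, 1),
                     n_peaks = 1L)
    deg <- DegTable(data.frame(gene_id = c("ga", "gb", "gc", "gd"),
                               gene_name = "x",
                               log2fc = c(-1, -2, 3, -4),
                               pvalue = c(0.2, 0.1, 0.3, 1e-6),
                               fdr = c(0.01, 0.01, 0.01, 0.01)))
    calls <- callDirectTargets(rp, deg)
    ## gd is a DEG with no peak in window: excluded
    expect_false("gd" %in% calls$gene_id)
    expect_equal(calls$rank_product[calls$gene_id == "ga"], 2 / 9)
    expect_equal(calls$rank_product[calls$gene_id == "gb"], 2 / 9)
    expect_equal(calls$rank_product[calls$gene_id == "gc"], 1)
    ## tie at 2/9 broken lexicographically: ga first
    expect_equal(calls$gene_id[1:2], c("ga", "gb"))
    expect_equal(calls$direction[calls$gene_id == "gc"], "repressed")
    ## no candidates -> empty result with a warning, not an error
    emptyDeg <- DegTable(data.frame(gene_id = "zz", gene_name = "z",
                                    log2fc = 1, pvalue = 0.001,
                                    fdr = 0.001))
    expect_warning(out <- callDirectTargets(rp, emptyDeg), "no direct")
    expect_equal(nrow(out), 0L)
})

test_that("rank-product order is invariant to monotone score transforms", {
    set.seed(13)
    rp <- data.frame(gene_id = sprintf("g%03d", 1:40),
                     score = runif(40, 0.01, 2), n_peaks = 1L)
    deg <- DegTable(data.frame(gene_id = rp$gene_id, gene_name = "x",
                               log2fc = rnorm(40), pvalue = runif(40),
                               fdr = 0.01))
    base <- callDirectTargets(rp, deg)
    rp2 <- transform(rp, score = score^3)
    rp3 <- transform(rp, score = log1p(score))
    expect_equal(callDirectTargets(rp2, deg)$gene_id, base$gene_id)
    expect_equal(callDirectTargets(rp3, deg)$gene_id, base$gene_id)
})

test_that("every call is a DEG with an assigned peak", {
    cfg <- smallConfig(seed = 41)
    sim <- simulateStudy(cfg, compendium = FALSE, phenotypes = FALSE)
    asg <- assignPeaksToGenes(sim$peaksA, sim$tss, cfg$windowBp)
    rp <- regulatoryPotential(asg, cfg$windowBp, sim$tss$gene_id)
    calls <- callDirectTargets(rp, sim$degA)
    ra <- degRecords(sim$degA)
    degIds <- ra$gene_id[ra$fdr <= 0.05]
    expect_true(all(calls$gene_id %in% degIds))
    expect_true(all(calls$gene_id %in% asg$gene_id))
})

test_that("KS verdicts recognize activators, dual factors and small groups", {
    set.seed(17)
    n <- 400
    ids <- sprintf("g%04d", 1:n)
    score <- runif(n, 0, 0.2)
    rp <- data.frame(gene_id = ids, score = score, n_peaks = 1L)
    ## activator wiring: down-regulated DEGs carry elevated scores
    lfc <- c(rep(-2, 60), rep(2, 30), rnorm(n - 90, 0, 0.1))
    fdr <- c(rep(0.001, 90), rep(0.9, n - 90))
    rp$score[1:60] <- rp$score[1:60] + 0.4
    degAct <- DegTable(data.frame(gene_id = ids, gene_name = ids,
                                  log2fc = lfc, pvalue = fdr, fdr = fdr))
    expect_equal(ksFunctionTest(rp, degAct)$verdict, "activator")
    ## dual wiring: both signs carry elevated scores
    rpDual <- rp; rpDual$score[61:90] <- rpDual$score[61:90] + 0.4
    expect_equal(ksFunctionTest(rpDual, degAct)$verdict, "dual")
    ## under-sized group: verdict none with warning
    degTiny <- DegTable(data.frame(gene_id = ids, gene_name = ids,
                                   log2fc = c(rep(-2, 60), rep(2, 2),
                                              rep(0, n - 62)),
                                   pvalue = fdr, fdr = fdr))
    expect_warning(v <- ksFunctionTest(rp, degTiny), "fewer than 5")
    expect_equal(v$verdict, "none")
})

test_that("planted direct targets are recovered with high sensitivity", {
    cfg <- smallConfig(seed = 43)
    sim <- simulateStudy(cfg, compendium = FALSE, phenotypes = FALSE)
    asg <- assignPeaksToGenes(sim$peaksA, sim$tss, cfg$windowBp)
    rp <- regulatoryPotential(asg, cfg$windowBp, sim$tss$gene_id)
    calls <- callDirectTargets(rp, sim$degA)
    tr <- sim$truth$genes
    planted <- tr$gene_id[tr$class %in% c("coreg_concordant",
                                          "coreg_antagonistic",
                                          "A_exclusive")]
    expect_gte(sum(planted %in% calls$gene_id), 0.9 * length(planted))
})
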