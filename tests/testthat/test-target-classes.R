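## Four-gene worked scenario exercising every class through the real
## machinery (overlap partition, assignment, common-peak pass, LOA).
buildToyScenario <- function() {
    tssPos <- c(gC = 10000, gD = 50000, gB = 90000, gA = 130000)
    tss <- GenomicRanges::GRanges("c", IRanges::IRanges(tssPos, width = 1L),
                                  strand = "+")
    tss$gene_id <- names(tssPos)
    peaksA <- PeakSet(data.frame(
        chrom = "c",
        start = c(9900, 49900, 129900),
        end = c(10300, 50300, 130300)), "A")      # near gC, gD, gA
    peaksB <- PeakSet(data.frame(
        chrom = "c",
        start = c(10000, 50000, 89900),
        end = c(10400, 50400, 90300)), "B")       # near gC, gD, gB
    mk <- function(lfc, p) DegTable(data.frame(
        gene_id = names(tssPos), gene_name = names(tssPos),
        log2fc = lfc, pvalue = p, fdr = p.adjust(p, "BH")))
    degA <- mk(c(-1.5, -1.2, 0.05, -2.0), c(1e-6, 1e-6, 0.8, 1e-6))
    degB <- mk(c(-0.8, 0.9, 1.1, -0.02), c(1e-6, 1e-6, 1e-6, 0.9))
    list(tss = tss, peaksA = peaksA, peaksB = peaksB,
         degA = degA, degB = degB)
}

test_that("the five classes fall out of the evidence combination", {
    s <- buildToyScenario()
    ov <- overlapPartition(s$peaksA, s$peaksB)
    asgA <- assignPeaksToGenes(s$peaksA, s$tss)
    asgB <- assignPeaksToGenes(s$peaksB, s$tss)
    gid <- s$tss$gene_id
    callsA <- callDirectTargets(
        regulatoryPotential(asgA, 3000, gid), s$degA)
    callsB <- callDirectTargets(
        regulatoryPotential(asgB, 3000, gid), s$degB)
    shared <- loaSharedDegs(s$degA, s$degB, 0.01)
    cps <- commonPeakSet(s$peaksA, s$peaksB, ov)
    ra <- degRecords(s$degA)
    callsC <- callDirectTargets(
        regulatoryPotential(assignPeaksToGenes(cps, s$tss), 3000, gid),
        DegTable(ra[ra$gene_id %in% shared$union, ]))
    cl <- classifyTargets(callsA, callsB, callsC, shared, ov,
                          asgA, asgB, s$degA, s$degB)
    got <- setNames(cl$class, cl$gene_id)
    expect_equal(unname(got["gC"]), "coreg_concordant")
    expect_equal(unname(got["gD"]), "coreg_antagonistic")
    expect_equal(unname(got["gB"]), "B_exclusive_repressed")
    expect_equal(unname(got["gA"]), "A_exclusive")
})

test_that("classes partition the called union and co-regulated genes are
           shared DEGs", {
    cfg <- smallConfig(seed = 51)
    sim <- simulateStudy(cfg, compendium = FALSE, phenotypes = FALSE)
    res <- suppressWarnings(runFullAnalysis(
        sim$peaksA, sim$peaksB, sim$degA, sim$degB, sim$tss,
        chromLengths = cfg$chromLengths, nRandomSeeds = 2, seed = 5))
    cl <- res$classified
    allCalled <- unique(c(res$beta$callsA$gene_id, res$beta$callsB$gene_id,
                          res$common$calls$gene_id))
    expect_setequal(cl$gene_id, allCalled)
    expect_equal(anyDuplicated(cl$gene_id), 0L)
    expect_equal(sum(classCounts(cl)), nrow(cl))
    coreg <- cl$gene_id[grepl("^coreg", cl$class)]
    expect_true(all(coreg %in% res$shared$union))
})

test_that("recovered planted targets keep their planted class", {
    cfg <- smallConfig(seed = 53)
    sim <- simulateStudy(cfg, compendium = FALSE, phenotypes = FALSE)
    res <- suppressWarnings(runFullAnalysis(
        sim$peaksA, sim$peaksB, sim$degA, sim$degB, sim$tss,
        chromLengths = cfg$chromLengths, nRandomSeeds = 2, seed = 5))
    tr <- sim$truth$genes
    fiveClasses <- c("coreg_concordant", "coreg_antagonistic",
                     "A_exclusive", "B_exclusive_activated",
                     "B_exclusive_repressed")
    m <- merge(res$classified, tr, by = "gene_id")
    m <- m[m$class.y %in% fiveClasses, ]
    expect_gte(nrow(m), 0.9 * sum(tr$class %in% fiveClasses))
    expect_gte(mean(m$class.x == m$class.y), 0.9)
})
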