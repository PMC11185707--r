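#' @importFrom stats rnorm rbeta
NULL

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module.  The defaults
#' emulate the motivating study's conditions on a scaled-down genome:
#' two factors with mean peak widths 400 and 250 bp, a co-binding
#' fraction of 0.7, a direct-target class mix proportional to the five
#' published class sizes (114:15:238:129:150), a 3 kb
#' regulatory-potential window, HOT-site structure in a 30-factor
#' compendium, and body-length arms with planted Glass' deltas.
#'
#' @param seed mandatory integer master seed; every generator draws
#'   from deterministic offsets of it.
#' @param chromLengths named chromosome lengths in bp (default six
#'   5 Mb chromosomes, a worm-like genome scaled for fast simulation).
#' @param nPeaksA,nPeaksB peaks per factor.
#' @param cobindFraction fraction of A peaks given an overlapping B
#'   partner.
#' @param widthMeanA,widthMeanB mean peak widths (bp).
#' @param widthSdFrac peak-width SD as a fraction of the mean.
#' @param minWidth floor on peak width (bp).
#' @param jitterSd SD (bp) of the partner-centroid offset.
#' @param nGenes genes in the genome.
#' @param minTssSpacing minimum TSS-to-TSS distance (bp); the default
#'   (2 * windowBp) keeps assignment windows of neighbouring genes
#'   disjoint.
#' @param classCounts named counts of planted direct-target genes per
#'   class (`coreg_concordant`, `coreg_antagonistic`, `A_exclusive`,
#'   `B_exclusive_activated`, `B_exclusive_repressed`).
#' @param nDecoyShared,nDecoyA,nDecoyB DEGs without functional peaks
#'   (indirect targets), shared or single-comparison.
#' @param functionalOffsetMax max distance (bp) of a planted functional
#'   centroid from its gene's TSS.
#' @param effectMean,effectSd,minEffect |log2FC| distribution of
#'   planted DEGs (truncated normal).
#' @param altPvalueShape shape `a` of the Beta(a, 1) alternative
#'   p-value model (a < 1 concentrates p near 0).
#' @param nullLog2fcSd SD of null genes' log2FC.
#' @param windowBp regulatory-potential window (bp).
#' @param nTfs,tfBackgroundPeaks compendium size and background peaks
#'   per factor.
#' @param hotspotFraction fraction of focal peaks planted inside a
#'   co-occupancy hotspot.
#' @param hotspotTfCount distinct factors planted at each hotspot.
#' @param controlMean,controlSd control-arm body length (microns).
#' @param armDeltas named planted Glass' deltas, one arm per entry.
#' @param nAnimals animals per arm.
#' @return a classed list (`synthConfig`).
#' @export
synthConfig <- function(seed,
                        chromLengths = c(I = 5e6, II = 5e6, III = 5e6,
                                         IV = 5e6, V = 5e6, X = 5e6),
                        nPeaksA = 2000, nPeaksB = 2000,
                        cobindFraction = 0.7,
                        widthMeanA = 400, widthMeanB = 250,
                        widthSdFrac = 0.2, minWidth = 50,
                        jitterSd = 60,
                        nGenes = 2000, minTssSpacing = 2 * windowBp,
                        classCounts = c(coreg_concordant = 35,
                                        coreg_antagonistic = 5,
                                        A_exclusive = 74,
                                        B_exclusive_activated = 40,
                                        B_exclusive_repressed = 46),
                        nDecoyShared = 30, nDecoyA = 40, nDecoyB = 40,
                        functionalOffsetMax = 1000,
                        effectMean = 2, effectSd = 0.5, minEffect = 0.5,
                        altPvalueShape = 0.005,
                        nullLog2fcSd = 0.2,
                        windowBp = 3000,
                        nTfs = 30, tfBackgroundPeaks = 100,
                        hotspotFraction = 0.2, hotspotTfCount = 20,
                        controlMean = 1000, controlSd = 50,
                        armDeltas = c(mutant_a = 2, mutant_b = 1.5,
                                      null_arm = 0),
                        nAnimals = 30) {
    if (missing(seed)) stop("seed is mandatory")
    cfg <- as.list(environment())
    stopifnot(cobindFraction >= 0, cobindFraction <= 1,
              hotspotFraction >= 0, hotspotFraction <= 1,
              all(classCounts >= 0), nGenes > 0)
    need <- c("coreg_concordant", "coreg_antagonistic", "A_exclusive",
              "B_exclusive_activated", "B_exclusive_repressed")
    if (!all(need %in% names(classCounts)))
        stop("classCounts must name all five classes")
    nPlanted <- sum(classCounts) + nDecoyShared + nDecoyA + nDecoyB
    if (nPlanted > nGenes)
        stop("more planted genes (", nPlanted, ") than genes (",
             nGenes, ")")
    nFuncA <- sum(classCounts[c("coreg_concordant", "coreg_antagonistic",
                                "A_exclusive")])
    nFuncB <- sum(classCounts[c("coreg_concordant", "coreg_antagonistic",
                                "B_exclusive_activated",
                                "B_exclusive_repressed")])
    if (nFuncA > nPeaksA || nFuncB > nPeaksB)
        stop("more functional peaks than the peak budget allows")
    structure(cfg, class = "synthConfig")
}

#' Generate the synthetic genome and TSS annotation
#'
#' TSS positions are drawn uniformly from a per-chromosome grid of
#' slots `minTssSpacing` apart, enforcing the minimum spacing; strands
#' are random.  Deterministic given the config seed.
#'
#' @param config a [synthConfig()].
#' @return width-1 `GRanges` of TSS positions with `gene_id`, as
#'   returned by [readTssTable()].
#' @export
makeGenome <- function(config) {
    .withSeed(config$seed + 101L, {
        slots <- do.call(rbind, lapply(names(config$chromLengths),
            function(ch) {
                L <- config$chromLengths[[ch]]
                pos <- seq(config$minTssSpacing, L - config$minTssSpacing,
                           by = config$minTssSpacing)
                data.frame(chrom = ch, pos = pos)
            }))
        if (nrow(slots) < config$nGenes)
            stop("genome too small for ", config$nGenes,
                 " genes at the configured TSS spacing")
        pick <- slots[sort(sample.int(nrow(slots), config$nGenes)), ]
        gr <- GenomicRanges::GRanges(
            pick$chrom, IRanges::IRanges(as.integer(pick$pos), width = 1L),
            strand = sample(c("+", "-"), config$nGenes, replace = TRUE))
        gr$gene_id <- sprintf("gene%04d", seq_len(config$nGenes))
        gr
    })
}

## draw peak widths
.drawWidths <- function(n, mean, sdFrac, minWidth) {
    w <- round(rnorm(n, mean, mean * sdFrac))
    pmax(as.integer(w), as.integer(minWidth))
}

## uniform background centroids over the genome, proportional to length
.uniformCentroids <- function(n, chromLengths, margin) {
    ch <- sample(names(chromLengths), n, replace = TRUE,
                 prob = as.numeric(chromLengths))
    pos <- vapply(ch, function(c1)
        margin + floor(runif(1) * (chromLengths[[c1]] - 2 * margin)), 0)
    data.frame(chrom = ch, pos = as.integer(pos))
}

.centroidsToPeaks <- function(chrom, pos, widths, chromLengths) {
    half <- widths %/% 2L
    start <- pmax(1L, as.integer(pos - half))
    end <- pmin(as.integer(chromLengths[chrom]),
                as.integer(start + widths - 1L))
    data.frame(chrom = chrom, start = start, end = end)
}

#' Generate the two peak sets with known ground truth
#'
#' Plants one functional peak (per relevant factor) within
#' `functionalOffsetMax` of every designated target gene's TSS:
#' co-regulated genes get an overlapping A/B pair (B centroid = A
#' centroid + Normal(0, jitterSd)), exclusive genes a single-factor
#' peak.  A fraction `cobindFraction` of all A peaks carries a B
#' partner (the planted co-regulated pairs count toward it; the
#' remainder is made up from background peaks).  All remaining peaks
#' are placed uniformly.
#'
#' @param config a [synthConfig()].
#' @param tss genome from [makeGenome()].
#' @return list with `peaksA`, `peaksB` ([PeakSet-class]), and `truth`
#'   (list of `genes` and per-factor peak role tables).
#' @export
makePeaks <- function(config, tss) {
    cl <- config$chromLengths
    .withSeed(config$seed + 202L, {
        cc <- config$classCounts
        classes <- c(rep("coreg_concordant", cc[["coreg_concordant"]]),
                     rep("coreg_antagonistic", cc[["coreg_antagonistic"]]),
                     rep("A_exclusive", cc[["A_exclusive"]]),
                     rep("B_exclusive_activated",
                         cc[["B_exclusive_activated"]]),
                     rep("B_exclusive_repressed",
                         cc[["B_exclusive_repressed"]]),
                     rep("decoy_shared", config$nDecoyShared),
                     rep("decoy_A", config$nDecoyA),
                     rep("decoy_B", config$nDecoyB))
        pick <- sample.int(length(tss), length(classes))
        geneTruth <- data.frame(gene_id = tss$gene_id,
                                class = "null", stringsAsFactors = FALSE)
        geneTruth$class[pick] <- classes
        tssChrom <- as.character(GenomicRanges::seqnames(tss))
        tssPos <- GenomicRanges::start(tss)

        funcCentroid <- function(i)  # near gene i's TSS
            tssPos[i] + sample(seq(-config$functionalOffsetMax,
                                   config$functionalOffsetMax), length(i),
                               replace = TRUE)
        aClasses <- c("coreg_concordant", "coreg_antagonistic",
                      "A_exclusive")
        bOnlyClasses <- c("B_exclusive_activated", "B_exclusive_repressed")
        aIdx <- pick[classes %in% aClasses]
        coregIdx <- pick[classes %in% c("coreg_concordant",
                                        "coreg_antagonistic")]
        bOnlyIdx <- pick[classes %in% bOnlyClasses]

        ## --- factor A: functional peaks then background fill
        aFuncPos <- funcCentroid(aIdx)
        nBgA <- config$nPeaksA - length(aIdx)
        bgA <- .uniformCentroids(nBgA, cl, margin = config$widthMeanA)
        aChrom <- c(tssChrom[aIdx], bgA$chrom)
        aPos <- c(aFuncPos, bgA$pos)
        aRole <- c(rep("functional", length(aIdx)),
                   rep("background", nBgA))
        aGene <- c(tss$gene_id[aIdx], rep(NA_character_, nBgA))

        ## --- partner budget: planted coreg pairs count toward rho
        nPartner <- round(config$cobindFraction * config$nPeaksA)
        coregInA <- match(coregIdx, aIdx)  # coreg rows within A peaks
        nExtra <- max(0L, nPartner - length(coregIdx))
        if (nExtra > nBgA)
            stop("cobindFraction requires more partners than available ",
                 "background A peaks")
        extraRows <- length(aIdx) + seq_len(nExtra)  # first background rows
        partnerRows <- c(coregInA, extraRows)
        aPartnered <- seq_along(aPos) %in% partnerRows

        ## --- factor B: functional (coreg partners + B-exclusive),
        ##     extra partners, background fill
        jit <- function(n) as.integer(round(rnorm(n, 0, config$jitterSd)))
        bCoregPos <- aPos[coregInA] + jit(length(coregInA))
        bExclPos <- funcCentroid(bOnlyIdx)
        bPartnerPos <- aPos[extraRows] + jit(nExtra)
        nBfunc <- length(coregInA) + length(bOnlyIdx) + nExtra
        nBgB <- config$nPeaksB - nBfunc
        if (nBgB < 0)
            stop("nPeaksB too small for functional + partner peaks")
        bgB <- .uniformCentroids(nBgB, cl, margin = config$widthMeanB)
        bChrom <- c(aChrom[coregInA], tssChrom[bOnlyIdx],
                    aChrom[extraRows], bgB$chrom)
        bPos <- c(bCoregPos, bExclPos, bPartnerPos, bgB$pos)
        bRole <- c(rep("functional", length(coregInA)),
                   rep("functional", length(bOnlyIdx)),
                   rep("partner", nExtra), rep("background", nBgB))
        bGene <- c(tss$gene_id[coregIdx], tss$gene_id[bOnlyIdx],
                   rep(NA_character_, nExtra + nBgB))

        wA <- .drawWidths(length(aPos), config$widthMeanA,
                          config$widthSdFrac, config$minWidth)
        wB <- .drawWidths(length(bPos), config$widthMeanB,
                          config$widthSdFrac, config$minWidth)
        bPos <- pmax(bPos, 1L)
        peaksA <- PeakSet(.centroidsToPeaks(aChrom, aPos, wA, cl),
                          "factorA")
        peaksB <- PeakSet(.centroidsToPeaks(bChrom, bPos, wB, cl),
                          "factorB")
        list(peaksA = peaksA, peaksB = peaksB,
             truth = list(
                 genes = geneTruth,
                 peaksA = data.frame(peak_id = seq_along(aPos),
                                     role = aRole, gene_id = aGene,
                                     partnered = aPartnered,
                                     stringsAsFactors = FALSE),
                 peaksB = data.frame(peak_id = seq_along(bPos),
                                     role = bRole, gene_id = bGene,
                                     stringsAsFactors = FALSE)))
    })
}

## signed log2FC per comparison; NA = not DE in that comparison
.classSigns <- function(class) {
    switch(class,
           coreg_concordant = c(A = -1, B = -1),
           coreg_antagonistic = c(A = -1, B = 1),
           A_exclusive = c(A = -1, B = NA),
           B_exclusive_activated = c(A = NA, B = -1),
           B_exclusive_repressed = c(A = NA, B = 1),
           decoy_shared = c(A = -1, B = -1),
           decoy_A = c(A = -1, B = NA),
           decoy_B = c(A = NA, B = -1),
           c(A = NA, B = NA))
}

#' Generate the two mutant-vs-wild-type DEG tables
#'
#' Planted DE genes receive a signed log2 fold change (activated by a
#' factor means negative in that factor's mutant) with magnitude from
#' a truncated normal, and a raw p-value from the peaked Beta(a, 1)
#' alternative; null genes get Uniform(0, 1) p-values and small
#' centered log2 fold changes.  The FDR column is Benjamini-Hochberg
#' over each full table.  P-values are generated directly rather than
#' via simulated counts because the pipeline consumes DE tables, not
#' reads.
#'
#' @param config a [synthConfig()].
#' @param truth truth list from [makePeaks()].
#' @return list with `degA` and `degB` ([DegTable-class]).
#' @export
makeDegTables <- function(config, truth) {
    genes <- truth$genes
    .withSeed(config$seed + 303L, {
        n <- nrow(genes)
        signs <- t(vapply(genes$class, .classSigns, c(A = 0, B = 0)))
        ## decoys get a random sign per significant comparison
        decoy <- grepl("^decoy", genes$class)
        flip <- matrix(sample(c(-1, 1), 2 * n, replace = TRUE), ncol = 2)
        signs[decoy, ] <- signs[decoy, , drop = FALSE] *
            flip[decoy, , drop = FALSE]
        oneTable <- function(colSign, label) {
            isAlt <- !is.na(colSign)
            eff <- pmax(abs(rnorm(n, config$effectMean, config$effectSd)),
                        config$minEffect)
            lfc <- ifelse(isAlt, colSign * eff,
                          rnorm(n, 0, config$nullLog2fcSd))
            p <- ifelse(isAlt, rbeta(n, config$altPvalueShape, 1),
                        runif(n))
            DegTable(data.frame(gene_id = genes$gene_id,
                                gene_name = genes$gene_id,
                                log2fc = lfc, pvalue = p,
                                fdr = stats::p.adjust(p, "BH"),
                                stringsAsFactors = FALSE), label)
        }
        list(degA = oneTable(signs[, "A"], "mutant A vs WT"),
             degB = oneTable(signs[, "B"], "mutant B vs WT"))
    })
}

#' Generate a TF compendium with planted co-occupancy hotspots
#'
#' A fraction `hotspotFraction` of the focal peaks is chosen as
#' hotspot loci; at each, `hotspotTfCount` randomly chosen factors
#' place a peak over the locus, so those focal peaks exceed the HOT
#' threshold.  Every factor additionally scatters
#' `tfBackgroundPeaks` uniform background peaks.
#'
#' @param config a [synthConfig()].
#' @param focal the focal [PeakSet-class] to plant hotspots over.
#' @return list with `compendium` ([TfCompendium-class]) and
#'   `hotPeakIds` (focal peak ids covered by a planted hotspot).
#' @export
makeTfCompendium <- function(config, focal) {
    cl <- config$chromLengths
    .withSeed(config$seed + 404L, {
        cen <- peakCentroids(focal)
        n <- length(cen)
        nHot <- round(config$hotspotFraction * n)
        hotRows <- sort(sample.int(n, nHot))
        tfs <- sprintf("TF%02d", seq_len(config$nTfs))
        perTf <- setNames(vector("list", config$nTfs), tfs)
        for (tf in tfs) {
            bg <- .uniformCentroids(config$tfBackgroundPeaks, cl, 200)
            perTf[[tf]] <- data.frame(chrom = bg$chrom,
                                      start = pmax(1L, bg$pos - 100L),
                                      end = bg$pos + 100L)
        }
        hotChrom <- as.character(GenomicRanges::seqnames(cen))[hotRows]
        hotPos <- GenomicRanges::start(cen)[hotRows]
        for (i in seq_along(hotRows)) {
            who <- sample(tfs, config$hotspotTfCount)
            for (tf in who)
                perTf[[tf]] <- rbind(perTf[[tf]],
                    data.frame(chrom = hotChrom[i],
                               start = pmax(1L, hotPos[i] - 100L),
                               end = hotPos[i] + 100L))
        }
        sets <- lapply(perTf, function(d) peaks(PeakSet(d, "tmp")))
        list(compendium = TfCompendium(sets),
             hotPeakIds = cen$peak_id[hotRows])
    })
}

#' Generate body-length phenotype arms with planted effect sizes
#'
#' The control arm is Normal(controlMean, controlSd); each named arm
#' with planted delta `d` is Normal(controlMean - d * controlSd,
#' controlSd), so smaller bodies carry positive planted deltas.
#'
#' @param config a [synthConfig()].
#' @return list with `phenotypes` (data.frame: `genotype`,
#'   `replicate`, `length_um`) and `truth` (named planted deltas).
#' @export
makePhenotypes <- function(config) {
    .withSeed(config$seed + 505L, {
        arms <- c(control = 0, config$armDeltas)
        rows <- lapply(names(arms), function(g) {
            mu <- config$controlMean - arms[[g]] * config$controlSd
            data.frame(genotype = g,
                       replicate = as.character(seq_len(config$nAnimals)),
                       length_um = rnorm(config$nAnimals, mu,
                                         config$controlSd),
                       stringsAsFactors = FALSE)
        })
        list(phenotypes = do.call(rbind, rows), truth = config$armDeltas)
    })
}

#' Generate a full synthetic study
#'
#' Convenience wrapper running [makeGenome()], [makePeaks()],
#' [makeDegTables()], [makeTfCompendium()] (over factor A's peaks) and
#' [makePhenotypes()] from one config.  Fully deterministic: identical
#' configs give byte-identical outputs.
#'
#' @param config a [synthConfig()].
#' @param compendium,phenotypes set `FALSE` to skip those components.
#' @return list with `config`, `tss`, `peaksA`, `peaksB`, `degA`,
#'   `degB`, `truth`, and optionally `compendium`, `hotPeakIds`,
#'   `phenotypes`, `phenotypeTruth`.
#' @export
simulateStudy <- function(config, compendium = TRUE, phenotypes = TRUE) {
    stopifnot(inherits(config, "synthConfig"))
    tss <- makeGenome(config)
    pk <- makePeaks(config, tss)
    dg <- makeDegTables(config, pk$truth)
    out <- list(config = config, tss = tss, peaksA = pk$peaksA,
                peaksB = pk$peaksB, degA = dg$degA, degB = dg$degB,
                truth = pk$truth)
    if (isTRUE(compendium)) {
        cp <- makeTfCompendium(config, pk$peaksA)
        out$compendium <- cp$compendium
        out$hotPeakIds <- cp$hotPeakIds
    }
    if (isTRUE(phenotypes)) {
        ph <- makePhenotypes(config)
        out$phenotypes <- ph$phenotypes
        out$phenotypeTruth <- ph$truth
    }
    out
}
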