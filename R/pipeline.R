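#' @importFrom stats setNames
NULL

## run a stage, prefixing any error with the stage name
.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full integration analysis
#'
#' Orchestrates the pipeline end to end: peak geometry (centroids,
#' nearest-neighbor distances with a randomized positional null,
#' overlap partition, width summaries), DEG filtering, conditional
#' shared-DEG analysis, per-factor and common-peak direct-target
#' calling with activator/repressor verdicts, target classification,
#' and (when inputs are provided) HOT-site co-occupancy and Glass'
#' effect-size screening.  Every threshold and decision flag is echoed
#' in the returned report.
#'
#' @param peaksA,peaksB [PeakSet-class] objects for the two factors.
#' @param degA,degB [DegTable-class] objects for the corresponding
#'   mutant-vs-wild-type comparisons.
#' @param tss TSS annotation (width-1 `GRanges` with `gene_id`).
#' @param compendium optional [TfCompendium-class] for HOT analysis.
#' @param phenotypes,controlGenotype optional phenotype table (see
#'   [readPhenotypes()]) and its control label.
#' @param fdrCutoff DEG / direct-target FDR (default 0.05).
#' @param loaFdr conditional shared-DEG FDR (default 0.01).
#' @param windowBp regulatory-potential window (default 3000 bp).
#' @param hotWindow,hotThreshold HOT-site parameters (400 bp, 15).
#' @param nnDirection nearest-neighbor direction (default `"A_to_B"`,
#'   factor A being the smaller peak set in the motivating study).
#' @param randomRange `"genome"` randomizes within `chromLengths`;
#'   `"observed"` within each chromosome's observed coordinate range.
#' @param chromLengths named chromosome lengths; defaults to
#'   [ws245ChromLengths()] when `randomRange = "genome"`.
#' @param nRandomSeeds number of randomization replicates averaged for
#'   the null midpoint (default 20).
#' @param seed base seed for the randomized null.
#' @param outDir when given, all result tables are written there as
#'   TSV plus a single JSON run report.
#' @return a list with `report` (parameters, counts, midpoints,
#'   verdicts, class counts) and the full result objects
#'   (`overlap`, `shared`, `callsA`, `callsB`, `callsCommon`,
#'   `classified`, `hot`, `phenotypeScreen`, ...).
#' @export
runFullAnalysis <- function(peaksA, peaksB, degA, degB, tss,
                            compendium = NULL, phenotypes = NULL,
                            controlGenotype = NULL,
                            fdrCutoff = 0.05, loaFdr = 0.01,
                            windowBp = 3000,
                            hotWindow = 400, hotThreshold = 15,
                            nnDirection = "A_to_B",
                            randomRange = c("genome", "observed"),
                            chromLengths = NULL,
                            nRandomSeeds = 20, seed = 1,
                            outDir = NULL) {
    randomRange <- match.arg(randomRange)
    if (is.null(tss)) stop("stage 'beta': TSS annotation is missing")

    ## --- peak geometry
    geom <- .stage("peak_geometry", {
        cenA <- peakCentroids(peaksA); cenB <- peakCentroids(peaksB)
        obs <- nearestNeighborDistances(cenA, cenB,
                                        direction = nnDirection)
        rng <- if (randomRange == "genome") {
            cl <- if (is.null(chromLengths)) ws245ChromLengths()
                  else chromLengths
            data.frame(chrom = names(cl), low = 1, high = as.numeric(cl))
        } else {
            rbind(observedRanges(cenA), observedRanges(cenB))
        }
        if (randomRange == "observed") {
            rng <- do.call(rbind, lapply(split(rng, rng$chrom), function(d)
                data.frame(chrom = d$chrom[1], low = min(d$low),
                           high = max(d$high))))
        }
        nullMids <- vapply(seq_len(nRandomSeeds), function(i) {
            ra <- randomizeCentroids(cenA, rng, seed = seed + 2L * i)
            rb <- randomizeCentroids(cenB, rng, seed = seed + 2L * i + 1L)
            nearestNeighborDistances(ra, rb,
                                     direction = nnDirection)$midpoint
        }, 0)
        list(observed = obs, nullMidpoint = mean(nullMids),
             nullMidpoints = nullMids,
             overlap = overlapPartition(peaksA, peaksB),
             widthsA = peakWidthSummary(peaksA),
             widthsB = peakWidthSummary(peaksB))
    })

    ## --- DEG filtering and conditional overlap
    degCounts <- .stage("deg_filter", list(
        A = filterDegs(degA, fdrCutoff), B = filterDegs(degB, fdrCutoff)))
    shared <- .stage("loa", loaSharedDegs(degA, degB, loaFdr))

    ## --- direct targets per factor and on the common peak set
    geneIds <- tss$gene_id
    beta <- .stage("beta", {
        asgA <- assignPeaksToGenes(peaksA, tss, windowBp)
        asgB <- assignPeaksToGenes(peaksB, tss, windowBp)
        rpA <- regulatoryPotential(asgA, windowBp, geneIds)
        rpB <- regulatoryPotential(asgB, windowBp, geneIds)
        list(asgA = asgA, asgB = asgB, rpA = rpA, rpB = rpB,
             callsA = callDirectTargets(rpA, degA, fdrCutoff),
             callsB = callDirectTargets(rpB, degB, fdrCutoff),
             ksA = ksFunctionTest(rpA, degA, fdrCutoff = fdrCutoff),
             ksB = ksFunctionTest(rpB, degB, fdrCutoff = fdrCutoff))
    })
    common <- .stage("common_peaks", {
        cps <- commonPeakSet(peaksA, peaksB, geom$overlap)
        asgC <- assignPeaksToGenes(cps, tss, windowBp)
        rpC <- regulatoryPotential(asgC, windowBp, geneIds)
        ## common pass: shared DEGs only, statistics from comparison A
        ra <- degRecords(degA)
        sharedDeg <- DegTable(ra[ra$gene_id %in% shared$union, ,
                                 drop = FALSE], "shared (A statistics)")
        calls <- if (nrow(degRecords(sharedDeg)))
            callDirectTargets(rpC, sharedDeg, fdrCutoff)
        else data.frame(gene_id = character())
        list(peaks = cps, asg = asgC, rp = rpC, calls = calls)
    })

    classified <- .stage("target_classes",
        classifyTargets(beta$callsA, beta$callsB, common$calls, shared,
                        geom$overlap, beta$asgA, beta$asgB, degA, degB,
                        fdrCutoff))

    hot <- if (!is.null(compendium)) .stage("hot_sites", {
        recA <- tfCooccupancy(peaksA, compendium, hotWindow, hotThreshold)
        recB <- tfCooccupancy(peaksB, compendium, hotWindow, hotThreshold)
        list(recordsA = recA, recordsB = recB,
             fractionA = hotFraction(recA)$fraction,
             fractionB = hotFraction(recB)$fraction)
    }) else NULL

    phen <- if (!is.null(phenotypes)) .stage("phenotype_stats", {
        if (is.null(controlGenotype))
            stop("controlGenotype is required with phenotypes")
        glassDeltaScreen(phenotypes, controlGenotype)
    }) else NULL

    report <- list(
        parameters = list(fdrCutoff = fdrCutoff, loaFdr = loaFdr,
                          windowBp = windowBp, hotWindow = hotWindow,
                          hotThreshold = hotThreshold,
                          nnDirection = nnDirection,
                          randomRange = randomRange,
                          nRandomSeeds = nRandomSeeds, seed = seed),
        peaks = list(nA = peakCount(peaksA), nB = peakCount(peaksB),
                     meanWidthA = geom$widthsA$mean,
                     meanWidthB = geom$widthsB$mean),
        geometry = list(nnMidpointObserved = geom$observed$midpoint,
                        nnMidpointRandomized = geom$nullMidpoint,
                        overlapEvents = geom$overlap$n_events,
                        overlapCounts = as.list(geom$overlap$counts),
                        overlapFractionA =
                            unname(geom$overlap$fractions["a"]),
                        overlapFractionB =
                            unname(geom$overlap$fractions["b"])),
        degs = list(A_down = degCounts$A$nDown, A_up = degCounts$A$nUp,
                    B_down = degCounts$B$nDown, B_up = degCounts$B$nUp,
                    shared = length(shared$union)),
        targets = list(nCallsA = nrow(beta$callsA),
                       nCallsB = nrow(beta$callsB),
                       nCallsCommon = nrow(common$calls),
                       verdictA = beta$ksA$verdict,
                       verdictB = beta$ksB$verdict,
                       classCounts = as.list(classCounts(classified))),
        hot = if (!is.null(hot)) list(fractionA = hot$fractionA,
                                      fractionB = hot$fractionB),
        phenotypes = if (!is.null(phen))
            setNames(as.list(phen$glass_delta), phen$genotype))

    result <- list(report = report, geometry = geom, shared = shared,
                   beta = beta, common = common, classified = classified,
                   hot = hot, phenotypeScreen = phen)
    if (!is.null(outDir)) .writeOutputs(result, peaksA, peaksB, outDir)
    result
}

.writeOutputs <- function(result, peaksA, peaksB, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name)
        write.table(df, file.path(outDir, name), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    wt(result$shared$shared, "shared_degs.tsv")
    wt(result$beta$callsA, "direct_targets_A.tsv")
    wt(result$beta$callsB, "direct_targets_B.tsv")
    wt(result$common$calls, "direct_targets_common.tsv")
    wt(result$classified, "target_classes.tsv")
    if (!is.null(result$hot)) {
        wt(result$hot$recordsA, "hot_cooccupancy_A.tsv")
        wt(result$hot$recordsB, "hot_cooccupancy_B.tsv")
    }
    if (!is.null(result$phenotypeScreen))
        wt(result$phenotypeScreen, "glass_deltas.tsv")
    jsonlite::write_json(result$report,
                         file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(outDir)
}

#' Recompute the published summary counts from supplementary exports
#'
#' Given a directory of TSV exports of the study's supplementary
#' tables, re-runs the pipeline stages that produced the printed
#' numbers: peak counts and overlap partition (with per-factor
#' fractions), the nearest-neighbor centroid midpoint and its
#' randomized null, DEG counts at FDR <= 0.05 per direction, the
#' conditional shared-DEG count, and the class-table sums.  Expected
#' file names (all TSV): `peaks_A.tsv`, `peaks_B.tsv` (chrom/start/end,
#' 1-based inclusive), `deg_A.tsv`, `deg_B.tsv` (DEG layout),
#' `shared_degs.tsv`, and class tabs
#' `class_A_exclusive.tsv`, `class_coreg_concordant.tsv`,
#' `class_coreg_antagonistic.tsv`, `class_B_exclusive_activated.tsv`,
#' `class_B_exclusive_repressed.tsv`.
#'
#' @param dir directory containing the exports.
#' @param nRandomSeeds randomization replicates for the null midpoint.
#' @param seed base seed for the randomized null.
#' @return list of recomputed quantities.
#' @export
reproducePublishedCounts <- function(dir, nRandomSeeds = 20, seed = 1) {
    pth <- function(f) file.path(dir, f)
    need <- c("peaks_A.tsv", "peaks_B.tsv", "deg_A.tsv", "deg_B.tsv",
              "shared_degs.tsv")
    miss <- need[!file.exists(pth(need))]
    if (length(miss))
        stop("missing supplementary exports in ", dir, ": ",
             paste(miss, collapse = ", "))
    pa <- readPeakTable(pth("peaks_A.tsv"), "SMA-3")
    pb <- readPeakTable(pth("peaks_B.tsv"), "SMA-9")
    ov <- overlapPartition(pa, pb)
    nn <- nearestNeighborDistances(pa, pb)
    nullMids <- vapply(seq_len(nRandomSeeds), function(i) {
        rng <- ws245ChromLengths()
        ra <- randomizeCentroids(peakCentroids(pa), rng, seed + 2L * i)
        rb <- randomizeCentroids(peakCentroids(pb), rng,
                                 seed + 2L * i + 1L)
        nearestNeighborDistances(ra, rb)$midpoint
    }, 0)
    da <- readDegTable(pth("deg_A.tsv"), "sma-3 vs WT")
    db <- readDegTable(pth("deg_B.tsv"), "sma-9 vs WT")
    fa <- filterDegs(da, 0.05); fb <- filterDegs(db, 0.05)
    loa <- loaSharedDegs(da, db, 0.01)
    sd4 <- read.delim(pth("shared_degs.tsv"), header = TRUE)
    classFiles <- c(A_exclusive = "class_A_exclusive.tsv",
                    coreg_concordant = "class_coreg_concordant.tsv",
                    coreg_antagonistic = "class_coreg_antagonistic.tsv",
                    B_exclusive_activated = "class_B_exclusive_activated.tsv",
                    B_exclusive_repressed = "class_B_exclusive_repressed.tsv")
    classSizes <- vapply(classFiles, function(f)
        if (file.exists(pth(f))) nrow(read.delim(pth(f), header = TRUE))
        else NA_integer_, integer(1))
    list(nPeaksA = peakCount(pa), nPeaksB = peakCount(pb),
         overlapEvents = ov$n_events,
         overlapFractionA = unname(ov$fractions["a"]),
         overlapFractionB = unname(ov$fractions["b"]),
         nnMidpoint = nn$midpoint,
         nnMidpointRandomized = mean(nullMids),
         degA_down = fa$nDown, degA_up = fa$nUp,
         degB_down = fb$nDown, degB_up = fb$nUp,
         sharedDegsLoa = length(loa$union),
         sharedDegsListed = nrow(sd4),
         classSizes = classSizes,
         coregTotal = unname(classSizes["coreg_concordant"] +
                             classSizes["coreg_antagonistic"]),
         bExclusiveTotal = unname(classSizes["B_exclusive_activated"] +
                                  classSizes["B_exclusive_repressed"]))
}
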