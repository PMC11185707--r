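#' Build the common (overlapping-pair) peak set
#'
#' Merges each connected component of overlapping A/B peaks into a
#' single interval; these merged regions are the "common occupancy
#' sites" fed to the common-peak direct-target pass.
#'
#' @param a,b [PeakSet-class] objects.
#' @param overlap result of [overlapPartition()] on `a` and `b`
#'   (recomputed when omitted).
#' @return a [PeakSet-class] labelled `"common"`, one interval per
#'   overlap event.
#' @export
commonPeakSet <- function(a, b, overlap = overlapPartition(a, b)) {
    if (!nrow(overlap$pairs))
        return(PeakSet(GenomicRanges::GRanges(), "common"))
    ga <- peaks(a)[overlap$pairs$a_index]
    gb <- peaks(b)[overlap$pairs$b_index]
    merged <- GenomicRanges::reduce(c(GenomicRanges::granges(ga),
                                      GenomicRanges::granges(gb)),
                                    min.gapwidth = 0L)
    PeakSet(merged, "common")
}

## gene ids having >= 1 overlapping A/B pair with both members assigned
## to the gene's window
.genesWithOverlappingPair <- function(overlap, assignA, assignB) {
    if (!nrow(overlap$pairs)) return(character())
    byGeneA <- split(assignA$peak_id, assignA$gene_id)
    byGeneB <- split(assignB$peak_id, assignB$gene_id)
    genes <- intersect(names(byGeneA), names(byGeneB))
    pairKey <- paste(overlap$pairs$a_index, overlap$pairs$b_index)
    has <- vapply(genes, function(g) {
        any(paste(rep(byGeneA[[g]], each = length(byGeneB[[g]])),
                  rep(byGeneB[[g]], times = length(byGeneA[[g]])))
            %in% pairKey)
    }, logical(1))
    genes[has]
}

#' Partition direct targets into co-regulated and exclusive classes
#'
#' Assigns every called direct target to exactly one of five classes.
#' A gene is *co-regulated* only when all three lines of evidence
#' agree: it is a shared DEG from the conditional overlap analysis, at
#' least one overlapping A/B peak pair lies within its assignment
#' window, and the common-peak direct-target pass calls it.
#' Co-regulated genes are *concordant* when the two mutant comparisons'
#' log2 fold changes share a sign, *antagonistic* otherwise.  Any gene
#' failing a co-regulation criterion is demoted to an exclusive class:
#' called for factor A (and not co-regulated) is `A_exclusive`;
#' remaining B calls split by the sign of log2 fold change in the B
#' mutant (`B_exclusive_activated` when down in the mutant,
#' `B_exclusive_repressed` when up).  Common-pass-only leftovers are
#' routed to A- or B-exclusive by which single comparison is
#' significant.  `A_exclusive` is not sign-split, but a warning is
#' emitted for any A-exclusive gene up-regulated in the A mutant.
#'
#' @param callsA,callsB,callsCommon outputs of [callDirectTargets()]
#'   for factor A's peaks, factor B's peaks, and the common peak set.
#' @param sharedDegs result of [loaSharedDegs()].
#' @param overlap result of [overlapPartition()].
#' @param assignA,assignB outputs of [assignPeaksToGenes()] for the
#'   two factors.
#' @param degA,degB the two [DegTable-class] objects (sign evidence).
#' @param fdrCutoff significance used to route ambiguous leftovers
#'   (default 0.05).
#' @return data.frame with `gene_id`, `class`, the two comparisons'
#'   log2 fold changes, and logical evidence columns `shared_deg`,
#'   `overlapping_pair`, `common_call`, `called_A`, `called_B`.
#' @export
classifyTargets <- function(callsA, callsB, callsCommon, sharedDegs,
                            overlap, assignA, assignB, degA, degB,
                            fdrCutoff = 0.05) {
    ra <- degRecords(degA); rb <- degRecords(degB)
    if (!length(intersect(ra$gene_id, rb$gene_id)))
        stop("inconsistent gene universes between the two DEG tables")
    allGenes <- sort(unique(c(callsA$gene_id, callsB$gene_id,
                              callsCommon$gene_id)))
    if (!length(allGenes))
        return(data.frame(gene_id = character(), class = character()))
    ovGenes <- .genesWithOverlappingPair(overlap, assignA, assignB)
    ev <- data.frame(
        gene_id = allGenes,
        called_A = allGenes %in% callsA$gene_id,
        called_B = allGenes %in% callsB$gene_id,
        common_call = allGenes %in% callsCommon$gene_id,
        shared_deg = allGenes %in% sharedDegs$union,
        overlapping_pair = allGenes %in% ovGenes,
        log2fc_A = ra$log2fc[match(allGenes, ra$gene_id)],
        fdr_A = ra$fdr[match(allGenes, ra$gene_id)],
        log2fc_B = rb$log2fc[match(allGenes, rb$gene_id)],
        fdr_B = rb$fdr[match(allGenes, rb$gene_id)],
        stringsAsFactors = FALSE)
    coreg <- ev$shared_deg & ev$overlapping_pair & ev$common_call
    concord <- !is.na(ev$log2fc_A) & !is.na(ev$log2fc_B) &
        sign(ev$log2fc_A) == sign(ev$log2fc_B)
    sigA <- !is.na(ev$fdr_A) & ev$fdr_A <= fdrCutoff
    cls <- character(nrow(ev))
    cls[coreg & concord] <- "coreg_concordant"
    cls[coreg & !concord] <- "coreg_antagonistic"
    aExcl <- !coreg & (ev$called_A | (!ev$called_B & sigA))
    cls[aExcl] <- "A_exclusive"
    rest <- !coreg & !aExcl
    cls[rest] <- ifelse(!is.na(ev$log2fc_B[rest]) & ev$log2fc_B[rest] < 0,
                        "B_exclusive_activated", "B_exclusive_repressed")
    ev$class <- cls
    nUpA <- sum(cls == "A_exclusive" & !is.na(ev$log2fc_A) & ev$log2fc_A > 0)
    if (nUpA)
        warning(nUpA, " A-exclusive gene(s) are up-regulated in the A ",
                "mutant (factor A acting as repressor there)")
    ev[, c("gene_id", "class", "log2fc_A", "log2fc_B", "shared_deg",
           "overlapping_pair", "common_call", "called_A", "called_B")]
}

#' Tabulate target classes
#'
#' @param classified output of [classifyTargets()].
#' @return named integer vector over the five classes.
#' @export
classCounts <- function(classified) {
    lv <- c("coreg_concordant", "coreg_antagonistic", "A_exclusive",
            "B_exclusive_activated", "B_exclusive_repressed")
    table(factor(classified$class, levels = lv))
}
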