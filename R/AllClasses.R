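#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList start end width seqnames
#'   strand findOverlaps granges mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
NULL

#' PeakSet: ChIP-seq peaks for one transcription factor
#'
#' A `PeakSet` bundles the binding intervals called for a single factor
#' with the factor's label.  Coordinates are stored 1-based inclusive
#' (the convention of the supplementary peak tables this package was
#' designed around); BED input is converted at the boundary by
#' [readPeakTable()].
#'
#' @slot factorName single character, e.g. `"SMA-3"`.
#' @slot peaks a [GenomicRanges::GRanges] of binding intervals.
#'
#' @seealso [readPeakTable()], [peakCentroids()], [overlapPartition()]
#' @export
setClass("PeakSet",
         representation(factorName = "character", peaks = "GRanges"))

setValidity("PeakSet", function(object) {
    msg <- character()
    if (length(object@factorName) != 1L || !nzchar(object@factorName))
        msg <- c(msg, "factorName must be a single non-empty string")
    if (length(object@peaks)) {
        if (any(GenomicRanges::start(object@peaks) < 1L))
            msg <- c(msg, "all peak starts must be >= 1")
        if (any(GenomicRanges::width(object@peaks) < 1L))
            msg <- c(msg, "all peaks must satisfy end >= start")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param peaks a `GRanges`, or a data.frame with columns
#'   `chrom`, `start`, `end` (1-based inclusive).
#' @param factorName label of the ChIP-ed factor.
#' @return a [PeakSet-class] object.
#' @examples
#' ps <- PeakSet(data.frame(chrom = "chrI", start = 100, end = 500), "TF-A")
#' peakCount(ps)
#' @export
PeakSet <- function(peaks, factorName) {
    if (is.data.frame(peaks)) {
        stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
        peaks <- GenomicRanges::GRanges(
            seqnames = as.character(peaks$chrom),
            ranges = IRanges::IRanges(start = as.integer(peaks$start),
                                      end = as.integer(peaks$end)))
    }
    new("PeakSet", factorName = as.character(factorName), peaks = peaks)
}

#' @describeIn PeakSet-class number of peaks
#' @param x,object a `PeakSet`
#' @export
peakCount <- function(x) length(x@peaks)

#' @describeIn PeakSet-class the underlying `GRanges`
#' @export
peaks <- function(x) x@peaks

#' @describeIn PeakSet-class the factor label
#' @export
factorName <- function(x) x@factorName

setMethod("show", "PeakSet", function(object) {
    cat("PeakSet for", object@factorName, "with", length(object@peaks),
        "peaks on", length(unique(as.character(
            GenomicRanges::seqnames(object@peaks)))), "chromosome(s)\n")
})

#' DegTable: one mutant-vs-wild-type differential expression comparison
#'
#' Stores per-gene log2 fold change (mutant relative to wild type), raw
#' p-value and FDR for a single pairwise comparison.  Gene ids must be
#' unique within a table.
#'
#' @slot comparison label, e.g. `"sma-3 vs WT"`.
#' @slot records a `DataFrame` with columns `gene_id`, `gene_name`,
#'   `log2fc`, `pvalue`, `fdr`.
#' @seealso [readDegTable()], [filterDegs()], [loaSharedDegs()]
#' @export
setClass("DegTable",
         representation(comparison = "character", records = "DataFrame"))

setValidity("DegTable", function(object) {
    msg <- character()
    req <- c("gene_id", "gene_name", "log2fc", "pvalue", "fdr")
    miss <- setdiff(req, colnames(object@records))
    if (length(miss))
        msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
    else {
        r <- object@records
        if (anyDuplicated(r$gene_id))
            msg <- c(msg, "duplicate gene_id values")
        pv <- r$pvalue[!is.na(r$pvalue)]
        if (length(pv) && (any(pv < 0) || any(pv > 1)))
            msg <- c(msg, "pvalue outside [0, 1]")
        fd <- r$fdr[!is.na(r$fdr)]
        if (length(fd) && any(fd < 0))
            msg <- c(msg, "fdr must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DegTable
#'
#' @param records data.frame (or DataFrame) with columns `gene_id`,
#'   `gene_name`, `log2fc`, `pvalue`, `fdr`.
#' @param comparison label for the comparison.
#' @return a [DegTable-class] object.
#' @examples
#' dt <- DegTable(data.frame(gene_id = "g1", gene_name = "fat-6",
#'                           log2fc = -1.2, pvalue = 0.001, fdr = 0.01),
#'                "mutant vs WT")
#' degRecords(dt)
#' @export
DegTable <- function(records, comparison = "comparison") {
    new("DegTable", comparison = as.character(comparison),
        records = S4Vectors::DataFrame(as.data.frame(records)))
}

#' @describeIn DegTable-class records as a base data.frame
#' @param x,object a `DegTable`
#' @export
degRecords <- function(x) as.data.frame(x@records)

#' @describeIn DegTable-class comparison label
#' @export
comparisonLabel <- function(x) x@comparison

setMethod("show", "DegTable", function(object) {
    cat("DegTable '", object@comparison, "': ", nrow(object@records),
        " genes\n", sep = "")
})

#' TfCompendium: peak sets for many transcription factors
#'
#' A named collection of peak interval sets, one per factor, in the
#' style of the modERN multi-factor compendium, used by
#' [tfCooccupancy()] to count distinct factors bound near a focal peak.
#'
#' @slot peakSets a named `GRangesList`, one element per factor.
#' @seealso [readTfCompendium()], [tfCooccupancy()]
#' @export
setClass("TfCompendium", representation(peakSets = "CompressedGRangesList"))

setValidity("TfCompendium", function(object) {
    nm <- names(object@peakSets)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
        "peakSets must have unique non-empty names"
    else TRUE
})

#' Construct a TfCompendium
#'
#' @param peakSets a named list of `GRanges` (or a named `GRangesList`),
#'   one per transcription factor.
#' @return a [TfCompendium-class] object.
#' @export
TfCompendium <- function(peakSets) {
    if (is.list(peakSets))
        peakSets <- GenomicRanges::GRangesList(peakSets)
    new("TfCompendium", peakSets = peakSets)
}

#' @describeIn TfCompendium-class factor labels
#' @param x,object a `TfCompendium`
#' @export
tfNames <- function(x) names(x@peakSets)

#' @describeIn TfCompendium-class the named `GRangesList` of peak sets
#' @export
tfPeakSets <- function(x) x@peakSets

setMethod("show", "TfCompendium", function(object) {
    cat("TfCompendium with", length(object@peakSets), "factors,",
        sum(lengths(object@peakSets)), "peaks total\n")
})
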