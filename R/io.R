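#' @importFrom utils read.delim write.table
NULL

## Split a delimited text file into a character matrix, keeping track of
## source line numbers so schema errors can name the offending row.
.readDelimMatrix <- function(path, sep = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(list(mat = NULL, lineno = integer()))
    if (is.null(sep))
        sep <- if (grepl("\t", lines[[1L]])) "\t" else if
            (grepl(",", lines[[1L]])) "," else "[[:space:]]+"
    parts <- strsplit(lines, sep)
    list(parts = lapply(parts, trimws), lineno = seq_along(lines))
}

.isNumericField <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a peak table into a PeakSet
#'
#' Reads a three-column peak table (chromosome, start, end).  Two
#' coordinate dialects are supported: `"tsv_1based_inclusive"`, the
#' layout of the supplementary peak tables (both coordinates 1-based and
#' inclusive), and `"bed_0based_halfopen"`, standard BED3.  BED input is
#' converted to the package-internal 1-based inclusive convention at the
#' boundary, so a BED line `chrI 99 500` becomes the interval
#' (chrI, 100, 500).
#'
#' The first row is treated as a header when either coordinate field is
#' non-numeric.  Chromosome labels are kept verbatim (no "chr" prefix
#' normalization).
#'
#' @param path file path.
#' @param factorName label for the ChIP-ed factor.
#' @param dialect `"tsv_1based_inclusive"` (default) or
#'   `"bed_0based_halfopen"`.
#' @return a [PeakSet-class]; row order of the file is preserved.
#' @examples
#' f <- tempfile()
#' writeLines(c("chrom\tstart\tend", "chrI\t100\t500", "chrI\t900\t950"), f)
#' peakCount(readPeakTable(f, "TF-A"))
#' @export
readPeakTable <- function(path, factorName,
                          dialect = c("tsv_1based_inclusive",
                                      "bed_0based_halfopen")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("peak table not found: ", path)
    d <- .readDelimMatrix(path)
    if (is.null(d$parts) || !length(d$parts))
        return(PeakSet(GenomicRanges::GRanges(), factorName))
    rows <- d$parts
    ## header if any coordinate column is non-numeric in the first row
    first <- rows[[1L]]
    if (length(first) >= 3L &&
        (!.isNumericField(first[2L]) || !.isNumericField(first[3L]))) {
        rows <- rows[-1L]
        d$lineno <- d$lineno[-1L]
    }
    if (!length(rows))
        return(PeakSet(GenomicRanges::GRanges(), factorName))
    chrom <- character(length(rows))
    start <- integer(length(rows))
    end <- integer(length(rows))
    for (i in seq_along(rows)) {
        f <- rows[[i]]
        if (length(f) < 3L)
            stop("malformed peak row at line ", d$lineno[i],
                 ": expected 3 fields, got ", length(f))
        if (!.isNumericField(f[2L]) || !.isNumericField(f[3L]))
            stop("non-numeric coordinate at line ", d$lineno[i])
        chrom[i] <- f[1L]
        start[i] <- as.integer(as.numeric(f[2L]))
        end[i] <- as.integer(as.numeric(f[3L]))
    }
    if (dialect == "bed_0based_halfopen") start <- start + 1L
    bad <- which(end < start)
    if (length(bad))
        stop("end < start at line ", d$lineno[bad[1L]])
    if (any(start < 1L))
        stop("start < 1 at line ", d$lineno[which(start < 1L)[1L]])
    PeakSet(data.frame(chrom = chrom, start = start, end = end), factorName)
}

#' Write a PeakSet to a peak table
#'
#' Inverse of [readPeakTable()]; the two dialects round-trip exactly.
#'
#' @param x a [PeakSet-class].
#' @param path output path.
#' @param dialect see [readPeakTable()].
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(x, path,
                           dialect = c("tsv_1based_inclusive",
                                       "bed_0based_halfopen")) {
    dialect <- match.arg(dialect)
    gr <- peaks(x)
    start <- GenomicRanges::start(gr)
    if (dialect == "bed_0based_halfopen") {
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = start - 1L, end = GenomicRanges::end(gr))
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    } else {
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = start, end = GenomicRanges::end(gr))
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

.DEG_ALIASES <- list(
    gene_id = c("gene_id", "geneid", "wormbase geneid", "wormbase_geneid",
                "id", "gene"),
    gene_name = c("gene_name", "name", "public_name", "public name",
                  "gene name", "symbol"),
    log2fc = c("log2fc", "logfc", "log2_fc", "log2 fold change",
               "log fold change", "lfc", "log2foldchange"),
    pvalue = c("pvalue", "p", "p-value", "p_value", "pval", "p value"),
    fdr = c("fdr", "padj", "adjusted p", "qvalue", "adj.p.val"))

#' Read a differential-expression table
#'
#' Reads a per-gene table with gene id, public name, log2 fold change
#' (mutant vs wild type), raw p-value and FDR, resolving columns by
#' header name (common aliases such as `logFC`, `padj` are accepted).
#'
#' @param path file path (TSV or CSV, header required).
#' @param comparison label stored on the result.
#' @return a [DegTable-class].
#' @export
readDegTable <- function(path, comparison = basename(path)) {
    if (!file.exists(path)) stop("DEG table not found: ", path)
    sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    lc <- tolower(trimws(colnames(df)))
    idx <- vapply(.DEG_ALIASES, function(al) {
        m <- which(lc %in% al)
        if (length(m)) m[1L] else NA_integer_
    }, integer(1))
    if (anyNA(idx)) {
        miss <- names(idx)[is.na(idx)]
        stop("missing DEG table column(s): ", paste(miss, collapse = ", "),
             "; accepted header names: ",
             paste(vapply(.DEG_ALIASES[miss], paste, "", collapse = "/"),
                   collapse = "; "))
    }
    out <- df[, idx]
    names(out) <- names(.DEG_ALIASES)
    for (col in c("log2fc", "pvalue", "fdr")) {
        v <- suppressWarnings(as.numeric(out[[col]]))
        bad <- which(is.na(v) & !is.na(out[[col]]) & nzchar(out[[col]]))
        if (length(bad))
            stop("non-numeric ", col, " at data row ", bad[1L])
        out[[col]] <- v
    }
    if (anyDuplicated(out$gene_id))
        stop("duplicated gene_id in DEG table: ",
             out$gene_id[which(duplicated(out$gene_id))[1L]])
    DegTable(out, comparison)
}

#' Write a DegTable
#'
#' @param x a [DegTable-class].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
writeDegTable <- function(x, path) {
    write.table(degRecords(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a TSS annotation
#'
#' Accepts either a four-column table (`gene_id`, `chrom`, `tss`,
#' `strand`) or a GFF3 file, from which the TSS of each `gene` feature
#' is taken as the strand-aware 5' end (the `start` coordinate on `+`,
#' the `end` coordinate on `-`).
#'
#' @param path file path.
#' @return a width-1 [GenomicRanges::GRanges] positioned at each TSS,
#'   with metadata column `gene_id` and the gene's strand.
#' @examples
#' f <- tempfile()
#' writeLines(c("gene_id\tchrom\ttss\tstrand", "g1\tchrI\t10000\t+"), f)
#' readTssTable(f)
#' @export
readTssTable <- function(path) {
    if (!file.exists(path)) stop("TSS annotation not found: ", path)
    head1 <- readLines(path, n = 1L)
    isGff <- grepl("^##gff", head1) ||
        grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)
    if (isGff) {
        gr <- rtracklayer::import(path, format = "gff3")
        gr <- gr[gr$type == "gene"]
        if (!length(gr)) stop("no gene features in GFF3: ", path)
        gid <- if (!is.null(gr$gene_id)) gr$gene_id
               else if (!is.null(gr$ID)) gr$ID
               else if (!is.null(gr$Name)) gr$Name
               else stop("GFF3 gene features lack ID/gene_id/Name")
        str <- as.character(GenomicRanges::strand(gr))
        if (any(str == "*"))
            stop("GFF3 gene feature without strand; TSS is undefined")
        pos <- ifelse(str == "+", GenomicRanges::start(gr),
                      GenomicRanges::end(gr))
        chrom <- as.character(GenomicRanges::seqnames(gr))
    } else {
        sep <- if (grepl("\t", head1)) "\t" else ","
        df <- read.delim(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
        lc <- tolower(trimws(colnames(df)))
        need <- c("gene_id", "chrom", "tss", "strand")
        if (!all(need %in% lc))
            stop("TSS table must have columns: ",
                 paste(need, collapse = ", "))
        df <- df[, match(need, lc)]
        names(df) <- need
        gid <- as.character(df$gene_id)
        chrom <- as.character(df$chrom)
        pos <- suppressWarnings(as.numeric(df$tss))
        if (anyNA(pos)) stop("non-numeric tss at data row ",
                             which(is.na(pos))[1L])
        str <- as.character(df$strand)
    }
    if (any(pos < 1)) stop("tss position < 1")
    if (!all(str %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (anyDuplicated(gid)) stop("duplicated gene_id in TSS annotation")
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(as.integer(pos), width = 1L),
                                 strand = str)
    gr$gene_id <- gid
    gr
}

#' Read a multi-factor peak compendium
#'
#' Accepts either a directory of per-factor peak files (`*.bed` parsed as
#' 0-based half-open, `*.tsv`/`*.txt` as 1-based inclusive; the factor
#' label is the file name without extension) or a single long-format
#' table with columns `tf`, `chrom`, `start`, `end` (1-based inclusive).
#'
#' @param path directory or long-table file path.
#' @return a [TfCompendium-class].
#' @export
readTfCompendium <- function(path) {
    if (dir.exists(path)) {
        files <- list.files(path, pattern = "\\.(bed|tsv|txt)$",
                            full.names = TRUE)
        if (!length(files)) stop("no peak files in compendium dir: ", path)
        sets <- lapply(files, function(f) {
            dia <- if (grepl("\\.bed$", f)) "bed_0based_halfopen"
                   else "tsv_1based_inclusive"
            peaks(readPeakTable(f, "tmp", dialect = dia))
        })
        names(sets) <- sub("\\.[^.]*$", "", basename(files))
        if (anyDuplicated(names(sets)))
            stop("duplicate factor labels in compendium directory")
        return(TfCompendium(sets))
    }
    if (!file.exists(path)) stop("compendium not found: ", path)
    sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE)
    lc <- tolower(trimws(colnames(df)))
    need <- c("tf", "chrom", "start", "end")
    if (!all(need %in% lc))
        stop("long-format compendium must have columns: ",
             paste(need, collapse = ", "))
    df <- df[, match(need, lc)]
    names(df) <- need
    sets <- lapply(split(df, df$tf), function(d)
        peaks(PeakSet(d[, c("chrom", "start", "end")], "tmp")))
    TfCompendium(sets)
}

#' Read phenotype (body length) measurements
#'
#' Reads a table of per-animal body-length measurements with columns
#' `genotype`, `replicate` (optional) and `length_um` (aliases
#' `length`, `body_length` accepted).  Lengths must be positive.
#'
#' @param path CSV/TSV path.
#' @return a data.frame with columns `genotype`, `replicate`,
#'   `length_um`.
#' @export
readPhenotypes <- function(path) {
    if (!file.exists(path)) stop("phenotype table not found: ", path)
    sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE)
    lc <- tolower(trimws(colnames(df)))
    gcol <- which(lc == "genotype")
    lcol <- which(lc %in% c("length_um", "length", "body_length",
                            "body length (um)"))
    if (!length(gcol) || !length(lcol))
        stop("phenotype table needs 'genotype' and 'length_um' columns")
    rcol <- which(lc %in% c("replicate", "rep", "worm"))
    out <- data.frame(
        genotype = as.character(df[[gcol[1L]]]),
        replicate = if (length(rcol)) as.character(df[[rcol[1L]]])
                    else as.character(seq_len(nrow(df))),
        length_um = suppressWarnings(as.numeric(df[[lcol[1L]]])),
        stringsAsFactors = FALSE)
    if (anyNA(out$length_um))
        stop("non-numeric length at data row ",
             which(is.na(out$length_um))[1L])
    if (any(out$length_um <= 0)) stop("body lengths must be positive")
    out
}
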