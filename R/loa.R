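#' @importFrom stats p.adjust
NULL

#' Filter a DEG table at an FDR cutoff
#'
#' Keeps records with `fdr <= fdrCutoff` whose log2 fold change sign
#' matches `direction` (`"up"`: log2fc > 0 in the mutant, `"down"`:
#' log2fc < 0, `"both"`: either).
#'
#' @param x a [DegTable-class].
#' @param fdrCutoff FDR threshold (default 0.05, the conventional
#'   genome-wide cutoff).
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @return a list with `table` (the filtered [DegTable-class]),
#'   `nUp`, `nDown`, `fdrCutoff` and `direction`.
#' @examples
#' dt <- DegTable(data.frame(gene_id = c("g1", "g2", "g3"),
#'                           gene_name = c("a", "b", "c"),
#'                           log2fc = c(-2, 1, -3),
#'                           pvalue = c(1e-4, 1e-3, 0.1),
#'                           fdr = c(0.01, 0.04, 0.2)))
#' filterDegs(dt, 0.05)$nDown  # 1
#' @export
filterDegs <- function(x, fdrCutoff = 0.05,
                       direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    stopifnot(fdrCutoff >= 0, fdrCutoff < 1)
    r <- degRecords(x)
    keep <- !is.na(r$fdr) & r$fdr <= fdrCutoff
    keep <- keep & switch(direction,
                          both = TRUE,
                          up = r$log2fc > 0,
                          down = r$log2fc < 0)
    sub <- r[keep, , drop = FALSE]
    list(table = DegTable(sub, comparisonLabel(x)),
         nUp = sum(sub$log2fc > 0), nDown = sum(sub$log2fc < 0),
         fdrCutoff = fdrCutoff, direction = direction)
}

## BH re-adjustment of comparison-B raw p-values within one stratum.
.strataAdjust <- function(recB, strata) {
    adj <- rep(NA_real_, nrow(recB))
    for (s in unique(strata)) {
        i <- which(strata == s)
        adj[i] <- stats::p.adjust(recB$pvalue[i], method = "BH")
    }
    adj
}

## One directed LOA pass: condition on table `cond`, re-test `test`.
.loaPass <- function(cond, test, stratifyFdr, callFdr) {
    rc <- degRecords(cond); rt <- degRecords(test)
    s1Genes <- rc$gene_id[!is.na(rc$fdr) & rc$fdr <= stratifyFdr]
    ## genes absent from the conditioning table fall into stratum S2
    inS1 <- rt$gene_id %in% s1Genes
    strata <- ifelse(inS1, "S1", "S2")
    adj <- .strataAdjust(rt, strata)
    shared <- rt$gene_id[inS1 & !is.na(adj) & adj <= callFdr]
    list(shared = shared,
         strataSizes = c(S1 = sum(inS1), S2 = sum(!inS1)),
         nCondOnly = sum(!(s1Genes %in% rt$gene_id)),
         adjusted = data.frame(gene_id = rt$gene_id, stratum = strata,
                               pvalue = rt$pvalue, stratum_fdr = adj))
}

#' Luperchio overlap analysis: conditional shared DEGs
#'
#' Identifies genes differentially expressed in both of two
#' mutant-vs-wild-type comparisons without paying the full genome-wide
#' multiplicity price twice.  Genes significant in the first comparison
#' (FDR at or below `stratifyFdr`) define stratum S1; within S1 (and,
#' separately, its complement S2) the second comparison's raw p-values
#' are re-adjusted by Benjamini-Hochberg.  Shared DEGs are the S1 genes
#' whose stratum-adjusted statistic is at or below `callFdr`.  The
#' symmetric pass (roles swapped) is also run; the default shared set
#' is the union of the two passes.
#'
#' Genes present in only one table are assigned to stratum S2 of the
#' pass that re-tests that table (they cannot be conditioned on), and
#' their count is reported.
#'
#' @param tableA,tableB [DegTable-class] objects sharing (part of) a
#'   gene universe; both must carry raw p-values.
#' @param fdrConditional the single FDR used both to stratify and to
#'   call, following the one-threshold description of the procedure
#'   (default 0.01).
#' @param stratifyFdr,callFdr override the stratification / final-call
#'   thresholds independently; both default to `fdrConditional`.
#' @return a list with `shared` (data.frame of union shared genes with
#'   both comparisons' log2fc, fdr, and a `concordant` sign flag),
#'   `union`, `intersection` (gene-id vectors), and per-pass detail
#'   (`passAB`, `passBA`).
#' @examples
#' a <- DegTable(data.frame(gene_id = paste0("g", 1:4), gene_name = "x",
#'                          log2fc = -1, pvalue = c(1e-4, .15, 4e-4, .4),
#'                          fdr = c(0.001, 0.2, 0.004, 0.5)))
#' b <- DegTable(data.frame(gene_id = paste0("g", 1:4), gene_name = "x",
#'                          log2fc = -1, pvalue = c(0.002, .8, 0.004, .9),
#'                          fdr = c(0.01, 0.9, 0.02, 0.95)))
#' loaSharedDegs(a, b)$union  # g1, g3
#' @export
loaSharedDegs <- function(tableA, tableB, fdrConditional = 0.01,
                          stratifyFdr = fdrConditional,
                          callFdr = fdrConditional) {
    ra <- degRecords(tableA); rb <- degRecords(tableB)
    if (anyNA(ra$pvalue) || anyNA(rb$pvalue))
        stop("LOA requires raw p-values in both tables")
    common <- intersect(ra$gene_id, rb$gene_id)
    if (!length(common))
        stop("gene universes of the two tables are disjoint")
    ab <- .loaPass(tableA, tableB, stratifyFdr, callFdr)
    ba <- .loaPass(tableB, tableA, stratifyFdr, callFdr)
    un <- sort(union(ab$shared, ba$shared))
    it <- sort(intersect(ab$shared, ba$shared))
    ia <- match(un, ra$gene_id); ib <- match(un, rb$gene_id)
    shared <- data.frame(
        gene_id = un,
        gene_name = ifelse(is.na(ia), rb$gene_name[ib], ra$gene_name[ia]),
        log2fc_A = ra$log2fc[ia], fdr_A = ra$fdr[ia],
        log2fc_B = rb$log2fc[ib], fdr_B = rb$fdr[ib],
        stringsAsFactors = FALSE)
    shared$concordant <- sign(shared$log2fc_A) == sign(shared$log2fc_B)
    list(shared = shared, union = un, intersection = it,
         passAB = ab, passBA = ba,
         thresholds = c(stratifyFdr = stratifyFdr, callFdr = callFdr))
}
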