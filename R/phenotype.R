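#' @importFrom stats sd t.test
NULL

#' Glass' effect size for a body-length comparison
#'
#' `delta = (mean(control) - mean(treatment)) / sd(control)` with the
#' sample (n-1) standard deviation, so a treatment group with smaller
#' bodies than control gives a positive delta.  The normalized mean is
#' `mean(treatment) / mean(control)` (control = 1).
#'
#' @param treatment,control numeric measurement vectors (e.g. body
#'   lengths in microns).
#' @param flipSign set `TRUE` to report
#'   `(mean(treatment) - mean(control)) / sd(control)` instead.
#' @param welch also compute a two-sided Welch t-test p (default TRUE).
#' @return list with `delta`, `n_treatment`, `n_control`,
#'   `mean_treatment`, `mean_control`, `sd_control`,
#'   `normalized_mean`, and optionally `welch_p`.
#' @examples
#' glassDelta(rep(900, 3), c(950, 1000, 1050))$delta  # 2
#' @export
glassDelta <- function(treatment, control, flipSign = FALSE, welch = TRUE) {
    if (length(control) < 2L) stop("need >= 2 control measurements")
    if (length(treatment) < 1L) stop("need >= 1 treatment measurement")
    sdc <- stats::sd(control)
    if (sdc == 0) stop("control standard deviation is zero")
    d <- (mean(control) - mean(treatment)) / sdc
    if (flipSign) d <- -d
    out <- list(delta = d,
                n_treatment = length(treatment),
                n_control = length(control),
                mean_treatment = mean(treatment),
                mean_control = mean(control),
                sd_control = sdc,
                normalized_mean = mean(treatment) / mean(control))
    if (welch && length(treatment) >= 2L)
        out$welch_p <- stats::t.test(treatment, control)$p.value
    out
}

#' Glass' effect-size screen across genotypes
#'
#' Computes [glassDelta()] for every genotype in a phenotype table
#' against the named control genotype.
#'
#' @param phenotypes data.frame from [readPhenotypes()] (columns
#'   `genotype`, `length_um`).
#' @param control control genotype label (must be present).
#' @param flipSign see [glassDelta()].
#' @return data.frame with one row per non-control genotype:
#'   `genotype`, `n`, `mean_um`, `normalized_mean`, `glass_delta`,
#'   `welch_p`.
#' @export
glassDeltaScreen <- function(phenotypes, control, flipSign = FALSE) {
    if (!control %in% phenotypes$genotype)
        stop("control genotype '", control, "' not in phenotype table")
    ctrl <- phenotypes$length_um[phenotypes$genotype == control]
    others <- setdiff(unique(phenotypes$genotype), control)
    rows <- lapply(others, function(g) {
        tr <- phenotypes$length_um[phenotypes$genotype == g]
        gd <- glassDelta(tr, ctrl, flipSign = flipSign)
        data.frame(genotype = g, n = gd$n_treatment,
                   mean_um = gd$mean_treatment,
                   normalized_mean = gd$normalized_mean,
                   glass_delta = gd$delta,
                   welch_p = if (is.null(gd$welch_p)) NA_real_
                             else gd$welch_p,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
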