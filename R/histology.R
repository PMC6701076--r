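#' Ordinal tumor-infiltrating lymphocyte (TIL) score
#'
#' Bins TIL counts per 10 high-power fields into the 0-3 scale: 0 for
#' fewer than 1 TIL, 1 for 1-15, 2 for more than 15 but fewer than 215,
#' and 3 for more than 215. A count of exactly 215 falls in bin 2 (the
#' conservative lower bin; the published bins leave that point open).
#'
#' @param count non-negative TIL count(s) per 10 HPF (vectorized).
#' @return integer score(s) in 0-3.
#' @examples
#' tilScore(c(0, 15, 16, 100, 300))  # 0 1 2 2 3
#' @export
tilScore <- function(count) {
    if (any(count < 0)) stop("TIL count must be non-negative",
                             call. = FALSE)
    ifelse(count < 1, 0L,
           ifelse(count <= 15, 1L,
                  ifelse(count <= 215, 2L, 3L)))
}

#' Ordinal peritumoral lymphocyte aggregate score
#'
#' 0 for no aggregates, 1 for a few (up to 5), 2 for more than 5.
#' Exactly 5 aggregates score 1.
#'
#' @param n non-negative aggregate count(s) (vectorized).
#' @return integer score(s) in 0-2.
#' @examples
#' aggregateScore(c(0, 3, 8))  # 0 1 2
#' @export
aggregateScore <- function(n) {
    if (any(n < 0)) stop("aggregate count must be non-negative",
                         call. = FALSE)
    ifelse(n == 0, 0L, ifelse(n <= 5, 1L, 2L))
}

#' Ordinal immunostain score (0-2+ scale)
#'
#' 0 for no staining, 1+ for faint staining (positive but below the low
#' cutpoint), 2+ for moderate or strong staining. The published scale is
#' qualitative; the percent-based default cutpoint of 10\% positive cells
#' is this package's operationalization and is configurable.
#'
#' @param pctPositive percent positive cells in [0, 100] (vectorized).
#' @param lowCut boundary between 1+ and 2+ (default 10).
#' @return integer score(s) in 0-2.
#' @export
stainScore <- function(pctPositive, lowCut = 10) {
    if (any(pctPositive < 0 | pctPositive > 100))
        stop("percent positive must lie in [0, 100]", call. = FALSE)
    ifelse(pctPositive == 0, 0L,
           ifelse(pctPositive < lowCut, 1L, 2L))
}

#' Mismatch-repair protein status and sample dMMR call
#'
#' A protein is scored positive when at least \code{threshold} percent of
#' cells stain (default 10\%), lost otherwise; the sample is deficient-MMR
#' (dMMR) when at least one protein is lost, else proficient (pMMR).
#'
#' @param pctPositive named numeric vector, percent positive cells per
#'   protein (e.g. \code{c(MLH1 = 12, MSH2 = 50)}).
#' @param threshold positivity threshold in percent (default 10).
#' @return list with \code{proteins} (named \code{positive}/\code{lost}
#'   vector) and \code{status} (\code{pMMR}/\code{dMMR}).
#' @examples
#' mmrStatus(c(MLH1 = 2, MSH2 = 50))  # MLH1 lost -> dMMR
#' @export
mmrStatus <- function(pctPositive, threshold = 10) {
    if (!length(pctPositive))
        stop("at least one protein must be measured", call. = FALSE)
    prot <- ifelse(pctPositive >= threshold, "positive", "lost")
    names(prot) <- names(pctPositive)
    list(proteins = prot,
         status = if (any(prot == "lost")) "dMMR" else "pMMR")
}

#' Bethesda marker-panel MSI call
#'
#' Applies the Bethesda convention to the five-marker panel (dinucleotide
#' repeats D2S123, D5S346, D17S250 and mononucleotide repeats BAT25,
#' BAT26): MSI-H with two or more unstable markers, MSI-L with exactly
#' one, MSS with none.
#'
#' @param markerUnstable logical (or 0/1) vector of exactly five
#'   instability flags, in panel order.
#' @return \code{"MSI-H"}, \code{"MSI-L"}, or \code{"MSS"}.
#' @examples
#' msiPanel(c(FALSE, FALSE, FALSE, TRUE, TRUE))  # MSI-H
#' @export
msiPanel <- function(markerUnstable) {
    if (length(markerUnstable) != 5 || anyNA(markerUnstable))
        stop("exactly five marker flags are required", call. = FALSE)
    k <- sum(as.logical(markerUnstable))
    if (k >= 2) "MSI-H" else if (k == 1) "MSI-L" else "MSS"
}

#' Dichotomize TIL and TAN load at the cohort medians
#'
#' High when the percent load strictly exceeds the median (defaults: 5\%
#' TILs, 2\% CD66b+ TANs); a value equal to the median goes to low, for
#' determinism.
#'
#' @param tilPct,tanPct percent loads (vectorized).
#' @param tilMedian,tanMedian dichotomization medians.
#' @return data.frame with \code{til_group} and \code{tan_group}
#'   (\code{high}/\code{low}).
#' @export
tilTanGroups <- function(tilPct, tanPct, tilMedian = 5, tanMedian = 2) {
    if (any(c(tilPct, tanPct) < 0 | c(tilPct, tanPct) > 100))
        stop("percent loads must lie in [0, 100]", call. = FALSE)
    data.frame(til_group = ifelse(tilPct > tilMedian, "high", "low"),
               tan_group = ifelse(tanPct > tanMedian, "high", "low"),
               stringsAsFactors = FALSE)
}

#' Pfaffl efficiency-corrected relative quantification
#'
#' Relative mRNA ratio of a target gene against a reference gene from
#' RT-qPCR: \code{E_target^dCt_target / E_ref^dCt_ref}, with
#' \code{dCt = Ct(control) - Ct(sample)} and per-gene amplification
#' efficiencies E in (1, 2.2].
#'
#' @param eTarget,eRef amplification efficiencies (2 = perfect doubling).
#' @param dCtTarget,dCtRef delta-Ct values (control minus sample).
#' @return positive numeric ratio(s).
#' @examples
#' pfafflRatio(2, 3, 2, 1)  # 8 / 2 = 4
#' @export
pfafflRatio <- function(eTarget, dCtTarget, eRef, dCtRef) {
    if (any(eTarget <= 1 | eRef <= 1))
        stop("amplification efficiencies must exceed 1", call. = FALSE)
    if (any(eTarget > 2.2 | eRef > 2.2))
        stop("amplification efficiencies above 2.2 are not plausible",
             call. = FALSE)
    eTarget^dCtTarget / eRef^dCtRef
}
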