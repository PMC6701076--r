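#' Differential agretopicity index
#'
#' DAI = wild-type IC50 / mutant IC50: the factor by which the mutant
#' peptide's predicted MHC binding improves over its non-mutated
#' counterpart (IC50 is inversely related to affinity, so larger DAI
#' means the mutant binds more strongly).
#'
#' @param wtIc50,mutIc50 positive IC50 values in nM (vectorized), or a
#'   data.frame of affinity records as the first argument.
#' @return positive numeric DAI values.
#' @export
computeDai <- function(wtIc50, mutIc50 = NULL) {
    if (is.data.frame(wtIc50)) {
        mutIc50 <- wtIc50$mut_ic50
        wtIc50 <- wtIc50$wt_ic50
    }
    if (any(wtIc50 <= 0 | mutIc50 <= 0, na.rm = TRUE) ||
        anyNA(wtIc50) || anyNA(mutIc50))
        stop("IC50 values must be strictly positive", call. = FALSE)
    wtIc50 / mutIc50
}

#' Classify candidate peptides into neoepitope categories
#'
#' A peptide is a classically defined neoepitope (CDN) when its mutant
#' IC50 is strictly below the cutoff (default 50 nM); an alternatively
#' defined neoepitope (ADN) when its DAI is strictly above the
#' class-specific cutoff (default 10 for MHC-I, 4 for MHC-II); and a
#' priority neoepitope when it meets both criteria, or meets the CDN
#' criterion and derives from a frameshift mutation. All inequalities are
#' strict, so a mutant IC50 of exactly 50 nM is not a CDN.
#'
#' @param affinities data.frame of affinity records (see
#'   \code{\link{readAffinities}}).
#' @param config a \linkS4class{CytConfig} supplying the cutoffs.
#' @return the input with added columns \code{dai}, \code{dai_log2},
#'   \code{is_cdn}, \code{is_adn}, \code{is_priority}.
#' @examples
#' aff <- data.frame(sample_id = "S1", peptide_id = "p1",
#'                   mhc_class = "I", mut_ic50 = 5, wt_ic50 = 100,
#'                   variant_type = "missense")
#' classifyNeoepitopes(aff)[, c("is_cdn", "is_adn", "is_priority")]
#' @export
classifyNeoepitopes <- function(affinities, config = cytConfig()) {
    stopifnot(methods::is(config, "CytConfig"))
    if (any(!affinities$mhc_class %in% c("I", "II")))
        stop("unknown mhc_class value(s): ",
             paste(unique(setdiff(affinities$mhc_class, c("I", "II"))),
                   collapse = ", "), call. = FALSE)
    dai <- computeDai(affinities$wt_ic50, affinities$mut_ic50)
    daiCut <- ifelse(affinities$mhc_class == "I",
                     config@daiCutoffMhc1, config@daiCutoffMhc2)
    out <- affinities
    out$dai <- dai
    out$dai_log2 <- log2(dai)
    out$is_cdn <- affinities$mut_ic50 < config@cdnIc50Cutoff
    out$is_adn <- dai > daiCut
    out$is_priority <- (out$is_cdn & out$is_adn) |
        (out$is_cdn & affinities$variant_type == "frameshift")
    out
}

#' Per-sample neoepitope loads
#'
#' Tallies classified peptides into per-sample counts of MHC-I and MHC-II
#' CDNs and ADNs and of priority neoepitopes. Samples in the roster
#' without any record get zeros.
#'
#' @param calls data.frame from \code{\link{classifyNeoepitopes}}.
#' @param samples optional full sample roster.
#' @return data.frame with \code{sample_id}, \code{cdn_I}, \code{cdn_II},
#'   \code{adn_I}, \code{adn_II}, \code{priority}.
#' @export
neoepitopeLoad <- function(calls, samples = NULL) {
    if (is.null(samples)) samples <- sort(unique(calls$sample_id))
    sid <- factor(calls$sample_id, levels = samples)
    cnt <- function(keep) as.integer(table(sid[keep]))
    data.frame(
        sample_id = samples,
        cdn_I  = cnt(calls$is_cdn & calls$mhc_class == "I"),
        cdn_II = cnt(calls$is_cdn & calls$mhc_class == "II"),
        adn_I  = cnt(calls$is_adn & calls$mhc_class == "I"),
        adn_II = cnt(calls$is_adn & calls$mhc_class == "II"),
        priority = cnt(calls$is_priority),
        stringsAsFactors = FALSE)
}

#' Correlate neoepitope loads with the cytolytic index
#'
#' Pearson correlation (with two-sided p) of each load type against the
#' per-sample cytolytic index; zero-variance inputs are reported as
#' unavailable.
#'
#' @param loads data.frame from \code{\link{neoepitopeLoad}}.
#' @param cyt data.frame with \code{sample_id} and \code{cyt_index}.
#' @return data.frame with \code{load_type}, \code{pearson_r}, \code{p},
#'   \code{n}.
#' @export
correlateLoadCyt <- function(loads, cyt) {
    m <- merge(loads, cyt[, c("sample_id", "cyt_index")], by = "sample_id")
    if (nrow(m) < 3)
        stop("need at least 3 paired observations", call. = FALSE)
    types <- c("cdn_I", "cdn_II", "adn_I", "adn_II", "priority")
    rows <- lapply(intersect(types, colnames(m)), function(tp) {
        x <- m[[tp]]; y <- m$cyt_index
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            return(data.frame(load_type = tp, pearson_r = NA_real_,
                              p = NA_real_, n = nrow(m)))
        ct <- cor.test(x, y, method = "pearson")
        data.frame(load_type = tp, pearson_r = unname(ct$estimate),
                   p = ct$p.value, n = nrow(m), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
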