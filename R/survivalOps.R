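#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of overall survival; censored subjects leave
#' the risk set without an event step.
#'
#' @param clinical data.frame with \code{os_time} and \code{os_event}
#'   (see \code{\link{readClinical}}).
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{n_censor}, \code{survival}; S(0) = 1 is implicit and the step
#'   function is non-increasing.
#' @examples
#' kmEstimate(data.frame(os_time = 1:3, os_event = 1))
#' @export
kmEstimate <- function(clinical) {
    stopifnot(nrow(clinical) >= 1)
    if (any(clinical$os_time < 0))
        stop("negative survival time", call. = FALSE)
    fit <- survival::survfit(
        survival::Surv(os_time, os_event) ~ 1, data = clinical)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               survival = fit$surv)
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Observed-minus-expected event sums over the shared event times,
#' referred to a 1-df chi-square.
#'
#' @param clinical data.frame with \code{os_time} and \code{os_event}.
#' @param groups vector of two group labels, one per row of
#'   \code{clinical}.
#' @return list with \code{chi2}, \code{p}, and the per-group observed
#'   and expected event counts.
#' @export
logrankTest <- function(clinical, groups) {
    groups <- as.factor(as.character(groups))
    if (nlevels(groups) != 2)
        stop("log-rank test requires exactly two groups", call. = FALSE)
    if (any(table(groups) == 0))
        stop("a group has no subjects", call. = FALSE)
    d <- data.frame(os_time = clinical$os_time,
                    os_event = clinical$os_event, grp = groups)
    if (!any(d$os_event == 1))
        stop("no events observed in either group", call. = FALSE)
    sd <- survival::survdiff(
        survival::Surv(os_time, os_event) ~ grp, data = d, rho = 0)
    list(chi2 = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Two-gene synergy groups
#'
#' Dichotomizes each gene at its cohort median (values at or below the
#' median count as low, for determinism) and partitions samples into
#' \code{both_high}, \code{both_low}, and \code{other}.
#'
#' @param exprValues numeric matrix or data.frame with two columns (one
#'   per gene) and sample IDs as row names, e.g. TPM of GZMA and PRF1, or
#'   of CTLA4 and CD274.
#' @return data.frame with \code{sample_id} and \code{synergy_group};
#'   groups partition the samples.
#' @export
synergyGroups <- function(exprValues) {
    exprValues <- as.matrix(exprValues)
    stopifnot(ncol(exprValues) == 2, !is.null(rownames(exprValues)))
    if (nrow(exprValues) < 8)
        stop("need at least 8 samples", call. = FALSE)
    for (j in 1:2)
        if (stats::sd(exprValues[, j]) == 0)
            stop("gene '", colnames(exprValues)[j],
                 "' is constant; median split degenerate", call. = FALSE)
    high <- sweep(exprValues, 2, apply(exprValues, 2, median), ">")
    grp <- ifelse(high[, 1] & high[, 2], "both_high",
                  ifelse(!high[, 1] & !high[, 2], "both_low", "other"))
    data.frame(sample_id = rownames(exprValues), synergy_group = grp,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Survival tests for two-gene synergy groups
#'
#' Runs the two log-rank comparisons of interest — both-low vs all other
#' patients and both-high vs all other patients — and returns the
#' Kaplan-Meier curves of all three groups.
#'
#' @param clinical data.frame with \code{sample_id}, \code{os_time},
#'   \code{os_event}.
#' @param grouping data.frame from \code{\link{synergyGroups}}.
#' @return list with \code{tests} (data.frame: comparison, chi2, p, n)
#'   and \code{curves} (named list of KM curve data.frames); a comparison
#'   whose group is empty is skipped with a note.
#' @export
synergySurvival <- function(clinical, grouping) {
    m <- merge(clinical, grouping, by = "sample_id")
    tests <- list()
    for (grp in c("both_low", "both_high")) {
        inGrp <- m$synergy_group == grp
        if (!any(inGrp) || all(inGrp)) {
            message("skipping ", grp, " vs rest: empty comparison group")
            next
        }
        lr <- logrankTest(m, ifelse(inGrp, grp, "rest"))
        tests[[grp]] <- data.frame(
            comparison = paste0(grp, "_vs_rest"), chi2 = lr$chi2,
            p = lr$p, n = sum(inGrp), stringsAsFactors = FALSE)
    }
    curves <- lapply(split(m, m$synergy_group), kmEstimate)
    list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
         curves = curves)
}
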