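#' Count somatic copy-number events per sample
#'
#' An amplification event is a segment with segment mean at or above
#' \code{ampCutoff} (default 0.6) and a deletion event one at or below
#' \code{delCutoff} (default -0.4); both boundaries are inclusive.
#' Segment means are thresholded as provided (no re-centering, no
#' segment-length weighting). Besides the event counts, the literal sums
#' of qualifying segment means are reported as an auxiliary burden
#' measure.
#'
#' @param segments data.frame of segments (see \code{\link{readSegments}}).
#' @param ampCutoff,delCutoff segment-mean cutoffs, requiring
#'   \code{delCutoff < 0 < ampCutoff}.
#' @param samples optional full sample roster (absent samples get 0).
#' @return data.frame with \code{sample_id}, \code{amp_count},
#'   \code{del_count}, \code{total_count}, \code{amp_sum},
#'   \code{del_sum}.
#' @examples
#' seg <- data.frame(Sample = "S1", Chromosome = 1, Start = 1,
#'                   End = 100, Num_Probes = 10,
#'                   Segment_Mean = c(0.7, 0.6, 0.59, -0.4, -0.39, 0))
#' countScnaEvents(seg)  # amp 2, del 1, total 3
#' @export
countScnaEvents <- function(segments, ampCutoff = 0.6, delCutoff = -0.4,
                            samples = NULL) {
    if (!(delCutoff < 0 && 0 < ampCutoff))
        stop("require delCutoff < 0 < ampCutoff", call. = FALSE)
    if (is.null(samples)) samples <- sort(unique(segments$Sample))
    sid <- factor(segments$Sample, levels = samples)
    amp <- segments$Segment_Mean >= ampCutoff
    del <- segments$Segment_Mean <= delCutoff
    data.frame(
        sample_id = samples,
        amp_count = as.integer(table(sid[amp])),
        del_count = as.integer(table(sid[del])),
        total_count = as.integer(table(sid[amp | del])),
        amp_sum = as.numeric(tapply(segments$Segment_Mean * amp, sid, sum,
                                    default = 0)),
        del_sum = as.numeric(tapply(segments$Segment_Mean * del, sid, sum,
                                    default = 0)),
        stringsAsFactors = FALSE)
}

#' Compare copy-number event burden between cytolytic strata
#'
#' Two-sided Mann-Whitney U test of total event counts between CYT-high
#' and CYT-low samples.
#'
#' @param scna data.frame from \code{\link{countScnaEvents}}.
#' @param strata data.frame from \code{\link{stratifyCyt}}.
#' @return list with \code{U}, \code{p}, and the per-stratum mean counts
#'   \code{mean_high}, \code{mean_low}.
#' @export
compareScnaBurden <- function(scna, strata) {
    m <- merge(scna, strata[, c("sample_id", "stratum")], by = "sample_id")
    hi <- m$total_count[m$stratum == "CYT-high"]
    lo <- m$total_count[m$stratum == "CYT-low"]
    if (!length(hi) || !length(lo))
        stop("both CYT-high and CYT-low strata must be non-empty",
             call. = FALSE)
    ht <- suppressWarnings(wilcox.test(hi, lo, alternative = "two.sided"))
    list(U = unname(ht$statistic), p = ht$p.value,
         mean_high = mean(hi), mean_low = mean(lo))
}
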