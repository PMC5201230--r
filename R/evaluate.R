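# Method-comparison statistics: Bland-Altman agreement, intra-time-point
# replicate variability, and time-profile coverage.

#' Bland-Altman agreement statistics
#'
#' Mean and SD of the paired differences `a - b` with limits of agreement
#' at mean +/- 2 SD.
#'
#' @param a,b equal-length paired measurement series (ms).
#' @return List: `mean_diff`, `sd_diff`, `limits` (length 2), `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    jt_stop("jt_input_error", "paired series must have equal length")
  keep <- is.finite(a) & is.finite(b)
  d <- a[keep] - b[keep]
  if (length(d) < 2)
    jt_stop("jt_insufficient_data_error", "need at least 2 complete pairs")
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, limits = c(lower = m - 2 * s, upper = m + 2 * s),
       n = length(d))
}

#' Intra-time-point replicate variability
#'
#' Computes the SD across replicates for each subject x time point,
#' averages it per subject, and (when two methods are supplied) compares
#' the per-subject means with a two-sided paired t-test.  Time points
#' with a single replicate are dropped with a warning.
#'
#' @param measurements data.frame with columns `subject`, `timepoint`,
#'   `replicate`, `value`, and optionally `method` (exactly 1 or 2
#'   levels).
#' @return List: `per_subject` (data.frame subject, method, mean_sd),
#'   `mean_sd` (named per method), and for two methods `diff`,
#'   `conf_int`, `p_value` from the paired t-test.
#' @export
intra_timepoint_sd <- function(measurements) {
  m <- as.data.frame(measurements)
  need <- c("subject", "timepoint", "replicate", "value")
  missing <- setdiff(need, names(m))
  if (length(missing))
    jt_stop("jt_input_error",
            sprintf("measurements lack column(s): %s", paste(missing, collapse = ", ")))
  if (is.null(m$method)) m$method <- "method"
  m <- m[is.finite(m$value), , drop = FALSE]
  counts <- stats::aggregate(value ~ subject + timepoint + method, m, length)
  if (any(counts$value < 2)) {
    warning(sprintf("dropping %d subject x time point cell(s) with a single replicate",
                    sum(counts$value < 2)))
    bad <- counts[counts$value < 2, c("subject", "timepoint", "method")]
    key <- function(d) paste(d$subject, d$timepoint, d$method)
    m <- m[!key(m) %in% key(bad), , drop = FALSE]
  }
  if (!nrow(m)) jt_stop("jt_insufficient_data_error", "no cells with >= 2 replicates")
  sds <- stats::aggregate(value ~ subject + timepoint + method, m, stats::sd)
  per_subject <- stats::aggregate(value ~ subject + method, sds, mean)
  names(per_subject)[names(per_subject) == "value"] <- "mean_sd"
  methods <- sort(unique(per_subject$method))
  mean_sd <- vapply(methods, function(mm)
    mean(per_subject$mean_sd[per_subject$method == mm]), numeric(1))
  out <- list(per_subject = per_subject, mean_sd = mean_sd)
  if (length(methods) == 2) {
    wide <- merge(per_subject[per_subject$method == methods[1], c("subject", "mean_sd")],
                  per_subject[per_subject$method == methods[2], c("subject", "mean_sd")],
                  by = "subject", suffixes = c("_a", "_b"))
    tt <- stats::t.test(wide$mean_sd_a, wide$mean_sd_b, paired = TRUE)
    out$diff <- unname(tt$estimate)
    out$conf_int <- unname(tt$conf.int)
    out$p_value <- tt$p.value
  } else if (length(methods) > 2) {
    jt_stop("jt_input_error", "at most two methods are supported")
  }
  out
}

#' Fraction of differences within thresholds
#'
#' For each threshold, the fraction of differences with absolute value
#' strictly below it -- the time-profile agreement metric (e.g. the share
#' of time points within 1 ms / 2 ms).
#'
#' @param diff_series numeric differences (ms); must be nonempty.
#' @param thresholds_ms numeric thresholds (ms).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
coverage_within <- function(diff_series, thresholds_ms = c(1, 2)) {
  d <- diff_series[is.finite(diff_series)]
  if (!length(d)) jt_stop("jt_insufficient_data_error", "empty difference series")
  out <- vapply(thresholds_ms, function(th) mean(abs(d) < th), numeric(1))
  names(out) <- paste0("within_", thresholds_ms, "ms")
  out
}
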