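# Group-level statistics: parieto-central SRP averages, pointwise paired
# t-tests with Benjamini-Hochberg correction, scalar paired tests, and the
# behavioral/latency correlation.

#' Condition-mean SRP trace for one participant
#'
#' Mean over the epochs of a condition, then over the channel set.
#'
#' @param epochs an `srp_epochs`.
#' @param condition_mask logical per epoch.
#' @param channels channel names to average (default the parieto-central
#'   seven).
#' @return numeric trace (one value per epoch sample), or `NULL` when the
#'   condition has no epochs.
#' @export
participant_srp <- function(epochs, condition_mask,
                            channels = srp_channel_set()) {
  if (length(channels) == 0) stop("empty channel set")
  stopifnot(length(condition_mask) == dim(epochs$data)[1])
  if (!any(condition_mask)) return(NULL)
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("channel(s) not present in the epoch set")
  sub <- epochs$data[condition_mask, ci, , drop = FALSE]
  colMeans(apply(sub, c(1, 3), mean))   # epochs -> mean, then channels
}

#' Grand-average SRP traces across participants
#'
#' @param traces participants x samples matrix (per-participant condition
#'   means; rows with any `NA` are dropped).
#' @return list with `grand` (unweighted mean trace), `sem` and `n`.
#' @export
average_srp <- function(traces) {
  keep <- stats::complete.cases(traces)
  tr <- traces[keep, , drop = FALSE]
  list(grand = colMeans(tr),
       sem = apply(tr, 2, sd) / sqrt(nrow(tr)),
       n = nrow(tr))
}

#' Pointwise paired t-tests along the epoch time axis
#'
#' Per time sample, a two-sided paired t-test across participants between
#' two condition traces, with an uncorrected significance mask at `alpha`
#' and a Benjamini-Hochberg corrected mask over all samples of the epoch.
#' Samples with zero variance of the paired differences get p = 1 and are
#' flagged.
#'
#' @param traces_a,traces_b participants x samples matrices (paired rows;
#'   participants with `NA` in either condition are dropped pairwise).
#' @param times time axis, s.
#' @param alpha significance level (default 0.05).
#' @return object of class `srp_pointwise`: `times`, `t`, `p`,
#'   `sig_uncorrected`, `sig_bh`, `n`, `zero_variance` (logical mask).
#' @export
pointwise_paired_ttest <- function(traces_a, traces_b, times = NULL,
                                   alpha = 0.05) {
  stopifnot(all(dim(traces_a) == dim(traces_b)))
  keep <- stats::complete.cases(traces_a) & stats::complete.cases(traces_b)
  a <- traces_a[keep, , drop = FALSE]; b <- traces_b[keep, , drop = FALSE]
  n <- nrow(a)
  if (n < 3) stop("need >= 3 participants with both conditions")
  d <- a - b
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  zero_var <- s == 0
  tval <- ifelse(zero_var, 0, m / (s / sqrt(n)))
  p <- ifelse(zero_var, 1, 2 * pt(-abs(tval), df = n - 1))
  if (is.null(times)) times <- seq_len(ncol(a))
  structure(list(times = times, t = tval, p = p,
                 sig_uncorrected = p < alpha,
                 sig_bh = bh_correct(p, alpha),
                 n = n, alpha = alpha, zero_variance = zero_var),
            class = "srp_pointwise")
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up FDR control: reject the hypotheses whose BH-adjusted p-value is
#' at most `alpha`. The mask is returned in the original order and is
#' always a subset of the uncorrected mask.
#'
#' @param p p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return logical vector.
#' @export
bh_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH") <= alpha
}

#' Paired t-test on per-participant feature means
#'
#' @param a,b paired per-participant values (pairs with `NA` dropped).
#' @return list `t`, `df`, `p`, `mean_diff`, `n`; zero-variance
#'   differences are flagged via `zero_variance`.
#' @export
paired_feature_test <- function(a, b) {
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need >= 3 paired observations")
  d <- a - b
  if (sd(d) == 0)
    return(list(t = if (mean(d) == 0) 0 else NA_real_,
                df = length(a) - 1L, p = 1,
                mean_diff = mean(d), n = length(a), zero_variance = TRUE))
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), n = length(a),
       zero_variance = FALSE)
}

#' Correlation between math performance and monitoring hit rate
#'
#' Pearson correlation with a two-sided t-based p-value.
#'
#' @param math_scores,hit_rates paired per-participant vectors.
#' @return list `r`, `p`, `n`; zero-variance input yields `NA` with a
#'   warning.
#' @export
correlate_performance <- function(math_scores, hit_rates) {
  keep <- !(is.na(math_scores) | is.na(hit_rates))
  x <- math_scores[keep]; y <- hit_rates[keep]
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
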