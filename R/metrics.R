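# System-validity metrics: log-likelihood-ratio cost (Cllr) and equal
# error rate (EER), with IQR screening of metric values across iterations.

#' Log-likelihood-ratio cost (Cllr)
#'
#' Proper-scoring-rule summary of likelihood-ratio validity:
#' `Cllr = 1/2 * (mean over same-speaker of log2(1 + 1/LR)
#'              + mean over different-speaker of log2(1 + LR))`.
#' A system that outputs LR = 1 for every comparison scores exactly 1;
#' 0 is perfect.
#'
#' @param lr_ss,lr_ds Positive likelihood ratios (not logs) from
#'   same-speaker and different-speaker comparisons; both nonempty.
#' @return Scalar Cllr (>= 0).
#' @export
#' @examples
#' cllr(rep(1, 10), rep(1, 45))     # exactly 1
#' cllr(3, 0.5)                     # 0.5
cllr <- function(lr_ss, lr_ds) {
  if (length(lr_ss) == 0 || length(lr_ds) == 0) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  if (any(lr_ss <= 0) || any(lr_ds <= 0) ||
      any(!is.finite(c(lr_ss, lr_ds)))) {
    stop("likelihood ratios must be positive and finite", call. = FALSE)
  }
  0.5 * (mean(log2(1 + 1 / lr_ss)) + mean(log2(1 + lr_ds)))
}

#' Equal error rate
#'
#' Sweeps thresholds over the pooled score set; at threshold `t`,
#' `FRR(t)` is the fraction of same-speaker scores below `t` and `FAR(t)`
#' the fraction of different-speaker scores at or above `t` (ties count
#' as false accepts). The default `"crossing"` variant reports
#' `(FAR + FRR) / 2` at the balance point, linearly interpolating between
#' adjacent empirical thresholds where `FAR - FRR` changes sign; this is
#' the operating point where the two error rates coincide (0 = perfect,
#' 0.5 = chance). The `"as-printed"` variant halves that value once more,
#' reproducing a published formula whose chance level is 0.25. Values
#' above 0.5 (pathologically reversed systems) are returned as computed
#' with a warning.
#'
#' @param scores_ss,scores_ds Same- and different-speaker scores
#'   (log10 LRs or any common monotone score); both nonempty.
#' @param variant `"crossing"` (default) or `"as-printed"`.
#' @return Scalar EER.
#' @export
#' @examples
#' eer(c(2, 3), c(-3, -2))   # 0: perfectly separated
#' eer(c(0, 1), c(0, 1))     # 0.5: chance
eer <- function(scores_ss, scores_ds, variant = c("crossing", "as-printed")) {
  variant <- match.arg(variant)
  if (length(scores_ss) == 0 || length(scores_ds) == 0) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  thr <- sort(unique(c(scores_ss, scores_ds, Inf)))
  frr <- vapply(thr, function(t) mean(scores_ss < t), numeric(1))
  far <- vapply(thr, function(t) mean(scores_ds >= t), numeric(1))
  d <- far - frr  # nonincreasing minus nondecreasing: monotone in t
  i0 <- which(d == 0)
  if (length(i0) > 0) {
    i <- i0[1]
    out <- (far[i] + frr[i]) / 2
  } else {
    # sign change between adjacent thresholds: interpolate the crossing
    i <- which(d[-length(d)] > 0 & d[-1] < 0)
    if (length(i) == 0) {
      # no crossing inside the sweep: take the threshold minimising |d|
      i <- which.min(abs(d))
      out <- (far[i] + frr[i]) / 2
    } else {
      i <- i[1]
      alpha <- d[i] / (d[i] - d[i + 1])
      far_x <- far[i] + alpha * (far[i + 1] - far[i])
      frr_x <- frr[i] + alpha * (frr[i + 1] - frr[i])
      out <- (far_x + frr_x) / 2
    }
  }
  if (out > 0.5) {
    warning("EER above 0.5: system orders scores in reverse", call. = FALSE)
  }
  if (variant == "as-printed") out <- out / 2
  out
}

#' Metrics for a table of calibrated scores
#'
#' Convenience wrapper computing Cllr and EER from calibrated log10 LRs.
#'
#' @param scores Data frame with columns `hypothesis` (`"Hs"`/`"Hd"`) and
#'   `log10_lr`.
#' @return One-row data frame `(n_ss, n_ds, cllr, eer)`.
#' @export
score_metrics <- function(scores) {
  ss <- scores$log10_lr[scores$hypothesis == "Hs"]
  ds <- scores$log10_lr[scores$hypothesis == "Hd"]
  data.frame(n_ss = length(ss), n_ds = length(ds),
             cllr = cllr(10^ss, 10^ds), eer = eer(ss, ds))
}

#' Aggregate metric results across iterations and groups
#'
#' Within each condition x subset cell, screens Cllr and EER values
#' independently with the `[Q1 - k * IQR, Q3 + k * IQR]` rule (quartiles
#' by linear interpolation), then summarises the surviving values.
#'
#' @param results Data frame of per-iteration metric rows with columns
#'   `condition`, `subset`, `cllr`, `eer` (as from [run_matched()]).
#' @param k IQR multiplier (default 2.5); `Inf` disables screening.
#' @return Data frame, one row per condition x subset:
#'   `(condition, subset, n, n_removed_cllr, n_removed_eer, cllr_mean,
#'   cllr_median, cllr_q1, cllr_q3, eer_mean, eer_median, eer_q1, eer_q3)`.
#' @export
aggregate_metrics <- function(results, k = 2.5) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  cells <- split(results, list(results$condition, results$subset), drop = TRUE)
  screen <- function(x) {
    if (!is.finite(k)) return(rep(TRUE, length(x)))
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    x >= q[1] - k * iqr & x <= q[2] + k * iqr
  }
  out <- lapply(cells, function(cell) {
    kc <- screen(cell$cllr)
    ke <- screen(cell$eer)
    qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                      names = FALSE)
    qc <- qs(cell$cllr[kc]); qe <- qs(cell$eer[ke])
    data.frame(condition = cell$condition[1], subset = cell$subset[1],
               n = nrow(cell),
               n_removed_cllr = sum(!kc), n_removed_eer = sum(!ke),
               cllr_mean = mean(cell$cllr[kc]), cllr_median = qc[2],
               cllr_q1 = qc[1], cllr_q3 = qc[3],
               eer_mean = mean(cell$eer[ke]), eer_median = qe[2],
               eer_q1 = qe[1], eer_q3 = qe[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$condition, res$subset), , drop = FALSE]
}
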