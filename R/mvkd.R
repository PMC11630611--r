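# Two-level multivariate kernel-density (MVKD) likelihood-ratio scoring.
#
# Background model per vowel x formant subset: within-speaker variation is
# normal with pooled covariance W; between-speaker variation is a kernel
# density over the m background speaker mean vectors with normal kernels of
# covariance h^2 * B (B = covariance of the speaker means, h the
# normal-reference bandwidth). The evidence for a comparison is the pair of
# sample mean vectors (questioned, reference):
#
#   numerator  = (1/m) sum_i N2d((ybar_q, ybar_r); (mu_i, mu_i),
#                              [[h^2 B + W/n_q, h^2 B], [h^2 B, h^2 B + W/n_r]])
#   denominator = [(1/m) sum_i N(ybar_q; mu_i, h^2 B + W/n_q)] *
#                 [(1/m) sum_i N(ybar_r; mu_i, h^2 B + W/n_r)]
#
# i.e. the same-source hypothesis integrates a common unknown source mean
# over the kernel-density between-speaker distribution, while the
# different-source hypothesis treats the two samples as independent draws
# from it. Scores are returned as log10 LR, clamped to [-10, 10].

FORMANT_NAMES <- c("F1", "F2", "F3", "F4")

LLR_CLAMP <- 10

#' Assemble a comparison sample
#'
#' Bundles one speaker's tokens of one vowel restricted to a formant
#' subset, the unit compared by [score_pair()].
#'
#' @param matrix_hz Numeric matrix, tokens x selected formants (Hz), at
#'   least 2 complete rows.
#' @param speaker_id,vowel Provenance labels.
#' @param subset Integer vector of formant indices in 1..4 (e.g. `c(3, 4)`
#'   for F3+F4), matching the columns of `matrix_hz`.
#' @return A `comparison_sample` list with fields `speaker_id`, `vowel`,
#'   `subset`, `x`, `n`, `mean`.
#' @export
comparison_sample <- function(matrix_hz, speaker_id = "?", vowel = "?",
                              subset = seq_len(ncol(matrix_hz))) {
  x <- as.matrix(matrix_hz)
  subset <- as.integer(subset)
  if (nrow(x) < 2) stop("a comparison sample needs >= 2 tokens", call. = FALSE)
  if (ncol(x) != length(subset)) {
    stop("subset length must match the number of columns", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("sample rows must be complete", call. = FALSE)
  if (any(subset < 1 | subset > 4)) {
    stop("formant indices must lie in 1..4", call. = FALSE)
  }
  structure(list(speaker_id = speaker_id, vowel = vowel, subset = subset,
                 x = x, n = nrow(x), mean = colMeans(x)),
            class = "comparison_sample")
}

#' Fit an MVKD background model
#'
#' Estimates the two-level background model for one vowel and formant
#' subset: pooled within-speaker covariance `W` (per-speaker centered
#' cross-products summed and divided by `N - m`), per-speaker mean vectors,
#' their covariance `B` (divisor `m - 1`), and the normal-reference kernel
#' bandwidth `h = (4 / ((2 d + 1) m))^(1 / (d + 4))`.
#'
#' @param background List of `comparison_sample`s, one per background
#'   speaker (>= 3), all for the same vowel and subset, each with >= 2
#'   tokens.
#' @return An `mvkd_model` list with fields `subset`, `vowel`,
#'   `speaker_means` (m x d), `W`, `B`, `h`, `m`.
#' @export
fit_background <- function(background) {
  m <- length(background)
  if (m < 3) stop("need >= 3 background speakers", call. = FALSE)
  subset <- background[[1]]$subset
  vowel <- background[[1]]$vowel
  d <- length(subset)
  for (s in background) {
    if (!identical(s$subset, subset) || !identical(s$vowel, vowel)) {
      stop("background samples must share one vowel and formant subset",
           call. = FALSE)
    }
  }
  means <- matrix(vapply(background, function(s) s$mean, numeric(d)),
                  ncol = d, byrow = TRUE)
  N <- sum(vapply(background, function(s) s$n, numeric(1)))
  Sw <- matrix(0, d, d)
  for (s in background) {
    c_ <- sweep(s$x, 2, s$mean)
    Sw <- Sw + crossprod(c_)
  }
  W <- Sw / (N - m)
  ok <- tryCatch({chol(W); TRUE}, error = function(e) FALSE)
  if (!ok) {
    stop("pooled within-speaker covariance is singular; ",
         "use more tokens per speaker or fewer formants", call. = FALSE)
  }
  B <- stats::cov(means)
  h <- (4 / ((2 * d + 1) * m))^(1 / (d + 4))
  structure(list(subset = subset, vowel = vowel, speaker_means = means,
                 W = W, B = B, h = h, m = m),
            class = "mvkd_model")
}

# Fast path: log10 LR from sample means and counts under a fitted model.
# Returns an unclamped value; callers clamp. Inlined Gaussian algebra:
# this sits in the innermost loop of the cross-validation protocol.
mvkd_llr10 <- function(model, mean_q, n_q, mean_r, n_r) {
  mu <- model$speaker_means
  m <- nrow(mu)
  d <- ncol(mu)
  C <- model$h^2 * model$B
  Dq <- C + model$W / n_q
  Dr <- C + model$W / n_r
  dev_q <- rep(mean_q, each = m) - mu  # m x d deviations from each kernel
  dev_r <- rep(mean_r, each = m) - mu
  l2pi <- log(2 * pi)
  chq <- chol(Dq)
  chr_ <- chol(Dr)
  zq <- backsolve(chq, t(dev_q), transpose = TRUE)
  zr <- backsolve(chr_, t(dev_r), transpose = TRUE)
  lq <- -0.5 * d * l2pi - sum(log(diag(chq))) - 0.5 * colSums(zq * zq)
  lr <- -0.5 * d * l2pi - sum(log(diag(chr_))) - 0.5 * colSums(zr * zr)
  chs <- chol(rbind(cbind(Dq, C), cbind(C, Dr)))
  zs <- backsolve(chs, t(cbind(dev_q, dev_r)), transpose = TRUE)
  ln <- -d * l2pi - sum(log(diag(chs))) - 0.5 * colSums(zs * zs)
  (logsumexp(ln) - logsumexp(lq) - logsumexp(lr) + log(m)) / log(10)
}

#' Score a questioned-vs-reference comparison
#'
#' Evaluates the MVKD likelihood ratio for the pair of sample means under
#' `model` (see the model description in [fit_background()]). Positive
#' log10 LR supports same origin; the score is clamped to `[-10, 10]`
#' (attribute `clamped` records whether clamping occurred).
#'
#' @param model An `mvkd_model`.
#' @param questioned,reference `comparison_sample`s with the model's vowel
#'   and subset.
#' @return Scalar log10 likelihood ratio with attribute `clamped`.
#' @export
score_pair <- function(model, questioned, reference) {
  if (!identical(questioned$subset, model$subset) ||
      !identical(reference$subset, model$subset) ||
      !identical(questioned$vowel, model$vowel) ||
      !identical(reference$vowel, model$vowel)) {
    stop("sample vowel/subset must match the model", call. = FALSE)
  }
  llr <- mvkd_llr10(model, questioned$mean, questioned$n,
                    reference$mean, reference$n)
  clamped <- FALSE
  if (!is.finite(llr) || abs(llr) > LLR_CLAMP) {
    llr <- max(min(llr, LLR_CLAMP, na.rm = TRUE), -LLR_CLAMP)
    clamped <- TRUE
  }
  structure(llr, clamped = clamped)
}

#' Raw MVKD scores for all comparisons in a speaker group
#'
#' Scores every unordered pair in `group` (one Hd comparison per pair,
#' speaker a's questioned sample against speaker b's reference sample)
#' under per-vowel background models fit on the remaining group members
#' (leave-pair-out), and every speaker's same-speaker comparison
#' (questioned vs reference sample) under models fit on the other members
#' (leave-one-out). A 10-speaker group thus yields 45 Hd and 10 Hs scores
#' per vowel. Vowels with fewer than `min_tokens` tokens in either sample
#' of a comparison are skipped.
#'
#' @param group Character vector of group members.
#' @param prepared A prepared-data object from [prepare_condition_data()].
#' @param subset Integer formant indices (1..4).
#' @param min_tokens Minimum tokens per vowel per sample (default 3).
#' @return Data frame of raw scores
#'   `(speaker_a, speaker_b, hypothesis, vowel, log10_lr)` where
#'   `hypothesis` is `"Hs"` or `"Hd"`.
#' @export
score_all <- function(group, prepared, subset, min_tokens = 3) {
  group <- sort(group)
  if (length(group) < 5) {
    stop("group too small: background would have < 3 speakers", call. = FALSE)
  }
  subset <- as.integer(subset)
  pairs <- enumerate_pairs(group)
  out <- lapply(seq_len(nrow(pairs)), function(pi) {
    a <- pairs$speaker_a[pi]; b <- pairs$speaker_b[pi]
    models <- fit_models_for(setdiff(group, c(a, b)), prepared, subset,
                             prepared$vowels)
    rows <- data.frame(speaker_a = a, speaker_b = b, hypothesis = "Hd",
                       stringsAsFactors = FALSE)
    long_scores(rows, score_rows(rows, models, prepared, min_tokens))
  })
  own <- lapply(group, function(s) {
    models <- fit_models_for(setdiff(group, s), prepared, subset,
                             prepared$vowels)
    rows <- data.frame(speaker_a = s, speaker_b = s, hypothesis = "Hs",
                       stringsAsFactors = FALSE)
    long_scores(rows, score_rows(rows, models, prepared, min_tokens))
  })
  res <- do.call(rbind, c(out, own))
  rownames(res) <- NULL
  res
}
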