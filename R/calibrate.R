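# Logistic-regression calibration and per-vowel score fusion under the
# leave-pair-out cross-validation protocol.
#
# Fusion and calibration are one operation: a binary logistic regression of
# the hypothesis label on the vector of per-vowel log10 LRs. Classes are
# weighted to equal effective priors (each class contributes total weight
# 1/2), so the fitted linear predictor is directly an equal-prior
# log-posterior-odds, i.e. a calibrated natural-log LR; division by ln(10)
# returns it to the log10 domain. With a single input dimension fusion
# reduces to plain calibration.

#' Fit a logistic-regression fusion/calibration model
#'
#' @param dev_scores Numeric matrix of development scores, one row per
#'   comparison, one column per input dimension (per-vowel log10 LRs);
#'   `NA` entries (vowel unavailable for that comparison) are imputed with
#'   the column's development mean.
#' @param labels Character vector (`"Hs"`/`"Hd"`) or logical (TRUE =
#'   same-speaker), one per row; needs >= 2 of each.
#' @param ridge_lambda L2 penalty on the weights (intercept unpenalised).
#'   The penalty is always applied: per-fold development sets are small
#'   (tens of comparisons) and per-vowel scores are highly correlated, so
#'   the unpenalised maximum-likelihood fit is frequently separable or
#'   sign-unstable. The default (`NULL`) scales the penalty to the
#'   overfitting magnitude of the development set,
#'   `lambda = d / (2 n_eff)` with `d` the number of score dimensions and
#'   `n_eff` the Kish effective sample size of the class-balancing
#'   weights -- the expected spurious log-likelihood gain per fitted
#'   weight, so that a score dimension is retained only insofar as it
#'   beats chance on the development data. The penalty vanishes as
#'   development data grow, recovering the unpenalised fit used with
#'   large-scale calibration pools. A numeric value overrides the rule.
#' @return A `calibration_model`: list with `weights`, `intercept`,
#'   `dims`, `col_means`, `lambda`, `separable` (logical: the development
#'   set was perfectly separated by the fitted direction).
#' @export
fit_fusion <- function(dev_scores, labels, ridge_lambda = NULL) {
  x <- as.matrix(dev_scores)
  if (is.null(colnames(x))) colnames(x) <- paste0("dim", seq_len(ncol(x)))
  y <- if (is.logical(labels)) labels else labels == "Hs"
  if (length(y) != nrow(x)) stop("labels must match rows", call. = FALSE)
  if (sum(y) < 2 || sum(!y) < 2) {
    stop("need >= 2 same-speaker and >= 2 different-speaker comparisons",
         call. = FALSE)
  }
  keep <- which(colSums(!is.na(x)) > 0)
  if (length(keep) == 0) stop("all score columns are empty", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  col_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- col_means[j]

  # equal effective priors: each class carries total weight 1/2 (weights
  # kept on this scale so the ridge penalty is well defined)
  wts <- ifelse(y, 0.5 / sum(y), 0.5 / sum(!y))
  if (is.null(ridge_lambda)) {
    n_eff <- 1 / sum(wts^2)  # Kish effective sample size
    ridge_lambda <- ncol(x) / (2 * n_eff)
  }
  beta <- ridge_logistic(x, y, wts, lambda = ridge_lambda)
  eta <- drop(cbind(1, x) %*% beta)
  separable <- all(eta[y] > 0) && all(eta[!y] < 0)
  structure(list(weights = stats::setNames(beta[-1], colnames(x)),
                 intercept = unname(beta[1]),
                 dims = colnames(x), col_means = col_means,
                 lambda = ridge_lambda, separable = separable),
            class = "calibration_model")
}

# Newton/IRLS for L2-penalised weighted logistic regression; the intercept
# is unpenalised.
ridge_logistic <- function(x, y, wts, lambda = 1e-3, max_iter = 200,
                           tol = 1e-12) {
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  yn <- as.numeric(y)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- crossprod(X, wts * (yn - mu)) - pen %*% beta
    s <- pmax(wts * mu * (1 - mu), 1e-12)
    H <- crossprod(X * s, X) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Apply a fusion/calibration model
#'
#' @param model A `calibration_model`.
#' @param scores Numeric matrix (or vector for one comparison) of raw
#'   per-vowel log10 LRs with columns named as the model's `dims`; `NA`
#'   entries are imputed with the development column means.
#' @return Numeric vector of calibrated log10 LRs.
#' @export
predict_fusion <- function(model, scores) {
  x <- if (is.null(dim(scores))) matrix(scores, nrow = 1,
                                        dimnames = list(NULL, names(scores)))
       else as.matrix(scores)
  if (!is.null(colnames(x))) {
    miss_dim <- setdiff(model$dims, colnames(x))
    for (d in miss_dim) x <- cbind(x, stats::setNames(
      data.frame(rep(NA_real_, nrow(x))), d)[[1]])
    if (length(miss_dim) > 0) colnames(x)[(ncol(x) - length(miss_dim) + 1):ncol(x)] <- miss_dim
    x <- x[, model$dims, drop = FALSE]
  } else if (ncol(x) != length(model$dims)) {
    stop("score columns do not match the model's dimensions", call. = FALSE)
  }
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- model$col_means[model$dims[j]]
  }
  drop(model$intercept + x %*% model$weights) / log(10)
}

# ---- leave-pair-out cross-validation within a speaker group ----

# Builds the per-fold structures for one group: for every tested pair,
# per-vowel MVKD models fit on the remaining members, development scores
# from background-only comparisons, and raw scores for the tested
# comparisons. Internal workhorse shared by score_all() and
# crossval_group().
crossval_folds <- function(group, prepared, subset, min_tokens = 3) {
  group <- sort(group)
  if (length(group) < 5) {
    stop("group too small: background would have < 3 speakers", call. = FALSE)
  }
  subset <- as.integer(subset)
  vowels <- prepared$vowels
  pairs <- enumerate_pairs(group)
  lapply(seq_len(nrow(pairs)), function(pi) {
    a <- pairs$speaker_a[pi]; b <- pairs$speaker_b[pi]
    bg <- setdiff(group, c(a, b))
    models <- fit_models_for(bg, prepared, subset, vowels)
    usable <- names(models)
    # development: all Hd pairs and all Hs comparisons among background only
    bg_pairs <- enumerate_pairs(bg)
    dev_rows <- rbind(
      data.frame(speaker_a = bg_pairs$speaker_a,
                 speaker_b = bg_pairs$speaker_b,
                 hypothesis = "Hd", stringsAsFactors = FALSE),
      data.frame(speaker_a = bg, speaker_b = bg, hypothesis = "Hs",
                 stringsAsFactors = FALSE))
    dev <- score_rows(dev_rows, models, prepared, min_tokens)
    test_rows <- data.frame(
      speaker_a = c(a, a, b), speaker_b = c(b, a, b),
      hypothesis = c("Hd", "Hs", "Hs"), stringsAsFactors = FALSE)
    test <- score_rows(test_rows, models, prepared, min_tokens)
    test_raw <- cbind(test_rows, as.data.frame(test))
    list(pair = c(a, b), dev_rows = dev_rows, dev = dev,
         test_rows = test_rows, test = test, test_raw = long_scores(test_rows, test))
  })
}

fit_models_for <- function(bg, prepared, subset, vowels) {
  models <- list()
  for (v in vowels) {
    st <- lapply(bg, function(s) prepared$bg[[s]][[v]])
    st <- st[!vapply(st, is.null, logical(1))]
    st <- st[vapply(st, function(e) e$n >= 2, logical(1))]
    if (length(st) < 3) next
    d <- length(subset)
    means <- matrix(vapply(st, function(e) e$mean[subset], numeric(d)),
                    ncol = d, byrow = TRUE)
    N <- sum(vapply(st, function(e) e$n, numeric(1)))
    Sw <- Reduce(`+`, lapply(st, function(e) e$S[subset, subset, drop = FALSE]))
    W <- Sw / (N - length(st))
    if (inherits(tryCatch(chol(W), error = identity), "error")) next
    B <- stats::cov(means)
    h <- (4 / ((2 * d + 1) * length(st)))^(1 / (d + 4))
    models[[v]] <- structure(
      list(subset = subset, vowel = v, speaker_means = means, W = W, B = B,
           h = h, m = length(st)),
      class = "mvkd_model")
  }
  models
}

# Score a set of (speaker_a, speaker_b, hypothesis) rows per vowel.
# Questioned material comes from speaker_a, reference from speaker_b
# (for Hs rows both are the same speaker's questioned/reference split or
# cross-style samples). Returns a rows x vowels matrix of clamped log10
# LRs with NA where a vowel is unavailable.
score_rows <- function(rows, models, prepared, min_tokens) {
  vowels <- names(models)
  out <- matrix(NA_real_, nrow(rows), length(vowels),
                dimnames = list(NULL, vowels))
  subset <- if (length(models) > 0) models[[1]]$subset else integer()
  for (v in vowels) {
    model <- models[[v]]
    for (i in seq_len(nrow(rows))) {
      q <- prepared$qst[[rows$speaker_a[i]]][[v]]
      r <- prepared$ref[[rows$speaker_b[i]]][[v]]
      if (is.null(q) || is.null(r) || q$n < min_tokens || r$n < min_tokens) next
      llr <- mvkd_llr10(model, q$mean[subset], q$n, r$mean[subset], r$n)
      if (is.nan(llr)) next  # numerical failure: leave this vowel missing
      out[i, v] <- max(min(llr, LLR_CLAMP), -LLR_CLAMP)
    }
  }
  out
}

long_scores <- function(rows, score_mat) {
  if (ncol(score_mat) == 0) {
    return(cbind(rows[0, ], data.frame(vowel = character(),
                                       log10_lr = numeric())))
  }
  do.call(rbind, lapply(colnames(score_mat), function(v) {
    keep <- !is.na(score_mat[, v])
    if (!any(keep)) return(NULL)
    cbind(rows[keep, , drop = FALSE],
          data.frame(vowel = v, log10_lr = score_mat[keep, v],
                     stringsAsFactors = FALSE))
  }))
}

#' Cross-validated calibrated likelihood ratios for a speaker group
#'
#' Runs the leave-pair-out protocol: for each of the `C(n, 2)` tested
#' pairs, per-vowel MVKD background models are fit on the remaining
#' members; development scores for fusion are all same- and
#' different-speaker comparisons computable among background members only
#' (28 Hd + 8 Hs at group size 10); a fused, calibrated log10 LR is
#' emitted for the tested pair and for each tested member's same-speaker
#' comparison under the same fold's models. Tested speakers' tokens never
#' enter background fitting or development scoring.
#'
#' @inheritParams score_all
#' @return Data frame `(speaker_a, speaker_b, hypothesis, log10_lr)` of
#'   calibrated scores: one Hd row per pair plus two Hs rows per fold.
#' @export
crossval_group <- function(group, prepared, subset, min_tokens = 3) {
  folds <- crossval_folds(group, prepared, subset, min_tokens)
  out <- lapply(folds, function(f) {
    dev <- f$dev
    ok_col <- colSums(!is.na(dev)) > 0
    dev <- dev[, ok_col, drop = FALSE]
    ok_row <- rowSums(!is.na(dev)) > 0
    if (ncol(dev) == 0 ||
        sum(f$dev_rows$hypothesis[ok_row] == "Hs") < 2 ||
        sum(f$dev_rows$hypothesis[ok_row] == "Hd") < 2) {
      return(NULL)  # fold unusable: too little development data
    }
    model <- fit_fusion(dev[ok_row, , drop = FALSE],
                        f$dev_rows$hypothesis[ok_row])
    test <- f$test[, colnames(dev)[colnames(dev) %in% colnames(f$test)],
                   drop = FALSE]
    scorable <- rowSums(!is.na(test)) > 0
    if (!any(scorable)) return(NULL)
    cal <- predict_fusion(model, test[scorable, , drop = FALSE])
    cal <- pmin(pmax(as.numeric(cal), -LLR_CLAMP), LLR_CLAMP)
    cbind(f$test_rows[scorable, , drop = FALSE],
          data.frame(log10_lr = cal))
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}
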