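# Penalised weighted logistic log-likelihood used as the independent
# optimiser oracle (optim/BFGS instead of IRLS).
oracle_fit <- function(x, y, lambda) {
  x <- as.matrix(x)
  wts <- ifelse(y, 0.5 / sum(y), 0.5 / sum(!y))
  obj <- function(beta) {
    eta <- drop(cbind(1, x) %*% beta)
    -sum(wts * (as.numeric(y) * eta - log1p(exp(eta)))) +
      lambda / 2 * sum(beta[-1]^2)
  }
  stats::optim(rep(0, ncol(x) + 1), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$par
}

test_that("a symmetric one-dimensional dev set calibrates the midpoint to zero", {
  dev <- matrix(c(rep(1, 5), rep(-1, 5)), ncol = 1)
  labels <- rep(c("Hs", "Hd"), each = 5)
  m <- fit_fusion(dev, labels)
  expect_equal(unname(predict_fusion(m, matrix(0))), 0, tolerance = 1e-9)
  expect_true(m$separable)
})

test_that("identical Hs and Hd score distributions yield weights near zero", {
  x <- matrix(c(0.3, -1.2, 0.8, 2.0, 0.3, -1.2, 0.8, 2.0), ncol = 1)
  m <- fit_fusion(x, rep(c("Hs", "Hd"), each = 4))
  expect_lt(abs(m$weights), 1e-8)
  expect_lt(abs(predict_fusion(m, matrix(1.7))), 1e-8)
})

test_that("fitted calibration matches an independent optimiser", {
  # 2-vowel toy development set of 8 comparisons
  set.seed(301)
  x <- cbind(a = c(1.2, 0.8, 1.5, 0.3, -0.9, -1.1, -0.2, -1.6),
             i = c(0.9, 1.1, 0.2, 0.7, -0.4, -1.3, -0.8, -0.5))
  y <- rep(c(TRUE, FALSE), each = 4)
  for (lam in c(1e-3, 0.05)) {
    m <- fit_fusion(x, y, ridge_lambda = lam)
    beta <- oracle_fit(x, y, lam)
    newx <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("a", "i")))
    want <- drop(beta[1] + newx %*% beta[-1]) / log(10)
    expect_equal(unname(predict_fusion(m, newx)), unname(want),
                 tolerance = 1e-6)
  }
})

test_that("degenerate label sets are rejected", {
  x <- matrix(rnorm(8), ncol = 1)
  expect_error(fit_fusion(x, rep("Hs", 8)), ">= 2")
  expect_error(fit_fusion(x, c("Hs", rep("Hd", 7))), ">= 2")
})

test_that("missing dimensions at prediction are imputed with dev means", {
  x <- cbind(a = c(2, 1, -1, -2, 1.5, -1.5), i = c(1, 2, -2, -1, 1.2, -0.8))
  m <- fit_fusion(x, rep(c("Hs", "Hd", "Hs"), each = 2))
  p_full <- predict_fusion(m, cbind(a = 1, i = mean(x[, "i"])))
  p_miss <- predict_fusion(m, cbind(a = 1, i = NA_real_))
  expect_equal(p_full, p_miss)
})

test_that("calibration does not worsen dev-set Cllr beyond the penalty slack", {
  # the balanced-weight logistic objective equals ln2 * Cllr plus the
  # ridge penalty, so the fitted map's dev Cllr can exceed that of any
  # fixed affine comparator by at most the comparator's own penalty
  # (divided by ln 2); here the comparator maps raw scores identically
  # via their mean (unit total weight, zero offset)
  corp <- small_synth_corpus(seed = 15, tokens = c(150, 220))
  ds <- downsample(corp, "dialogue", seed = 5)
  prep <- formantlr:::prepare_condition_data(ds, "matched", seed = 6)
  g <- make_groups(corpus_speakers(corp), twin_map(corp), n_groups = 1,
                   seed = 2)[[1]]
  folds <- formantlr:::crossval_folds(g, prep, c(3L, 4L))
  for (f in folds[seq(1, 45, by = 5)]) {
    hs <- f$dev_rows$hypothesis == "Hs"
    m <- fit_fusion(f$dev, f$dev_rows$hypothesis)
    cal <- predict_fusion(m, f$dev)
    cal_cllr <- cllr(10^cal[hs], 10^cal[!hs])
    raw <- rowMeans(f$dev, na.rm = TRUE)
    raw_cllr <- cllr(10^raw[hs], 10^raw[!hs])
    k <- length(m$dims)
    slack <- m$lambda * log(10)^2 / (2 * k) / log(2)
    expect_lte(cal_cllr, raw_cllr + slack + 1e-9)
  }
})

test_that("fold accounting and leakage exclusion follow the protocol", {
  corp <- small_synth_corpus(seed = 16, tokens = c(120, 160))
  ds <- downsample(corp, "dialogue", seed = 5)
  prep <- formantlr:::prepare_condition_data(ds, "matched", seed = 6)
  g <- make_groups(corpus_speakers(corp), twin_map(corp), n_groups = 1,
                   seed = 3)[[1]]
  folds <- formantlr:::crossval_folds(g, prep, c(1L, 2L))
  expect_length(folds, 45)
  for (f in folds[c(1, 20, 45)]) {
    # 28 background Hd + 8 background Hs development comparisons
    expect_equal(sum(f$dev_rows$hypothesis == "Hd"), 28)
    expect_equal(sum(f$dev_rows$hypothesis == "Hs"), 8)
    # tested speakers never appear in development scoring
    dev_spk <- unique(c(f$dev_rows$speaker_a, f$dev_rows$speaker_b))
    expect_length(intersect(f$pair, dev_spk), 0)
    # one Hd test row for the pair plus one Hs per member
    expect_equal(f$test_rows$hypothesis, c("Hd", "Hs", "Hs"))
  }
})

test_that("calibrated group scores cover all pairs and both hypotheses", {
  corp <- small_synth_corpus(seed = 18, tokens = c(120, 160))
  ds <- downsample(corp, "dialogue", seed = 5)
  prep <- formantlr:::prepare_condition_data(ds, "matched", seed = 6)
  g <- make_groups(corpus_speakers(corp), twin_map(corp), n_groups = 1,
                   seed = 4)[[1]]
  cal <- crossval_group(g, prep, c(3L, 4L))
  expect_equal(sum(cal$hypothesis == "Hd"), 45)
  expect_equal(sum(cal$hypothesis == "Hs"), 90)
  expect_true(all(abs(cal$log10_lr) <= 10))
  # well-separated synthetic data: calibrated system beats the
  # uninformative reference value
  expect_lt(score_metrics(cal)$cllr, 1)
})

test_that("fused all-vowel scores do no worse than the best single vowel", {
  corp <- small_synth_corpus(seed = 20, tokens = c(150, 220))
  gs <- make_groups(corpus_speakers(corp), twin_map(corp), n_groups = 4,
                    seed = 5)
  fused <- c(); per_vowel <- list()
  for (rep_i in 1:5) {
    ds <- downsample(corp, "dialogue", seed = 100 + rep_i)
    prep <- formantlr:::prepare_condition_data(ds, "matched",
                                               seed = 200 + rep_i)
    for (g in gs) {
      cal <- crossval_group(g, prep, c(1L, 2L))
      fused <- c(fused, score_metrics(cal)$cllr)
      for (v in c("a", "i")) {
        pv <- prep; pv$vowels <- v
        cal_v <- crossval_group(g, pv, c(1L, 2L))
        per_vowel[[v]] <- c(per_vowel[[v]], score_metrics(cal_v)$cllr)
      }
    }
  }
  best_single <- min(vapply(per_vowel, mean, numeric(1)))
  expect_lte(mean(fused), best_single + 0.05)
})
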