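# Toy background with exactly known model quantities (d = 1):
# speaker means mu, two tokens per speaker at mu -/+ delta so the pooled
# within-speaker variance is 2 * delta^2.
toy_background <- function(mu = c(0, 1, 2), delta = 1 / sqrt(2)) {
  lapply(seq_along(mu), function(i) {
    comparison_sample(matrix(c(mu[i] - delta, mu[i] + delta), ncol = 1),
                      speaker_id = paste0("S", i), vowel = "a", subset = 1L)
  })
}

samp <- function(values, spk = "q") {
  comparison_sample(matrix(values, ncol = 1), speaker_id = spk,
                    vowel = "a", subset = 1L)
}

# Independent quadrature oracle for the d = 1 two-level kernel LR.
quadrature_llr10 <- function(model, yq, nq, yr, nr) {
  W <- model$W[1, 1]; B <- model$B[1, 1]; h <- model$h
  mu <- model$speaker_means[, 1]
  num <- mean(vapply(mu, function(m) {
    stats::integrate(function(th) {
      stats::dnorm(yq, th, sqrt(W / nq)) * stats::dnorm(yr, th, sqrt(W / nr)) *
        stats::dnorm(th, m, h * sqrt(B))
    }, -Inf, Inf, rel.tol = 1e-12)$value
  }, numeric(1)))
  den_q <- mean(stats::dnorm(yq, mu, sqrt(h^2 * B + W / nq)))
  den_r <- mean(stats::dnorm(yr, mu, sqrt(h^2 * B + W / nr)))
  log10(num / (den_q * den_r))
}

test_that("background fitting reproduces hand-computed pooled quantities", {
  bg <- toy_background(mu = c(0, 1, 2), delta = 1 / sqrt(2))
  model <- fit_background(bg)
  # pooled within: sum of per-speaker SS / (N - m) = 3 * (2 * 1/2) / 3 = 1
  expect_equal(model$W[1, 1], 1)
  expect_equal(model$speaker_means[, 1], c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(model$B[1, 1], stats::var(c(0, 1, 2)))
  expect_equal(model$m, 3)
  # normal-reference bandwidth at d = 1, m = 3
  expect_equal(model$h, (4 / 9)^(1 / 5))
})

test_that("the bandwidth follows the normal-reference rule", {
  bg8 <- toy_background(mu = seq(0, 7), delta = 0.5)
  model <- fit_background(bg8)
  expect_equal(model$h, (4 / (3 * 8))^(1 / 5))
  expect_equal(model$h, 0.699, tolerance = 1e-3)
})

test_that("degenerate backgrounds are rejected", {
  # identical constant tokens per speaker give singular pooled covariance
  bg <- lapply(1:3, function(i) {
    comparison_sample(matrix(c(i, i), ncol = 1), vowel = "a", subset = 1L)
  })
  expect_error(fit_background(bg), "singular")
  expect_error(fit_background(toy_background()[1:2]), ">= 3")
})

test_that("scores match direct numerical integration on d = 1 toys", {
  model <- fit_background(toy_background(mu = c(0, 1, 2)))
  cases <- list(c(0.9, 1.1, 1.0, 1.2), c(-0.5, 0.5, 1.5, 2.5),
                c(2.2, 2.6, 2.3, 2.5), c(0.0, 0.4, 1.9, 2.1))
  for (cs in cases) {
    q <- samp(cs[1:2]); r <- samp(cs[3:4])
    got <- as.numeric(score_pair(model, q, r))
    want <- quadrature_llr10(model, mean(cs[1:2]), 2, mean(cs[3:4]), 2)
    expect_equal(10^got, 10^want, tolerance = 1e-6)
  }
})

test_that("with one effective component the score equals the normal two-level LR", {
  # all background means equal: the kernel mixture collapses to a single
  # Gaussian with between variance tau^2 = h^2 * B; compare against an
  # independently derived closed form based on the difference/weighted-mean
  # factorisation of the bivariate normal
  model <- structure(list(subset = 1L, vowel = "a",
                          speaker_means = matrix(rep(1.5, 3), ncol = 1),
                          W = matrix(1, 1, 1), B = matrix(0.8, 1, 1),
                          h = 1.2, m = 3),
                     class = "mvkd_model")
  tau2 <- model$h^2 * 0.8
  for (cs in list(c(1.4, 1.7), c(0.2, 2.9), c(3.0, 3.4))) {
    yq <- cs[1]; yr <- cs[2]; a <- 1 / 2; b <- 1 / 2
    mstar <- (yq / a + yr / b) / (1 / a + 1 / b)
    num <- stats::dnorm(yq - yr, 0, sqrt(a + b)) *
      stats::dnorm(mstar, 1.5, sqrt(tau2 + 1 / (1 / a + 1 / b)))
    den <- stats::dnorm(yq, 1.5, sqrt(tau2 + a)) *
      stats::dnorm(yr, 1.5, sqrt(tau2 + b))
    want <- log10(num / den)
    got <- formantlr:::mvkd_llr10(model, yq, 2, yr, 2)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("similar atypical samples support same origin; displaced samples do not", {
  # background far away from the compared samples (>= 10 pooled sd)
  bg <- toy_background(mu = c(20, 21, 22))
  model <- fit_background(bg)
  q <- samp(c(-0.1, 0.1))
  expect_gt(as.numeric(score_pair(model, q, samp(c(-0.1, 0.1), "r"))), 0)
  # questioned displaced >= 10 within-sd from reference, both typical
  model2 <- fit_background(toy_background(mu = c(0, 10, 20)))
  expect_lt(as.numeric(score_pair(model2, samp(c(-0.2, 0.2)),
                                  samp(c(19.8, 20.2), "r"))), 0)
})

test_that("widening the mean difference weakly decreases the score", {
  model <- fit_background(toy_background(mu = c(0, 1, 2)))
  seps <- c(0, 0.25, 0.5, 1, 2, 4)
  scores <- vapply(seps, function(s) {
    q <- samp(c(1 - s / 2 - 0.1, 1 - s / 2 + 0.1))
    r <- samp(c(1 + s / 2 - 0.1, 1 + s / 2 + 0.1), "r")
    as.numeric(score_pair(model, q, r))
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("scores are clamped to the +/-10 log10 range", {
  model <- fit_background(toy_background(mu = c(0, 0.5, 1), delta = 0.05))
  far <- score_pair(model, samp(c(-0.01, 0.01)), samp(c(99.9, 100.1), "r"))
  expect_equal(as.numeric(far), -10)
  expect_true(attr(far, "clamped"))
})

test_that("sample and model contracts are enforced", {
  model <- fit_background(toy_background())
  expect_error(score_pair(model, samp(c(0, 1)),
                          comparison_sample(matrix(c(0, 1), ncol = 1),
                                            vowel = "a", subset = 2L)),
               "must match")
  expect_error(comparison_sample(matrix(1, 1, 1)), ">= 2 tokens")
  expect_error(comparison_sample(matrix(c(1, NA), 2, 1)), "complete")
})

test_that("same-speaker scores exceed different-speaker scores on synthetic data", {
  corp <- small_synth_corpus(seed = 77, tokens = c(150, 200))
  dial <- corp[corp$style == "dialogue" & corp$vowel == "a", ]
  spk <- unique(dial$speaker)
  samples <- lapply(spk, function(s) {
    x <- as.matrix(dial[dial$speaker == s, c("f3_hz", "f4_hz")])
    comparison_sample(x, speaker_id = s, vowel = "a", subset = c(3L, 4L))
  })
  names(samples) <- spk
  model <- fit_background(samples[spk[1:8]])
  test_spk <- spk[9:16]
  hs <- vapply(test_spk, function(s) {
    x <- samples[[s]]$x
    half <- seq_len(nrow(x) %/% 2)
    as.numeric(score_pair(model,
      comparison_sample(x[half, ], s, "a", c(3L, 4L)),
      comparison_sample(x[-half, ], s, "a", c(3L, 4L))))
  }, numeric(1))
  pairs <- utils::combn(test_spk, 2)
  hd <- vapply(seq_len(ncol(pairs)), function(i) {
    as.numeric(score_pair(model, samples[[pairs[1, i]]],
                          samples[[pairs[2, i]]]))
  }, numeric(1))
  expect_gt(mean(hs), mean(hd))
})

test_that("group-level raw scoring yields 45 Hd and 10 Hs scores per vowel", {
  corp <- small_synth_corpus(seed = 81, tokens = c(150, 200))
  ds <- downsample(corp, "dialogue", seed = 5)
  prep <- formantlr:::prepare_condition_data(ds, "matched", seed = 6)
  g <- make_groups(corpus_speakers(corp), twin_map(corp), n_groups = 1,
                   seed = 9)[[1]]
  raw <- score_all(g, prep, c(3L, 4L))
  per_vowel_hd <- table(raw$vowel[raw$hypothesis == "Hd"])
  per_vowel_hs <- table(raw$vowel[raw$hypothesis == "Hs"])
  expect_true(all(per_vowel_hd <= 45))
  expect_true(all(per_vowel_hs <= 10))
  expect_equal(unname(per_vowel_hd["a"]), 45)  # /a/ always above minimum
  expect_equal(unname(per_vowel_hs["a"]), 10)
  expect_true(all(abs(raw$log10_lr) <= 10))
})
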