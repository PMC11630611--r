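# Synthetic vowel-formant corpus generator with known ground truth.
#
# Token model per formant k:
#   x = mu[vowel, k] + speaker_offset[spk, k] + style_offset[spk, style, k] + noise
# with Gaussian speaker offsets (twin siblings correlated), Gaussian
# speaker-specific style offsets (dialogue is the baseline style), and
# independent Gaussian within-speaker token noise. Tokens violating the
# formant ordering invariant are redrawn (a slight truncation of the
# Gaussian model).

#' Default per-vowel formant means (Hz)
#'
#' Male Brazilian Portuguese monophthong targets for the baseline
#' (dialogue) style. Calibrated so the per-vowel F1 means span about
#' 331-586 Hz, F2 about 1074-2027 Hz, F3 about 2368-2655 Hz and F4 about
#' 3387-3570 Hz, matching descriptive ranges reported for this speaker
#' population.
#'
#' @return 7 x 4 numeric matrix, rows named by [bp_vowels()], columns
#'   `f1_hz`..`f4_hz`.
#' @export
default_vowel_means <- function() {
  m <- rbind(
    i = c(331, 2027, 2655, 3570),
    e = c(410, 1900, 2560, 3500),
    E = c(530, 1750, 2500, 3450),
    a = c(586, 1350, 2430, 3420),
    O = c(560, 1150, 2390, 3400),
    o = c(430, 1100, 2380, 3390),
    u = c(350, 1074, 2368, 3387))
  colnames(m) <- c("f1_hz", "f2_hz", "f3_hz", "f4_hz")
  m
}

#' Configuration for the synthetic corpus generator
#'
#' @param n_speakers Number of speakers (default 20).
#' @param n_twin_pairs Number of identical twin pairs among them (default
#'   10; requires `2 * n_twin_pairs <= n_speakers`).
#' @param vowel_means 7 x 4 matrix of per-vowel formant means (Hz), rows
#'   named by [bp_vowels()]; default [default_vowel_means()].
#' @param between_speaker_sd Length-4 vector: SD (Hz) of speaker offsets
#'   per formant. Defaults make F3/F4 (and F1) carry more speaker-specific
#'   information relative to their within-speaker spread than F2, the
#'   configuration under which formant-subset orderings are studied.
#' @param within_speaker_sd Length-4 vector: SD (Hz) of token noise per
#'   formant, or a 4 x 4 within-speaker covariance matrix (Hz^2) when
#'   correlated token noise is wanted.
#' @param twin_similarity Correlation of twin siblings' speaker offsets,
#'   in `[0, 1]` (default 0.9).
#' @param style_shift_sd Length-4 vector: SD (Hz) of speaker-specific
#'   interview-style offsets per formant (dialogue is the baseline).
#' @param vowel_probs Named length-7 simplex over vowels; defaults to the
#'   relative token frequencies 5995:2910:1838:1684:1479:1063:973 for
#'   /a i u E e o O/ observed in the corpus this generator emulates.
#' @param tokens_per_speaker_style `c(min, max)` range for per-speaker
#'   per-style token counts (drawn uniformly), or a named list
#'   `list(dialogue = c(min, max), interview = c(min, max))` for per-style
#'   ranges. One designated minority speaker is forced to the range
#'   minimum in each style so downsampling has a unique minority class.
#' @param seed Integer seed; identical seeds give byte-identical corpora.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_speakers = 20,
                         n_twin_pairs = 10,
                         vowel_means = default_vowel_means(),
                         between_speaker_sd = c(45, 60, 140, 160),
                         within_speaker_sd = c(60, 170, 150, 170),
                         twin_similarity = 0.9,
                         style_shift_sd = c(25, 45, 55, 65),
                         vowel_probs = NULL,
                         tokens_per_speaker_style = c(200, 550),
                         seed = 1L) {
  if (is.null(vowel_probs)) {
    counts <- c(a = 5995, i = 2910, u = 1838, E = 1684,
                e = 1479, o = 1063, O = 973)
    vowel_probs <- counts[bp_vowels()] / sum(counts)
  }
  cfg <- list(n_speakers = as.integer(n_speakers),
              n_twin_pairs = as.integer(n_twin_pairs),
              vowel_means = vowel_means,
              between_speaker_sd = between_speaker_sd,
              within_speaker_sd = within_speaker_sd,
              twin_similarity = twin_similarity,
              style_shift_sd = style_shift_sd,
              vowel_probs = vowel_probs,
              tokens_per_speaker_style = tokens_per_speaker_style,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_speakers < 1) stop("n_speakers must be >= 1", call. = FALSE)
  if (2 * cfg$n_twin_pairs > cfg$n_speakers) {
    stop("2 * n_twin_pairs must not exceed n_speakers", call. = FALSE)
  }
  vm <- cfg$vowel_means
  if (!is.matrix(vm) || ncol(vm) != 4 ||
      !setequal(rownames(vm), bp_vowels())) {
    stop("vowel_means must be a 7 x 4 matrix with rows named by bp_vowels()",
         call. = FALSE)
  }
  if (length(cfg$between_speaker_sd) != 4 || any(cfg$between_speaker_sd < 0)) {
    stop("between_speaker_sd must be 4 nonnegative values", call. = FALSE)
  }
  wsd <- cfg$within_speaker_sd
  if (is.matrix(wsd)) {
    if (!identical(dim(wsd), c(4L, 4L)) || !isSymmetric(unname(wsd))) {
      stop("within_speaker_sd matrix must be symmetric 4 x 4", call. = FALSE)
    }
  } else if (length(wsd) != 4 || any(wsd < 0)) {
    stop("within_speaker_sd must be 4 nonnegative SDs or a 4 x 4 covariance",
         call. = FALSE)
  }
  if (cfg$twin_similarity < 0 || cfg$twin_similarity > 1) {
    stop("twin_similarity must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$style_shift_sd) != 4 || any(cfg$style_shift_sd < 0)) {
    stop("style_shift_sd must be 4 nonnegative values", call. = FALSE)
  }
  vp <- cfg$vowel_probs
  if (length(vp) != 7 || !setequal(names(vp), bp_vowels()) ||
      any(vp < 0) || abs(sum(vp) - 1) > 1e-8) {
    stop("vowel_probs must be a simplex named by bp_vowels()", call. = FALSE)
  }
  rng <- cfg$tokens_per_speaker_style
  check_range <- function(r) {
    length(r) == 2 && r[1] >= 1 && r[1] <= r[2]
  }
  if (is.list(rng)) {
    if (!setequal(names(rng), speaking_styles()) ||
        !all(vapply(rng, check_range, logical(1)))) {
      stop("per-style token ranges must name both styles with min <= max",
           call. = FALSE)
    }
  } else if (!check_range(rng)) {
    stop("tokens_per_speaker_style must satisfy 1 <= min <= max", call. = FALSE)
  }
  invisible(TRUE)
}

token_range_for_style <- function(cfg, style) {
  rng <- cfg$tokens_per_speaker_style
  if (is.list(rng)) rng[[style]] else rng
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws a corpus under the additive Gaussian model described in
#' [synth_config()]. Twin siblings share correlated speaker offsets
#' (correlation `twin_similarity`); each speaker receives an independent
#' interview-style offset; tokens violating `F1 < F2 < F3 < F4` (or the
#' 5000 Hz ceiling) are redrawn. One designated minority speaker (the
#' last) is forced to the minimum of the token-count range in each style
#' so the minority class in downsampling is unique.
#'
#' @param config A [synth_config()].
#' @return List with elements `corpus` (a `formant_corpus`) and `truth`
#'   (list: `speaker_offsets` n x 4 matrix, `style_offsets` named list of
#'   n x 4 matrices per style, `config`).
#' @export
#' @examples
#' cfg <- synth_config(n_speakers = 4, n_twin_pairs = 2,
#'                     tokens_per_speaker_style = c(30, 40), seed = 7)
#' gen <- generate_corpus(cfg)
#' summary(gen$corpus$f1_hz)
generate_corpus <- function(config) {
  validate_synth_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_speakers
    speakers <- sprintf("S%02d", seq_len(n))
    pair_of <- rep(NA_character_, n)
    if (cfg$n_twin_pairs > 0) {
      pair_of[seq_len(2 * cfg$n_twin_pairs)] <-
        rep(sprintf("T%02d", seq_len(cfg$n_twin_pairs)), each = 2)
    }

    # Speaker offsets: twin siblings get correlated draws via a shared
    # component: off = sqrt(rho) * shared + sqrt(1 - rho) * own.
    sB <- cfg$between_speaker_sd
    rho <- cfg$twin_similarity
    off <- matrix(0, n, 4, dimnames = list(speakers, NULL))
    k <- 1L
    while (k <= n) {
      if (!is.na(pair_of[k]) && k < n && identical(pair_of[k], pair_of[k + 1])) {
        shared <- stats::rnorm(4) * sB
        for (j in 0:1) {
          off[k + j, ] <- sqrt(rho) * shared +
            sqrt(1 - rho) * stats::rnorm(4) * sB
        }
        k <- k + 2L
      } else {
        off[k, ] <- stats::rnorm(4) * sB
        k <- k + 1L
      }
    }

    style_off <- list(
      dialogue = matrix(0, n, 4, dimnames = list(speakers, NULL)),
      interview = matrix(stats::rnorm(n * 4), n, 4,
                         dimnames = list(speakers, NULL)) *
        rep(cfg$style_shift_sd, each = n))

    wsd <- cfg$within_speaker_sd
    w_chol <- if (is.matrix(wsd)) chol(wsd) else NULL

    draw_noise <- function(m) {
      if (is.null(w_chol)) {
        matrix(stats::rnorm(m * 4), m, 4) * rep(wsd, each = m)
      } else {
        matrix(stats::rnorm(m * 4), m, 4) %*% w_chol
      }
    }

    vm <- cfg$vowel_means[bp_vowels(), , drop = FALSE]
    rows <- vector("list", n * 2)
    ri <- 0L
    for (s in seq_len(n)) {
      for (style in speaking_styles()) {
        rng <- token_range_for_style(cfg, style)
        m <- if (s == n) rng[1] else {
          if (rng[1] == rng[2]) rng[1] else
            sample(seq.int(rng[1], rng[2]), 1)
        }
        vow <- sample(bp_vowels(), m, replace = TRUE,
                      prob = cfg$vowel_probs[bp_vowels()])
        mu <- vm[vow, , drop = FALSE] +
          matrix(off[s, ] + style_off[[style]][s, ], m, 4, byrow = TRUE)
        x <- mu + draw_noise(m)
        bad <- which(x[, 1] <= 0 | x[, 1] >= x[, 2] | x[, 2] >= x[, 3] |
                       x[, 3] >= x[, 4] | x[, 4] >= 5000)
        tries <- 0L
        while (length(bad) > 0) {
          x[bad, ] <- mu[bad, , drop = FALSE] + draw_noise(length(bad))
          bad <- bad[x[bad, 1] <= 0 | x[bad, 1] >= x[bad, 2] |
                       x[bad, 2] >= x[bad, 3] | x[bad, 3] >= x[bad, 4] |
                       x[bad, 4] >= 5000]
          tries <- tries + 1L
          if (tries > 1000L) {
            stop("rejection sampling failed; configured variances are ",
                 "incompatible with the formant ordering constraint",
                 call. = FALSE)
          }
        }
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          speaker = speakers[s], twin_pair = pair_of[s], style = style,
          vowel = vow,
          duration_s = round(exp(stats::rnorm(m, log(0.08), 0.4)), 4),
          f1_hz = round(x[, 1], 1), f2_hz = round(x[, 2], 1),
          f3_hz = round(x[, 3], 1), f4_hz = round(x[, 4], 1),
          stringsAsFactors = FALSE)
      }
    }
    corpus <- formant_corpus(do.call(rbind, rows[seq_len(ri)]))
    truth <- list(speaker_offsets = off, style_offsets = style_off,
                  config = cfg)
    list(corpus = corpus, truth = truth)
  })
}

#' Recover between- and within-speaker variance components
#'
#' Method-of-moments estimates from a one-way ANOVA decomposition
#' (speakers as the grouping factor) computed per formant within each
#' vowel x style cell and pooled across cells by degrees of freedom:
#' `sigma_w^2 = MSW` and `sigma_b^2 = (MSB - MSW) / n0` with
#' `n0 = (N - sum(n_i^2)/N) / (m - 1)`. A parameter-recovery harness for
#' [generate_corpus()].
#'
#' @param corpus A `formant_corpus` with at least 5 speakers and at least
#'   10 tokens per speaker.
#' @return Data frame `(formant, between_sd, within_sd)` in Hz.
#' @export
recover_variance_components <- function(corpus) {
  spk <- corpus_speakers(corpus)
  if (length(spk) < 5) stop("need at least 5 speakers", call. = FALSE)
  if (min(table(corpus$speaker)) < 10) {
    stop("need at least 10 tokens per speaker", call. = FALSE)
  }
  fcols <- c("f1_hz", "f2_hz", "f3_hz", "f4_hz")
  out <- data.frame(formant = c("F1", "F2", "F3", "F4"),
                    between_sd = NA_real_, within_sd = NA_real_)
  cells <- split(seq_len(nrow(corpus)),
                 interaction(corpus$vowel, corpus$style, drop = TRUE))
  for (k in seq_along(fcols)) {
    ssw <- 0; dfw <- 0; sb_num <- 0; sb_den <- 0
    for (idx in cells) {
      g <- corpus$speaker[idx]
      if (length(unique(g)) < 2) next
      x <- corpus[[fcols[k]]][idx]
      ni <- table(g)
      m <- length(ni); N <- length(x)
      gm <- tapply(x, g, mean)
      ssw_c <- sum((x - gm[g])^2)
      ssb_c <- sum(ni * (gm - mean(x))^2)
      msw <- ssw_c / (N - m)
      msb <- ssb_c / (m - 1)
      n0 <- (N - sum(ni^2) / N) / (m - 1)
      ssw <- ssw + ssw_c; dfw <- dfw + (N - m)
      # pool the per-cell between-variance estimates by their df
      sb_num <- sb_num + (m - 1) * max((msb - msw) / n0, 0)
      sb_den <- sb_den + (m - 1)
    }
    if (dfw == 0 || sb_den == 0) {
      stop("insufficient data to estimate variance components", call. = FALSE)
    }
    out$within_sd[k] <- sqrt(ssw / dfw)
    out$between_sd[k] <- sqrt(sb_num / sb_den)
  }
  out
}
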