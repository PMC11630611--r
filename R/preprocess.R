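# Outlier screening and minority-class downsampling.

#' Interquartile-range outlier screening
#'
#' Within each speaker x style x vowel cell and for each formant F1-F4
#' independently, flags tokens whose formant value falls outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` (quartiles by linear interpolation,
#' `stats::quantile` type 7). A token is removed if any formant flags it;
#' screening is applied once, not iterated.
#'
#' @param corpus A `formant_corpus`.
#' @param k IQR multiplier, `> 0` (default 2.5, the deliberately
#'   permissive bound that avoids discarding genuine speaker-specific
#'   extremes).
#' @return List: `corpus` (screened), `removed` (data frame
#'   `(row, speaker, style, vowel, formant, value, lower, upper)` with one
#'   row per flagged token x triggering formant).
#' @export
remove_outliers <- function(corpus, k = 2.5) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  fcols <- c("f1_hz", "f2_hz", "f3_hz", "f4_hz")
  n <- nrow(corpus)
  drop <- logical(n)
  rem <- list()
  cells <- split(seq_len(n),
                 interaction(corpus$speaker, corpus$style, corpus$vowel,
                             drop = TRUE))
  for (idx in cells) {
    for (col in fcols) {
      x <- corpus[[col]][idx]
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - k * iqr
      hi <- q[2] + k * iqr
      bad <- x < lo | x > hi
      if (any(bad)) {
        drop[idx[bad]] <- TRUE
        rem[[length(rem) + 1L]] <- data.frame(
          row = idx[bad],
          speaker = corpus$speaker[idx[bad]],
          style = corpus$style[idx[bad]],
          vowel = corpus$vowel[idx[bad]],
          formant = toupper(sub("_hz", "", col)),
          value = x[bad], lower = lo, upper = hi,
          stringsAsFactors = FALSE)
      }
    }
  }
  removed <- if (length(rem) > 0) {
    r <- do.call(rbind, rem)
    r[order(r$row, r$formant), , drop = FALSE]
  } else {
    data.frame(row = integer(), speaker = character(), style = character(),
               vowel = character(), formant = character(), value = numeric(),
               lower = numeric(), upper = numeric())
  }
  rownames(removed) <- NULL
  out <- corpus[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(corpus)
  list(corpus = out, removed = removed)
}

#' Minority-class downsampling within one speaking style
#'
#' Restricts the corpus to `style` and equalises per-speaker token counts
#' to the minority speaker's count `m`: every other speaker's tokens are
#' sampled uniformly without replacement down to `m`, while the minority
#' speaker's tokens pass through unsampled. The natural vowel distribution
#' is preserved (no per-vowel balancing).
#'
#' @param corpus A `formant_corpus`.
#' @param style One of [speaking_styles()].
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @return A `formant_corpus` with exactly `m` tokens per speaker.
#' @export
downsample <- function(corpus, style, seed = NULL) {
  style <- match.arg(style, speaking_styles())
  sub <- corpus[corpus$style == style, , drop = FALSE]
  counts <- table(factor(sub$speaker, levels = corpus_speakers(corpus)))
  if (any(counts == 0)) {
    stop("speaker(s) with no '", style, "' tokens: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  m <- min(counts)
  with_seed(seed, downsample_to(sub, per_speaker = m))
}

# Sample each speaker in `sub` (single- or mixed-style rows) down to
# `per_speaker` tokens within each style present; cells already at the
# target pass through unsampled.
downsample_to <- function(sub, per_speaker) {
  keep <- unlist(lapply(
    split(seq_len(nrow(sub)), list(sub$speaker, sub$style), drop = TRUE),
    function(idx) {
      if (length(idx) == per_speaker) idx
      else sort(sample(idx, per_speaker))
    }), use.names = FALSE)
  out <- sub[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("formant_corpus", "data.frame")
  out
}

#' Cross-style downsampling for mismatched comparisons
#'
#' Equalises every speaker's token count in each style to the global
#' minimum per-speaker-per-style count `m*` taken across both styles, so
#' reference (interview) and questioned (dialogue) samples carry the same
#' number of observations for every speaker.
#'
#' @inheritParams downsample
#' @return A `formant_corpus` with exactly `m*` tokens per speaker per
#'   style.
#' @export
downsample_mismatched <- function(corpus, seed = NULL) {
  spk <- corpus_speakers(corpus)
  counts <- table(factor(corpus$speaker, levels = spk),
                  factor(corpus$style, levels = speaking_styles()))
  if (any(counts == 0)) {
    bad <- rownames(counts)[rowSums(counts == 0) > 0]
    stop("speaker(s) missing a style entirely: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- min(counts)
  with_seed(seed, downsample_to(corpus, per_speaker = m))
}
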