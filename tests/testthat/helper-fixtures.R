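# Shared fixtures: small corpora built in code.

# A minimal hand-written corpus: `n` tokens per speaker x style, valid
# formant values, single vowel by default.
toy_corpus <- function(speakers = c("S01", "S02", "S03"),
                       styles = "dialogue", vowels = "a", n = 3,
                       f_base = c(500, 1500, 2500, 3500),
                       twin_pairs = NULL) {
  rows <- expand.grid(speaker = speakers, style = styles, vowel = vowels,
                      tok = seq_len(n), stringsAsFactors = FALSE)
  jitter <- (seq_len(nrow(rows)) %% 7) * 3
  tp <- if (is.null(twin_pairs)) rep(NA_character_, nrow(rows)) else
    twin_pairs[rows$speaker]
  formant_corpus(data.frame(
    speaker = rows$speaker, twin_pair = tp, style = rows$style,
    vowel = rows$vowel, duration_s = 0.08,
    f1_hz = f_base[1] + jitter, f2_hz = f_base[2] + jitter,
    f3_hz = f_base[3] + jitter, f4_hz = f_base[4] + jitter))
}

# Canonical 20-speaker / 10-twin-pair map.
canonical_twin_map <- function() {
  stats::setNames(rep(sprintf("T%02d", 1:10), each = 2), sprintf("S%02d", 1:20))
}

# Small but non-degenerate synthetic corpus for pipeline tests.
small_synth_corpus <- function(seed = 42, tokens = c(200, 300)) {
  cfg <- synth_config(tokens_per_speaker_style = tokens, seed = seed)
  generate_corpus(cfg)$corpus
}

# Independent convex-hull (gift wrapping) + fan-triangulation area oracle.
hull_area_oracle <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    nxt <- cand[1]
    for (q in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
        (pts[nxt, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      if (cr < 0 ||
          (cr == 0 && sum((pts[q, ] - pts[p, ])^2) >
             sum((pts[nxt, ] - pts[p, ])^2))) {
        nxt <- q
      }
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) stop("hull oracle failed")
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  # fan triangulation from the first hull vertex
  a <- 0
  for (i in 2:(length(hull) - 1)) {
    a <- a + 0.5 * abs((hx[i] - hx[1]) * (hy[i + 1] - hy[1]) -
                         (hx[i + 1] - hx[1]) * (hy[i] - hy[1]))
  }
  a
}
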