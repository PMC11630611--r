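# Corpus data model and tab-separated token-table I/O.
#
# A corpus is a data frame of vowel tokens, one row per measured token:
# speaker, twin_pair, style, vowel, duration_s, f1_hz..f4_hz. Vowel labels
# are stored as ASCII codes for the seven Brazilian Portuguese oral
# monophthongs; `vowel_ipa()` maps them to IPA.

#' Vowel label inventory
#'
#' ASCII codes used for the seven Brazilian Portuguese oral monophthongs
#' /i e ɛ a ɔ o u/. The open-mid vowels are coded `E` (IPA
#' ɛ) and `O` (IPA ɔ); the remaining labels coincide with IPA.
#'
#' @return Character vector of the seven vowel codes.
#' @export
#' @examples
#' bp_vowels()
#' vowel_ipa(bp_vowels())
bp_vowels <- function() c("i", "e", "E", "a", "O", "o", "u")

#' @rdname bp_vowels
#' @param vowel Character vector of ASCII vowel codes.
#' @export
vowel_ipa <- function(vowel) {
  map <- c(i = "i", e = "e", E = "ɛ", a = "a",
           O = "ɔ", o = "o", u = "u")
  unname(map[vowel])
}

#' Speaking style labels
#' @return Character vector `c("dialogue", "interview")`.
#' @export
speaking_styles <- function() c("dialogue", "interview")

corpus_columns <- function() {
  c("speaker", "twin_pair", "style", "vowel", "duration_s",
    "f1_hz", "f2_hz", "f3_hz", "f4_hz")
}

#' Construct a formant corpus
#'
#' Builds and validates a `formant_corpus`: a data frame with columns
#' `speaker`, `twin_pair`, `style`, `vowel`, `duration_s`, `f1_hz`,
#' `f2_hz`, `f3_hz`, `f4_hz`. Validation enforces the measurement
#' invariants: positive duration, formant ordering
#' `0 < F1 < F2 < F3 < F4 < 5000` Hz (the LPC extraction ceiling), vowel
#' labels drawn from [bp_vowels()], styles from [speaking_styles()], and a
#' twin map in which every twin-pair label covers exactly two speakers
#' (`NA` marks speakers without a twin in the corpus).
#'
#' @param tokens Data frame with the columns above.
#' @return A `formant_corpus` (data frame subclass), row order preserved.
#' @export
#' @examples
#' tok <- data.frame(speaker = "S01", twin_pair = NA, style = "dialogue",
#'                   vowel = "a", duration_s = 0.08,
#'                   f1_hz = 600, f2_hz = 1300, f3_hz = 2400, f4_hz = 3400)
#' formant_corpus(tok)
formant_corpus <- function(tokens) {
  stopifnot(is.data.frame(tokens))
  missing <- setdiff(corpus_columns(), names(tokens))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tokens <- as.data.frame(tokens)[, corpus_columns()]
  tokens$speaker <- as.character(tokens$speaker)
  tokens$twin_pair <- as.character(tokens$twin_pair)
  tokens$style <- as.character(tokens$style)
  tokens$vowel <- as.character(tokens$vowel)
  for (col in c("duration_s", "f1_hz", "f2_hz", "f3_hz", "f4_hz")) {
    tokens[[col]] <- as.numeric(tokens[[col]])
  }
  validate_corpus(tokens)
  class(tokens) <- c("formant_corpus", "data.frame")
  tokens
}

validate_corpus <- function(tokens) {
  if (nrow(tokens) == 0) return(invisible(TRUE))
  bad_style <- !tokens$style %in% speaking_styles()
  if (any(bad_style)) {
    stop("invalid style label(s) in rows: ",
         paste(utils::head(which(bad_style), 10), collapse = ", "),
         call. = FALSE)
  }
  bad_vowel <- !tokens$vowel %in% bp_vowels()
  if (any(bad_vowel)) {
    stop("invalid vowel label(s) in rows: ",
         paste(utils::head(which(bad_vowel), 10), collapse = ", "),
         " (expected one of ", paste(bp_vowels(), collapse = " "), ")",
         call. = FALSE)
  }
  num <- as.matrix(tokens[, c("duration_s", "f1_hz", "f2_hz", "f3_hz", "f4_hz")])
  if (any(!is.finite(num))) {
    stop("non-finite numeric value(s) in rows: ",
         paste(utils::head(which(rowSums(!is.finite(num)) > 0), 10),
               collapse = ", "), call. = FALSE)
  }
  if (any(tokens$duration_s <= 0)) {
    stop("non-positive duration in rows: ",
         paste(utils::head(which(tokens$duration_s <= 0), 10), collapse = ", "),
         call. = FALSE)
  }
  f <- as.matrix(tokens[, c("f1_hz", "f2_hz", "f3_hz", "f4_hz")])
  bad_ord <- f[, 1] <= 0 | f[, 1] >= f[, 2] | f[, 2] >= f[, 3] |
    f[, 3] >= f[, 4] | f[, 4] >= 5000
  if (any(bad_ord)) {
    stop("formant ordering violated (need 0 < F1 < F2 < F3 < F4 < 5000 Hz) ",
         "in rows: ", paste(utils::head(which(bad_ord), 10), collapse = ", "),
         call. = FALSE)
  }
  tw <- stats::na.omit(unique(tokens[, c("speaker", "twin_pair")]))
  if (nrow(tw) > 0) {
    n_per_pair <- table(tw$twin_pair)
    bad <- names(n_per_pair)[!n_per_pair %in% c(2L)]
    if (length(bad) > 0) {
      stop("twin pair(s) not mapping to exactly two speakers: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    per_spk <- tapply(tw$twin_pair, tw$speaker, function(x) length(unique(x)))
    if (any(per_spk > 1)) {
      stop("speaker(s) assigned to more than one twin pair: ",
           paste(names(per_spk)[per_spk > 1], collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Speakers and twin map of a corpus
#'
#' @param corpus A `formant_corpus`.
#' @return `corpus_speakers()`: character vector of speaker ids.
#'   `twin_map()`: named character vector mapping speaker id to twin-pair
#'   label (`NA` if the speaker has no twin in the corpus).
#' @export
corpus_speakers <- function(corpus) sort(unique(corpus$speaker))

#' @rdname corpus_speakers
#' @export
twin_map <- function(corpus) {
  u <- unique(corpus[, c("speaker", "twin_pair")])
  out <- stats::setNames(u$twin_pair, u$speaker)
  out[sort(names(out))]
}

#' Read a vowel token table
#'
#' Reads the tab-separated token-table format written by [write_corpus()]
#' (header + one token per row, `.` decimal separator, UTF-8). Parsing is
#' strict: missing columns, non-numeric formant or duration fields
#' (including values with thousands separators), and rows violating the
#' formant-ordering invariant are errors, never silent drops.
#'
#' @param path Path to a token table.
#' @param sep Field delimiter (default tab).
#' @return A `formant_corpus`, rows in file order.
#' @export
read_corpus <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", na.strings = "NA",
                           fileEncoding = "UTF-8", check.names = FALSE,
                           quote = "")
  missing <- setdiff(corpus_columns(), names(raw))
  if (length(missing) > 0) {
    stop("token table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("duration_s", "f1_hz", "f2_hz", "f3_hz", "f4_hz")) {
    v <- raw[[col]]
    ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", v)
    if (any(!ok)) {
      stop("non-numeric value in column '", col, "' at data row(s): ",
           paste(utils::head(which(!ok), 10), collapse = ", "),
           " (thousands separators are not accepted)", call. = FALSE)
    }
    raw[[col]] <- as.numeric(v)
  }
  formant_corpus(raw)
}

#' Write a vowel token table
#'
#' Writes the corpus in the canonical tab-separated layout (UTF-8, `.`
#' decimal separator). [read_corpus()] of the written file reproduces the
#' corpus token for token.
#'
#' @param corpus A `formant_corpus`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  utils::write.table(as.data.frame(corpus), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Token counts by speaker, style and vowel
#'
#' Tabulates token counts per speaker x style x vowel cell in long format,
#' with per-speaker-per-style subtotals and a grand total as attributes.
#'
#' @param corpus A `formant_corpus`.
#' @return Data frame `(speaker, style, vowel, n)` covering occupied cells,
#'   with attributes `by_speaker_style` (data frame `(speaker, style, n)`)
#'   and `total` (corpus size).
#' @export
summarize_corpus <- function(corpus) {
  validate_corpus(corpus)
  if (nrow(corpus) == 0) {
    out <- data.frame(speaker = character(), style = character(),
                      vowel = character(), n = integer())
    attr(out, "by_speaker_style") <-
      data.frame(speaker = character(), style = character(), n = integer())
    attr(out, "total") <- 0L
    return(out)
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(corpus))),
                          by = list(speaker = corpus$speaker,
                                    style = corpus$style,
                                    vowel = corpus$vowel),
                          FUN = sum)
  agg <- agg[order(agg$speaker, agg$style, agg$vowel), ]
  rownames(agg) <- NULL
  ss <- stats::aggregate(list(n = agg$n),
                         by = list(speaker = agg$speaker, style = agg$style),
                         FUN = sum)
  ss <- ss[order(ss$speaker, ss$style), ]
  rownames(ss) <- NULL
  attr(agg, "by_speaker_style") <- ss
  attr(agg, "total") <- sum(agg$n)
  agg
}

#' @export
print.formant_corpus <- function(x, ...) {
  spk <- corpus_speakers(x)
  cat("formant_corpus: ", nrow(x), " tokens, ", length(spk), " speakers, ",
      length(unique(x$style)), " style(s), ",
      length(unique(x$vowel)), " vowel(s)\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
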