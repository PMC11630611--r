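# Orchestration of the matched-style, mismatched-style, and per-vowel
# designs, plus vowel-space descriptives.

#' Parse a formant-subset label
#'
#' @param label String like `"F3"` or `"F1+F2+F3+F4"`.
#' @return Sorted integer vector of formant indices in 1..4.
#' @export
#' @examples
#' parse_subset("F3+F4")
parse_subset <- function(label) {
  parts <- strsplit(gsub(" ", "", label), "+", fixed = TRUE)[[1]]
  idx <- match(parts, FORMANT_NAMES)
  if (any(is.na(idx)) || length(idx) == 0 || anyDuplicated(idx)) {
    stop("invalid formant subset label: ", label, call. = FALSE)
  }
  sort(idx)
}

subset_label <- function(idx) paste(FORMANT_NAMES[sort(idx)], collapse = "+")

#' Experiment configuration
#'
#' @param formant_subsets Character vector of subset labels over
#'   `F1..F4`, e.g. `c("F1+F2", "F3+F4", "F1+F2+F3+F4")`.
#' @param conditions Subset of
#'   `c("matched-dialogue", "matched-interview", "mismatched")`.
#' @param n_groups Number of random speaker groups (study design: 150).
#' @param n_downsample_reps Number of downsampling repetitions per group
#'   (study design: 100).
#' @param group_size Speakers per group (default 10).
#' @param min_tokens Minimum tokens per vowel per comparison sample
#'   (default 3).
#' @param seed Master seed; all group formation, downsampling and
#'   splitting seeds derive from it deterministically.
#' @param scale `"desk"` (default; caps `n_groups <= 10` and
#'   `n_downsample_reps <= 5` for tractable runs) or `"paper"` (no caps;
#'   the full design multiplies out to millions of scored comparisons).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(formant_subsets = c("F1+F2", "F3+F4",
                                                  "F1+F2+F3+F4"),
                              conditions = c("matched-dialogue",
                                             "matched-interview",
                                             "mismatched"),
                              n_groups = 5,
                              n_downsample_reps = 3,
                              group_size = 10,
                              min_tokens = 3,
                              seed = 1L,
                              scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  conditions <- match.arg(conditions,
                          c("matched-dialogue", "matched-interview",
                            "mismatched"), several.ok = TRUE)
  if (length(formant_subsets) == 0) stop("need >= 1 subset", call. = FALSE)
  lapply(formant_subsets, parse_subset)  # validate
  if (scale == "desk") {
    if (n_groups > 10 || n_downsample_reps > 5) {
      stop("desk scale caps n_groups at 10 and n_downsample_reps at 5; ",
           "use scale = \"paper\" for the full design", call. = FALSE)
    }
  }
  structure(list(formant_subsets = formant_subsets, conditions = conditions,
                 n_groups = as.integer(n_groups),
                 n_downsample_reps = as.integer(n_downsample_reps),
                 group_size = as.integer(group_size),
                 min_tokens = as.integer(min_tokens),
                 seed = as.integer(seed), scale = scale),
            class = "experiment_config")
}

# Deterministic sub-seeds: a salted draw from the master seed.
derive_seeds <- function(seed, n, salt) {
  with_seed(seed + salt, sample.int(.Machine$integer.max - 1L, n))
}

# Per-speaker per-vowel sufficient statistics for one condition.
# Roles: `bg` (background fitting: n, 4-mean, 4x4 centered cross-product),
# `ref` and `qst` (scoring: n, 4-mean).
# matched: ref/qst are a random 50/50 split of the speaker's downsampled
# tokens; bg uses all of them.
# mismatched: ref = interview tokens, qst = dialogue tokens, bg = both.
prepare_condition_data <- function(ds, condition, seed = NULL) {
  stopifnot(condition %in% c("matched", "mismatched"))
  fcols <- c("f1_hz", "f2_hz", "f3_hz", "f4_hz")
  X <- as.matrix(ds[, fcols])
  spk <- corpus_speakers(ds)
  role <- with_seed(seed, {
    if (condition == "matched") {
      r <- character(nrow(ds))
      for (idx in split(seq_len(nrow(ds)), ds$speaker)) {
        half <- sample(idx, floor(length(idx) / 2))
        r[half] <- "ref"
        r[setdiff(idx, half)] <- "qst"
      }
      r
    } else {
      ifelse(ds$style == "interview", "ref", "qst")
    }
  })
  stats_of <- function(rows, with_S) {
    x <- X[rows, , drop = FALSE]
    out <- list(n = nrow(x), mean = colMeans(x))
    if (with_S) out$S <- crossprod(sweep(x, 2, out$mean))
    out
  }
  build <- function(rows_by_cell, with_S) {
    res <- lapply(spk, function(s) {
      cells <- rows_by_cell[[s]]
      if (is.null(cells)) return(list())
      lapply(cells, stats_of, with_S = with_S)
    })
    names(res) <- spk
    res
  }
  split_cells <- function(keep) {
    i <- which(keep)
    lapply(split(i, ds$speaker[i]),
           function(rows) split(rows, ds$vowel[rows]))
  }
  list(vowels = sort(unique(ds$vowel)),
       bg = build(split_cells(rep(TRUE, nrow(ds))), with_S = TRUE),
       ref = build(split_cells(role == "ref"), with_S = FALSE),
       qst = build(split_cells(role == "qst"), with_S = FALSE))
}

run_condition <- function(corpus, config, condition, vowels = NULL) {
  style <- switch(condition,
                  "matched-dialogue" = "dialogue",
                  "matched-interview" = "interview",
                  "mismatched" = NA_character_)
  groups <- make_groups(corpus_speakers(corpus), twin_map(corpus),
                        n_groups = config$n_groups,
                        group_size = config$group_size,
                        seed = config$seed)
  salt <- switch(condition, "matched-dialogue" = 101L,
                 "matched-interview" = 202L, "mismatched" = 303L)
  ds_seeds <- derive_seeds(config$seed, config$n_downsample_reps, salt)
  sp_seeds <- derive_seeds(config$seed, config$n_downsample_reps, salt + 7L)
  rows <- list()
  for (rep_i in seq_len(config$n_downsample_reps)) {
    ds <- if (is.na(style)) {
      downsample_mismatched(corpus, seed = ds_seeds[rep_i])
    } else {
      downsample(corpus, style, seed = ds_seeds[rep_i])
    }
    prepared <- prepare_condition_data(
      ds, if (is.na(style)) "mismatched" else "matched",
      seed = sp_seeds[rep_i])
    if (!is.null(vowels)) prepared$vowels <- intersect(prepared$vowels, vowels)
    for (gi in seq_along(groups)) {
      for (sl in config$formant_subsets) {
        cal <- crossval_group(groups[[gi]], prepared, parse_subset(sl),
                              min_tokens = config$min_tokens)
        if (is.null(cal) || nrow(cal) == 0 ||
            length(unique(cal$hypothesis)) < 2) next
        met <- score_metrics(cal)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(condition = condition, subset = sl, group_id = gi,
                     iteration = rep_i, stringsAsFactors = FALSE),
          met)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Run the style-matched designs
#'
#' For each matched condition in the configuration: repeatedly downsample
#' the style's tokens to the minority speaker's count, split each
#' speaker's tokens 50/50 into reference and questioned halves, score all
#' group comparisons with leave-pair-out MVKD models, fuse and calibrate
#' per fold, and compute Cllr and EER per (group, iteration, subset).
#'
#' @param corpus A `formant_corpus` (outlier-screened).
#' @param config An [experiment_config()].
#' @return Data frame of metric rows `(condition, subset, group_id,
#'   iteration, n_ss, n_ds, cllr, eer)`.
#' @export
run_matched <- function(corpus, config) {
  conds <- intersect(config$conditions,
                     c("matched-dialogue", "matched-interview"))
  if (length(conds) == 0) stop("no matched condition configured", call. = FALSE)
  do.call(rbind, lapply(conds, function(cc) run_condition(corpus, config, cc)))
}

#' Run the mismatched-style design
#'
#' Interview tokens act as reference material and dialogue tokens as
#' questioned material. Different-speaker comparisons pair one speaker's
#' dialogue sample with another's interview sample; same-speaker
#' comparisons pair a speaker's own dialogue and interview samples (no
#' within-style split). Token counts are equalised across speakers and
#' styles by [downsample_mismatched()].
#'
#' @inheritParams run_matched
#' @return Data frame of metric rows as in [run_matched()].
#' @export
run_mismatched <- function(corpus, config) {
  if (!"mismatched" %in% config$conditions) {
    stop("'mismatched' not among the configured conditions", call. = FALSE)
  }
  run_condition(corpus, config, "mismatched")
}

#' Per-vowel discriminatory power (F1+F2)
#'
#' Runs the matched pipeline separately for each vowel with the formant
#' subset fixed to F1+F2 and no cross-vowel fusion (single-dimension
#' calibration), giving each vowel's own Cllr and EER.
#'
#' @inheritParams run_matched
#' @param vowels Vowels to assess (default all seven).
#' @return Data frame `(condition, vowel, subset, group_id, iteration,
#'   n_ss, n_ds, cllr, eer)` with `subset == "F1+F2"`.
#' @export
run_per_vowel <- function(corpus, config, vowels = bp_vowels()) {
  conds <- intersect(config$conditions,
                     c("matched-dialogue", "matched-interview"))
  if (length(conds) == 0) stop("no matched condition configured", call. = FALSE)
  cfg <- config
  cfg$formant_subsets <- "F1+F2"
  out <- list()
  for (cc in conds) {
    for (v in intersect(vowels, unique(corpus$vowel))) {
      res <- run_condition(corpus, cfg, cc, vowels = v)
      if (is.null(res) || nrow(res) == 0) {
        warning("vowel '", v, "' produced no usable comparisons in ", cc,
                call. = FALSE)
        next
      }
      res$vowel <- v
      out[[length(out) + 1L]] <-
        res[, c("condition", "vowel", "subset", "group_id", "iteration",
                "n_ss", "n_ds", "cllr", "eer")]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Shoelace area of a polygon given vertex coordinates in order; fewer
# than 3 distinct vertices span zero area.
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  0.5 * abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y))
}

#' Vowel-space descriptives
#'
#' Per speaker x style: per-vowel mean (F1, F2), the convex hull of those
#' category means in the F1 x F2 plane, and its shoelace area (Hz^2).
#' Also summarises, per style, the range of per-vowel mean values for
#' each formant with a percent difference computed as
#' `(max - min) / mean(c(min, max)) * 100`.
#'
#' @param corpus A `formant_corpus`.
#' @return List of three data frames: `areas` `(speaker, style, n_vowels,
#'   area_hz2)` (`NA` area below 3 vowel categories), `vowel_means`
#'   `(style, vowel, f1_hz..f4_hz)` averaged over speakers, and
#'   `formant_ranges` `(style, formant, min_hz, max_hz, pct_diff)`.
#' @export
vowel_space_summary <- function(corpus) {
  cells <- split(seq_len(nrow(corpus)),
                 list(corpus$speaker, corpus$style), drop = TRUE)
  areas <- do.call(rbind, lapply(cells, function(idx) {
    vm <- stats::aggregate(
      cbind(f1 = corpus$f1_hz[idx], f2 = corpus$f2_hz[idx]),
      by = list(vowel = corpus$vowel[idx]), FUN = mean)
    area <- if (nrow(vm) >= 3) {
      hull <- grDevices::chull(vm$f2, vm$f1)
      shoelace_area(vm$f2[hull], vm$f1[hull])
    } else NA_real_
    data.frame(speaker = corpus$speaker[idx[1]],
               style = corpus$style[idx[1]],
               n_vowels = nrow(vm), area_hz2 = area,
               stringsAsFactors = FALSE)
  }))
  areas <- areas[order(areas$speaker, areas$style), ]
  rownames(areas) <- NULL

  fcols <- c("f1_hz", "f2_hz", "f3_hz", "f4_hz")
  vm <- stats::aggregate(corpus[, fcols],
                         by = list(style = corpus$style,
                                   vowel = corpus$vowel), FUN = mean)
  vm <- vm[order(vm$style, vm$vowel), ]
  rownames(vm) <- NULL

  ranges <- do.call(rbind, lapply(split(vm, vm$style), function(sv) {
    do.call(rbind, lapply(seq_along(fcols), function(k) {
      x <- sv[[fcols[k]]]
      lo <- min(x); hi <- max(x)
      data.frame(style = sv$style[1], formant = FORMANT_NAMES[k],
                 min_hz = lo, max_hz = hi,
                 pct_diff = (hi - lo) / mean(c(lo, hi)) * 100,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(ranges) <- NULL
  list(areas = areas, vowel_means = vm, formant_ranges = ranges)
}
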