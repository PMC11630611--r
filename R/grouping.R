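# Random speaker-group formation with twin-pair exclusion.

#' Form random speaker groups excluding twin pairs
#'
#' Draws `n_groups` groups of `group_size` speakers such that no group
#' contains both members of a twin pair. In the canonical design
#' (`2 * n_pairs == n_speakers` and `group_size == n_pairs`) each group is
#' built by an independent fair coin per twin pair choosing which sibling
#' enters, so every group holds exactly one member of every pair. Other
#' configurations use rejection sampling with an attempt cap. Groups are
#' sampled with replacement: duplicates across the `n_groups` draws are
#' permitted.
#'
#' @param speakers Character vector of speaker ids.
#' @param twin_map Named vector mapping speaker id to twin-pair label
#'   (`NA` for unpaired speakers), as from [twin_map()].
#' @param n_groups Number of groups (default 150).
#' @param group_size Speakers per group (default 10).
#' @param seed Integer seed (or `NULL`).
#' @return List of `n_groups` character vectors (sorted members), class
#'   `speaker_groups`.
#' @export
#' @examples
#' tm <- stats::setNames(rep(sprintf("T%02d", 1:10), each = 2),
#'                       sprintf("S%02d", 1:20))
#' g <- make_groups(names(tm), tm, n_groups = 5, seed = 1)
#' lengths(g)
make_groups <- function(speakers, twin_map, n_groups = 150, group_size = 10,
                        seed = NULL) {
  speakers <- sort(unique(as.character(speakers)))
  n <- length(speakers)
  if (group_size > n) {
    stop("group_size exceeds the number of speakers", call. = FALSE)
  }
  tm <- twin_map[speakers]
  pairs <- split(speakers[!is.na(tm)], tm[!is.na(tm)])
  unpaired <- speakers[is.na(tm)]
  n_pairs <- length(pairs)
  # feasibility: at most one speaker per pair can enter a group
  if (group_size > n_pairs + length(unpaired)) {
    stop("no twin-free group of size ", group_size, " exists", call. = FALSE)
  }
  canonical <- length(unpaired) == 0 && 2L * n_pairs == n &&
    group_size == n_pairs
  groups <- with_seed(seed, {
    lapply(seq_len(n_groups), function(g) {
      if (canonical) {
        pick <- stats::rbinom(n_pairs, 1, 0.5) + 1L
        sort(vapply(seq_len(n_pairs),
                    function(p) pairs[[p]][pick[p]], character(1)))
      } else {
        for (attempt in seq_len(10000L)) {
          cand <- sample(speakers, group_size)
          tp <- tm[cand]
          if (!anyDuplicated(tp[!is.na(tp)])) return(sort(cand))
        }
        stop("could not draw a twin-free group within the attempt cap",
             call. = FALSE)
      }
    })
  })
  structure(groups, class = "speaker_groups")
}

#' Enumerate all unordered speaker pairs of a group
#'
#' @param group Character vector of group members (>= 2).
#' @return Data frame `(speaker_a, speaker_b)` with all `C(n, 2)` pairs,
#'   lexicographically ordered, `speaker_a < speaker_b`.
#' @export
#' @examples
#' nrow(enumerate_pairs(sprintf("S%02d", 1:10)))  # 45
enumerate_pairs <- function(group) {
  members <- sort(unique(as.character(group)))
  if (length(members) < 2) stop("group needs at least 2 members", call. = FALSE)
  cmb <- utils::combn(members, 2)
  data.frame(speaker_a = cmb[1, ], speaker_b = cmb[2, ],
             stringsAsFactors = FALSE)
}
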