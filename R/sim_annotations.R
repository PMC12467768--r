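## Synthetic annotation sets with controlled animacy and abstraction.
##
## Abstraction truth is realized through the *shape* of the label
## distribution: the generator picks the integer partition of the
## n_annotators labels whose normalized entropy is closest to the target,
## then assigns one distinct word per partition block. Animacy truth is
## realized through the fraction of labels drawn from the animate lexicon.

## all integer partitions of n (n small), as a list of count vectors
integer_partitions <- function(n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  recurse <- function(remaining, max_part, acc) {
    if (remaining == 0) {
      out[[length(out) + 1]] <<- acc
      return(invisible(NULL))
    }
    for (p in seq_len(min(max_part, remaining))) {
      recurse(remaining - p, p, c(acc, p))
    }
  }
  recurse(n, n, integer(0))
  out
}

partition_entropy <- function(counts, n) {
  p <- counts / n
  H <- -sum(p * log(p))
  if (n <= 1) 0 else H / log(n)
}

inanimate_lexicon <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("inanimate_lexicon.txt")
  words <- trimws(readLines(path, warn = FALSE))
  words[nzchar(words) & !startsWith(words, "#")]
}

PART_TAGS_ANIMATE <- c("head", "leg", "wing", "tail", "body", "arm", "neck",
                       "ear")
PART_TAGS_INANIMATE <- c("roof", "wall", "base", "mast", "wheel", "handle",
                         "top", "edge")

#' Generate annotation sets with known dimension truths
#'
#' For each figure, draws `n_annotators` global labels whose animate-word
#' fraction matches the animacy truth (to rounding) and whose label
#' diversity realizes the abstraction truth: the integer partition of the
#' labels with normalized entropy closest to the target is selected and
#' each partition block receives one distinct word. Part labels are drawn
#' from animacy-appropriate part-tag vocabularies.
#'
#' @param figure_ids character ids.
#' @param animacy_truth,abstraction_truth numeric vectors in \[0, 1\], one
#'   per figure.
#' @param n_annotators labels per figure (default 10).
#' @param seed integer seed.
#' @return named list of `annotation_set` objects with attributes
#'   `animacy_truth` and `abstraction_truth`.
#' @export
gen_annotations <- function(figure_ids, animacy_truth, abstraction_truth,
                            n_annotators = 10, seed = 1) {
  stopifnot(length(figure_ids) == length(animacy_truth),
            length(figure_ids) == length(abstraction_truth),
            all(animacy_truth >= 0 & animacy_truth <= 1),
            all(abstraction_truth >= 0 & abstraction_truth <= 1))
  parts_list <- integer_partitions(n_annotators)
  part_H <- vapply(parts_list, partition_entropy, numeric(1),
                   n = n_annotators)
  animate_words <- animate_lexicon()
  inanimate_words <- inanimate_lexicon()

  ## partitions of every possible animate/inanimate group size, so the
  ## animate quota can be met exactly while the *joint* label distribution
  ## hits the entropy target
  sub_parts <- lapply(0:n_annotators, integer_partitions)

  with_seed(seed, {
    out <- lapply(seq_along(figure_ids), function(i) {
      quota <- round(n_annotators * animacy_truth[i])
      pa <- sub_parts[[quota + 1]]
      pi_ <- sub_parts[[n_annotators - quota + 1]]
      best <- NULL; best_err <- Inf
      for (p1 in pa) {
        for (p2 in pi_) {
          H <- partition_entropy(c(p1, p2), n_annotators)
          err <- abs(H - abstraction_truth[i])
          if (err < best_err) { best_err <- err; best <- list(p1, p2) }
        }
      }
      counts <- c(best[[1]], best[[2]])
      animate_block <- rep(c(TRUE, FALSE),
                           c(length(best[[1]]), length(best[[2]])))
      words <- character(length(counts))
      words[animate_block] <- sample(animate_words, sum(animate_block))
      words[!animate_block] <- sample(inanimate_words, sum(!animate_block))
      labels <- sample(rep(words, counts))
      tag_pool <- if (animacy_truth[i] >= 0.5) PART_TAGS_ANIMATE else
        PART_TAGS_INANIMATE
      tags <- sample(tag_pool, 1 + stats::rbinom(1, 2, 0.5))
      part_df <- data.frame(
        annotator = "a1",
        piece_id = sample(PIECE_IDS, length(tags)),
        part = tags)
      annotation_set(figure_ids[i],
                     data.frame(annotator = paste0("a", seq_along(labels)),
                                label = labels),
                     part_df)
    })
    names(out) <- figure_ids
    attr(out, "animacy_truth") <- animacy_truth
    attr(out, "abstraction_truth") <- abstraction_truth
    out
  })
}
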