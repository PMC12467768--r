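## Annotation sets and the annotation-derived representation dimensions.

#' Construct an annotation set for one figure
#'
#' @param figure_id character id.
#' @param global_labels data.frame with columns `annotator`, `label` (one
#'   whole-figure interpretation per row), or a character vector of labels.
#' @param part_labels optional data.frame with columns `annotator`,
#'   `piece_id`, `part` (e.g. "head", "leg", "wing").
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(figure_id, global_labels,
                           part_labels = NULL) {
  if (is.character(global_labels)) {
    global_labels <- data.frame(
      annotator = paste0("a", seq_along(global_labels)),
      label = global_labels)
  }
  if (nrow(global_labels) < 1) {
    stop("missing-data error: at least one global label is required",
         call. = FALSE)
  }
  if (nrow(global_labels) < 10) {
    warning("figure ", figure_id, " has fewer than 10 global annotations (",
            nrow(global_labels), ")", call. = FALSE)
  }
  if (is.null(part_labels)) {
    part_labels <- data.frame(annotator = character(0),
                              piece_id = character(0), part = character(0))
  }
  structure(list(figure_id = as.character(figure_id),
                 global_labels = global_labels, part_labels = part_labels),
            class = "annotation_set")
}

#' Canonicalize an annotation label
#'
#' Lowercases, strips punctuation, and singularizes the head (final) noun
#' token with a simple suffix rule.
#'
#' @param x character vector of labels.
#' @return character vector of canonical head nouns.
#' @export
canonical_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z ]", "", x)
  head_noun <- vapply(strsplit(x, "\\s+"), function(t) {
    t <- t[nzchar(t)]
    if (!length(t)) "" else t[length(t)]
  }, character(1))
  singularize(head_noun)
}

singularize <- function(w) {
  keep <- c("bus", "glass", "dress", "grass", "chess", "its", "this")
  out <- w
  idx <- !(w %in% keep)
  ies <- idx & grepl("ies$", w) & nchar(w) > 4
  out[ies] <- sub("ies$", "y", w[ies])
  es <- idx & !ies & grepl("(sh|ch|x|s|z)es$", w)
  out[es] <- sub("es$", "", w[es])
  s <- idx & !ies & !es & grepl("[^su]s$", w) & nchar(w) > 3
  out[s] <- sub("s$", "", w[s])
  out
}

#' Load the shipped animate-word lexicon
#'
#' An editable word list of animals, people and other body-capable agents;
#' matching is on the canonicalized final noun token of each label.
#'
#' @param path optional path to an alternative lexicon file (one lowercase
#'   singular word per line, `#` comments allowed).
#' @return character vector of animate head nouns.
#' @export
animate_lexicon <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("animate_lexicon.txt")
  words <- trimws(readLines(path, warn = FALSE))
  words[nzchar(words) & !startsWith(words, "#")]
}

#' Animacy score of a figure
#'
#' Fraction of global labels whose canonical head noun is in the animate
#' lexicon.
#'
#' @param ann an `annotation_set`.
#' @param lexicon animate word list (default the shipped lexicon).
#' @return scalar in \[0, 1\].
#' @export
animacy_score <- function(ann, lexicon = animate_lexicon()) {
  stopifnot(inherits(ann, "annotation_set"))
  labs <- ann$global_labels$label
  if (!length(labs)) stop("missing-data error: empty annotations",
                          call. = FALSE)
  mean(canonical_label(labs) %in% lexicon)
}

#' Abstraction level of a figure
#'
#' Normalized Shannon entropy of the canonicalized global-label
#' distribution: `H / log(n_labels)`, in \[0, 1\]. Zero means perfect
#' annotator agreement (one shared interpretation); one means every
#' annotator produced a different label. An alternative operationalization,
#' one minus the modal-label agreement, is available via `method`.
#'
#' @param ann an `annotation_set`.
#' @param method `"entropy"` (default) or `"modal"`.
#' @return scalar in \[0, 1\].
#' @export
abstraction_level <- function(ann, method = c("entropy", "modal")) {
  method <- match.arg(method)
  stopifnot(inherits(ann, "annotation_set"))
  labs <- canonical_label(ann$global_labels$label)
  n <- length(labs)
  if (n < 2) {
    stop("insufficient-annotations error: need at least 2 global labels",
         call. = FALSE)
  }
  if (method == "modal") {
    return(1 - max(table(labs)) / n)
  }
  p <- as.numeric(table(labs)) / n
  H <- -sum(p * log(p))
  H / log(n)
}

#' Read / write an annotations CSV
#'
#' Long format: `figure_id, annotator, kind {global|part}, piece_id (blank
#' for global rows), label`.
#'
#' @param path file path.
#' @return `read_annotations_csv`: named list of `annotation_set` objects.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("figure_id", "annotator", "kind", "piece_id", "label")
  if (!all(need %in% names(df))) {
    stop("format error: annotations CSV needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$figure_id), function(d) {
    g <- d[d$kind == "global", c("annotator", "label")]
    p <- d[d$kind == "part", c("annotator", "piece_id", "label")]
    names(p) <- c("annotator", "piece_id", "part")
    annotation_set(d$figure_id[1], g, p)
  })
  out[order(names(out))]
}

#' @rdname read_annotations_csv
#' @param anns list of `annotation_set` objects.
#' @export
write_annotations_csv <- function(anns, path) {
  rows <- lapply(anns, function(a) {
    g <- data.frame(figure_id = a$figure_id,
                    annotator = a$global_labels$annotator, kind = "global",
                    piece_id = "", label = a$global_labels$label)
    if (nrow(a$part_labels)) {
      p <- data.frame(figure_id = a$figure_id,
                      annotator = a$part_labels$annotator, kind = "part",
                      piece_id = a$part_labels$piece_id,
                      label = a$part_labels$part)
      rbind(g, p)
    } else g
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
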