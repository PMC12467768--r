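## Reading and writing tangram figures.
##
## Input files carry no piece identities: triangles are ranked by area into
## large/medium/small and quadrilaterals are split square vs parallelogram by
## a right-angle test. A/B members of the identical pairs are assigned by
## lexicographic centroid (x, then y).

## classify 7 anonymous polygons into the canonical identities
assign_piece_identities <- function(polys, tol) {
  n_v <- vapply(polys, nrow, integer(1))
  areas <- vapply(polys, function(v) abs(signed_area(v)), numeric(1))
  tris <- which(n_v == 3L)
  quads <- which(n_v == 4L)
  if (length(tris) != 5L || length(quads) != 2L) {
    stop("format error: a tangram figure needs 5 triangles and 2 ",
         "quadrilaterals; got ", length(tris), " and ", length(quads),
         call. = FALSE)
  }
  tris <- tris[order(areas[tris], decreasing = TRUE)]
  large <- tris[1:2]; medium <- tris[3]; small <- tris[4:5]

  is_square <- vapply(quads, function(i) {
    v <- polys[[i]]
    e <- polygon_edges(v)
    d <- e$q - e$p
    lens <- sqrt(rowSums(d^2))
    dots <- abs(rowSums(d * d[c(2:4, 1), , drop = FALSE]))
    all(dots <= tol * lens * lens[c(2:4, 1)] * 10) &&
      diff(range(lens)) <= 10 * tol
  }, logical(1))
  if (sum(is_square) != 1L) {
    stop("format error: could not distinguish square from parallelogram",
         call. = FALSE)
  }
  sq <- quads[is_square]; par <- quads[!is_square]

  centroid <- function(i) colMeans(polys[[i]])
  ab_order <- function(pair) {
    cs <- t(vapply(pair, centroid, numeric(2)))
    pair[order(cs[, 1], cs[, 2])]
  }
  large <- ab_order(large); small <- ab_order(small)

  order_idx <- c(large, medium, small, sq, par)
  mapply(function(i, id) piece(id, polys[[i]]), order_idx, PIECE_IDS,
         SIMPLIFY = FALSE)
}

figure_from_polygons <- function(figure_id, polys, ...) {
  if (length(polys) != 7L) {
    stop("format error: expected 7 polygons, got ", length(polys),
         call. = FALSE)
  }
  all_coords <- do.call(rbind, polys)
  tol <- 1e-6 * bbox_diagonal(all_coords)
  tangram_figure(figure_id, assign_piece_identities(polys, tol), ...)
}

#' Read a tangram figure from JSON or SVG
#'
#' The JSON layout is `{"figure_id": str, "pieces": [{"vertices":
#' [[x,y],...]}, x7]}`. The SVG reader accepts `<polygon>` elements and
#' `<path>` elements made of straight segments (`M`/`L`/`H`/`V`/`Z`).
#' Piece identities are assigned by area ranking (triangles) and a
#' right-angle test (quadrilaterals); see [tangram_figure()] for validation.
#'
#' @param path file path.
#' @param format `"json"` or `"svg"`; inferred from the extension by default.
#' @param ... passed to [tangram_figure()] (e.g. `ratio_error`).
#' @return a `tangram_figure`.
#' @export
read_figure <- function(path, format = c("auto", "json", "svg"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.svg$", path, ignore.case = TRUE)) "svg" else "json"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                              simplifyDataFrame = FALSE)
    if (is.null(obj$pieces)) stop("format error: missing 'pieces'",
                                  call. = FALSE)
    polys <- lapply(obj$pieces, function(p) {
      v <- p$vertices
      if (is.list(v)) v <- do.call(rbind, v)
      matrix(as.numeric(v), ncol = 2)
    })
    figure_id <- if (is.null(obj$figure_id)) "figure" else obj$figure_id
    figure_from_polygons(figure_id, polys, ...)
  } else {
    read_figure_svg(path, ...)
  }
}

parse_svg_path_points <- function(d) {
  toks <- regmatches(d, gregexpr("[MmLlHhVvZz]|-?[0-9.eE+]+", d))[[1]]
  pts <- matrix(numeric(0), 0, 2)
  cur <- c(0, 0)
  mode <- "M"
  i <- 1
  while (i <= length(toks)) {
    t <- toks[i]
    if (grepl("^[MmLlHhVvZz]$", t)) {
      mode <- t
      if (t %in% c("Z", "z")) break
      i <- i + 1
      next
    }
    rel <- mode %in% c("m", "l", "h", "v")
    if (mode %in% c("H", "h")) {
      x <- as.numeric(t)
      cur <- c(if (rel) cur[1] + x else x, cur[2])
      i <- i + 1
    } else if (mode %in% c("V", "v")) {
      y <- as.numeric(t)
      cur <- c(cur[1], if (rel) cur[2] + y else y)
      i <- i + 1
    } else {
      xy <- as.numeric(toks[i:(i + 1)])
      cur <- if (rel) cur + xy else xy
      i <- i + 2
      if (mode == "M") mode <- "L" else if (mode == "m") mode <- "l"
    }
    pts <- rbind(pts, cur)
  }
  ## drop a closing point duplicating the first
  if (nrow(pts) > 1 && sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) <
      1e-9 * (1 + bbox_diagonal(pts))) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  pts
}

read_figure_svg <- function(path, ...) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_strip(doc)
  polys <- list()
  for (node in xml2::xml_find_all(doc, ".//polygon")) {
    txt <- xml2::xml_attr(node, "points")
    nums <- as.numeric(regmatches(txt, gregexpr("-?[0-9.eE+]+", txt))[[1]])
    polys[[length(polys) + 1]] <- matrix(nums, ncol = 2, byrow = TRUE)
  }
  for (node in xml2::xml_find_all(doc, ".//path")) {
    d <- xml2::xml_attr(node, "d")
    if (grepl("[CcSsQqTtAa]", d)) {
      stop("format error: SVG path contains curved segments", call. = FALSE)
    }
    polys[[length(polys) + 1]] <- parse_svg_path_points(d)
  }
  id <- xml2::xml_attr(xml2::xml_root(doc), "id")
  if (is.na(id)) id <- sub("\\.svg$", "", basename(path), ignore.case = TRUE)
  figure_from_polygons(id, polys, ...)
}

#' Write a tangram figure to JSON
#'
#' Writes the canonical-order pieces with full coordinate precision so that
#' `read_figure(write_figure(fig))` reproduces coordinates to 1e-9.
#'
#' @param fig a `tangram_figure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_figure <- function(fig, path) {
  stopifnot(inherits(fig, "tangram_figure"))
  obj <- list(
    figure_id = fig$figure_id,
    pieces = lapply(fig$pieces, function(p) list(vertices = p$vertices))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write / read an encoding matrix as CSV
#'
#' Seven integer columns headed by the canonical piece ids, seven rows.
#'
#' @param m a `cae_matrix`.
#' @param path file path.
#' @return `write_cae_csv`: `path` invisibly; `read_cae_csv`: a `cae_matrix`.
#' @export
write_cae_csv <- function(m, path) {
  stopifnot(inherits(m, "cae_matrix"))
  utils::write.csv(as.data.frame(unclass(m)[,]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cae_csv
#' @export
read_cae_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cae_matrix(as.matrix(df))
}
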