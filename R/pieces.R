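#' @keywords internal
"_PACKAGE"

## Canonical piece identities, in the fixed matrix-axis order.
PIECE_IDS <- c("large_tri_a", "large_tri_b", "medium_tri",
               "small_tri_a", "small_tri_b", "square", "parallelogram")

## Canonical vertex sets (small-triangle leg = 1 unit), counter-clockwise.
## Areas follow the tangram ratios: large 2, medium 1, small 0.5,
## square 1, parallelogram 1 (square/parallelogram = the small-triangle pair).
canonical_piece_coords <- function(piece_id) {
  s2 <- sqrt(2)
  switch(piece_id,
    large_tri_a   = ,
    large_tri_b   = rbind(c(0, 0), c(2, 0), c(0, 2)),
    medium_tri    = rbind(c(0, 0), c(s2, 0), c(0, s2)),
    small_tri_a   = ,
    small_tri_b   = rbind(c(0, 0), c(1, 0), c(0, 1)),
    square        = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    parallelogram = rbind(c(0, 0), c(s2, 0), c(3 * s2 / 2, s2 / 2),
                          c(s2 / 2, s2 / 2)),
    stop("unknown piece_id: ", piece_id)
  )
}

## Canonical areas in matrix-axis order.
canonical_areas <- function() {
  c(large_tri_a = 2, large_tri_b = 2, medium_tri = 1,
    small_tri_a = 0.5, small_tri_b = 0.5, square = 1, parallelogram = 1)
}

#' Construct a tangram piece
#'
#' A piece is a simple convex polygon with one of the seven canonical tangram
#' identities. Vertices are stored counter-clockwise; clockwise input is
#' reversed silently.
#'
#' @param piece_id one of `"large_tri_a"`, `"large_tri_b"`, `"medium_tri"`,
#'   `"small_tri_a"`, `"small_tri_b"`, `"square"`, `"parallelogram"`.
#' @param vertices numeric matrix (rows = vertices, columns = x, y).
#' @return an object of class `tangram_piece`.
#' @export
piece <- function(piece_id, vertices) {
  piece_id <- match.arg(piece_id, PIECE_IDS)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L) stop("vertices must have two columns (x, y)")
  n_expect <- if (grepl("tri", piece_id)) 3L else 4L
  if (nrow(vertices) != n_expect) {
    stop("invalid-piece: ", piece_id, " requires ", n_expect, " vertices, got ",
         nrow(vertices), call. = FALSE)
  }
  a <- signed_area(vertices)
  if (abs(a) < .Machine$double.eps * 100) {
    stop("invalid-piece: degenerate (zero-area) polygon for ", piece_id,
         call. = FALSE)
  }
  if (a < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  if (!is_simple_polygon(vertices)) {
    stop("invalid-piece: self-intersecting polygon for ", piece_id,
         call. = FALSE)
  }
  structure(list(piece_id = piece_id, vertices = vertices),
            class = "tangram_piece")
}

#' @export
print.tangram_piece <- function(x, ...) {
  cat("<tangram_piece>", x$piece_id, "area =",
      format(signed_area(x$vertices), digits = 5), "\n")
  invisible(x)
}

## ---- low-level polygon helpers ------------------------------------------

signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_edges <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  list(p = v, q = v[j, , drop = FALSE])
}

## segment intersection test for simplicity check (proper crossings only)
segments_cross <- function(p1, q1, p2, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- o(p1, q1, p2); o2 <- o(p1, q1, q2)
  o3 <- o(p2, q2, p1); o4 <- o(p2, q2, q1)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  e <- polygon_edges(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ## skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(e$p[i, ], e$q[i, ], e$p[j, ], e$q[j, ])) return(FALSE)
    }
  }
  TRUE
}

point_seg_dist <- function(pt, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(sum((pt - a)^2)))
  t <- sum((pt - a) * ab) / L2
  t <- min(1, max(0, t))
  proj <- a + t * ab
  sqrt(sum((pt - proj)^2))
}

## Sutherland-Hodgman clip of convex polygon `subj` by convex polygon `clip`;
## returns intersection area. Both CCW.
convex_intersection_area <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(0)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    ## keep points on left of a->b (CCW interior)
    cx <- b[1] - a[1]; cy <- b[2] - a[2]
    sides <- cx * (out[, 2] - a[2]) - cy * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(2:n, 1L)[seq_len(n)]
    if (n == 1) nxt <- 1L
    res <- matrix(0, 0, 2)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      cur_in <- sides[k] >= 0
      nxt_in <- sides[k2] >= 0
      if (cur_in) res <- rbind(res, out[k, ])
      if (xor(cur_in, nxt_in)) {
        d <- sides[k] - sides[k2]
        t <- if (d == 0) 0 else sides[k] / d
        res <- rbind(res, out[k, ] + t * (out[k2, ] - out[k, ]))
      }
    }
    out <- res
  }
  if (nrow(out) < 3) return(0)
  abs(signed_area(out))
}

piece_area <- function(p) abs(signed_area(p$vertices))

bbox_diagonal <- function(coords) {
  rng_x <- range(coords[, 1]); rng_y <- range(coords[, 2])
  sqrt(diff(rng_x)^2 + diff(rng_y)^2)
}

## ---- transforms ----------------------------------------------------------

transform_coords <- function(v, rotate = 0, scale = 1, translate = c(0, 0),
                             reflect = FALSE) {
  if (reflect) v[, 1] <- -v[, 1]
  if (rotate != 0) {
    R <- matrix(c(cos(rotate), sin(rotate), -sin(rotate), cos(rotate)), 2, 2)
    v <- v %*% t(R)
  }
  v <- v * scale
  v[, 1] <- v[, 1] + translate[1]
  v[, 2] <- v[, 2] + translate[2]
  v
}

#' Apply a similarity transform to a figure
#'
#' Rotation (radians, about the origin), uniform scaling and translation; the
#' cognitive-associative encoding is invariant under all three.
#'
#' @param fig a `tangram_figure`.
#' @param rotate rotation angle in radians.
#' @param scale positive scale factor.
#' @param translate length-2 numeric offset.
#' @return the transformed `tangram_figure`.
#' @export
transform_figure <- function(fig, rotate = 0, scale = 1, translate = c(0, 0)) {
  stopifnot(inherits(fig, "tangram_figure"), scale > 0)
  fig$pieces <- lapply(fig$pieces, function(p) {
    p$vertices <- transform_coords(p$vertices, rotate, scale, translate)
    p
  })
  fig
}

#' Assemble a tangram figure from seven pieces
#'
#' Validates that all seven canonical identities are present exactly once,
#' that piece areas respect the canonical tangram ratios
#' (large : medium : small = 4 : 2 : 1; square and parallelogram equal the
#' small-triangle pair), and that piece interiors are pairwise disjoint.
#'
#' @param figure_id character id.
#' @param pieces list of exactly 7 [piece()] objects.
#' @param tol coincidence tolerance; default `1e-6 *` the figure bounding-box
#'   diagonal.
#' @param ratio_tol relative tolerance on canonical area ratios (warning
#'   beyond it, or error when `ratio_error = TRUE`).
#' @param ratio_error escalate the area-ratio warning to an error.
#' @return an object of class `tangram_figure`.
#' @export
tangram_figure <- function(figure_id, pieces, tol = NULL, ratio_tol = 0.05,
                           ratio_error = FALSE) {
  if (length(pieces) != 7L) {
    stop("format error: a tangram figure requires exactly 7 pieces, got ",
         length(pieces), call. = FALSE)
  }
  ids <- vapply(pieces, function(p) p$piece_id, character(1))
  if (!setequal(ids, PIECE_IDS) || anyDuplicated(ids)) {
    stop("invalid-configuration: the 7 canonical piece identities must each ",
         "appear exactly once", call. = FALSE)
  }
  pieces <- pieces[match(PIECE_IDS, ids)]
  all_coords <- do.call(rbind, lapply(pieces, `[[`, "vertices"))
  if (is.null(tol)) tol <- 1e-6 * bbox_diagonal(all_coords)

  ## area-ratio validation (scale-free: normalize by small-triangle area)
  areas <- vapply(pieces, piece_area, numeric(1))
  scale2 <- mean(areas[PIECE_IDS %in% c("small_tri_a", "small_tri_b")]) / 0.5
  expect <- canonical_areas() * scale2
  rel <- abs(areas - expect) / expect
  if (any(rel > ratio_tol)) {
    msg <- paste0("piece areas violate canonical tangram ratios: ",
                  paste(PIECE_IDS[rel > ratio_tol], collapse = ", "))
    if (ratio_error) stop("validation error: ", msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  ## pairwise interior disjointness
  for (i in 1:6) {
    for (j in (i + 1):7) {
      ov <- convex_intersection_area(pieces[[i]]$vertices,
                                     pieces[[j]]$vertices)
      lim <- tol * min(areas[i], areas[j])
      if (ov > lim) {
        stop("invalid-configuration: pieces ", PIECE_IDS[i], " and ",
             PIECE_IDS[j], " have overlapping interiors (area ",
             format(ov, digits = 4), ")", call. = FALSE)
      }
    }
  }
  structure(list(figure_id = as.character(figure_id), pieces = pieces,
                 tol = tol),
            class = "tangram_figure")
}

#' @export
print.tangram_figure <- function(x, ...) {
  cat("<tangram_figure>", x$figure_id, "with 7 pieces\n")
  invisible(x)
}
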