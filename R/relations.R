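## Boundary-contact relation codes between tangram pieces.
##
## 0 no overlap, 1 complete line overlap, 2 partial line overlap,
## 3 line containment, 4 point-line contact, 5 point overlap.

RELATION_LEVELS <- c(no_overlap = 0L, complete_line_overlap = 1L,
                     partial_line_overlap = 2L, line_containment = 3L,
                     point_line_contact = 4L, point_overlap = 5L)

#' Relation code names
#'
#' @return named integer vector mapping relation names to codes 0-5.
#' @export
relation_codes <- function() RELATION_LEVELS

## Collinear overlap between segments (p1,q1) and (p2,q2).
## Returns NULL when the segments are not collinear within tol, otherwise a
## list with the shared-segment length and the positions (1-D parameters along
## the common line) of both segments and of the shared part.
collinear_overlap <- function(p1, q1, p2, q2, tol) {
  d1 <- q1 - p1
  L1 <- sqrt(sum(d1^2))
  if (L1 < tol) return(NULL)
  u <- d1 / L1
  ## both endpoints of the second segment must lie on the first line
  off_p2 <- abs((p2[1] - p1[1]) * u[2] - (p2[2] - p1[2]) * u[1])
  off_q2 <- abs((q2[1] - p1[1]) * u[2] - (q2[2] - p1[2]) * u[1])
  if (off_p2 > tol || off_q2 > tol) return(NULL)
  ## project all endpoints on the common axis
  t1 <- c(0, L1)
  t2 <- sort(c(sum((p2 - p1) * u), sum((q2 - p1) * u)))
  lo <- max(t1[1], t2[1])
  hi <- min(t1[2], t2[2])
  if (hi - lo <= tol) return(NULL)
  list(length = hi - lo, seg1 = t1, seg2 = t2, shared = c(lo, hi))
}

## Classify one collinear-overlap locus into codes 1/2/3.
classify_line_locus <- function(ov, tol) {
  len1 <- ov$seg1[2] - ov$seg1[1]
  len2 <- ov$seg2[2] - ov$seg2[1]
  eq1 <- abs(ov$length - len1) <= tol
  eq2 <- abs(ov$length - len2) <= tol
  if (eq1 && eq2) return(1L)
  if (xor(eq1, eq2)) {
    ## the fully-shared edge must sit strictly inside the other edge
    inner <- if (eq1) ov$seg1 else ov$seg2
    outer <- if (eq1) ov$seg2 else ov$seg1
    if (inner[1] - outer[1] > tol && outer[2] - inner[2] > tol) return(3L)
  }
  2L
}

#' Classify the boundary relation between two pieces
#'
#' Determines which of the six boundary-contact relation types holds between
#' two pieces with disjoint interiors: collinear edge pairs sharing a segment
#' of positive length yield complete line overlap (1) when the shared segment
#' equals both edges, line containment (3) when it equals exactly one edge
#' lying strictly inside the other, and partial line overlap (2) otherwise;
#' with no positive-length shared segment, a vertex coincident with a
#' non-vertex edge point yields point-line contact (4) and coincident vertices
#' yield point overlap (5); no contact yields 0. When several relations hold
#' at distinct loci the lowest nonzero code is reported (line-based contact is
#' the cognitively tighter coupling).
#'
#' @param a,b `tangram_piece` objects.
#' @param tol coincidence tolerance in coordinate units; default `1e-6 *` the
#'   bounding-box diagonal of the pair.
#' @return integer relation code in 0..5.
#' @export
classify_relationship <- function(a, b, tol = NULL) {
  stopifnot(inherits(a, "tangram_piece"), inherits(b, "tangram_piece"))
  va <- a$vertices; vb <- b$vertices
  if (is.null(tol)) tol <- 1e-6 * bbox_diagonal(rbind(va, vb))
  if (abs(signed_area(va)) <= tol^2 || abs(signed_area(vb)) <= tol^2) {
    stop("invalid-piece: degenerate (zero-area) piece", call. = FALSE)
  }
  ov_area <- convex_intersection_area(va, vb)
  if (ov_area > tol * min(abs(signed_area(va)), abs(signed_area(vb)))) {
    stop("invalid-configuration: pieces ", a$piece_id, " and ", b$piece_id,
         " have overlapping interiors beyond tolerance", call. = FALSE)
  }

  codes <- integer(0)
  ea <- polygon_edges(va); eb <- polygon_edges(vb)
  na <- nrow(va); nb <- nrow(vb)

  ## line-based loci
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      ov <- collinear_overlap(ea$p[i, ], ea$q[i, ], eb$p[j, ], eb$q[j, ], tol)
      if (!is.null(ov)) codes <- c(codes, classify_line_locus(ov, tol))
    }
  }
  if (length(codes)) return(min(codes))

  ## point-based loci
  has4 <- FALSE; has5 <- FALSE
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (sqrt(sum((va[i, ] - vb[j, ])^2)) <= tol) has5 <- TRUE
    }
  }
  vertex_on_edge <- function(verts, other_p, other_q) {
    hit <- FALSE
    for (i in seq_len(nrow(verts))) {
      v <- verts[i, ]
      for (j in seq_len(nrow(other_p))) {
        if (point_seg_dist(v, other_p[j, ], other_q[j, ]) <= tol &&
            sqrt(sum((v - other_p[j, ])^2)) > tol &&
            sqrt(sum((v - other_q[j, ])^2)) > tol) hit <- TRUE
      }
    }
    hit
  }
  if (vertex_on_edge(va, eb$p, eb$q) || vertex_on_edge(vb, ea$p, ea$q)) {
    has4 <- TRUE
  }
  if (has4) return(4L)
  if (has5) return(5L)
  0L
}

#' Encode a figure as a cognitive-associative adjacency matrix
#'
#' Builds the 7 x 7 symmetric integer matrix whose (i, j) entry is the
#' boundary-relation code between pieces i and j, with pieces indexed in the
#' canonical order (two large triangles, medium triangle, two small
#' triangles, square, parallelogram). The encoding is invariant under global
#' translation, rotation and uniform scaling because all coincidence
#' predicates use a tolerance proportional to the figure's bounding-box
#' diagonal.
#'
#' @param fig a `tangram_figure`.
#' @param tol coincidence tolerance; default the figure's stored tolerance
#'   (`1e-6 *` bounding-box diagonal).
#' @return an integer matrix of class `cae_matrix` with entries in 0..5,
#'   zero diagonal, dimnames the canonical piece ids, and the tolerance in
#'   attribute `"tol"`.
#' @export
encode <- function(fig, tol = NULL) {
  stopifnot(inherits(fig, "tangram_figure"))
  if (is.null(tol)) tol <- fig$tol
  m <- matrix(0L, 7, 7, dimnames = list(PIECE_IDS, PIECE_IDS))
  for (i in 1:6) {
    for (j in (i + 1):7) {
      code <- tryCatch(
        classify_relationship(fig$pieces[[i]], fig$pieces[[j]], tol = tol),
        error = function(e) {
          stop("encoding failed for pair (", PIECE_IDS[i], ", ", PIECE_IDS[j],
               "): ", conditionMessage(e), call. = FALSE)
        })
      m[i, j] <- m[j, i] <- code
    }
  }
  cae_matrix(m, tol = tol)
}

#' Construct / validate a cognitive-associative encoding matrix
#'
#' @param m 7 x 7 integer matrix with entries in 0..5, symmetric, zero
#'   diagonal.
#' @param tol the construction tolerance to record.
#' @return the validated matrix with class `cae_matrix`.
#' @export
cae_matrix <- function(m, tol = 1e-6) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(7, 7))) {
    stop("dimension error: cae_matrix must be 7 x 7", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (any(m < 0L | m > 5L)) stop("cae_matrix entries must lie in 0..5",
                                 call. = FALSE)
  if (any(diag(m) != 0L)) stop("cae_matrix diagonal must be zero",
                               call. = FALSE)
  if (!isTRUE(all.equal(unname(m), unname(t(m))))) {
    stop("cae_matrix must be symmetric", call. = FALSE)
  }
  dimnames(m) <- list(PIECE_IDS, PIECE_IDS)
  structure(m, tol = tol, class = c("cae_matrix", "matrix", "array"))
}

#' @export
print.cae_matrix <- function(x, ...) {
  cat("<cae_matrix> 7 x 7 relation codes\n")
  print(unclass(x)[,]) # nolint
  invisible(x)
}

## upper-triangle cell index helpers (column-major over i < j), used by the
## granularity, matching and distance code paths
ut_index <- function() which(upper.tri(matrix(0, 7, 7)))

ut_pairs <- function() {
  idx <- which(upper.tri(matrix(0, 7, 7)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Vectorize the upper triangle of an encoding
#'
#' @param m a `cae_matrix`.
#' @return integer vector of the 21 upper-triangle cells, named `"i_j"`.
#' @export
cae_upper <- function(m) {
  pr <- ut_pairs()
  v <- unclass(m)[cbind(pr[, 1], pr[, 2])]
  names(v) <- paste0(pr[, 1], "_", pr[, 2])
  v
}
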