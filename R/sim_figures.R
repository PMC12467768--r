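## Constructive generation of tangram figures realizing a target relation
## template.
##
## Pieces are placed sequentially along the (acyclic) nonzero-relation
## graph: each required relation is realized by snapping the child piece's
## edge or vertex onto the parent's, on the parent's outside, so the
## resulting contact is exact to machine precision. Every generated figure
## is re-encoded and checked against the template before being returned.

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

vec_angle <- function(v) atan2(v[2], v[1])

edge_list <- function(verts) {
  n <- nrow(verts)
  j <- c(2:n, 1L)
  d <- verts[j, , drop = FALSE] - verts
  data.frame(i = seq_len(n), j = j, len = sqrt(rowSums(d^2)))
}

## rigid transform: map child so edge (a -> b) runs along -u with vertex a
## landing at point `target`
map_edge_to <- function(child, a_idx, b_idx, u, target) {
  a <- child[a_idx, ]; b <- child[b_idx, ]
  theta <- vec_angle(-u) - vec_angle(b - a)
  R <- rot2(theta)
  out <- sweep(child, 2, a) %*% t(R)
  sweep(out, 2, target, `+`)
}

## rigid transform: rotate child about vertex v_idx so the internal-angle
## bisector points along w, then move the vertex to `target`
map_vertex_to <- function(child, v_idx, w, target) {
  n <- nrow(child)
  nxt <- if (v_idx == n) 1L else v_idx + 1L
  prv <- if (v_idx == 1L) n else v_idx - 1L
  d1 <- child[nxt, ] - child[v_idx, ]
  d2 <- child[prv, ] - child[v_idx, ]
  bis <- d1 / sqrt(sum(d1^2)) + d2 / sqrt(sum(d2^2))
  theta <- vec_angle(w) - vec_angle(bis)
  R <- rot2(theta)
  out <- sweep(child, 2, child[v_idx, ]) %*% t(R)
  sweep(out, 2, target, `+`)
}

## minimum boundary distance between two convex polygons
poly_min_dist <- function(a, b) {
  ea <- polygon_edges(a); eb <- polygon_edges(b)
  d <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- min(d, point_seg_dist(a[i, ], eb$p[j, ], eb$q[j, ]),
               point_seg_dist(b[j, ], ea$p[i, ], ea$q[i, ]))
    }
  }
  d
}

## canonical piece coords, optionally mirrored (the physical parallelogram
## can be flipped; both chiralities are the same identity)
child_base <- function(piece_id, mirrored = FALSE) {
  v <- canonical_piece_coords(piece_id)
  if (mirrored) {
    v[, 1] <- -v[, 1]
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  }
  v
}

## internal half-angle of a polygon at vertex vi
vertex_half_angle <- function(v, vi) {
  n <- nrow(v)
  nxt <- if (vi == n) 1L else vi + 1L
  prv <- if (vi == 1L) n else vi - 1L
  d1 <- v[nxt, ] - v[vi, ]; d2 <- v[prv, ] - v[vi, ]
  acos(min(1, max(-1, sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))))) / 2
}

## every discrete way of attaching `child_id` to the placed parent `pv`
## with relation `code`: (mirror, parent edge/vertex, child edge/vertex,
## overhang side)
enumerate_combos <- function(pv, child_id, code) {
  mirrors <- if (child_id == "parallelogram") c(FALSE, TRUE) else FALSE
  pe <- edge_list(pv)
  out <- list()
  for (mir in mirrors) {
    cv <- child_base(child_id, mir)
    ce <- edge_list(cv)
    if (code %in% 1:3) {
      for (pi_ in seq_len(nrow(pe))) {
        for (ci in seq_len(nrow(ce))) {
          lp <- pe$len[pi_]; lc <- ce$len[ci]
          okpair <- switch(as.character(code),
                           "1" = abs(lc - lp) < 1e-9,
                           "2" = TRUE,
                           "3" = abs(lc - lp) > 1e-9)
          if (!okpair) next
          for (side in if (code == 2) 1:2 else 1) {
            out[[length(out) + 1]] <- list(mir = mir, pi = pi_, ci = ci,
                                           side = side)
          }
        }
      }
    } else if (code == 4L) {
      ## child vertex on a parent edge, and the reverse anchoring
      for (ai in seq_len(nrow(pe))) {
        for (ci in seq_len(nrow(cv))) {
          out[[length(out) + 1]] <- list(mir = mir, pi = ai, ci = ci,
                                         side = 1, rev = FALSE)
        }
      }
      for (ai in seq_len(nrow(pv))) {
        for (ci in seq_len(nrow(ce))) {
          out[[length(out) + 1]] <- list(mir = mir, pi = ai, ci = ci,
                                         side = 1, rev = TRUE)
        }
      }
    } else {
      for (ai in seq_len(nrow(pv))) {
        for (ci in seq_len(nrow(cv))) {
          out[[length(out) + 1]] <- list(mir = mir, pi = ai, ci = ci,
                                         side = 1)
        }
      }
    }
  }
  out
}

## realize one discrete combo with fresh continuous parameters
realize_combo <- function(pv, child_id, code, cb, margin = 0.1) {
  cv <- child_base(child_id, cb$mir)
  ce <- edge_list(cv); pe <- edge_list(pv)
  if (code %in% 1:3) {
    pp <- pv[pe$i[cb$pi], ]; pq <- pv[pe$j[cb$pi], ]
    Lp <- pe$len[cb$pi]
    u <- (pq - pp) / Lp
    Lc <- ce$len[cb$ci]
    tpos <- switch(as.character(code),
      "1" = Lp,
      "2" = {
        ov <- stats::runif(1, 0.35, 0.65) * min(Lp, Lc)
        if (cb$side == 1) Lp + Lc - ov else ov
      },
      "3" = if (Lc < Lp) {
        Lc + stats::runif(1, 0.15, 0.85) * (Lp - Lc)
      } else {
        Lp + stats::runif(1, 0.15, 0.85) * (Lc - Lp)
      })
    return(map_edge_to(cv, ce$i[cb$ci], ce$j[cb$ci], u, pp + u * tpos))
  }
  if (code == 4L) {
    if (!isTRUE(cb$rev)) {
      pp <- pv[pe$i[cb$pi], ]; pq <- pv[pe$j[cb$pi], ]
      u <- (pq - pp) / pe$len[cb$pi]
      outward <- c(u[2], -u[1])  # right of the CCW edge = outside
      target <- pp + u * stats::runif(1, 0.25, 0.75) * pe$len[cb$pi]
      h <- vertex_half_angle(cv, cb$ci)
      span <- pi / 2 - h - margin
      if (span <= 0) return(NULL)
      w <- rot2(stats::runif(1, -span, span)) %*% outward
      return(map_vertex_to(cv, cb$ci, as.numeric(w), target))
    }
    ## reverse: a parent vertex sits on the interior of a child edge; the
    ## child edge line supports the parent's vertex cone from outside
    vi <- cb$pi
    n <- nrow(pv)
    nxt <- if (vi == n) 1L else vi + 1L
    prv <- if (vi == 1L) n else vi - 1L
    e1 <- pv[nxt, ] - pv[vi, ]; e2 <- pv[prv, ] - pv[vi, ]
    bis <- e1 / sqrt(sum(e1^2)) + e2 / sqrt(sum(e2^2))
    beta <- vec_angle(bis)
    ph <- vertex_half_angle(pv, vi)
    span <- pi / 2 - ph - margin
    if (span <= 0) return(NULL)
    nhat_ang <- beta + pi + stats::runif(1, -span, span)
    that <- c(cos(nhat_ang - pi / 2), sin(nhat_ang - pi / 2))
    Lc <- ce$len[cb$ci]
    s <- stats::runif(1, 0.25, 0.75) * Lc
    target <- pv[vi, ] - that * s
    return(map_edge_to(cv, ce$i[cb$ci], ce$j[cb$ci], -that, target))
  }
  ## code 5: child wedge anywhere in the exterior angular gap at the vertex
  vi <- cb$pi
  n <- nrow(pv)
  nxt <- if (vi == n) 1L else vi + 1L
  prv <- if (vi == 1L) n else vi - 1L
  e1 <- pv[nxt, ] - pv[vi, ]; e2 <- pv[prv, ] - pv[vi, ]
  bis <- e1 / sqrt(sum(e1^2)) + e2 / sqrt(sum(e2^2))
  beta <- vec_angle(bis)
  ph <- vertex_half_angle(pv, vi)
  h <- vertex_half_angle(cv, cb$ci)
  lo <- beta + ph + h + margin
  hi <- beta + 2 * pi - ph - h - margin
  if (hi <= lo) return(NULL)
  psi <- stats::runif(1, lo, hi)
  map_vertex_to(cv, cb$ci, c(cos(psi), sin(psi)), pv[vi, ])
}

edge_lengths_of <- function(piece_id) {
  edge_list(canonical_piece_coords(piece_id))$len
}

code1_feasible <- function(id_a, id_b) {
  la <- edge_lengths_of(id_a); lb <- edge_lengths_of(id_b)
  any(outer(la, lb, function(x, y) abs(x - y) < 1e-9))
}

#' Specification for synthetic tangram figures
#'
#' @param template `"random"` or a 7 x 7 symmetric integer matrix of target
#'   relation codes (0..5, zero diagonal). Random templates are sampled as
#'   acyclic relation graphs (forests) so that sequential constructive
#'   placement can realize them; complete-line-overlap (code 1) is only
#'   assigned to piece pairs sharing an edge length.
#' @param density edge density of random templates (fraction of the 21
#'   pairs that are nonzero, capped at 6/21, the spanning-forest maximum).
#' @param jitter vertex jitter amplitude applied after placement (keep below
#'   a tenth of the coincidence tolerance to preserve the template).
#' @param seed integer seed.
#' @return object of class `sim_figure_spec`.
#' @export
sim_figure_spec <- function(template = "random", density = 0.3, jitter = 0,
                            seed = 1) {
  if (!identical(template, "random")) {
    template <- unclass(cae_matrix(template))
  }
  stopifnot(density >= 0, density <= 1, jitter >= 0)
  structure(list(template = template, density = density, jitter = jitter,
                 seed = seed),
            class = "sim_figure_spec")
}

#' Sample a random satisfiable relation template
#'
#' Templates are sampled as path-structured relation graphs (a random piece
#' ordering linked consecutively, thinned to the requested density), with
#' two constructive constraints: complete line overlap (code 1) is only
#' assigned to piece pairs sharing an edge length, and each piece hosts at
#' most one collinear-type contact (codes 1-3; a second contact on the same
#' piece is point-based). These constraints keep every sampled template
#' realizable by sequential snapping while exercising all five contact
#' types.
#'
#' @param density fraction of the 21 pairs to make nonzero (capped at 6/21,
#'   the spanning-forest maximum).
#' @return a `cae_matrix` template.
#' @export
random_template <- function(density = 0.3) {
  m_edges <- min(6L, round(density * 21))
  perm <- sample(7)
  links <- cbind(perm[-7], perm[-1])
  if (m_edges < 6) links <- links[sort(sample(6, m_edges)), , drop = FALSE]
  m <- matrix(0L, 7, 7)
  has_line <- logical(7)
  for (r in seq_len(nrow(links))) {
    i <- links[r, 1]; j <- links[r, 2]
    feas <- if (has_line[i] || has_line[j]) 4:5 else
      c(if (code1_feasible(PIECE_IDS[i], PIECE_IDS[j])) 1L, 2:5)
    code <- if (length(feas) == 1) feas else sample(feas, 1)
    m[i, j] <- m[j, i] <- code
    if (code <= 3) has_line[i] <- has_line[j] <- TRUE
  }
  cae_matrix(m)
}

place_figure_once <- function(template, gap = 0.08) {
  ids <- PIECE_IDS
  adj <- template > 0
  ## connected components of the relation graph
  comp <- 1:7
  repeat {
    changed <- FALSE
    for (i in 1:7) for (j in 1:7) {
      if (adj[i, j] && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j]); comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  placed <- vector("list", 7)
  comp_ids <- unique(comp)
  for (k in seq_along(comp_ids)) {
    members <- which(comp == comp_ids[k])
    offset <- c(((k - 1) %% 3) * 40, ((k - 1) %/% 3) * 40)
    root <- if (length(members) == 1) members else sample(members, 1)
    root_pose <- child_base(ids[root],
                            ids[root] == "parallelogram" &&
                              stats::runif(1) < 0.5)
    root_pose <- root_pose %*% t(rot2(stats::runif(1, 0, 2 * pi)))
    placed[[root]] <- sweep(root_pose, 2, offset, `+`)
    frontier <- root
    done <- root
    while (length(frontier)) {
      parent <- frontier[1]; frontier <- frontier[-1]
      kids <- setdiff(which(adj[parent, ]), done)
      if (length(kids) > 1) kids <- sample(kids)
      for (child in kids) {
        code <- template[parent, child]
        childv <- NULL
        combos <- enumerate_combos(placed[[parent]], ids[child], code)
        if (!length(combos)) return(NULL)
        for (cb in sample(combos)) {
          for (draw in 1:3) {
            cand <- realize_combo(placed[[parent]], ids[child], code, cb)
            if (is.null(cand)) break
            ## exact relation to the parent, clean separation from the rest
            ok <- tryCatch(
              classify_relationship(piece(ids[parent], placed[[parent]]),
                                    piece(ids[child], cand)) == code,
              error = function(e) FALSE)
            if (!ok) next
            for (other in setdiff(done, parent)) {
              if (convex_intersection_area(cand, placed[[other]]) > 1e-12 ||
                  poly_min_dist(cand, placed[[other]]) < gap) {
                ok <- FALSE
                break
              }
            }
            if (ok) { childv <- cand; break }
          }
          if (!is.null(childv)) break
        }
        if (is.null(childv)) return(NULL)
        placed[[child]] <- childv
        done <- c(done, child)
        frontier <- c(frontier, child)
      }
    }
  }
  placed
}

#' Generate tangram figures with known relation structure
#'
#' Constructively places the seven pieces so that the figure's encoding
#' equals the target template, then verifies the round trip with
#' [encode()]. Templates whose relation graph is cyclic, or that request a
#' complete line overlap between pieces sharing no edge length, are
#' unsatisfiable for the sequential placer and raise a constructive-failure
#' error (condition class `cae_constructive_failure`), as does any template
#' that cannot be realized within the bounded retries.
#'
#' @param spec a [sim_figure_spec()].
#' @param n number of figures.
#' @param max_retries placement attempts per figure.
#' @return list with `figures` (named list of `tangram_figure`), `encodings`
#'   (their verified `cae_matrix` encodings) and `templates` (the targets).
#' @export
gen_figures <- function(spec, n = 1, max_retries = 60) {
  stopifnot(inherits(spec, "sim_figure_spec"))
  with_seed(spec$seed, {
    figures <- list(); encodings <- list(); templates <- list()
    for (f in seq_len(n)) {
      template <- if (identical(spec$template, "random")) {
        unclass(random_template(spec$density))
      } else spec$template
      check_template_feasible(template)
      fig <- NULL
      for (r in seq_len(max_retries)) {
        placed <- place_figure_once(template)
        if (is.null(placed)) next
        pieces <- mapply(piece, PIECE_IDS, placed, SIMPLIFY = FALSE)
        cand <- tryCatch(
          tangram_figure(sprintf("sim%03d", f), pieces),
          error = function(e) NULL, warning = function(w) NULL)
        if (is.null(cand)) next
        enc <- tryCatch(encode(cand), error = function(e) NULL)
        if (is.null(enc)) next
        if (all(unclass(enc) == template)) { fig <- cand; break }
      }
      if (is.null(fig)) {
        stop(structure(class = c("cae_constructive_failure", "error",
                                 "condition"),
                       list(message = paste0(
                         "constructive-failure: template for figure ", f,
                         " not realized within ", max_retries, " retries"),
                         call = NULL)))
      }
      if (spec$jitter > 0) {
        fig$pieces <- lapply(fig$pieces, function(p) {
          p$vertices <- p$vertices +
            matrix(stats::runif(length(p$vertices), -spec$jitter,
                                spec$jitter), ncol = 2)
          p
        })
      }
      id <- fig$figure_id
      figures[[id]] <- fig
      encodings[[id]] <- encode(fig)
      templates[[id]] <- cae_matrix(template)
    }
    list(figures = figures, encodings = encodings, templates = templates)
  })
}

check_template_feasible <- function(template) {
  pr <- ut_pairs()
  ## cycles
  comp <- 1:7
  n_edges <- 0L
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    if (template[i, j] > 0) {
      n_edges <- n_edges + 1L
      if (comp[i] == comp[j]) {
        stop(structure(class = c("cae_constructive_failure", "error",
                                 "condition"),
                       list(message = paste0(
                         "constructive-failure: relation graph contains a ",
                         "cycle (unsatisfiable for sequential placement)"),
                         call = NULL)))
      }
      comp[comp == comp[j]] <- comp[i]
    }
    if (template[i, j] == 1L &&
        !code1_feasible(PIECE_IDS[i], PIECE_IDS[j])) {
      stop(structure(class = c("cae_constructive_failure", "error",
                               "condition"),
                     list(message = paste0(
                       "constructive-failure: pieces ", PIECE_IDS[i], " and ",
                       PIECE_IDS[j], " share no edge length; complete line ",
                       "overlap is unsatisfiable"),
                       call = NULL)))
    }
  }
  invisible(TRUE)
}
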