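# Brute-force boundary-sampling oracle for the pairwise relation codes.
# Independent of the analytic classifier: both boundaries are densely
# sampled and the contact set is classified by its measured length and
# endpoint structure.

oracle_point_seg_dist <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax; aby <- by - ay
  L2 <- abx^2 + aby^2
  t <- ((px - ax) * abx + (py - ay) * aby) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((ax + t * abx - px)^2 + (ay + t * aby - py)^2)
}

# distance of many points to the nearest boundary point of polygon v
oracle_dist_to_boundary <- function(pts, v) {
  n <- nrow(v)
  d <- rep(Inf, nrow(pts))
  for (e in seq_len(n)) {
    a <- v[e, ]; b <- v[if (e == n) 1 else e + 1, ]
    d <- pmin(d, oracle_point_seg_dist(pts[, 1], pts[, 2],
                                       a[1], a[2], b[1], b[2]))
  }
  d
}

# sampling-based relation code; returns NA for marginal configurations
# (any measured quantity within `margin` of a category boundary)
oracle_relation <- function(va, vb, eps, n_samp = 600) {
  edges <- function(v) {
    n <- nrow(v)
    lapply(seq_len(n), function(e) {
      list(a = v[e, ], b = v[if (e == n) 1 else e + 1, ],
           len = sqrt(sum((v[if (e == n) 1 else e + 1, ] - v[e, ])^2)))
    })
  }
  ea <- edges(va); eb <- edges(vb)
  margin <- 2 * eps

  # measured collinear overlap length for each edge pair
  best <- NULL
  line_codes <- integer(0)
  for (i in seq_along(ea)) {
    for (j in seq_along(eb)) {
      e <- ea[[i]]; f <- eb[[j]]
      tseq <- seq(0, 1, length.out = n_samp)
      pts <- cbind(e$a[1] + tseq * (e$b[1] - e$a[1]),
                   e$a[2] + tseq * (e$b[2] - e$a[2]))
      d <- oracle_point_seg_dist(pts[, 1], pts[, 2], f$a[1], f$a[2],
                                 f$b[1], f$b[2])
      on_f <- d <= eps
      len <- sum(on_f) / n_samp * e$len
      if (len > 3 * e$len / n_samp + eps) {
        # a genuine shared segment; classify by its extent
        eq_e <- abs(len - e$len)
        # measure the overlap from f's side as well
        tseq2 <- seq(0, 1, length.out = n_samp)
        pts2 <- cbind(f$a[1] + tseq2 * (f$b[1] - f$a[1]),
                      f$a[2] + tseq2 * (f$b[2] - f$a[2]))
        d2 <- oracle_point_seg_dist(pts2[, 1], pts2[, 2], e$a[1], e$a[2],
                                    e$b[1], e$b[2])
        len2 <- sum(d2 <= eps) / n_samp * f$len
        eq_f <- abs(len2 - f$len)
        step <- max(e$len, f$len) / n_samp * 3 + margin
        if (eq_e < step && eq_f < step) {
          line_codes <- c(line_codes, 1L)
        } else if (xor(eq_e < step, eq_f < step)) {
          # the fully-covered edge: strictly inside the other?
          inner <- if (eq_e < step) e else f
          outer <- if (eq_e < step) f else e
          d_ends <- c(
            min(sqrt(sum((inner$a - outer$a)^2)),
                sqrt(sum((inner$a - outer$b)^2))),
            min(sqrt(sum((inner$b - outer$a)^2)),
                sqrt(sum((inner$b - outer$b)^2))))
          if (all(d_ends > step)) {
            line_codes <- c(line_codes, 3L)
          } else if (all(d_ends > margin | d_ends < margin)) {
            line_codes <- c(line_codes, 2L)
          }
        } else {
          line_codes <- c(line_codes, 2L)
        }
      }
    }
  }
  if (length(line_codes)) return(min(line_codes))

  # point contacts: vertices of one polygon near the other's boundary
  vv <- FALSE; ve <- FALSE
  for (i in seq_len(nrow(va))) {
    dvv <- sqrt(rowSums(sweep(vb, 2, va[i, ])^2))
    db <- oracle_dist_to_boundary(va[i, , drop = FALSE], vb)
    if (any(dvv <= eps)) vv <- TRUE
    else if (db <= eps) ve <- TRUE
    else if (db < margin) return(NA_integer_)  # marginal
  }
  for (j in seq_len(nrow(vb))) {
    dvv <- sqrt(rowSums(sweep(va, 2, vb[j, ])^2))
    db <- oracle_dist_to_boundary(vb[j, , drop = FALSE], va)
    if (any(dvv <= eps)) next
    else if (db <= eps) ve <- TRUE
    else if (db < margin) return(NA_integer_)
  }
  if (ve) return(4L)
  if (vv) return(5L)
  0L
}
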