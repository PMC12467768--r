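# Pairwise relation classification and figure encoding.

test_that("relation codes match their definitions on constructed contacts", {
  # complete line overlap: congruent triangles sharing the full hypotenuse
  t1 <- piece("small_tri_a", rbind(c(0, 0), c(1, 0), c(0, 1)))
  t2 <- piece("small_tri_b", rbind(c(1, 0), c(1, 1), c(0, 1)))
  expect_identical(classify_relationship(t1, t2), 1L)

  # disjoint squares
  expect_identical(classify_relationship(sq(0, 0), sq(3, 0)), 0L)

  # point-line contact: apex at the midpoint of a square edge, no
  # collinear segments
  apex <- piece("small_tri_a",
                rbind(c(0.5, 1), c(1.2, 1.8), c(0.2, 2)))
  expect_identical(classify_relationship(sq(0, 0), apex), 4L)

  # line containment: unit edge strictly inside a collinear length-2 edge
  lt <- piece("large_tri_a", rbind(c(0, 0), c(2, 0), c(0, 2)))
  st <- piece("small_tri_a", rbind(c(0.4, 0), c(1.4, 0), c(0.4, -1)))
  expect_identical(classify_relationship(lt, st), 3L)

  # partial line overlap: collinear with overhang on both sides
  st2 <- piece("small_tri_a", rbind(c(1.5, 0), c(2.5, 0), c(1.5, -1)))
  expect_identical(classify_relationship(lt, st2), 2L)

  # point overlap: coincident vertices, nothing collinear
  st3 <- piece("small_tri_a", rbind(c(2, 0), c(3, -0.3), c(3.2, 0.9)))
  expect_identical(classify_relationship(lt, st3), 5L)
})

test_that("classification is symmetric and rejects invalid configurations", {
  t1 <- piece("small_tri_a", rbind(c(0, 0), c(1, 0), c(0, 1)))
  t2 <- piece("small_tri_b", rbind(c(1, 0), c(1, 1), c(0, 1)))
  expect_identical(classify_relationship(t1, t2),
                   classify_relationship(t2, t1))
  # overlapping interiors
  expect_error(classify_relationship(sq(0, 0), sq(0.5, 0.5)),
               "invalid-configuration")
  # degenerate piece
  expect_error(piece("small_tri_a", rbind(c(0, 0), c(1, 0), c(2, 0))),
               "invalid-piece")
  # wrong vertex count
  expect_error(piece("square", rbind(c(0, 0), c(1, 0), c(0, 1))),
               "invalid-piece")
})

test_that("classifier agrees with the boundary-sampling oracle", {
  set.seed(101)
  n_checked <- 0
  n_marginal <- 0
  while (n_checked < 220) {
    cfg <- random_pair_config()
    if (is.null(cfg)) next
    va <- cfg$a$vertices; vb <- cfg$b$vertices
    eps <- 1e-6 * tangramcae:::bbox_diagonal(rbind(va, vb))
    o <- oracle_relation(va, vb, eps)
    if (is.na(o)) { n_marginal <- n_marginal + 1; next }
    expect_identical(classify_relationship(cfg$a, cfg$b), o,
                     label = paste("config code", cfg$code))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 220)
})

test_that("encode builds symmetric matrices and reports offending pairs", {
  g <- gen_figures(sim_figure_spec(template = matrix(0L, 7, 7), seed = 2), 1)
  m <- g$encodings[[1]]
  expect_s3_class(m, "cae_matrix")
  expect_identical(sum(unclass(m)), 0L)

  # chain of point overlaps on the super/sub-diagonal
  tm <- matrix(0L, 7, 7)
  for (i in 1:6) tm[i, i + 1] <- tm[i + 1, i] <- 5L
  g5 <- gen_figures(sim_figure_spec(template = tm, seed = 3), 1)
  expect_identical(unname(unclass(g5$encodings[[1]])[, ]), tm)

  # overlapping figure is rejected with the pair identified
  bad <- g$figures[[1]]
  bad$pieces[[2]]$vertices <- bad$pieces[[1]]$vertices + 0.1
  expect_error(encode(bad), "large_tri_a, large_tri_b")
})

test_that("encoding is invariant under similarity transforms", {
  set.seed(7)
  g <- gen_figures(sim_figure_spec(seed = 31), 12)
  for (k in seq_along(g$figures)) {
    fig <- g$figures[[k]]
    ref <- unclass(g$encodings[[k]])
    for (r in 1:4) {
      tf <- transform_figure(fig, rotate = runif(1, 0, 2 * pi),
                             scale = exp(runif(1, -2, 2)),
                             translate = runif(2, -100, 100))
      expect_identical(unclass(encode(tf))[, ], ref[, ])
    }
  }
})

test_that("coordinate jitter far below tolerance never changes codes", {
  set.seed(8)
  g <- gen_figures(sim_figure_spec(seed = 17), 5)
  for (k in seq_along(g$figures)) {
    fig <- g$figures[[k]]
    tol <- fig$tol
    fig$pieces <- lapply(fig$pieces, function(p) {
      p$vertices <- p$vertices +
        matrix(runif(length(p$vertices), -tol / 10, tol / 10), ncol = 2)
      p
    })
    expect_identical(unclass(encode(fig))[, ],
                     unclass(g$encodings[[k]])[, ])
  }
})

test_that("figure JSON round trip preserves coordinates and encoding", {
  g <- gen_figures(sim_figure_spec(seed = 41), 3)
  for (k in seq_along(g$figures)) {
    fig <- g$figures[[k]]
    path <- withr::local_tempfile(fileext = ".json")
    write_figure(fig, path)
    back <- read_figure(path)
    all_in <- do.call(rbind, lapply(fig$pieces, `[[`, "vertices"))
    all_out <- do.call(rbind, lapply(back$pieces, `[[`, "vertices"))
    # identity assignment may swap A/B pairs; compare sorted coordinates
    expect_lt(max(abs(all_in[order(all_in[, 1], all_in[, 2]), ] -
                        all_out[order(all_out[, 1], all_out[, 2]), ])),
              1e-9)
    expect_equal(cae_distance(encode(back), g$encodings[[k]]), 0)
  }
})

test_that("SVG import matches the JSON twin's encoding", {
  g <- gen_figures(sim_figure_spec(seed = 43), 2)
  for (fig in g$figures) {
    jpath <- withr::local_tempfile(fileext = ".json")
    spath <- withr::local_tempfile(fileext = ".svg")
    write_figure(fig, jpath)
    polys <- vapply(fig$pieces, function(p) {
      paste(apply(p$vertices, 1, function(v) {
        sprintf("%.12f,%.12f", v[1], v[2])
      }), collapse = " ")
    }, character(1))
    svg <- c('<svg xmlns="http://www.w3.org/2000/svg">',
             sprintf('<polygon points="%s"/>', polys), "</svg>")
    writeLines(svg, spath)
    expect_identical(unclass(encode(read_figure(spath)))[, ],
                     unclass(encode(read_figure(jpath)))[, ])
  }
})

test_that("malformed figure files raise format errors", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(figure_id = "x", pieces = lapply(1:6, function(i)
    list(vertices = matrix(c(0, 0, 1, 0, 0, 1) + i * 3, ncol = 2)))),
    path, digits = NA, auto_unbox = TRUE)
  expect_error(read_figure(path), "format error")
})

test_that("encoding CSV round trips", {
  g <- gen_figures(sim_figure_spec(seed = 47), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cae_csv(g$encodings[[1]], path)
  expect_identical(unclass(read_cae_csv(path))[, ],
                   unclass(g$encodings[[1]])[, ])
})
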