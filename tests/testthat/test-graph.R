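test_that("lattice contiguity matches the analytic king/rook move graphs", {
  g22 <- make_lattice(2, 2, "queen")
  expect_true(all(lengths(g22$neighbors) == 3))

  g13 <- make_lattice(1, 3, "queen")
  expect_equal(unname(lengths(g13$neighbors)), c(1, 2, 1))  # path graph

  rook <- make_lattice(3, 3, "rook")
  queen <- make_lattice(3, 3, "queen")
  expect_equal(length(rook$neighbors[["r2c2"]]), 4)
  expect_equal(length(queen$neighbors[["r2c2"]]), 8)

  expect_error(make_lattice(1, 1), "at least 2")

  # full analytic check on a 4 x 5 lattice: queen neighbours are exactly the
  # cells within Chebyshev distance 1
  g <- make_lattice(4, 5, "queen")
  for (r in 1:4) for (c in 1:5) {
    id <- paste0("r", r, "c", c)
    expected <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (r + dr >= 1 && r + dr <= 4 && c + dc >= 1 && c + dc <= 5) {
        expected <- c(expected, paste0("r", r + dr, "c", c + dc))
      }
    }
    expect_setequal(g$neighbors[[id]], expected)
  }
})

test_that("queen contiguity from polygons detects shared edges and corners", {
  polys <- square_polys(2, 2)
  g <- queen_contiguity(polys)
  expect_true(all(lengths(g$neighbors) == 3))  # K4: shared corner counts

  # two disjoint squares
  far <- list(a = cbind(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0)),
              b = cbind(x = c(5, 6, 6, 5, 5), y = c(0, 0, 1, 1, 0)))
  g2 <- queen_contiguity(far)
  expect_equal(max(g2$components), 2)
  expect_true(all(lengths(g2$neighbors) == 0))

  g3 <- queen_contiguity(square_polys(3, 3))
  expect_equal(length(g3$neighbors[["r2c2"]]), 8)
  expect_equal(length(g3$neighbors[["r1c1"]]), 3)

  dup <- far; names(dup) <- c("a", "a")
  expect_error(queen_contiguity(dup), "unique")
  bad <- far; bad$b <- bad$b[1:2, ]
  expect_error(queen_contiguity(bad), "invalid geometry for area b")

  # polygon-derived graph equals the direct lattice construction
  gl <- make_lattice(3, 4, "queen")
  gp <- queen_contiguity(gl$polygons)
  expect_identical(gp$neighbors[gl$area_ids], gl$neighbors)
})

test_that("weight styles satisfy their defining invariants", {
  path3 <- area_graph(c("a", "b", "c"),
                      list(a = "b", b = c("a", "c"), c = "b"))
  Wr <- to_weights(path3, "row_standardized")
  expect_equal(as.numeric(Wr["b", ]), c(0.5, 0, 0.5))
  expect_equal(unname(Matrix::rowSums(Wr)), c(1, 1, 1))

  set.seed(4)
  g <- make_lattice(4, 4)
  Wb <- to_weights(g, "binary")
  expect_true(Matrix::isSymmetric(Wb))
  expect_true(all(Wb@x %in% c(0, 1)))

  k4 <- make_lattice(2, 2)
  Ws <- to_weights(k4, "self_included_binary")
  expect_equal(unname(Matrix::rowSums(Ws)), rep(4, 4))
  expect_equal(unname(Matrix::diag(Ws)), rep(1, 4))
})

test_that("intrinsic CAR precision is the graph Laplacian with its identities", {
  path3 <- area_graph(c("a", "b", "c"),
                      list(a = "b", b = c("a", "c"), c = "b"))
  Q <- as.matrix(icar_precision(path3)$Q)
  expect_equal(unname(Q), rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  g <- make_lattice(4, 4, "queen")
  ip <- icar_precision(g)
  expect_true(all(abs(Matrix::rowSums(ip$Q)) < 1e-12))
  ev <- eigen(as.matrix(ip$Q), symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10)          # positive semidefinite
  expect_equal(sum(abs(ev) < 1e-8), 1)   # one zero eigenvalue per component

  # pairwise-difference identity x'Qx = sum_{i~j} (x_i - x_j)^2
  W <- as.matrix(to_weights(g, "binary"))
  edges <- which(upper.tri(W) & W == 1, arr.ind = TRUE)
  set.seed(11)
  for (r in 1:100) {
    x <- rnorm(16)
    expect_lt(abs(drop(t(x) %*% as.matrix(ip$Q) %*% x) -
                    sum((x[edges[, 1]] - x[edges[, 2]])^2)), 1e-10)
  }
})

test_that("scaled ICAR attains geometric-mean marginal variance 1 (dense oracle)", {
  g <- make_lattice(4, 4, "queen")
  ip <- icar_precision(g, scaled = TRUE)
  # dense pseudo-inverse oracle under the sum-to-zero constraint
  Qs <- as.matrix(ip$Q_scaled)
  e <- eigen(Qs, symmetric = TRUE)
  n <- nrow(Qs)
  V <- e$vectors[, 1:(n - 1)]
  pinv <- V %*% diag(1 / e$values[1:(n - 1)]) %*% t(V)
  gm <- exp(mean(log(diag(pinv))))
  expect_lt(abs(gm - 1), 1e-8)
  expect_lt(max(abs(ip$marginal_variances - diag(pinv))), 1e-8)
})

test_that("GAL files round-trip and asymmetric lists are rejected", {
  g <- make_lattice(5, 5, "queen")
  path <- withr::local_tempfile(fileext = ".gal")
  write_gal(g, path)
  g2 <- read_gal(path)
  expect_identical(g2$neighbors[g$area_ids], g$neighbors)

  bad <- c("2", "a 1", "b", "b 0", "")
  badfile <- withr::local_tempfile(fileext = ".gal")
  writeLines(bad, badfile)
  expect_error(read_gal(badfile), "asymmetric")

  iso <- c("3", "a 1", "b", "b 1", "a", "c 0", "")
  isofile <- withr::local_tempfile(fileext = ".gal")
  writeLines(iso, isofile)
  g3 <- read_gal(isofile)
  expect_equal(g3$neighbors[["c"]], character(0))
  expect_equal(max(g3$components), 2)
})

test_that("GAL round-trip is the identity on random graphs", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.3)
    A <- A + t(A)
    ids <- paste0("n", seq_len(n))
    nb <- lapply(seq_len(n), function(i) ids[A[i, ] == 1])
    names(nb) <- ids
    g <- area_graph(ids, nb)
    f <- tempfile(fileext = ".gal")
    write_gal(g, f)
    g2 <- read_gal(f)
    expect_identical(g2$neighbors[ids], g$neighbors)
    unlink(f)
  }
})

test_that("GeoJSON polygons round-trip through the reader", {
  g <- make_lattice(3, 3)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(g$polygons, f)
  polys <- read_geojson(f)
  expect_setequal(names(polys), g$area_ids)
  g2 <- queen_contiguity(polys)
  expect_identical(g2$neighbors[g$area_ids], g$neighbors)
})
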