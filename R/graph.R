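#' Areal contiguity graph
#'
#' An `area_graph` records which areas of an areal partition are neighbours.
#' It is the backbone of every spatial operation in the package: the intrinsic
#' CAR precision matrix, the spatial weight matrices used by Moran/LISA/Gi*,
#' and the structured random effect of the BYM model are all derived from it.
#'
#' @param area_ids character vector of unique area identifiers, in order.
#' @param neighbors named list; `neighbors[[id]]` is a character vector of the
#'   ids adjacent to `id`. Must be symmetric and irreflexive.
#' @param polygons optional named list of closed polygon rings (two-column
#'   coordinate matrices) so the graph can round-trip through GeoJSON.
#'
#' @return An object of class `area_graph` with elements `area_ids`,
#'   `neighbors`, `components` (integer component label per area) and
#'   optionally `polygons`.
#' @export
area_graph <- function(area_ids, neighbors, polygons = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area ids: ", paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  }
  nb <- lapply(area_ids, function(id) {
    v <- neighbors[[id]]
    if (is.null(v)) character(0) else sort(unique(as.character(v)))
  })
  names(nb) <- area_ids
  unknown <- setdiff(unlist(nb), area_ids)
  if (length(unknown)) stop("neighbor lists name unknown ids: ", paste(unknown, collapse = ", "))
  bad_pairs <- character(0)
  for (id in area_ids) {
    if (id %in% nb[[id]]) stop("area ", id, " listed as its own neighbor")
    for (j in nb[[id]]) {
      if (!(id %in% nb[[j]])) bad_pairs <- c(bad_pairs, paste0(id, "~", j))
    }
  }
  if (length(bad_pairs)) {
    stop("asymmetric neighbor lists: ", paste(bad_pairs, collapse = ", "))
  }
  g <- structure(
    list(area_ids = area_ids, neighbors = nb,
         components = .graph_components(area_ids, nb),
         polygons = polygons),
    class = "area_graph")
  g
}

#' @export
print.area_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat("area_graph:", length(x$area_ids), "areas,",
      sum(deg) / 2, "edges,", max(x$components), "component(s)\n")
  invisible(x)
}

# connected components by breadth-first search; returns integer labels 1..k
.graph_components <- function(area_ids, neighbors) {
  n <- length(area_ids)
  idx <- seq_len(n)
  names(idx) <- area_ids
  comp <- integer(n)
  queue <- integer(n)  # preallocated ring buffer
  k <- 0L
  for (s in idx) {
    if (comp[s] > 0L) next
    k <- k + 1L
    head_ptr <- 1L; tail_ptr <- 1L
    queue[1L] <- s
    comp[s] <- k
    while (head_ptr <= tail_ptr) {
      v <- queue[head_ptr]
      head_ptr <- head_ptr + 1L
      for (w in idx[neighbors[[v]]]) {
        if (comp[w] == 0L) {
          comp[w] <- k
          tail_ptr <- tail_ptr + 1L
          queue[tail_ptr] <- w
        }
      }
    }
  }
  names(comp) <- area_ids
  comp
}

#' Regular lattice of square areas
#'
#' Builds an `n_rows` by `n_cols` grid of unit squares together with its
#' contiguity graph. Queen contiguity joins squares that share an edge or a
#' corner; rook contiguity joins edge-sharing squares only. Each area carries
#' its square polygon so the lattice can be written to GeoJSON and re-read
#' through [queen_contiguity()].
#'
#' @param n_rows,n_cols positive integers; the product must be at least 2.
#' @param contiguity `"queen"` (default) or `"rook"`.
#' @return An [area_graph] whose ids are `"r<i>c<j>"` in row-major order.
#' @export
make_lattice <- function(n_rows, n_cols, contiguity = c("queen", "rook")) {
  contiguity <- match.arg(contiguity)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L || n_rows * n_cols < 2L) {
    stop("lattice must contain at least 2 areas")
  }
  ids <- as.vector(outer(seq_len(n_cols), seq_len(n_rows),
                         function(c, r) paste0("r", r, "c", c)))
  rowcol <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  steps <- if (contiguity == "rook") {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5L, , drop = FALSE]
  }
  nb <- vector("list", length(ids))
  names(nb) <- ids
  for (i in seq_along(ids)) {
    r <- rowcol$row[i]; c <- rowcol$col[i]
    rr <- r + steps[, 1L]; cc <- c + steps[, 2L]
    ok <- rr >= 1L & rr <= n_rows & cc >= 1L & cc <= n_cols
    nb[[i]] <- paste0("r", rr[ok], "c", cc[ok])
  }
  polys <- lapply(seq_along(ids), function(i) {
    r <- rowcol$row[i]; c <- rowcol$col[i]
    cbind(x = c(c - 1, c, c, c - 1, c - 1),
          y = c(r - 1, r - 1, r, r, r - 1))
  })
  names(polys) <- ids
  area_graph(ids, nb, polygons = polys)
}

#' Queen contiguity from polygons
#'
#' Two areas are neighbours when their boundaries share at least one point
#' (edge or corner). The predicate is exact: a vertex of one ring lying on a
#' boundary segment of the other (or vice versa) establishes contiguity; an
#' optional tolerance can absorb sloppy coordinates from real-world sources.
#'
#' @param polygons named list of closed two-column coordinate matrices, keyed
#'   by unique area id.
#' @param tolerance nonnegative snap distance; 0 (default) demands exact
#'   coincidence.
#' @return An [area_graph] with the polygons attached.
#' @export
queen_contiguity <- function(polygons, tolerance = 0) {
  ids <- names(polygons)
  if (is.null(ids) || anyDuplicated(ids)) stop("polygons must be a named list with unique ids")
  for (id in ids) {
    p <- polygons[[id]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 4L || anyNA(p)) {
      stop("invalid geometry for area ", id)
    }
  }
  n <- length(ids)
  boxes <- t(vapply(polygons, function(p)
    c(min(p[, 1L]), max(p[, 1L]), min(p[, 2L]), max(p[, 2L])), numeric(4L)))
  nb <- lapply(ids, function(id) character(0))
  names(nb) <- ids
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        # bounding-box reject before the exact predicate
        if (boxes[i, 1L] > boxes[j, 2L] + tolerance ||
            boxes[j, 1L] > boxes[i, 2L] + tolerance ||
            boxes[i, 3L] > boxes[j, 4L] + tolerance ||
            boxes[j, 3L] > boxes[i, 4L] + tolerance) next
        if (.rings_touch(polygons[[i]], polygons[[j]], tolerance)) {
          nb[[i]] <- c(nb[[i]], ids[j])
          nb[[j]] <- c(nb[[j]], ids[i])
        }
      }
    }
  }
  area_graph(ids, nb, polygons = polygons)
}

# boundaries share >= 1 point: some vertex of one ring lies on a segment of
# the other. For valid non-overlapping polygons any boundary contact
# (shared vertex, T-junction, or collinear edge overlap) is witnessed by at
# least one such vertex-on-segment incidence.
.rings_touch <- function(a, b, tol) {
  .any_vertex_on_ring(a, b, tol) || .any_vertex_on_ring(b, a, tol)
}

.any_vertex_on_ring <- function(pts, ring, tol) {
  nseg <- nrow(ring) - 1L
  for (s in seq_len(nseg)) {
    p1 <- ring[s, ]; p2 <- ring[s + 1L, ]
    d <- p2 - p1
    len2 <- sum(d * d)
    if (len2 == 0) {
      dist <- sqrt((pts[, 1L] - p1[1L])^2 + (pts[, 2L] - p1[2L])^2)
    } else {
      t <- pmin(1, pmax(0, ((pts[, 1L] - p1[1L]) * d[1L] + (pts[, 2L] - p1[2L]) * d[2L]) / len2))
      px <- p1[1L] + t * d[1L]; py <- p1[2L] + t * d[2L]
      dist <- sqrt((pts[, 1L] - px)^2 + (pts[, 2L] - py)^2)
    }
    if (any(dist <= tol + 1e-12)) return(TRUE)
  }
  FALSE
}

#' Spatial weight matrix from a contiguity graph
#'
#' @param graph an [area_graph].
#' @param style `"binary"` (0/1 adjacency), `"row_standardized"` (rows sum to
#'   1; all-zero rows for isolates), or `"self_included_binary"` (adjacency
#'   plus unit diagonal, the Gi* convention).
#' @return A sparse `Matrix::dgCMatrix` with `dimnames` set to the area ids
#'   and a `"style"` attribute.
#' @export
to_weights <- function(graph, style = c("binary", "row_standardized", "self_included_binary")) {
  style <- match.arg(style)
  ids <- graph$area_ids
  n <- length(ids)
  idx <- seq_len(n); names(idx) <- ids
  deg <- lengths(graph$neighbors)
  ii <- rep.int(idx, deg)
  jj <- idx[unlist(graph$neighbors, use.names = FALSE)]
  xx <- rep.int(1, length(ii))
  if (style == "row_standardized" && length(ii)) {
    xx <- 1 / deg[ii]
  }
  if (style == "self_included_binary") {
    ii <- c(ii, idx); jj <- c(jj, idx); xx <- c(xx, rep.int(1, n))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ids, ids))
  attr(W, "style") <- style
  W
}

#' Intrinsic CAR precision structure
#'
#' Returns the graph Laplacian `Q = D - A` (unit conditional precision), the
#' improper precision of the intrinsic CAR prior in which each area's effect
#' is conditionally Gaussian around the mean of its neighbours. With
#' `scaled = TRUE` the generalized marginal variances are computed per
#' connected component under the component-wise sum-to-zero constraint and
#' the scaling constant `c` with geometric-mean marginal variance of `Q/c`
#' equal to 1 is returned (the BYM2 convention, so that the structured
#' effect is on the same scale as a unit-variance IID effect). Components of
#' size 1 (isolates) carry no structured effect; they are flagged and their
#' marginal variance is excluded from the scaling.
#'
#' @param graph an [area_graph].
#' @param scaled compute the variance-scaling constant (default `FALSE`).
#' @return list with `Q` (sparse), `components`, `isolates` (ids), and when
#'   scaled, `scale_c` (scalar, per the definition above), `Q_scaled = Q / scale_c`,
#'   and `marginal_variances` of the scaled precision (NA for isolates).
#' @export
icar_precision <- function(graph, scaled = FALSE) {
  ids <- graph$area_ids
  n <- length(ids)
  A <- to_weights(graph, "binary")
  deg <- lengths(graph$neighbors)
  Q <- Matrix::Diagonal(n, x = deg) - A
  dimnames(Q) <- list(ids, ids)
  comp <- graph$components
  isolates <- ids[deg == 0L]
  out <- list(Q = Q, components = comp, isolates = isolates)
  if (scaled) {
    mv <- rep(NA_real_, n)
    names(mv) <- ids
    for (k in unique(comp)) {
      members <- which(comp == k)
      m <- length(members)
      if (m < 2L) next
      Qk <- as.matrix(Q[members, members, drop = FALSE])
      mv[members] <- .constrained_marginal_variances(Qk)
    }
    ok <- !is.na(mv)
    if (!any(ok)) stop("graph has no component with >= 2 areas; no structured effect possible")
    gm <- exp(mean(log(mv[ok])))
    scale_c <- 1 / gm  # geometric-mean marginal variance of Q/scale_c is 1
    out$scale_c <- scale_c
    out$Q_scaled <- Q / scale_c
    out$marginal_variances <- mv / gm
  }
  out
}

# marginal variances of the intrinsic GMRF with precision Qk under a
# sum-to-zero constraint: diagonal of the constrained generalized inverse,
# computed by eigen-decomposition (the null space is the constant vector)
.constrained_marginal_variances <- function(Qk) {
  e <- eigen(Qk, symmetric = TRUE)
  m <- nrow(Qk)
  lam <- e$values[seq_len(m - 1L)]
  V <- e$vectors[, seq_len(m - 1L), drop = FALSE]
  rowSums(sweep(V^2, 2L, lam, "/"))
}

#' Read and write GAL contiguity files
#'
#' The GAL dialect accepted: an optional leading metadata token line whose
#' last-but-two field is the area count, i.e. the header is either `n` alone
#' or `0 n <shapefile> <id-variable>`; then for each area a line `id degree`
#' followed by a line with `degree` neighbour ids (blank for isolates).
#'
#' @param path file path.
#' @return [read_gal()] returns an [area_graph]; [write_gal()] returns the
#'   path invisibly.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- if (length(header) == 1L) as.integer(header) else as.integer(header[[2L]])
  if (is.na(n) || n < 1L) stop("malformed GAL header: ", lines[[1L]])
  ids <- character(n); nb <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    hd <- strsplit(trimws(lines[[pos]]), "\\s+")[[1L]]
    if (length(hd) != 2L) stop("malformed GAL area header at line ", pos)
    ids[i] <- hd[[1L]]
    degree <- as.integer(hd[[2L]])
    nbline <- if (pos + 1L <= length(lines)) trimws(lines[[pos + 1L]]) else ""
    nbi <- if (nzchar(nbline)) strsplit(nbline, "\\s+")[[1L]] else character(0)
    if (length(nbi) != degree) {
      stop("area ", ids[i], ": declared degree ", degree, " but ", length(nbi), " neighbors listed")
    }
    nb[[i]] <- nbi
    pos <- pos + 2L
  }
  names(nb) <- ids
  area_graph(ids, nb)  # validates symmetry and unknown ids
}

#' @rdname read_gal
#' @param graph an [area_graph].
#' @export
write_gal <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(graph$area_ids)), con)
  for (id in graph$area_ids) {
    nb <- graph$neighbors[[id]]
    writeLines(paste(id, length(nb)), con)
    writeLines(paste(nb, collapse = " "), con)
  }
  invisible(path)
}

#' Read and write areal polygons as GeoJSON
#'
#' A minimal RFC 7946 FeatureCollection interface: each feature must carry a
#' Polygon (outer ring only) and a unique id in the named property.
#'
#' @param path file path.
#' @param id_property name of the feature property holding the area id.
#' @return [read_geojson()] returns a named list of polygon rings suitable
#'   for [queen_contiguity()]; [write_geojson()] returns the path invisibly.
#' @export
read_geojson <- function(path, id_property = "area_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a GeoJSON FeatureCollection")
  polys <- list()
  props <- list()
  for (f in gj$features) {
    id <- as.character(f$properties[[id_property]])
    if (!length(id) || !nzchar(id)) stop("feature without property '", id_property, "'")
    if (!identical(f$geometry$type, "Polygon")) {
      stop("area ", id, ": only Polygon geometries are supported")
    }
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    colnames(m) <- c("x", "y")
    if (id %in% names(polys)) stop("duplicate area id in GeoJSON: ", id)
    polys[[id]] <- m
    props[[id]] <- f$properties
  }
  attr(polys, "properties") <- props
  polys
}

#' @rdname read_geojson
#' @param polygons named list of polygon rings (e.g. `graph$polygons`).
#' @param properties optional named list (per area id) of extra properties.
#' @export
write_geojson <- function(polygons, path, id_property = "area_id", properties = NULL) {
  features <- lapply(names(polygons), function(id) {
    ring <- polygons[[id]]
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
    props <- c(stats::setNames(list(id), id_property),
               if (!is.null(properties)) as.list(properties[[id]]))
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a weight matrix as sparse triplets
#'
#' Writes `(i, j, w)` rows (area ids, weight) to CSV.
#' @param W weight matrix from [to_weights()].
#' @param path file path.
#' @export
write_weights_csv <- function(W, path) {
  T <- methods::as(W, "TsparseMatrix")
  ids <- rownames(W)
  df <- data.frame(i = ids[T@i + 1L], j = ids[T@j + 1L], w = T@x)
  df <- df[order(df$i, df$j), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
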