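#' Spatial weight matrices for areal zones
#'
#' A `spatial_weights` object holds the ordered zone identifiers, the n x n
#' nonnegative weight matrix W, its style (`"binary"` adjacency or
#' `"row-standardized"`), the normalizer `s0 = sum(W)`, and an optional cache
#' of the spectrum of the row-standardized matrix used by the model
#' likelihoods.
#'
#' @param w numeric n x n matrix, zero diagonal, nonnegative entries.
#' @param ids character vector of zone identifiers, one per row of `w`.
#' @param style `"binary"` or `"row-standardized"`.
#' @return An object of class `spatial_weights`.
#' @export
spatial_weights <- function(w, ids, style = c("binary", "row-standardized")) {
  style <- match.arg(style)
  w <- as.matrix(w)
  n <- nrow(w)
  ids <- as.character(ids)
  if (length(ids) != n || ncol(w) != n)
    stop("`w` must be square with one id per row")
  if (anyDuplicated(ids))
    stop("duplicated zone ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.finite(w)) || any(w < 0))
    stop("`w` must be finite and nonnegative")
  if (any(diag(w) != 0))
    stop("`w` must have a zero diagonal")
  if (style == "binary") {
    if (!all(w %in% c(0, 1)))
      stop("binary style requires 0/1 entries")
    if (!isTRUE(all.equal(w, t(w), tolerance = 0)))
      stop("binary style requires a symmetric matrix")
  } else {
    rs <- rowSums(w)
    if (any(rs > 0 & abs(rs - 1) > 1e-10))
      stop("row-standardized style requires nonzero rows to sum to 1")
  }
  dimnames(w) <- list(ids, ids)
  structure(
    list(ids = ids, w = w, style = style, s0 = sum(w), eigenvalues = NULL),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", length(x$ids), "zones,", x$style, "style, S0 =",
      format(x$s0), "\n")
  invisible(x)
}

n_zones <- function(w) length(w$ids)

#' Build binary weights from an undirected edge list
#'
#' Pairs are undirected; duplicates (in either orientation) collapse to a
#' single edge.
#'
#' @param edges two-column matrix or data frame of zone-id pairs.
#' @param ids ordered zone identifiers defining the matrix rows.
#' @return A binary symmetric [spatial_weights()] object.
#' @export
from_edge_list <- function(edges, ids) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicated zone ids")
  w <- matrix(0, n, n)
  if (NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("`edges` must have two columns")
    a <- match(as.character(edges[, 1]), ids)
    b <- match(as.character(edges[, 2]), ids)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(edges[, 1][is.na(a)], edges[, 2][is.na(b)]))
      stop("unknown zone id in edge list: ", paste(bad, collapse = ", "))
    }
    if (any(a == b))
      stop("self-loop in edge list at id: ",
           paste(unique(ids[a[a == b]]), collapse = ", "))
    w[cbind(a, b)] <- 1
    w[cbind(b, a)] <- 1
  }
  spatial_weights(w, ids, style = "binary")
}

## Exact-coordinate contiguity predicates. Vertices are keyed by their full
## decimal representation; synthetic lattices are exact, so no snapping.
vertex_keys <- function(ring) {
  m <- nrow(ring)
  # drop a closing vertex equal to the first
  if (m > 1 && all(ring[1, ] == ring[m, ])) m <- m - 1
  sprintf("%.17g|%.17g", ring[seq_len(m), 1], ring[seq_len(m), 2])
}

edge_keys <- function(ring) {
  v <- vertex_keys(ring)
  m <- length(v)
  a <- v
  b <- v[c(2:m, 1)]
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

as_rings <- function(geom, id) {
  if (is.matrix(geom)) return(list(geom))
  if (is.list(geom) && all(vapply(geom, is.matrix, TRUE))) return(geom)
  stop("invalid geometry for zone ", id,
       ": expected a coordinate matrix or list of ring matrices")
}

#' Contiguity weights from polygon geometries
#'
#' Queen contiguity joins zones sharing at least one boundary point (vertex);
#' rook contiguity requires a shared boundary segment of positive length.
#' Predicates are exact on the input coordinates (no snapping), which is the
#' right convention for programmatically generated lattices; real boundary
#' files should be topologically cleaned upstream.
#'
#' @param geometries named list (by zone id) of polygon rings: a numeric
#'   two-column coordinate matrix, or a list of such matrices for
#'   multi-ring zones.
#' @param rule `"queen"` (default, the rule used throughout the analysis) or
#'   `"rook"`.
#' @return A binary symmetric [spatial_weights()] object.
#' @export
contiguity_from_polygons <- function(geometries, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  ids <- names(geometries)
  if (is.null(ids) || any(ids == ""))
    stop("`geometries` must be a named list keyed by zone_id")
  if (anyDuplicated(ids))
    stop("duplicated zone_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keyfun <- if (rule == "queen") vertex_keys else edge_keys
  keys <- lapply(ids, function(id) {
    rings <- as_rings(geometries[[id]], id)
    ks <- unlist(lapply(rings, function(r) {
      if (!is.numeric(r) || ncol(r) != 2 || nrow(r) < 3)
        stop("invalid/empty geometry for zone ", id)
      keyfun(r)
    }))
    unique(ks)
  })
  n <- length(ids)
  w <- matrix(0, n, n)
  # invert: key -> zones touching it; zones sharing a key are neighbors
  zone_of <- rep.int(seq_len(n), lengths(keys))
  key_all <- unlist(keys)
  by_key <- split(zone_of, key_all)
  for (zs in by_key) {
    if (length(zs) > 1) {
      pr <- utils::combn(zs, 2)
      w[t(pr)] <- 1
      w[t(pr[2:1, , drop = FALSE])] <- 1
    }
  }
  spatial_weights(w, ids, style = "binary")
}

#' Row-standardize a binary weight matrix
#'
#' Divides each nonzero row by its row sum so that spatial lags are neighbor
#' averages and the spatial coefficients of the model family live in an
#' interpretable interval.
#'
#' @param w a binary [spatial_weights()] object.
#' @param islands how to treat zero rows: `"error"` (default) or `"zero"`
#'   (leave the row zero, with a warning).
#' @return A row-standardized `spatial_weights` object with the spectrum of
#'   the standardized matrix cached.
#' @export
row_standardize <- function(w, islands = c("error", "zero")) {
  islands <- match.arg(islands)
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style == "row-standardized") return(ensure_spectrum(w))
  rs <- rowSums(w$w)
  isl <- which(rs == 0)
  if (length(isl)) {
    if (islands == "error")
      stop("island (no-neighbor) zones: ", paste(w$ids[isl], collapse = ", "),
           "; use islands = \"zero\" to keep zero rows")
    warning("leaving ", length(isl), " island row(s) zero")
    rs[isl] <- 1
  }
  out <- spatial_weights(w$w / rs, w$ids, style = "row-standardized")
  # spectrum from the symmetric similar form of the binary source (exact, real)
  d <- rs
  s <- w$w / sqrt(outer(d, d))
  out$eigenvalues <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  out
}

#' Cache the spectrum of the row-standardized weight matrix
#'
#' The row-standardized matrix D^-1 A (A symmetric binary, D the degree
#' matrix) is similar to the symmetric D^-1/2 A D^-1/2, so its eigenvalues
#' are real; they drive the log-determinant term of every spatial likelihood
#' and the admissible interval for the spatial coefficients.
#'
#' @param w a `spatial_weights` object.
#' @return `w` with `$eigenvalues` filled (computed once, then reused).
#' @export
ensure_spectrum <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(w$eigenvalues)) return(w)
  ww <- w$w
  if (w$style == "binary") {
    rs <- rowSums(ww)
    rs[rs == 0] <- 1
    ww <- ww / rs
  }
  # use the similar symmetric form D^-1/2 A D^-1/2 when adjacency is symmetric
  ev <- if (isTRUE(all.equal(unname(w$w), unname(t(w$w)), tolerance = 1e-12))) {
    d <- rowSums(w$w)
    d[d == 0] <- 1
    s <- w$w / sqrt(outer(d, d))
    eigen(s, symmetric = TRUE, only.values = TRUE)$values
  } else {
    v <- eigen(ww, only.values = TRUE)$values
    if (max(abs(Im(v))) > 1e-8)
      stop("complex spectrum for asymmetric weights; supply symmetric adjacency")
    Re(v)
  }
  w$eigenvalues <- sort(ev)
  w
}

#' Connectivity summary of a weight matrix
#'
#' @param w a `spatial_weights` object.
#' @return A list with n, edge count, neighbor-count summary, island ids and
#'   the number of connected components.
#' @export
connectivity_report <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  adj <- w$w > 0
  deg <- rowSums(adj)
  n <- n_zones(w)
  # BFS over the symmetrized adjacency
  und <- adj | t(adj)
  comp <- rep.int(0L, n)
  ncomp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      ncomp <- ncomp + 1L
      queue <- i
      comp[i] <- ncomp
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(und[v, ] & comp == 0L)
        comp[nb] <- ncomp
        queue <- c(queue, nb)
      }
    }
  }
  list(
    n = n,
    edges = sum(adj | t(adj)) / 2,
    min_neighbors = min(deg),
    mean_neighbors = mean(deg),
    max_neighbors = max(deg),
    islands = w$ids[deg == 0],
    components = ncomp
  )
}

#' Read a GAL neighbor-list file
#'
#' Dialect: line 1 holds the zone count n; then, for each zone, one line
#' `"zone_id k"` followed by one line of k whitespace-separated neighbor ids.
#' Ids are opaque strings.
#'
#' @param path file path.
#' @return A binary [spatial_weights()] object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- sub("\\s+$", "", lines)
  if (!length(lines)) stop("GAL parse error at line 1: empty file")
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1]))
  if (is.na(n) || n < 1) stop("GAL parse error at line 1: invalid zone count")
  expect <- 1 + 2L * n
  if (length(lines) < expect)
    stop("GAL parse error: header declares ", n, " zones but file has ",
         length(lines), " lines (expected ", expect, ")")
  ids <- character(n)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    hline <- 2L * i
    toks <- strsplit(trimws(lines[hline]), "\\s+")[[1]]
    if (length(toks) != 2)
      stop("GAL parse error at line ", hline, ": expected \"zone_id k\"")
    k <- suppressWarnings(as.integer(toks[2]))
    if (is.na(k) || k < 0)
      stop("GAL parse error at line ", hline, ": invalid neighbor count")
    ids[i] <- toks[1]
    nline <- 2L * i + 1L
    ntoks <- if (nzchar(trimws(lines[nline])))
      strsplit(trimws(lines[nline]), "\\s+")[[1]] else character(0)
    if (length(ntoks) != k)
      stop("GAL parse error at line ", nline, ": zone \"", toks[1],
           "\" declares ", k, " neighbors but lists ", length(ntoks))
    nb[[i]] <- ntoks
  }
  if (anyDuplicated(ids)) stop("GAL parse error: duplicated zone id")
  unknown <- setdiff(unique(unlist(nb)), ids)
  if (length(unknown))
    stop("GAL parse error: unknown neighbor id(s): ",
         paste(unknown, collapse = ", "))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- match(nb[[i]], ids)
    w[i, j] <- 1
  }
  w <- pmax(w, t(w))  # GAL files list both directions; be tolerant
  spatial_weights(w, ids, style = "binary")
}

#' Write a GAL neighbor-list file
#'
#' Row-standardized matrices are re-binarized on write (GAL stores adjacency
#' only), with a warning.
#'
#' @param w a `spatial_weights` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style != "binary")
    warning("re-binarizing row-standardized weights for GAL output")
  adj <- (w$w > 0) | (t(w$w) > 0)
  n <- n_zones(w)
  con <- file(path, "wb")  # enforce LF endings
  on.exit(close(con))
  writeLines(as.character(n), con, sep = "\n")
  for (i in seq_len(n)) {
    nbr <- w$ids[adj[i, ]]
    writeLines(paste(w$ids[i], length(nbr)), con, sep = "\n")
    writeLines(paste(nbr, collapse = " "), con, sep = "\n")
  }
  invisible(path)
}

#' Read zone polygons from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file; one Feature per zone, Polygon or MultiPolygon.
#' @param id_key property name carrying the zone id (default `"zone_id"`).
#' @return Named list of ring coordinate matrices suitable for
#'   [contiguity_from_polygons()].
#' @export
read_geojson_zones <- function(path, id_key = "zone_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    id <- f$properties[[id_key]]
    if (is.null(id)) stop("feature missing property \"", id_key, "\"")
    id <- as.character(id)
    geom <- f$geometry
    ring_to_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_to_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ring_to_mat)), recursive = FALSE),
      stop("unsupported geometry type \"", geom$type, "\" for zone ", id)
    )
    if (!is.null(out[[id]])) stop("duplicated zone_id: ", id)
    out[[id]] <- rings
  }
  out
}

#' Write zone polygons (with optional per-zone properties) as GeoJSON
#'
#' @param geometries named list of ring coordinate matrices (or lists of
#'   rings) keyed by zone id.
#' @param path output path.
#' @param properties optional data frame of per-zone properties; must contain
#'   a `zone_id` column matching `names(geometries)`.
#' @return `path`, invisibly.
#' @export
write_geojson_zones <- function(geometries, path, properties = NULL) {
  ids <- names(geometries)
  if (!is.null(properties)) {
    stopifnot("zone_id" %in% names(properties))
    properties <- properties[match(ids, properties$zone_id), , drop = FALSE]
  }
  features <- lapply(seq_along(ids), function(i) {
    rings <- as_rings(geometries[[i]], ids[i])
    coords <- lapply(rings, function(r) {
      m <- r
      if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
      lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
    })
    props <- list(zone_id = ids[i])
    if (!is.null(properties))
      for (nm in setdiff(names(properties), "zone_id"))
        props[[nm]] <- properties[[nm]][i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
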