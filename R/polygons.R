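#' Polygon sets: named, classed polygons for annotations and regions
#'
#' A polygon set is a tibble with one row per polygon and columns
#' `name` (unique within the set), `class_label` (e.g. a histology class
#' such as "tumor", or a TMA core class) and `coords`, a list-column of
#' n-by-2 numeric matrices giving the ring vertices in micrometres.
#' Rings are stored implicitly closed: the first vertex is not repeated.
#' The `scope` attribute distinguishes annotations (histology labels)
#' from regions (structural units such as TMA cores used to split a
#' dataset).
#'
#' @param name character vector of polygon names (unique within the set).
#' @param class_label character vector of class labels, recycled.
#' @param coords list of n-by-2 numeric matrices (x, y in micrometres).
#' @param scope `"annotation"` or `"region"`.
#' @return A tibble of class `polygon_set`.
#' @export
polygon_set <- function(name = character(), class_label = character(),
                        coords = list(), scope = c("annotation", "region")) {
  scope <- match.arg(scope)
  stopifnot(length(name) == length(coords))
  if (length(class_label) == 1L) class_label <- rep(class_label, length(name))
  if (length(name) > 0L && anyDuplicated(name)) {
    stop("polygon names must be unique within a set", call. = FALSE)
  }
  coords <- lapply(coords, as_ring)
  out <- tibble::tibble(name = as.character(name),
                        class_label = as.character(class_label),
                        coords = coords)
  structure(out, scope = scope,
            class = c("polygon_set", class(out)))
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set scope=%s, %d polygon(s)>\n",
              attr(x, "scope"), nrow(x)))
  NextMethod()
}

#' @rdname polygon_set
#' @param x object to query.
#' @export
polygon_scope <- function(x) attr(x, "scope") %||% "annotation"

# Validate and canonicalize a ring: numeric n x 2 matrix, implicitly closed,
# >= 3 distinct vertices.
as_ring <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("polygon must be an n x 2 matrix", call. = FALSE)
  # drop explicit closure if present
  if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(unique(p)) < 3L) {
    stop("invalid polygon: fewer than 3 distinct vertices", call. = FALSE)
  }
  if (!all(is.finite(p))) stop("polygon vertices must be finite", call. = FALSE)
  dimnames(p) <- NULL
  p
}

#' Shoelace area of a polygon ring
#'
#' @param polygon an n-by-2 matrix of ring vertices (implicitly closed),
#'   in micrometres.
#' @return Non-negative area in square micrometres.
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 1
#' @export
polygon_area <- function(polygon) {
  p <- as_ring(polygon)
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param points an n-by-2 matrix (or data frame with columns x, y).
#' @param polygon an m-by-2 ring matrix, implicitly closed.
#' @return Logical vector of length n.
#' @export
points_in_polygon <- function(points, polygon) {
  p <- as_ring(polygon)
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  points <- matrix(as.numeric(points), ncol = 2L)
  n <- nrow(points)
  if (n == 0L) return(logical(0L))
  px <- points[, 1L]; py <- points[, 2L]
  m <- nrow(p)
  inside <- logical(n)
  on_edge <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    xi <- p[i, 1L]; yi <- p[i, 2L]
    xj <- p[j, 1L]; yj <- p[j, 2L]
    # boundary: point on segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    cross <- dx * (py - yi) - dy * (px - xi)
    within <- (px >= pmin(xi, xj) - 1e-12) & (px <= pmax(xi, xj) + 1e-12) &
      (py >= pmin(yi, yj) - 1e-12) & (py <= pmax(yi, yj) + 1e-12)
    on_edge <- on_edge | (abs(cross) <= 1e-9 * pmax(1, abs(dx) + abs(dy)) & within)
    # even-odd ray cast (horizontal ray towards +x)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# Clip a ring to an axis-aligned rectangle (Sutherland-Hodgman).
# Returns an n x 2 matrix (possibly with < 3 rows -> empty) or NULL.
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  poly <- as_ring(ring)
  clip_edge <- function(poly, keep, intersect) {
    if (nrow(poly) == 0L) return(poly)
    out <- matrix(numeric(0), ncol = 2L)
    n <- nrow(poly)
    for (i in seq_len(n)) {
      cur <- poly[i, ]; prv <- poly[if (i == 1L) n else i - 1L, ]
      cin <- keep(cur); pin <- keep(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(a, b, t) a + (b - a) * t
  poly <- clip_edge(poly, function(p) p[1L] >= xmin, function(a, b) {
    t <- (xmin - a[1L]) / (b[1L] - a[1L]); c(xmin, ix(a[2L], b[2L], t))
  })
  poly <- clip_edge(poly, function(p) p[1L] <= xmax, function(a, b) {
    t <- (xmax - a[1L]) / (b[1L] - a[1L]); c(xmax, ix(a[2L], b[2L], t))
  })
  poly <- clip_edge(poly, function(p) p[2L] >= ymin, function(a, b) {
    t <- (ymin - a[2L]) / (b[2L] - a[2L]); c(ix(a[1L], b[1L], t), ymin)
  })
  poly <- clip_edge(poly, function(p) p[2L] <= ymax, function(a, b) {
    t <- (ymax - a[2L]) / (b[2L] - a[2L]); c(ix(a[1L], b[1L], t), ymax)
  })
  if (nrow(poly) > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(poly))) < 1e-12)
    poly <- poly[!dup, , drop = FALSE]
    if (nrow(poly) > 1L && all(abs(poly[1L, ] - poly[nrow(poly), ]) < 1e-12)) {
      poly <- poly[-nrow(poly), , drop = FALSE]
    }
  }
  if (nrow(poly) < 3L) return(NULL)
  poly
}

# Axis-aligned rectangle ring helper.
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

ring_bbox <- function(ring) {
  p <- as_ring(ring)
  c(xmin = min(p[, 1L]), ymin = min(p[, 2L]),
    xmax = max(p[, 1L]), ymax = max(p[, 2L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
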