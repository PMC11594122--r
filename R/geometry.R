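# Planar geometry primitives used across the package.
#
# Representation conventions (shared by every module):
#  * ring      — an n x 2 numeric matrix of vertices, NOT closed (the last
#                vertex differs from the first); orientation is irrelevant.
#  * part      — a list of rings; the first ring is the exterior boundary,
#                any further rings are holes.
#  * geometry  — a list of parts (a multipolygon). Single squares are still
#                wrapped: geometry(list(part(list(ring)))).
# All coordinates live in one planar CRS; 1 map unit = 1 m for synthetic data.

#' Build a rectangular ring
#'
#' @param xmin,ymin,xmax,ymax rectangle corners (map units).
#' @return A 4 x 2 vertex matrix (counter-clockwise, not closed).
#' @export
rectRing <- function(xmin, ymin, xmax, ymax) {
    stopifnot(xmax > xmin, ymax > ymin)
    cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Wrap a single ring as a full (multi)polygon geometry
#'
#' @param ring an n x 2 vertex matrix.
#' @return A geometry: list of one part holding one exterior ring.
#' @export
ringGeometry <- function(ring) {
    stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 3)
    list(list(ring))
}

## signed shoelace area of one ring
ringArea <- function(ring) {
    x <- ring[, 1]; y <- ring[, 2]
    j <- c(seq_len(nrow(ring))[-1], 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Area of a geometry
#'
#' Exterior-ring areas minus hole areas, summed over parts (shoelace formula,
#' planar units squared).
#'
#' @param geom a geometry (list of parts, each a list of rings).
#' @return Numeric scalar area.
#' @export
geometryArea <- function(geom) {
    sum(vapply(geom, function(part) {
        a <- ringArea(part[[1]])
        if (length(part) > 1)
            a <- a - sum(vapply(part[-1], ringArea, numeric(1)))
        a
    }, numeric(1)))
}

## bounding box c(xmin, ymin, xmax, ymax) of a geometry
geometryBBox <- function(geom) {
    xs <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 1])))
    ys <- unlist(lapply(geom, function(p) lapply(p, function(r) r[, 2])))
    c(min(xs), min(ys), max(xs), max(ys))
}

#' Test points against a geometry (boundary inclusive)
#'
#' @param x,y coordinate vectors of equal length.
#' @param geom a geometry.
#' @return Logical vector; TRUE where the point lies inside or on the boundary
#'   of the polygon (and outside its holes).
#' @export
pointsInGeometry <- function(x, y, geom) {
    stopifnot(length(x) == length(y))
    points_in_geometry_cpp(as.numeric(x), as.numeric(y), geom)
}

## Sutherland-Hodgman clip of a convex ring by the half-plane of points at
## least as close to p as to q (the Voronoi dominance region of p over q).
clipHalfPlane <- function(ring, p, q) {
    n <- q - p
    m <- (p + q) / 2
    s <- (ring[, 1] - m[1]) * n[1] + (ring[, 2] - m[2]) * n[2]
    nv <- nrow(ring)
    keep <- s <= 0
    if (all(keep)) return(ring)
    if (!any(keep)) return(NULL)
    out <- vector("list", 2L * nv)
    k <- 0L
    for (i in seq_len(nv)) {
        j <- if (i == nv) 1L else i + 1L
        if (keep[i]) {
            k <- k + 1L; out[[k]] <- ring[i, ]
        }
        if (xor(keep[i], keep[j])) {
            t <- s[i] / (s[i] - s[j])
            k <- k + 1L
            out[[k]] <- ring[i, ] + t * (ring[j, ] - ring[i, ])
        }
    }
    do.call(rbind, out[seq_len(k)])
}

## Voronoi cell of site i among sites (k x 2), clipped to the extent rectangle.
voronoiCell <- function(i, sites, extent) {
    cell <- rectRing(extent[1], extent[2], extent[3], extent[4])
    p <- sites[i, ]
    for (j in seq_len(nrow(sites))) {
        if (j == i) next
        cell <- clipHalfPlane(cell, p, sites[j, ])
        if (is.null(cell)) stop("degenerate Voronoi cell: coincident sites?")
    }
    cell
}

## perpendicular distance of points to the segment (a, b)
pointSegmentDistance <- function(pts, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    px <- a[1] + t * ab[1]
    py <- a[2] + t * ab[2]
    sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

## Douglas-Peucker on an open polyline (keeps both endpoints).
dpPolyline <- function(coords, tol) {
    n <- nrow(coords)
    if (n <= 2) return(coords)
    d <- pointSegmentDistance(coords[2:(n - 1), , drop = FALSE],
                              coords[1, ], coords[n, ])
    imax <- which.max(d)
    if (d[imax] <= tol)
        return(coords[c(1, n), , drop = FALSE])
    split <- imax + 1L
    left <- dpPolyline(coords[1:split, , drop = FALSE], tol)
    right <- dpPolyline(coords[split:n, , drop = FALSE], tol)
    rbind(left[-nrow(left), , drop = FALSE], right)
}

## Douglas-Peucker for a closed ring: anchor at vertex 1 and the vertex
## farthest from it, simplify both halves, re-join. tol = 0 returns the ring
## unchanged.
dpRing <- function(ring, tol) {
    stopifnot(tol >= 0)
    if (nrow(ring) < 4) stop("ring must have at least 4 vertices to simplify")
    if (tol == 0) return(ring)
    d <- sqrt((ring[, 1] - ring[1, 1])^2 + (ring[, 2] - ring[1, 2])^2)
    k <- which.max(d)
    n <- nrow(ring)
    half1 <- dpPolyline(ring[1:k, , drop = FALSE], tol)
    half2 <- dpPolyline(ring[c(k:n, 1L), , drop = FALSE], tol)
    out <- rbind(half1[-nrow(half1), , drop = FALSE],
                 half2[-nrow(half2), , drop = FALSE])
    if (nrow(out) < 3) out <- ring[sort(unique(c(1L, k,
        k + which.max(d[k:n] - 0)))), , drop = FALSE]
    out
}

## Does the segment (x1,y1)-(x2,y2) pass through the OPEN rectangle interior?
## Liang-Barsky clip; a clipped midpoint strictly inside decides.
segmentCrossesRect <- function(x1, y1, x2, y2, xmin, ymin, xmax, ymax) {
    dx <- x2 - x1; dy <- y2 - y1
    p <- c(-dx, dx, -dy, dy)
    q <- c(x1 - xmin, xmax - x1, y1 - ymin, ymax - y1)
    t0 <- 0; t1 <- 1
    for (k in 1:4) {
        if (p[k] == 0) {
            if (q[k] < 0) return(FALSE)
        } else {
            r <- q[k] / p[k]
            if (p[k] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
        }
    }
    if (t0 > t1) return(FALSE)
    tm <- (t0 + t1) / 2
    mx <- x1 + tm * dx; my <- y1 + tm * dy
    mx > xmin && mx < xmax && my > ymin && my < ymax
}

## Is the axis-aligned rectangle entirely covered by the geometry?
## True iff all four corners are inside and no polygon edge (exterior or hole)
## passes through the open rectangle.
rectCoveredByGeometry <- function(xmin, ymin, xmax, ymax, geom) {
    cx <- c(xmin, xmax, xmax, xmin)
    cy <- c(ymin, ymin, ymax, ymax)
    if (!all(pointsInGeometry(cx, cy, geom))) return(FALSE)
    for (part in geom) {
        for (ring in part) {
            n <- nrow(ring)
            for (i in seq_len(n)) {
                j <- if (i == n) 1L else i + 1L
                if (segmentCrossesRect(ring[i, 1], ring[i, 2],
                                       ring[j, 1], ring[j, 2],
                                       xmin, ymin, xmax, ymax))
                    return(FALSE)
            }
        }
    }
    TRUE
}
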