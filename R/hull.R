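#' Minimum convex polygon in log brain-body space
#'
#' Builds the convex hull of a set of specimens in
#' (log10 body mass, log10 brain mass) space — the classical device for
#' delimiting class-level grades of encephalization (the mammal, bird and
#' reptile polygons). Vertices are returned counter-clockwise, starting at
#' the lexicographically smallest vertex; collinear interior vertices are
#' removed so the ring is strictly convex, and duplicated input points do
#' not affect the result.
#'
#' @param P body masses in grams (positive), or already-log10 values when
#'   `log10_input = TRUE`.
#' @param E brain masses/volumes in g or ml (positive), or log10 values.
#' @param label free-text polygon label (e.g. `"mammals"`).
#' @param log10_input set to `TRUE` when `P` and `E` are already log10
#'   coordinates.
#' @return an object of class `"convex_polygon"`: a list with `vertices`
#'   (matrix with columns `log10_P`, `log10_E`) and `label`.
#' @export
#' @examples
#' poly <- convex_polygon(c(10, 1000, 100), c(1, 1, 10), label = "demo")
#' poly$vertices
convex_polygon <- function(P, E, label = "", log10_input = FALSE) {
  if (length(P) != length(E)) stop("P and E lengths differ", call. = FALSE)
  keep <- !is.na(P) & !is.na(E)
  P <- P[keep]; E <- E[keep]
  if (!log10_input) {
    if (any(P <= 0) || any(E <= 0)) {
      stop("P and E must be positive", call. = FALSE)
    }
    x <- log10(P); y <- log10(E)
  } else {
    x <- P; y <- E
  }
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) stop("need at least 3 distinct points", call. = FALSE)
  idx <- grDevices::chull(pts[, 1], pts[, 2]) # clockwise order
  v <- pts[rev(idx), , drop = FALSE]          # counter-clockwise
  v <- drop_collinear(v)
  if (nrow(v) < 3) stop("degenerate geometry: all points collinear", call. = FALSE)
  v <- canonical_ring(v)
  colnames(v) <- c("log10_P", "log10_E")
  rownames(v) <- NULL
  structure(list(vertices = v, label = label), class = "convex_polygon")
}

# remove vertices collinear with their ring neighbours
drop_collinear <- function(v, eps = 1e-12) {
  repeat {
    n <- nrow(v)
    if (n < 3) return(v)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      a <- v[if (i == 1) n else i - 1, ]
      b <- v[i, ]
      c <- v[if (i == n) 1 else i + 1, ]
      cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (abs(cr) <= eps) keep[i] <- FALSE
    }
    if (all(keep)) return(v)
    v <- v[keep, , drop = FALSE]
  }
}

# rotate ring to start at the lexicographic minimum (min x, ties by min y)
canonical_ring <- function(v) {
  start <- order(v[, 1], v[, 2])[1]
  if (start > 1) v <- rbind(v[start:nrow(v), , drop = FALSE],
                            v[seq_len(start - 1), , drop = FALSE])
  v
}

#' @export
print.convex_polygon <- function(x, digits = 4, ...) {
  cat(sprintf("Convex polygon%s: %d vertices in (log10 P, log10 E)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$vertices)))
  print(round(x$vertices, digits))
  cat(sprintf("  area = %.4f (log10 units^2)\n", polygon_area(x)))
  invisible(x)
}

#' @export
plot.convex_polygon <- function(x, add = FALSE, ...) {
  v <- rbind(x$vertices, x$vertices[1, , drop = FALSE])
  if (!add) {
    graphics::plot(v, type = "l", xlab = "log10 body mass (g)",
                   ylab = "log10 brain mass (g)", main = x$label, ...)
  } else {
    graphics::lines(v, ...)
  }
  invisible(x)
}

#' Area of a convex polygon
#'
#' Shoelace area in squared log10 units; invariant under permutation and
#' duplication of the generating points.
#'
#' @param polygon a `"convex_polygon"`.
#' @return the enclosed area.
#' @export
polygon_area <- function(polygon) {
  v <- polygon$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# upper/lower boundary chain value of a CCW convex ring at abscissa x:
# max/min over edges spanning x of the edge's line evaluated at x
chain_y <- function(v, x, which = c("upper", "lower")) {
  which <- match.arg(which)
  n <- nrow(v)
  j <- c(2:n, 1)
  ys <- c()
  for (k in seq_len(n)) {
    x1 <- v[k, 1]; x2 <- v[j[k], 1]
    if ((x >= min(x1, x2)) && (x <= max(x1, x2))) {
      if (x1 == x2) {
        ys <- c(ys, v[k, 2], v[j[k], 2])
      } else {
        t <- (x - x1) / (x2 - x1)
        ys <- c(ys, v[k, 2] + t * (v[j[k], 2] - v[k, 2]))
      }
    }
  }
  if (which == "upper") max(ys) else min(ys)
}

#' Classify a specimen against a brain-body polygon
#'
#' Places a point, given in natural units, relative to a polygon in log10
#' space: `"inside"` or `"on_boundary"` by convex containment; otherwise
#' `"above"`/`"below"` when its log10 body mass falls within the
#' polygon's horizontal extent (log10 brain mass greater than the upper
#' or smaller than the lower boundary chain at that abscissa); otherwise
#' `"outside_range"`.
#'
#' @param P body mass, g.
#' @param E brain mass/volume, g or ml.
#' @param polygon a `"convex_polygon"`.
#' @param eps numeric tolerance for boundary membership.
#' @return one of `"inside"`, `"on_boundary"`, `"above"`, `"below"`,
#'   `"outside_range"`.
#' @export
#' @examples
#' poly <- convex_polygon(c(10, 1000, 100), c(1, 1, 10))
#' classify_point(100, 3, poly)
classify_point <- function(P, E, polygon, eps = 1e-9) {
  stopifnot(inherits(polygon, "convex_polygon"), P > 0, E > 0)
  p <- c(log10(P), log10(E))
  v <- polygon$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  cross <- (v[j, 1] - v[, 1]) * (p[2] - v[, 2]) -
    (v[j, 2] - v[, 2]) * (p[1] - v[, 1])
  scale <- sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2)
  d <- cross / scale # signed distance to each edge line (CCW: inside > 0)
  if (all(d > eps)) return("inside")
  if (all(d > -eps)) {
    # on an edge line: boundary only if within that edge's span
    on <- which(abs(d) <= eps)
    for (k in on) {
      within <- p[1] >= min(v[k, 1], v[j[k], 1]) - eps &&
        p[1] <= max(v[k, 1], v[j[k], 1]) + eps &&
        p[2] >= min(v[k, 2], v[j[k], 2]) - eps &&
        p[2] <= max(v[k, 2], v[j[k], 2]) + eps
      if (within) return("on_boundary")
    }
  }
  xr <- range(v[, 1])
  if (p[1] < xr[1] - eps || p[1] > xr[2] + eps) return("outside_range")
  if (p[2] > chain_y(v, p[1], "upper")) return("above")
  if (p[2] < chain_y(v, p[1], "lower")) return("below")
  "on_boundary"
}

#' Extend a polygon to larger body sizes along an allometric slope
#'
#' Reproduces the classical construction used to project a class-level
#' polygon (e.g. the extant-reptile polygon) out to dinosaur-grade body
#' sizes: the upper boundary is continued from the rightmost upper vertex
#' at the given slope out to `new_max_log10P`, and a parallel lower
#' boundary is drawn through the vertex of minimum log10 brain mass; the
#' result is re-convexified and always contains the original polygon.
#'
#' @param polygon a `"convex_polygon"`.
#' @param new_max_log10P target maximum log10 body mass; must not be less
#'   than the polygon's current maximum.
#' @param slope slope of the extension; default is the slope of the last
#'   (rightmost) upper-hull edge. Pass `2/3` for the theoretical
#'   geometric-scaling slope.
#' @return the extended `"convex_polygon"`.
#' @export
extend_polygon <- function(polygon, new_max_log10P, slope = NULL) {
  v <- polygon$vertices
  xmax <- max(v[, 1])
  if (new_max_log10P < xmax) {
    stop("new_max_log10P must not be less than the current maximum log10 P",
         call. = FALSE)
  }
  right <- which.max(v[, 1] + 1e-12 * v[, 2]) # rightmost, ties to upper
  if (is.null(slope)) {
    # last upper-hull edge: CCW ring means the edge *into* the rightmost
    # vertex from its predecessor belongs to the lower chain and the edge
    # out of it to the upper chain; the upper chain runs right-to-left
    nxt <- if (right == nrow(v)) 1 else right + 1
    slope <- (v[nxt, 2] - v[right, 2]) / (v[nxt, 1] - v[right, 1])
  }
  lowest <- which.min(v[, 2])
  new_upper <- c(new_max_log10P, v[right, 2] + slope * (new_max_log10P - v[right, 1]))
  new_lower <- c(new_max_log10P, v[lowest, 2] + slope * (new_max_log10P - v[lowest, 1]))
  allv <- rbind(v, new_upper, new_lower)
  out <- convex_polygon(allv[, 1], allv[, 2],
                        label = if (nzchar(polygon$label))
                          paste0(polygon$label, "-extended") else "extended",
                        log10_input = TRUE)
  out
}
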