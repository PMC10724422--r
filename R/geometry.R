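## Convex-polygon geometry for cell classification.
## Cells and stimulation regions are convex polygons in continuous image
## coordinates (micrometres). Overlap areas come from Sutherland-Hodgman
## clipping; adjacency from the minimum boundary distance.

poly_orient_ccw <- function(p) {
  n <- nrow(p)
  s <- sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])
  if (s < 0) p[n:1, , drop = FALSE] else p
}

poly_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
}

# clip subject polygon by one half-plane (inside = left of a->b)
clip_halfplane <- function(subj, a, b) {
  if (nrow(subj) == 0) return(subj)
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  side <- function(p) dx * (p[2] - a[2]) - dy * (p[1] - a[1])
  out <- matrix(numeric(0), ncol = 2)
  n <- nrow(subj)
  for (i in seq_len(n)) {
    cur <- subj[i, ]; prv <- subj[if (i == 1) n else i - 1, ]
    sc <- side(cur); sp <- side(prv)
    if (sc >= 0) {
      if (sp < 0) {
        t <- sp / (sp - sc)
        out <- rbind(out, prv + t * (cur - prv))
      }
      out <- rbind(out, cur)
    } else if (sp >= 0) {
      t <- sp / (sp - sc)
      out <- rbind(out, prv + t * (cur - prv))
    }
  }
  out
}

poly_intersection_area <- function(p, q) {
  p <- poly_orient_ccw(p); q <- poly_orient_ccw(q)
  subj <- p
  n <- nrow(q)
  for (i in seq_len(n)) {
    subj <- clip_halfplane(subj, q[i, ], q[if (i == n) 1 else i + 1, ])
    if (nrow(subj) < 3) return(0)
  }
  poly_area(subj)
}

point_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab * ab), .Machine$double.eps)
  t <- min(1, max(0, t))
  sqrt(sum((a + t * ab - p)^2))
}

seg_seg_dist <- function(a1, a2, b1, b2) {
  # segments intersect?
  d1 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
  d2 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
  d3 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
  d4 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(0)
  }
  min(point_seg_dist(a1, b1, b2), point_seg_dist(a2, b1, b2),
      point_seg_dist(b1, a1, a2), point_seg_dist(b2, a1, a2))
}

point_in_convex <- function(p, poly) {
  poly <- poly_orient_ccw(poly)
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    if ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) < 0) {
      return(FALSE)
    }
  }
  TRUE
}

poly_distance <- function(p, q) {
  if (poly_intersection_area(p, q) > 0 ||
      point_in_convex(p[1, ], q) || point_in_convex(q[1, ], p)) {
    return(0)
  }
  np <- nrow(p); nq <- nrow(q)
  best <- Inf
  for (i in seq_len(np)) {
    a1 <- p[i, ]; a2 <- p[if (i == np) 1 else i + 1, ]
    for (j in seq_len(nq)) {
      b1 <- q[j, ]; b2 <- q[if (j == nq) 1 else j + 1, ]
      best <- min(best, seg_seg_dist(a1, a2, b1, b2))
    }
  }
  best
}

#' An axis-aligned rectangle as a convex polygon
#'
#' @param x0,y0 lower-left corner (um).
#' @param width,height side lengths (um).
#' @return 4 x 2 vertex matrix (counter-clockwise).
#' @export
rect_polygon <- function(x0, y0, width, height) {
  if (width <= 0 || height <= 0) stop("rectangle sides must be positive")
  matrix(c(x0, y0,
           x0 + width, y0,
           x0 + width, y0 + height,
           x0, y0 + height), ncol = 2, byrow = TRUE)
}

#' Cell layout: cell outlines plus stimulation regions
#'
#' @param cells named list of convex polygons (n x 2 vertex matrices, um);
#'   names are the cell ids.
#' @param stim_regions list of convex polygons (the photostimulated
#'   rectangles); may be empty.
#' @param adjacency_eps two cells are adjacent when their boundary distance
#'   is at most this (um; default 0.5).
#' @return An object of class `ca_layout`.
#' @export
cell_layout <- function(cells, stim_regions = list(), adjacency_eps = 0.5) {
  if (is.null(names(cells)) || any(names(cells) == "")) {
    names(cells) <- paste0("cell_", seq_along(cells))
  }
  for (id in names(cells)) {
    p <- cells[[id]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop("cell ", id, " is not an n x 2 vertex matrix")
    }
    if (poly_area(p) <= 0) stop("cell ", id, " has zero area")
  }
  structure(list(cells = cells, stim_regions = stim_regions,
                 adjacency_eps = adjacency_eps),
            class = "ca_layout")
}

#' Classify cells as target / neighbor / other
#'
#' A cell is a *target* when its outline overlaps a stimulation region with
#' positive area; a *neighbor* when it is not a target but lies within the
#' adjacency distance of at least one target; every remaining cell is
#' *other*. With no stimulation region every cell is "other". The three
#' labels partition the layout.
#'
#' @param layout a [cell_layout()].
#' @return named character vector (one of `"target"`, `"neighbor"`,
#'   `"other"` per cell, names = cell ids).
#' @export
classify_cells <- function(layout) {
  stopifnot(inherits(layout, "ca_layout"))
  ids <- names(layout$cells)
  is_target <- vapply(layout$cells, function(p) {
    any(vapply(layout$stim_regions,
               function(s) poly_intersection_area(p, s) > 1e-12, logical(1)))
  }, logical(1))
  labels <- rep("other", length(ids))
  labels[is_target] <- "target"
  tgt <- which(is_target)
  if (length(tgt) > 0) {
    for (i in which(!is_target)) {
      d <- vapply(tgt, function(j) {
        poly_distance(layout$cells[[i]], layout$cells[[j]])
      }, numeric(1))
      if (any(d <= layout$adjacency_eps)) labels[i] <- "neighbor"
    }
  }
  stats::setNames(labels, ids)
}
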