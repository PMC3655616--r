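# Planar topographic interpolation on the epidural electrode montage.
# Barycentric linear interpolation on a Delaunay triangulation is the
# default (bounded between electrode extremes, exact at the nodes); a
# thin-plate spline is available for a smoother surface. Both are solved
# directly here — 12-14 nodes need no external geometry machinery.

# --- Bowyer-Watson Delaunay triangulation (small point sets) ---------------

circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)                 # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)             # centre, radius^2
}

delaunay <- function(pts) {
  n <- nrow(pts)
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  mid <- colMeans(pts[, 1:2])
  big <- rbind(mid + c(0, 20 * span), mid + c(-20 * span, -20 * span),
               mid + c(20 * span, -20 * span))
  all_pts <- rbind(as.matrix(pts[, 1:2]), big)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  for (i in seq_len(n)) {
    p <- all_pts[i, ]
    bad <- vapply(tris, function(tr) {
      cc <- circumcircle(all_pts[tr[1], ], all_pts[tr[2], ], all_pts[tr[3], ])
      !is.null(cc) && (p[1] - cc[1])^2 + (p[2] - cc[2])^2 < cc[3] - 1e-12
    }, logical(1))
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))
    }))
    tris <- tris[!bad]
    if (!is.null(edges)) {
      key <- paste(edges[, 1], edges[, 2])
      boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
      for (e in seq_len(nrow(boundary))) {
        tris[[length(tris) + 1]] <- c(boundary[e, ], i)
      }
    }
  }
  keep <- vapply(tris, function(tr) all(tr <= n), logical(1))
  do.call(rbind, tris[keep])
}

barycentric <- function(p, a, b, c_) {
  d <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
  l1 <- ((b[2] - c_[2]) * (p[, 1] - c_[1]) + (c_[1] - b[1]) * (p[, 2] - c_[2])) / d
  l2 <- ((c_[2] - a[2]) * (p[, 1] - c_[1]) + (a[1] - c_[1]) * (p[, 2] - c_[2])) / d
  cbind(l1, l2, 1 - l1 - l2)
}

#' Topographic interpolation of per-electrode values
#'
#' Interpolates one value per electrode over a regular grid covering the
#' montage, exactly reproducing the electrode values at their positions. No
#' extrapolation: grid points outside the convex hull of the electrodes are
#' masked (`NA`). The default scheme is barycentric linear interpolation on
#' a Delaunay triangulation of the electrode positions, which keeps the map
#' bounded between the electrode extremes; `method = "tps"` fits a
#' thin-plate spline instead.
#'
#' @param values Named numeric vector (names = electrode labels) or a tibble
#'   with columns `label` and `value`.
#' @param montage Montage tibble (see [rat_montage()]); only rows with
#'   `scalp = TRUE` and a matching value are used. At least 3 non-collinear
#'   electrodes are required.
#' @param resolution Grid points per axis (default 64).
#' @param method `"barycentric"` (default) or `"tps"`.
#' @param significant Optional character vector of electrode labels to mark
#'   as significant in plots.
#' @return An `eegbico_topomap`: list with `grid` (tibble `x`, `y`,
#'   `value`), `electrodes` (tibble `label`, `x`, `y`, `value`,
#'   `significant`), `method`.
#' @export
#' @examples
#' m <- rat_montage()
#' v <- setNames(rnorm(12), m$label[m$scalp])
#' tm <- interpolate_map(v, m)
interpolate_map <- function(values, montage = rat_montage(), resolution = 64,
                            method = c("barycentric", "tps"),
                            significant = character()) {
  method <- match.arg(method)
  if (is.data.frame(values)) values <- setNames(values$value, values$label)
  m <- montage[montage$scalp & montage$label %in% names(values), ]
  assert_that(nrow(m) >= 3, "need values on at least 3 scalp electrodes")
  px <- m$lateral_mm; py <- m$anterior_mm
  v <- unname(values[m$label])
  rx <- range(px); ry <- range(py)
  assert_that(diff(rx) > 0 && diff(ry) > 0, "electrodes are collinear")
  gx <- seq(rx[1], rx[2], length.out = resolution)
  gy <- seq(ry[1], ry[2], length.out = resolution)
  g <- expand.grid(x = gx, y = gy)
  z <- rep(NA_real_, nrow(g))
  if (method == "barycentric") {
    tris <- delaunay(cbind(px, py))
    for (t_i in seq_len(nrow(tris))) {
      tr <- tris[t_i, ]
      lam <- barycentric(as.matrix(g), c(px[tr[1]], py[tr[1]]),
                         c(px[tr[2]], py[tr[2]]), c(px[tr[3]], py[tr[3]]))
      inside <- rowSums(lam >= -1e-9) == 3
      z[inside] <- lam[inside, , drop = FALSE] %*% v[tr]
    }
  } else {
    z_all <- tps_eval(px, py, v, g$x, g$y)
    hull <- grDevices::chull(px, py)
    inside <- in_polygon(g$x, g$y, px[hull], py[hull])
    z[inside] <- z_all[inside]
  }
  structure(
    list(grid = as_tibble(cbind(g, value = z)),
         electrodes = tibble(label = m$label, x = px, y = py, value = v,
                             significant = m$label %in% significant),
         method = method),
    class = "eegbico_topomap"
  )
}

# thin-plate spline with affine part, solved directly
tps_eval <- function(px, py, v, qx, qy) {
  n <- length(px)
  rbf <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  K <- outer(seq_len(n), seq_len(n), function(i, j) {
    rbf((px[i] - px[j])^2 + (py[i] - py[j])^2)
  })
  P <- cbind(1, px, py)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  w <- solve(A, c(v, 0, 0, 0))
  Kq <- outer(seq_along(qx), seq_len(n), function(q, j) {
    rbf((qx[q] - px[j])^2 + (qy[q] - py[j])^2)
  })
  as.vector(Kq %*% w[1:n] + cbind(1, qx, qy) %*% w[(n + 1):(n + 3)])
}

# ray-casting point-in-polygon (closed hull, boundary counted inside)
in_polygon <- function(qx, qy, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(qx))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > qy) != (py[j] > qy)) &
      (qx < (px[j] - px[i]) * (qy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  # include boundary points within tolerance of an edge
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- px[j] - px[i]; ey <- py[j] - py[i]
    len2 <- ex^2 + ey^2
    t_ <- pmin(pmax(((qx - px[i]) * ex + (qy - py[i]) * ey) / len2, 0), 1)
    d2 <- (qx - (px[i] + t_ * ex))^2 + (qy - (py[i] + t_ * ey))^2
    inside <- inside | d2 < 1e-9
  }
  inside
}

#' @export
print.eegbico_topomap <- function(x, ...) {
  cat(sprintf("<eegbico_topomap> %s interpolation, %d electrodes, %d grid points (%d inside hull)\n",
              x$method, nrow(x$electrodes), nrow(x$grid), sum(!is.na(x$grid$value))))
  invisible(x)
}

#' @method tidy eegbico_topomap
#' @export
tidy.eegbico_topomap <- function(x, ...) x$grid

#' @method autoplot eegbico_topomap
#' @export
autoplot.eegbico_topomap <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value), na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(na.value = "transparent") +
    ggplot2::geom_point(data = object$electrodes,
                        ggplot2::aes(shape = .data$significant), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Lateral (mm)", y = "Anterior (mm)", fill = "Value") +
    ggplot2::theme_minimal()
}
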