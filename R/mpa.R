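# Minimal projection area: the smallest area, over all viewing directions,
# of the molecule's projected van der Waals silhouette.

# Raster area of a union of discs: centers (x, y), radii r, grid spacing dx.
.disc_union_area <- function(x, y, r, dx = 0.1) {
  xmin <- min(x - r) - dx; xmax <- max(x + r) + dx
  ymin <- min(y - r) - dx; ymax <- max(y + r) + dx
  nx <- ceiling((xmax - xmin) / dx)
  ny <- ceiling((ymax - ymin) / dx)
  gx <- xmin + (seq_len(nx) - 0.5) * dx
  gy <- ymin + (seq_len(ny) - 0.5) * dx
  covered <- logical(nx * ny)
  for (a in seq_along(x)) {
    ix <- which(abs(gx - x[a]) <= r[a])
    iy <- which(abs(gy - y[a]) <= r[a])
    if (length(ix) == 0L || length(iy) == 0L) next
    dx2 <- (gx[ix] - x[a])^2
    dy2 <- (gy[iy] - y[a])^2
    inside <- outer(dx2, dy2, `+`) <= r[a]^2
    cells <- as.vector(outer(ix, (iy - 1L) * nx, `+`))[as.vector(inside)]
    covered[cells] <- TRUE
  }
  sum(covered) * dx * dx
}

# Projected silhouette area along viewing direction u (unit vector).
.projection_area <- function(coords, radius, u, dx = 0.1) {
  # orthonormal basis perpendicular to u
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  .disc_union_area(coords %*% e1, coords %*% e2, radius, dx)
}

.sph_dir <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Minimal projection area of a conformer
#'
#' Minimizes the area of the projected van der Waals silhouette over viewing
#' directions. Projection areas are computed on a 2D raster (grid spacing
#' `dx`, default 0.1 Angstrom); the orientation search is a coarse grid over
#' the unit hemisphere (`coarse_deg` spacing, default 10 degrees) followed by
#' local grid refinement (halving the spacing `refine_levels` times around
#' the best direction).
#'
#' @param conf A `conformer3d` (or anything with `coords` and `radius`).
#' @param dx Raster spacing in Angstroms.
#' @param coarse_deg Coarse orientation grid spacing in degrees.
#' @param refine_levels Number of local refinement levels.
#' @return Minimal projection area in square Angstroms.
#' @examples
#' atom <- list(coords = matrix(0, 1, 3), radius = 1.7)
#' compute_mpa(atom)  # ~ pi * 1.7^2
#' @export
compute_mpa <- function(conf, dx = 0.1, coarse_deg = 10, refine_levels = 2) {
  coords <- conf$coords
  radius <- conf$radius
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            length(radius) == nrow(coords), all(radius > 0))
  step <- coarse_deg * pi / 180
  thetas <- seq(0, pi / 2, by = step)
  best_area <- Inf
  best_dir <- c(0, 0)
  for (th in thetas) {
    phis <- if (th < 1e-9) 0 else seq(0, 2 * pi - step, by = step)
    for (ph in phis) {
      a <- .projection_area(coords, radius, .sph_dir(th, ph), dx)
      if (a < best_area) {
        best_area <- a
        best_dir <- c(th, ph)
      }
    }
  }
  for (lev in seq_len(refine_levels)) {
    step <- step / 2
    th0 <- best_dir[1]; ph0 <- best_dir[2]
    for (dth in c(-step, 0, step)) {
      for (dph in c(-step, 0, step)) {
        if (dth == 0 && dph == 0) next
        a <- .projection_area(coords, radius,
                              .sph_dir(th0 + dth, ph0 + dph), dx)
        if (a < best_area) {
          best_area <- a
          best_dir <- c(th0 + dth, ph0 + dph)
        }
      }
    }
  }
  best_area
}
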