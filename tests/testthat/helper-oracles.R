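# Independent oracles used across the suite.  These deliberately do not call
# the package's production code paths.

# --- exhaustive ray/triangle scan -------------------------------------------
# Moller-Trumbore over every valid face, same numeric tolerances as the
# production caster (parallel cutoff 1e-14, barycentric slack 1e-12, tie band
# 1e-12 with lower face index winning), but as a vectorised all-faces scan.
brute_force_first_hit <- function(mesh, origin, dir, t_min = 1e-6) {
  keep <- which(mesh$valid)
  f <- mesh$faces[keep, , drop = FALSE]
  A <- mesh$vertices[f[, 1], , drop = FALSE]
  e1 <- mesh$vertices[f[, 2], , drop = FALSE] - A
  e2 <- mesh$vertices[f[, 3], , drop = FALSE] - A
  cross_rows <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  dmat <- matrix(dir, nrow(f), 3L, byrow = TRUE)
  p <- cross_rows(dmat, e2)
  det <- rowSums(e1 * p)
  tvec <- sweep(-A, 2L, origin, `+`)
  u <- rowSums(tvec * p) / det
  q <- cross_rows(tvec, e1)
  v <- rowSums(dmat * q) / det
  t <- rowSums(e2 * q) / det
  ok <- abs(det) >= 1e-14 & u >= -1e-12 & u <= 1 + 1e-12 &
    v >= -1e-12 & u + v <= 1 + 1e-12 & t > t_min
  if (!any(ok, na.rm = TRUE)) return(NULL)
  idx <- which(ok)
  tmin_val <- min(t[idx])
  tied <- idx[t[idx] < tmin_val + 1e-12]
  best <- min(tied)  # lowest face index among ties
  list(face = keep[best], t = t[best])
}

# --- linear-interpolation quantiles -----------------------------------------
quantile_linear_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, 0)
}

# --- union-find duplicate grouping (O(n^2)) ---------------------------------
union_find_groups <- function(df, radius) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (df$label[i] != df$label[j]) next
    if (df$source_image[i] == df$source_image[j]) next
    d <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2 +
                (df$z[i] - df$z[j])^2)
    if (d <= radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  split(df$annotation_id, roots)
}

# --- even-odd point-in-polygon and grid overlap estimate --------------------
points_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# intersection area over area(a), by counting grid samples over bbox(a)
grid_overlap_frac_oracle <- function(a, b, n_grid = 500) {
  xs <- seq(min(a[, 1]), max(a[, 1]), length.out = n_grid)
  ys <- seq(min(a[, 2]), max(a[, 2]), length.out = n_grid)
  px <- rep(xs, times = n_grid)
  py <- rep(ys, each = n_grid)
  ina <- points_in_poly(px, py, a)
  inb <- points_in_poly(px, py, b)
  sum(ina & inb) / sum(ina)
}

# --- independent geodesy: ENU -> ECEF -> geodetic (Vermeille 2002) ----------
oracle_geodetic_to_ecef <- function(lat_deg, lon_deg, h) {
  a <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  phi <- lat_deg * pi / 180; lam <- lon_deg * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  c((N + h) * cos(phi) * cos(lam), (N + h) * cos(phi) * sin(lam),
    (N * (1 - e2) + h) * sin(phi))
}

oracle_enu_to_ecef <- function(p, lat0, lon0, h0) {
  phi <- lat0 * pi / 180; lam <- lon0 * pi / 180
  x0 <- oracle_geodetic_to_ecef(lat0, lon0, h0)
  e_hat <- c(-sin(lam), cos(lam), 0)
  n_hat <- c(-sin(phi) * cos(lam), -sin(phi) * sin(lam), cos(phi))
  u_hat <- c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  x0 + p[1] * e_hat + p[2] * n_hat + p[3] * u_hat
}

# closed-form algebraic ECEF -> geodetic (no iteration)
oracle_ecef_to_geodetic <- function(xyz) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); e4 <- e2^2
  x <- xyz[1]; y <- xyz[2]; z <- xyz[3]
  p <- (x^2 + y^2) / a^2
  q <- (1 - e2) * z^2 / a^2
  r <- (p + q - e4) / 6
  s <- e4 * p * q / (4 * r^3)
  t <- (1 + s + sqrt(s * (2 + s)))^(1 / 3)
  u <- r * (1 + t + 1 / t)
  v <- sqrt(u^2 + e4 * q)
  w <- e2 * (u + v - q) / (2 * v)
  k <- sqrt(u + v + w^2) - w
  D <- k * sqrt(x^2 + y^2) / (k + e2)
  lat <- 2 * atan2(z, D + sqrt(D^2 + z^2))
  h <- (k + e2 - 1) / k * sqrt(D^2 + z^2)
  c(lat = lat * 180 / pi, lon = atan2(y, x) * 180 / pi, h = h)
}

oracle_enu_to_geodetic <- function(p, lat0, lon0, h0) {
  oracle_ecef_to_geodetic(oracle_enu_to_ecef(p, lat0, lon0, h0))
}
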