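# shared fixtures and independent oracles, built in code at test time

square_geom <- function(x0, y0, side) {
  polygon_geometry(rbind(c(x0, y0), c(x0 + side, y0),
                         c(x0 + side, y0 + side), c(x0, y0 + side)))
}

rect_geom <- function(x0, y0, x1, y1) {
  polygon_geometry(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

circle_geom <- function(cx, cy, r, n = 256L) {
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  polygon_geometry(cbind(cx + r * cos(ang), cy + r * sin(ang)))
}

# random simple star polygon (sorted angles), uses the caller's RNG stream
rand_star_geom <- function(n = 12L, cx = runif(1, 25, 40),
                           cy = runif(1, 25, 40), r = runif(1, 2, 18),
                           spread = c(0.5, 1.5)) {
  ang <- sort(runif(n, 0, 2 * pi))
  while (any(diff(ang) < 1e-9)) ang <- sort(runif(n, 0, 2 * pi))
  rad <- r * runif(n, spread[1L], spread[2L])
  polygon_geometry(cbind(cx + rad * cos(ang), cy + rad * sin(ang)))
}

# independent point-membership oracle: per-point crossing count, vectorized
# over points (no span extraction, unlike the package's scan conversion)
pip_vec <- function(px, py, geom, eps = 1e-9) {
  px <- px + eps; py <- py + eps
  inside <- rep(FALSE, length(px))
  for (poly in geom) {
    cr <- integer(length(px))
    for (ring in poly) {
      n <- nrow(ring)
      for (e in seq_len(n)) {
        j <- if (e == n) 1L else e + 1L
        x1 <- ring[e, 1L]; y1 <- ring[e, 2L]
        x2 <- ring[j, 1L]; y2 <- ring[j, 2L]
        hit <- (y1 <= py) != (y2 <= py)
        if (any(hit)) {
          xi <- x1 + (py[hit] - y1) * (x2 - x1) / (y2 - y1)
          cr[hit] <- cr[hit] + (xi > px[hit])
        }
      }
    }
    inside <- inside | (cr %% 2L == 1L)
  }
  inside
}

# brute-force rasterization oracle: evaluate the point rule at every pixel
brute_burn <- function(geom, nr, nc, strategy = "center") {
  off <- if (strategy == "center") 0.5 else 0
  cc <- rep(0:(nc - 1L), each = nr)
  rr <- rep(0:(nr - 1L), times = nc)
  matrix(pip_vec(cc + off, rr + off, geom), nr, nc)
}

# Monte-Carlo IoU oracle with a delta-method standard error
mc_iou <- function(polygon, mask, n = 1e6) {
  fg <- mask$grid > 0L
  bb <- geom_bbox(polygon)
  cells <- which(fg, arr.ind = TRUE)
  xmin <- min(bb[["xmin"]], min(cells[, 2L]) - 1)
  xmax <- max(bb[["xmax"]], max(cells[, 2L]))
  ymin <- min(bb[["ymin"]], min(cells[, 1L]) - 1)
  ymax <- max(bb[["ymax"]], max(cells[, 1L]))
  px <- runif(n, xmin, xmax); py <- runif(n, ymin, ymax)
  in_p <- pip_vec(px, py, polygon)
  col <- floor(px) + 1L; row <- floor(py) + 1L
  okc <- col >= 1L & col <= ncol(fg) & row >= 1L & row <= nrow(fg)
  in_r <- rep(FALSE, n)
  in_r[okc] <- fg[cbind(row[okc], col[okc])]
  I <- mean(in_p & in_r); U <- mean(in_p | in_r)
  iou <- I / U
  var_i <- I * (1 - I) / n
  var_u <- U * (1 - U) / n
  cov_iu <- I * (1 - U) / n             # intersection is a subset of union
  se <- sqrt(max(var_i / U^2 + I^2 * var_u / U^4 - 2 * I * cov_iu / U^3, 0))
  list(iou = iou, se = se)
}

# random multi-label blob mask (labels 0..3) for roundtrip properties
rand_blob_mask <- function(nr = sample(8:64, 1), nc = sample(8:64, 1)) {
  g <- matrix(0L, nr, nc)
  for (b in seq_len(sample(3:8, 1))) {
    lab <- sample(1:3, 1)
    r0 <- sample(seq_len(nr), 1); c0 <- sample(seq_len(nc), 1)
    g[r0:min(nr, r0 + sample(0:10, 1)), c0:min(nc, c0 + sample(0:10, 1))] <- lab
  }
  salt <- sample(length(g), length(g) %/% 10)
  g[salt] <- sample(0:3, length(salt), replace = TRUE)
  tile_mask(g, tile_spec(0, 0, nc, nr), label_map(c("a", "b", "c")))
}
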