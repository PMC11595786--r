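#' Generate the synthetic star-polygon dataset
#'
#' Emulates an artificial annotation benchmark: each polygon's vertices are
#' sampled at random angles around a fixed center, and the mean vertex
#' radius grows linearly across the dataset from `r_min` to `r_max`, so the
#' collection spans near-subpixel blobs up to many-pixel shapes with rough
#' outlines. Angles are sorted strictly increasing, which guarantees every
#' polygon is simple and valid; vertices are rounded to 1e-6 px so
#' regeneration is bit-identical across platforms for a fixed seed.
#'
#' @param n_polygons number of polygons (default 55).
#' @param n_points vertices per polygon (default 24, must be >= 3).
#' @param center fixed center `(x, y)` shared by all polygons.
#' @param r_min,r_max mean vertex radius of the first / last polygon, px.
#' @param jitter roughness in `[0, 1)`: vertex radii are drawn uniformly in
#'   `[(1 - jitter), (1 + jitter)] * r` and rescaled so their sample mean is
#'   exactly `r` (the dataset's mean radius is then strictly increasing by
#'   construction), and each vertex angle
#'   is perturbed from its evenly spaced position by up to
#'   `jitter * pi / n_points` (plus a random rotation of the whole
#'   polygon). `jitter = 0` gives exactly a regular `n_points`-gon of
#'   radius `r`, with area `n/2 * r^2 * sin(2*pi/n)`.
#' @param class_name class assigned to every polygon.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return Annotation tibble with `n_polygons` rows, mean vertex radius
#'   non-decreasing down the table.
#' @export
generate_star_polygons <- function(n_polygons = 55L, n_points = 24L,
                                   center = c(100, 100),
                                   r_min = 3, r_max = 60, jitter = 0.3,
                                   class_name = "Star", seed = 1L) {
  if (n_points < 3L) stop("a polygon needs at least 3 points", call. = FALSE)
  stopifnot(n_polygons >= 1L, r_min > 0, r_max >= r_min, jitter >= 0, jitter < 1)
  radii <- if (n_polygons == 1L) r_min else
    seq(r_min, r_max, length.out = n_polygons)
  geoms <- with_seed(seed, lapply(seq_len(n_polygons), function(i) {
    base <- 2 * pi * (seq_len(n_points) - 1L) / n_points
    ang <- stats::runif(1, 0, 2 * pi) + base +
      stats::runif(n_points, -jitter, jitter) * pi / n_points
    rad <- stats::runif(n_points, 1 - jitter, 1 + jitter)
    rad <- radii[i] * rad / mean(rad)   # pin the mean radius to the schedule
    shell <- round(cbind(center[1L] + rad * cos(ang),
                         center[2L] + rad * sin(ang)), 6)
    validate_geometry(polygon_geometry(shell))
  }))
  annotations(geoms, class_name = class_name,
              id = sprintf("star_%03d", seq_len(n_polygons)), validate = FALSE)
}

#' Toy shapes for discretization worked examples
#'
#' Four small ground-truth shapes that isolate the subpixel behavior of the
#' pixel-selection strategies:
#'
#' 1. `small_square` — the integer-aligned square `[1,4]^2`, which both
#'    strategies discretize exactly (IoU 1, HD 0);
#' 2. `offset_square` — the side-5 square `[0.5,5.5]^2` shifted by half a
#'    pixel in x and y, the canonical worked example: center-strategy
#'    rasterization burns the 5x5 block `[0,5]^2`, giving
#'    IoU = 20.25 / 29.75 = 0.6807 and HD = sqrt(0.5) = 0.7071 at the
#'    mismatched corners;
#' 3. `simple_circle` — a disk centered on a grid point;
#' 4. `offset_circle` — the same disk offset by `offset` in x and y.
#'
#' Circles are polygonized regular `segments`-gons.
#'
#' @param circle_radius disk radius in pixels (default 3).
#' @param circle_center grid-point center of the simple circle.
#' @param offset subpixel offset of the offset circle (default 0.5).
#' @param segments polygonization segment count for the circles.
#' @return Annotation tibble with ids naming the four shapes.
#' @export
make_toy_shapes <- function(circle_radius = 3, circle_center = c(8, 8),
                            offset = 0.5, segments = 256L) {
  square <- function(x0, y0, side) {
    polygon_geometry(rbind(c(x0, y0), c(x0 + side, y0),
                           c(x0 + side, y0 + side), c(x0, y0 + side)))
  }
  circle <- function(cx, cy, r) {
    ang <- 2 * pi * (seq_len(segments) - 1L) / segments
    polygon_geometry(cbind(cx + r * cos(ang), cy + r * sin(ang)))
  }
  annotations(
    list(square(1, 1, 3),
         square(0.5, 0.5, 5),
         circle(circle_center[1L], circle_center[2L], circle_radius),
         circle(circle_center[1L] + offset, circle_center[2L] + offset,
                circle_radius)),
    class_name = "Toy",
    id = c("small_square", "offset_square", "simple_circle", "offset_circle")
  )
}

#' Synthetic multi-channel image with paired annotations
#'
#' Builds a flat raster suitable as an end-to-end fixture: every class
#' paints intensity `foreground` into its own channel over a `background`
#' level, optionally with seeded Gaussian noise. If `annotations` is
#' omitted, a default set of integer-aligned rectilinear shapes (two
#' classes, one with two disjoint components) is used so that the
#' export-import-merge round trip is exact.
#'
#' @param width,height image extent in pixels.
#' @param ann optional annotation tibble; default rectilinear demo set.
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param background,foreground intensity levels in `[0, 1]`.
#' @param seed RNG seed for the noise.
#' @param dir if non-`NULL`, write `image.png` (channels averaged for > 3)
#'   and `annotations.geojson` into this directory.
#' @return List with `image` (rows x cols x channels array), `annotations`,
#'   and `label_map`.
#' @export
make_synthetic_image <- function(width = 512L, height = 512L, ann = NULL,
                                 noise_sd = 0.02, background = 0.1,
                                 foreground = 0.7, seed = 1L, dir = NULL) {
  stopifnot(width > 0, height > 0)
  if (is.null(ann)) ann <- demo_annotations(width, height)
  lm <- label_map(unique(ann$class_name))
  spec <- tile_spec(0, 0, width, height)
  multi <- rasterize_annotations(ann, spec, lm, strategy = "center",
                                 mode = "multi")
  img <- array(background, dim = c(height, width, length(lm)))
  for (k in seq_along(lm)) {
    ch <- img[, , k]
    ch[multi$channels[[k]] == 1L] <- foreground
    img[, , k] <- ch
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, array(stats::rnorm(length(img), 0, noise_sd),
                                       dim = dim(img)))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out <- pmin(pmax(img, 0), 1)
    if (dim(out)[3L] > 3L) out <- array(rowMeans(out, dims = 2L),
                                        dim = c(height, width))
    if (!is.na(dim(out)[3L] %||% NA) && dim(out)[3L] == 2L)
      out <- abind_channel(out)
    png::writePNG(out, target = file.path(dir, "image.png"))
    write_annotations(ann, file.path(dir, "annotations.geojson"))
  }
  list(image = img, annotations = ann, label_map = lm)
}

# pad a 2-channel image with a zero blue channel for PNG output
abind_channel <- function(img) {
  out <- array(0, dim = c(dim(img)[1:2], 3L))
  out[, , 1:2] <- img
  out
}

# default rectilinear demo annotations: three components, two classes
demo_annotations <- function(width, height) {
  sx <- width / 512; sy <- height / 512
  rect <- function(x0, y0, x1, y1) {
    polygon_geometry(rbind(c(x0 * sx, y0 * sy), c(x1 * sx, y0 * sy),
                           c(x1 * sx, y1 * sy), c(x0 * sx, y1 * sy)))
  }
  lshape <- polygon_geometry(rbind(
    c(300 * sx, 300 * sy), c(460 * sx, 300 * sy), c(460 * sx, 360 * sy),
    c(360 * sx, 360 * sy), c(360 * sx, 460 * sy), c(300 * sx, 460 * sy)))
  annotations(list(rect(40, 40, 200, 160), rect(80, 300, 180, 420), lshape),
              class_name = c("TypeA", "TypeA", "TypeB"),
              id = c("demo_a1", "demo_a2", "demo_b1"))
}

# run code with a local RNG state; restores the caller's state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
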