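make_mask_of <- function(geom, spec, strategy = "center") {
  rasterize_annotations(annotations(list(geom), "A", validate = FALSE),
                        spec, label_map("A"), strategy = strategy)
}

test_that("subpixel IoU reproduces the square worked examples", {
  spec <- tile_spec(0, 0, 8, 8)
  aligned <- square_geom(1, 1, 3)
  expect_equal(iou_subpixel(aligned, make_mask_of(aligned, spec)), 1)

  offset <- square_geom(0.5, 0.5, 5)
  m <- make_mask_of(offset, spec)
  # block [0,5]^2 vs square [0.5,5.5]^2: 4.5^2 / (2*25 - 4.5^2)
  expect_equal(iou_subpixel(offset, m), 20.25 / 29.75, tolerance = 1e-12)
  expect_equal(round(iou_subpixel(offset, m), 4), 0.6807)
  # the corner baseline gives the identical IoU on this rectangle
  mk <- make_mask_of(offset, spec, strategy = "corner")
  expect_equal(iou_subpixel(offset, mk), 20.25 / 29.75, tolerance = 1e-12)
})

test_that("IoU conventions for empty inputs hold", {
  spec <- tile_spec(0, 0, 8, 8)
  empty_mask <- tile_mask(matrix(0L, 8, 8), spec, label_map("A"))
  sq <- square_geom(1, 1, 3)
  expect_equal(iou_subpixel(NULL, empty_mask), 1)
  expect_equal(iou_subpixel(sq, empty_mask), 0)
  far <- make_mask_of(square_geom(5, 5, 2), spec)
  expect_equal(iou_subpixel(square_geom(0, 0, 2), far), 0)
})

test_that("boundary Hausdorff distance reproduces the worked examples", {
  spec <- tile_spec(0, 0, 8, 8)
  offset <- square_geom(0.5, 0.5, 5)
  m <- make_mask_of(offset, spec)
  expect_equal(hausdorff_boundary(offset, m), sqrt(0.5), tolerance = 1e-6)
  expect_equal(round(hausdorff_boundary(offset, m), 4), 0.7071)
  aligned <- square_geom(1, 1, 3)
  expect_equal(hausdorff_boundary(aligned, make_mask_of(aligned, spec)), 0,
               tolerance = 1e-9)
})

test_that("Hausdorff distance of a translated unit square is the corner gap", {
  # unit square [0,1]^2 vs the aligned mask of its (3,4) translate: the
  # largest boundary-to-boundary gap is corner (0,0) to corner (3,4) = 5
  spec <- tile_spec(0, 0, 8, 8)
  m <- make_mask_of(square_geom(3, 4, 1), spec)
  expect_equal(hausdorff_boundary(square_geom(0, 0, 1), m), 5,
               tolerance = 1e-6)
  # one empty side is reported as Inf
  empty_mask <- tile_mask(matrix(0L, 8, 8), spec, label_map("A"))
  expect_equal(hausdorff_boundary(square_geom(0, 0, 1), empty_mask), Inf)
  expect_equal(hausdorff_boundary(NULL, empty_mask), 0)
})

test_that("Hausdorff distance is symmetric and triangle-bounded", {
  withr::local_seed(12)
  spec <- tile_spec(0, 0, 48, 48)
  geoms <- lapply(1:3, function(i) rand_star_geom(cx = 24, cy = 24,
                                                  r = runif(1, 5, 14)))
  masks <- lapply(geoms, make_mask_of, spec = spec)
  hd <- function(a, b) {
    max(annotiler:::directed_hausdorff(a, b, step = 0.01),
        annotiler:::directed_hausdorff(b, a, step = 0.01))
  }
  regions <- lapply(masks, annotiler:::mask_foreground_geometry)
  d12 <- hd(regions[[1]], regions[[2]])
  d21 <- hd(regions[[2]], regions[[1]])
  expect_equal(d12, d21, tolerance = 1e-9)
  d13 <- hd(regions[[1]], regions[[3]])
  d23 <- hd(regions[[2]], regions[[3]])
  expect_lte(d13, d12 + d23 + 1e-9)
})

test_that("exact IoU matches a Monte-Carlo estimate on random pairs", {
  withr::local_seed(88)
  for (k in 1:5) {
    g <- rand_star_geom()
    spec <- tile_spec(0, 0, 64, 64)
    m <- make_mask_of(g, spec)
    exact <- iou_subpixel(g, m)
    mc <- mc_iou(g, m, n = 2e5)
    expect_lt(abs(exact - mc$iou), 3 * mc$se + 1e-4)
  }
})

test_that("center-strategy IoU increases with disk radius", {
  ious <- vapply(c(4, 8, 16, 32), function(r) {
    size <- 2 * r + 6
    disk <- circle_geom(size / 2, size / 2, r)
    iou_subpixel(disk, make_mask_of(disk, tile_spec(0, 0, size, size)))
  }, numeric(1))
  expect_true(all(diff(ious) > 0))
})

test_that("dataset evaluation returns tidy records and summaries", {
  ev <- evaluate_dataset(annotations(square_geom(1, 1, 3), "A", id = "sq"))
  expect_s3_class(ev, "annotiler_eval")
  expect_equal(nrow(ev), 2)                    # both strategies by default
  expect_named(tidy(ev), c("shape_id", "class_name", "strategy", "iou", "hd"))
  g <- glance(ev)
  expect_equal(g$mean_iou, c(1, 1))
  expect_equal(g$sd_iou, c(0, 0))
  expect_equal(g$mean_hd, c(0, 0), tolerance = 1e-9)
  one <- evaluate_dataset(annotations(square_geom(1, 1, 3), "A"),
                          strategies = "center")
  expect_equal(unique(one$strategy), "center")
})

test_that("toy-shape evaluation reproduces the square rows at 4 decimals", {
  ev <- tidy(evaluate_dataset(make_toy_shapes()))
  sq <- ev[ev$shape_id == "small_square", ]
  expect_equal(round(sq$iou, 4), c(1, 1))
  expect_equal(round(sq$hd, 4), c(0, 0))
  off <- ev[ev$shape_id == "offset_square", ]
  expect_equal(round(off$iou, 4), c(0.6807, 0.6807))
  expect_equal(round(off$hd, 4), c(0.7071, 0.7071))
  # circles: center strictly better in both metrics
  for (id in c("simple_circle", "offset_circle")) {
    rows <- ev[ev$shape_id == id, ]
    expect_gt(rows$iou[rows$strategy == "center"],
              rows$iou[rows$strategy == "corner"])
    expect_lt(rows$hd[rows$strategy == "center"],
              rows$hd[rows$strategy == "corner"])
  }
})
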