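test_that("GeoJSON reading handles the QuPath dialect", {
  f <- withr::local_tempfile(fileext = ".geojson")
  doc <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(list(c(0, 0), c(1, 0), c(1, 1),
                                              c(0, 1), c(0, 0)))),
      properties = list(classification = list(name = "Tumor"))
    ))
  )
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$class_name, "Tumor")
  expect_equal(geom_area(ann$geometry[[1]]), 1)
})

test_that("class name falls back to properties.name, then unclassified", {
  f <- withr::local_tempfile(fileext = ".geojson")
  poly <- list(type = "Polygon",
               coordinates = list(list(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0))))
  doc <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", geometry = poly, properties = list(name = "ROI")),
    list(type = "Feature", geometry = poly, properties = NULL)
  ))
  jsonlite::write_json(doc, f, auto_unbox = TRUE, null = "null")
  ann <- read_annotations(f)
  expect_equal(ann$class_name, c("ROI", "unclassified"))
})

test_that("empty FeatureCollection gives an empty annotation table", {
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type": "FeatureCollection", "features": []}', f)
  ann <- read_annotations(f)
  expect_s3_class(ann, "tbl_df")
  expect_equal(nrow(ann), 0)
})

test_that("clockwise shells are normalized on read, area preserved", {
  f <- withr::local_tempfile(fileext = ".geojson")
  cw <- list(c(0, 0), c(0, 3), c(3, 3), c(3, 0), c(0, 0))  # negative shoelace
  doc <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(cw)),
         properties = list(classification = list(name = "X")))))
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  ann <- read_annotations(f)
  shell <- ann$geometry[[1]][[1]][[1]]
  expect_gt(ring_area(shell), 0)
  expect_equal(geom_area(ann$geometry[[1]]), 9)
})

test_that("write/read round trip is vertexwise faithful", {
  withr::local_seed(11)
  geoms <- c(
    list(multipolygon_geometry(list(
      list(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))),
      list(rbind(c(5, 5), c(8, 5), c(8, 8), c(5, 8)) * 1.000000123)
    ))),
    lapply(1:20, function(i) rand_star_geom())
  )
  ann <- annotations(geoms, class_name = c("Multi", rep("Star", 20)),
                     id = sprintf("g%02d", seq_along(geoms)))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(back$id, ann$id)
  expect_equal(back$class_name, ann$class_name)
  for (i in seq_len(nrow(ann))) {
    expect_equal(unclass(back$geometry[[i]]), unclass(ann$geometry[[i]]),
                 tolerance = 1e-12)
    expect_lt(abs(geom_area(back$geometry[[i]]) - geom_area(ann$geometry[[i]])) /
                geom_area(ann$geometry[[i]]), 1e-9)
  }
  # multipolygon stays one feature
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(doc$features[[1]]$geometry$type, "MultiPolygon")
})

test_that("writing an empty annotation set yields a valid FeatureCollection", {
  f <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(annotations(list(), validate = FALSE), f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(doc$type, "FeatureCollection")
  expect_length(doc$features, 0)
  expect_equal(nrow(read_annotations(f)), 0)
})

test_that("mask PNG round trip is bit-exact and guarded", {
  spec <- tile_spec(0, 0, 4, 4)
  lm <- label_map(c("a", "b"))
  f <- withr::local_tempfile(fileext = ".png")

  zero <- tile_mask(matrix(0L, 4, 4), spec, lm)
  write_mask(zero, f)
  expect_identical(read_mask(f, spec, lm)$grid, zero$grid)

  g <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
  m <- tile_mask(g, spec, lm)
  write_mask(m, f)
  expect_identical(read_mask(f, spec, lm)$grid, m$grid)

  # 3-channel PNG is rejected
  png::writePNG(array(0.5, dim = c(4, 4, 3)), f)
  expect_error(read_mask(f, spec, lm), "single-channel")
  # dimension mismatch names both shapes
  write_mask(m, f)
  expect_error(read_mask(f, tile_spec(0, 0, 8, 8), lm), "8 x 8")
})

test_that("image region extraction pads and block-averages", {
  img <- matrix(as.numeric(1:64), 8, 8)
  whole <- read_image_region(img, tile_spec(0, 0, 8, 8))
  expect_equal(whole, img)
  # half off the right edge: right half zero-padded
  right <- read_image_region(img, tile_spec(4, 0, 8, 8))
  expect_equal(right[, 1:4], img[, 5:8])
  expect_true(all(right[, 5:8] == 0))
  # 2x2 block mean
  small <- matrix(c(0, 4, 2, 6), 2, 2)   # column-major: values 0,4 | 2,6
  expect_equal(read_image_region(small, tile_spec(0, 0, 2, 2, downsample = 2)),
               matrix(3, 1, 1))
  # multi-channel passthrough
  arr <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  expect_equal(read_image_region(arr, tile_spec(0, 0, 8, 8)), arr)
})
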