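test_that("an empty index answers every query with nothing", {
  idx <- build_index(annotations(list(), validate = FALSE))
  expect_length(query_index(idx, 0, 0, 100, 100), 0)
  expect_equal(nrow(get_tile_annotations(idx, tile_spec(0, 0, 64, 64))), 0)
})

test_that("single-annotation queries require true geometric intersection", {
  # L-shape whose envelope covers the query but whose geometry does not
  lshape <- polygon_geometry(rbind(c(0, 0), c(10, 0), c(10, 2), c(2, 2),
                                   c(2, 10), c(0, 10)))
  idx <- build_index(annotations(lshape, "L"))
  expect_equal(query_index(idx, 5, 5, 9, 9), integer(0))  # in envelope, off geometry
  expect_equal(query_index(idx, 0, 0, 1, 1), 1L)
  expect_equal(query_index(idx, 50, 50, 60, 60), integer(0))
})

test_that("STR-tree queries equal a brute-force geometric scan", {
  withr::local_seed(101)
  sqs <- lapply(1:300, function(i) {
    square_geom(runif(1, 0, 900), runif(1, 0, 900), runif(1, 1, 60))
  })
  ann <- annotations(sqs, sample(c("A", "B"), 300, replace = TRUE))
  idx <- build_index(ann)
  for (k in 1:40) {
    x0 <- runif(1, -50, 850); y0 <- runif(1, -50, 850)
    w <- runif(1, 5, 300); h <- runif(1, 5, 300)
    got <- query_index(idx, x0, y0, x0 + w, y0 + h)
    want <- which(vapply(ann$geometry, geom_intersects_rect, logical(1),
                         xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h))
    expect_identical(got, want)
  }
})

test_that("tile clipping preserves geometry inside and drops disjoint", {
  g <- square_geom(10, 10, 5)
  idx <- build_index(annotations(g, "A", id = "a1"))
  inside <- get_tile_annotations(idx, tile_spec(0, 0, 32, 32))
  expect_equal(nrow(inside), 1)
  expect_equal(geom_area(inside$geometry[[1]]), 25)
  expect_equal(geom_bbox(inside$geometry[[1]]),
               c(xmin = 10, ymin = 10, xmax = 15, ymax = 15))
  expect_equal(nrow(get_tile_annotations(idx, tile_spec(100, 100, 32, 32))), 0)
})

test_that("a unit square straddling the tile edge halfway is clipped to 0.5", {
  g <- square_geom(31.5, 10, 1)             # tile right edge at x = 32
  idx <- build_index(annotations(g, "A"))
  cl <- get_tile_annotations(idx, tile_spec(0, 0, 32, 32))
  expect_equal(geom_area(cl$geometry[[1]]), 0.5)
  # purely boundary-touching annotations are filtered entirely
  touch <- build_index(annotations(square_geom(32, 10, 1), "A"))
  expect_equal(nrow(get_tile_annotations(touch, tile_spec(0, 0, 32, 32))), 0)
  # but the raw index query reports the touch
  expect_equal(query_index(touch, 0, 0, 32, 32), 1L)
})

test_that("clipping respects the downsample mapping into mask coordinates", {
  g <- rect_geom(104, 206, 110, 212)
  idx <- build_index(annotations(g, "A"))
  cl <- get_tile_annotations(idx, tile_spec(100, 200, 20, 20, downsample = 2))
  expect_equal(geom_bbox(cl$geometry[[1]]),
               c(xmin = 2, ymin = 3, xmax = 5, ymax = 6))
})

test_that("tile grids ceil-cover the image", {
  expect_equal(nrow(tile_grid(1024, 1024, 512)), 4)
  expect_equal(nrow(tile_grid(1024, 1024, 512, overlap = 256)), 9)
  expect_equal(nrow(tile_grid(100, 100, 512)), 1)
  g <- tile_grid(1000, 700, 512)            # overhang tiles allowed
  expect_equal(nrow(g), 4)
  expect_true(all(g$x + 512 >= 1000 | g$x %% 512 == 0))
  expect_error(tile_grid(100, 100, 64, overlap = 64), "overlap")
})

test_that("clipped areas over a disjoint grid sum to the total area", {
  withr::local_seed(7)
  geoms <- lapply(1:40, function(i) rand_star_geom(cx = runif(1, 60, 400),
                                                   cy = runif(1, 60, 400),
                                                   r = runif(1, 3, 40)))
  ann <- annotations(geoms, "S")
  idx <- build_index(ann)
  total <- sum(vapply(ann$geometry, geom_area, numeric(1)))
  grid <- tile_grid(512, 512, 128)
  s <- 0
  for (i in seq_len(nrow(grid))) {
    ta <- get_tile_annotations(idx, grid$spec[[i]])
    if (nrow(ta)) s <- s + sum(vapply(ta$geometry, geom_area, numeric(1)))
  }
  expect_lt(abs(s - total) / total, 1e-6)
})

test_that("the tile-pair stream is lazy, complete, and deterministic", {
  fix <- make_synthetic_image(width = 256, height = 256, noise_sd = 0)
  idx <- build_index(fix$annotations)
  pairs1 <- collect_tile_pairs(fix$image[, , 1], idx, fix$label_map,
                               tile_size = 128)
  expect_length(pairs1, 4)
  pairs2 <- collect_tile_pairs(fix$image[, , 1], idx, fix$label_map,
                               tile_size = 128)
  for (i in seq_along(pairs1)) {
    expect_identical(pairs1[[i]]$mask$grid, pairs2[[i]]$mask$grid)
    expect_identical(pairs1[[i]]$image, pairs2[[i]]$image)
  }
  # annotated-only keeps just tiles with annotations
  one <- annotations(square_geom(10, 10, 20), "A")
  idx1 <- build_index(one)
  got <- collect_tile_pairs(matrix(0, 256, 256), idx1, label_map("A"),
                            tile_size = 128, annotated_only = TRUE)
  expect_length(got, 1)
  expect_equal(sum(got[[1]]$mask$grid), 400)
})

test_that("multi-channel mode preserves class overlaps", {
  a <- square_geom(2, 2, 6)
  b <- square_geom(5, 5, 6)
  ann <- annotations(list(a, b), c("A", "B"))
  spec <- tile_spec(0, 0, 16, 16)
  lm <- label_map(c("A", "B"))
  mm <- rasterize_annotations(ann, spec, lm, mode = "multi")
  expect_equal(sum(mm$channels$A), 36)
  expect_equal(sum(mm$channels$B), 36)
  expect_equal(sum(mm$channels$A & mm$channels$B), 9)
  # single mode: later annotation wins the overlap
  sm <- rasterize_annotations(ann, spec, lm, mode = "single")
  expect_equal(sum(sm$grid == 1L), 27)
  expect_equal(sum(sm$grid == 2L), 36)
})
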