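#' Label masks on a tile grid
#'
#' A `tile_mask` is a single-label mask: an integer matrix on a
#' [tile_spec()]'s grid with 0 for background and label `k` for class `k` of
#' its [label_map()]. A `tile_multimask` keeps one binary channel per class,
#' so overlaps between classes are preserved.
#'
#' @param grid integer matrix (rows x cols matching `mask_dim(spec)`).
#' @param spec the `tile_spec` defining the grid.
#' @param lm the `label_map` giving meaning to the labels.
#' @return A `tile_mask`.
#' @export
tile_mask <- function(grid, spec, lm) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  d <- mask_dim(spec)
  if (!identical(dim(grid), unname(as.integer(d))))
    stop(sprintf("mask grid is %d x %d but spec requires %d x %d",
                 nrow(grid), ncol(grid), d[1L], d[2L]), call. = FALSE)
  if (any(grid < 0L) || any(grid > length(lm)))
    stop("mask labels must lie in 0..", length(lm), call. = FALSE)
  structure(list(grid = grid, spec = spec, label_map = lm), class = "tile_mask")
}

#' @rdname tile_mask
#' @param channels list of binary (0/1) integer matrices, one per class.
#' @export
tile_multimask <- function(channels, spec, lm) {
  stopifnot(length(channels) == length(lm))
  d <- unname(as.integer(mask_dim(spec)))
  channels <- lapply(channels, function(ch) {
    ch <- as.matrix(ch)
    storage.mode(ch) <- "integer"
    if (!identical(dim(ch), d)) stop("channel dimensions do not match spec", call. = FALSE)
    if (any(ch < 0L | ch > 1L)) stop("channels must be binary", call. = FALSE)
    ch
  })
  names(channels) <- unclass(lm)
  structure(list(channels = channels, spec = spec, label_map = lm),
            class = "tile_multimask")
}

#' @export
print.tile_mask <- function(x, ...) {
  cat(sprintf("<tile_mask %d x %d, %d classes, %d foreground px>\n",
              nrow(x$grid), ncol(x$grid), length(x$label_map), sum(x$grid > 0L)))
  invisible(x)
}

#' @export
print.tile_multimask <- function(x, ...) {
  cat(sprintf("<tile_multimask %d x %d, %d channels>\n",
              nrow(x$channels[[1L]]), ncol(x$channels[[1L]]), length(x$channels)))
  invisible(x)
}

#' Read and write single-label masks as 8-bit grayscale PNG
#'
#' The PNG stores the raw integer labels (0 = background), so the round trip
#' is lossless for label maps with up to 255 classes. Reading checks that
#' the file is single-channel and that its dimensions match the spec's grid.
#'
#' @param mask a `tile_mask`.
#' @param path PNG file path.
#' @return `write_mask()`: `path` invisibly; `read_mask()`: a `tile_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tile_mask"))
  if (length(mask$label_map) > 255L)
    stop("8-bit PNG masks support at most 255 classes", call. = FALSE)
  png::writePNG(mask$grid / 255, target = path)
  invisible(path)
}

#' @rdname write_mask
#' @param spec expected `tile_spec`.
#' @param lm expected `label_map`.
#' @export
read_mask <- function(path, spec, lm) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 2L)
    stop(sprintf("expected a single-channel mask PNG, found %d channels",
                 dim(img)[3L]), call. = FALSE)
  d <- mask_dim(spec)
  if (nrow(img) != d[1L] || ncol(img) != d[2L])
    stop(sprintf("mask PNG is %d x %d but spec requires %d x %d",
                 nrow(img), ncol(img), d[1L], d[2L]), call. = FALSE)
  tile_mask(round(img * 255), spec, lm)
}

#' Extract an image region on a tile spec's grid
#'
#' Cuts the spec's region out of a flat raster array (matrix or
#' rows x cols x channels array, y down). Out-of-bounds area is zero-padded.
#' With `downsample > 1` each output pixel is the block mean of the level-0
#' pixels whose centers fall in its cell, so the reduction is deterministic
#' and well-defined for non-integer factors too.
#'
#' @param image 2-D or 3-D numeric array.
#' @param spec a `tile_spec`.
#' @return Array with the spec's grid dimensions (and the input's channels).
#' @examples
#' img <- matrix(c(0, 4, 2, 6), 2, 2)
#' read_image_region(img, tile_spec(0, 0, 2, 2, downsample = 2))  # 1x1 mean
#' @export
read_image_region <- function(image, spec) {
  dm <- dim(image)
  if (is.null(dm) || length(dm) < 2L) stop("image must be a matrix or array", call. = FALSE)
  h <- dm[1L]; w <- dm[2L]
  nch <- if (length(dm) == 3L) dm[3L] else 1L
  d <- spec$downsample
  out_d <- mask_dim(spec)
  nr <- out_d[[1L]]; nc <- out_d[[2L]]

  # map each level-0 row/col (0-based) to an output cell, or NA if outside
  src_rows <- 0:(h - 1L)
  src_cols <- 0:(w - 1L)
  orow <- floor((src_rows + 0.5 - spec$y) / d)
  ocol <- floor((src_cols + 0.5 - spec$x) / d)
  keep_r <- which(orow >= 0 & orow < nr)
  keep_c <- which(ocol >= 0 & ocol < nc)

  res <- array(0, dim = c(nr, nc, nch))
  if (length(keep_r) && length(keep_c)) {
    gr <- orow[keep_r]; gc <- ocol[keep_c]
    rows_present <- sort(unique(gr)); cols_present <- sort(unique(gc))
    cnt <- outer(as.numeric(table(gr)), as.numeric(table(gc)))
    for (ch in seq_len(nch)) {
      sub <- if (length(dm) == 3L) image[keep_r, keep_c, ch, drop = FALSE]
             else image[keep_r, keep_c, drop = FALSE]
      sub <- matrix(sub, length(keep_r), length(keep_c))
      acc <- rowsum(sub, group = gr, reorder = TRUE)
      acc <- t(rowsum(t(acc), group = gc, reorder = TRUE))
      mean_mat <- matrix(0, nr, nc)
      mean_mat[cbind(rep(rows_present + 1L, times = length(cols_present)),
                     rep(cols_present + 1L, each = length(rows_present)))] <-
        as.vector(acc / cnt)
      res[, , ch] <- mean_mat
    }
  }
  if (length(dm) == 2L) matrix(res[, , 1L], nr, nc) else res
}
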