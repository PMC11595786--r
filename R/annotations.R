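#' Annotation tables
#'
#' Annotations are kept in an ordinary tibble with one row per annotation and
#' three columns: `id` (character, may be `NA`), `class_name` (character) and
#' `geometry` (list of [polygon_geometry()] objects in level-0 slide pixel
#' coordinates). All user-facing functions take and return this shape so
#' pipelines compose with the usual dplyr verbs.
#'
#' @param geometry a `tile_geometry` or list of them.
#' @param class_name character vector of class names (recycled).
#' @param id optional character ids (recycled; default `NA`).
#' @param validate validate and orientation-normalize geometries on
#'   construction.
#' @return A tibble with columns `id`, `class_name`, `geometry`.
#' @examples
#' sq <- polygon_geometry(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
#' annotations(sq, "Tumor")
#' @export
annotations <- function(geometry, class_name = "unclassified", id = NA_character_,
                        validate = TRUE) {
  if (is_geometry(geometry)) geometry <- list(geometry)
  stopifnot(is.list(geometry))
  if (validate) geometry <- lapply(geometry, validate_geometry)
  tibble::tibble(
    id = rep_len(as.character(id), length(geometry)),
    class_name = rep_len(as.character(class_name), length(geometry)),
    geometry = geometry
  )
}

#' @rdname annotations
#' @param x object to check.
#' @export
is_annotations <- function(x) {
  is.data.frame(x) && all(c("id", "class_name", "geometry") %in% names(x))
}

empty_annotations <- function() {
  tibble::tibble(id = character(), class_name = character(), geometry = list())
}

#' Read annotations from a GeoJSON FeatureCollection
#'
#' Reads the QuPath GeoJSON dialect: Polygon / MultiPolygon features with the
#' class name under `properties.classification.name`, falling back to
#' `properties.name`, else `"unclassified"`. Geometries are validated and
#' ring orientation is normalized (shells to positive shoelace sign, holes
#' negative); an irreparably invalid geometry raises an error naming the
#' offending feature.
#'
#' @param path GeoJSON file.
#' @return Annotation tibble (see [annotations()]).
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection, got type ",
         deparse(doc$type), call. = FALSE)
  feats <- doc$features
  if (!length(feats)) return(empty_annotations())
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    fid <- f$id %||% f$properties$id %||% NA_character_
    g <- f$geometry
    polys <- switch(
      g$type %||% "",
      Polygon = list(lapply(g$coordinates, coords_to_ring)),
      MultiPolygon = lapply(g$coordinates, function(p) lapply(p, coords_to_ring)),
      stop(sprintf("feature %s: unsupported geometry type %s",
                   fid %||% i, deparse(g$type)), call. = FALSE)
    )
    geom <- tryCatch(
      validate_geometry(new_geometry(polys)),
      error = function(e) stop(sprintf("feature %s: invalid geometry (%s)",
                                       if (is.na(fid)) i else fid,
                                       conditionMessage(e)), call. = FALSE)
    )
    cls <- f$properties$classification$name %||% f$properties$name %||% "unclassified"
    list(id = as.character(fid), class_name = as.character(cls), geometry = geom)
  })
  tibble::tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    class_name = vapply(rows, `[[`, character(1), "class_name"),
    geometry = lapply(rows, `[[`, "geometry")
  )
}

coords_to_ring <- function(ring) {
  m <- matrix(unlist(ring, use.names = FALSE), ncol = 2L, byrow = TRUE)
  as_ring(m)
}

#' Write annotations to a GeoJSON FeatureCollection
#'
#' Inverse of [read_annotations()]: one feature per annotation, Polygon or
#' MultiPolygon geometry with closed rings, class name stored as the QuPath
#' `classification` property. Coordinates are written at full double
#' precision, so a read-back is vertexwise identical.
#'
#' @param ann annotation tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(is_annotations(ann))
  feats <- purrr::pmap(ann[c("id", "class_name", "geometry")],
                       function(id, class_name, geometry) {
    polys <- lapply(geometry, function(poly) lapply(poly, ring_to_coords))
    geo <- if (length(polys) == 1L) {
      list(type = "Polygon", coordinates = polys[[1L]])
    } else {
      list(type = "MultiPolygon", coordinates = polys)
    }
    f <- list(
      type = "Feature",
      geometry = geo,
      properties = list(
        classification = list(name = class_name),
        object_type = "annotation"
      )
    )
    if (!is.na(id)) f$id <- id
    f
  })
  doc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# closed ring as a list of [x, y] pairs; kept as an unnamed list so
# jsonlite serializes a JSON array of 2-arrays
ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1L, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1L], closed[i, 2L]))
}

#' Total annotated area per class
#'
#' @param ann annotation tibble.
#' @return Tibble with `class_name` and `area` columns.
#' @export
annotation_areas <- function(ann) {
  stopifnot(is_annotations(ann))
  ann |>
    dplyr::mutate(area = vapply(.data$geometry, geom_area, numeric(1))) |>
    dplyr::summarise(area = sum(.data$area), .by = "class_name")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
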