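ANNOTATION_LABELS <- c("SE", "LSIL", "HSIL", "p16_positive", "mitosis", "other")

#' Polygon annotation set
#'
#' Ordered polygon outlines in slide pixel coordinates (0-based, x = column),
#' as drawn in ASAP or exported as GeoJSON. Every polygon needs at least 3
#' vertices and a label from the fixed vocabulary used by this workflow.
#'
#' @param polygons list of polygons; each a list with `label` (character) and
#'   `points` (n x 2 numeric matrix of x, y vertices).
#' @param source_format `"asap_xml"` or `"geojson"`.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(polygons = list(), source_format = "asap_xml") {
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (is.null(p$points) || !is.matrix(p$points) || nrow(p$points) < 3)
      sil_data_error(sprintf("polygon %d has fewer than 3 vertices", i))
    if (!all(is.finite(p$points)))
      sil_data_error(sprintf("polygon %d has non-finite coordinates", i))
    if (!p$label %in% ANNOTATION_LABELS)
      sil_data_error(sprintf(
        "polygon %d label '%s' not in {%s}",
        i, p$label, paste(ANNOTATION_LABELS, collapse = ", ")
      ))
  }
  structure(
    list(polygons = polygons, source_format = source_format),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d polygon(s) [%s]\n",
    length(x$polygons), x$source_format
  ))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$polygons)

#' Read and write polygon annotations
#'
#' Supports ASAP XML (`Annotation`/`Coordinate` elements with an `Order`
#' attribute, label in `PartOfGroup`) and GeoJSON `FeatureCollection`s whose
#' features carry a `classification` property (the QuPath interchange
#' convention). Reading after writing reproduces vertices up to
#' floating-point round trip.
#'
#' @param path file path.
#' @param format `"asap_xml"` or `"geojson"`; guessed from the extension when
#'   omitted (`.xml` vs `.json`/`.geojson`).
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, format = NULL) {
  format <- format %||% guess_annotation_format(path)
  if (!file.exists(path)) sil_data_error(sprintf("file not found: %s", path))
  switch(format,
    asap_xml = read_asap_xml(path),
    geojson = read_geojson(path),
    sil_config_error(sprintf("unknown annotation format '%s'", format))
  )
}

#' @rdname read_annotations
#' @param a an [annotation_set()].
#' @export
write_annotations <- function(a, path, format = NULL) {
  format <- format %||% guess_annotation_format(path)
  switch(format,
    asap_xml = write_asap_xml(a, path),
    geojson = write_geojson(a, path),
    sil_config_error(sprintf("unknown annotation format '%s'", format))
  )
  invisible(path)
}

guess_annotation_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xml") "asap_xml"
  else if (ext %in% c("json", "geojson")) "geojson"
  else sil_config_error(sprintf("cannot guess annotation format from '.%s'", ext))
}

read_asap_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    sil_data_error(sprintf("malformed ASAP XML in %s: %s", path, conditionMessage(e)))
  })
  nodes <- xml2::xml_find_all(doc, ".//Annotation")
  polygons <- lapply(seq_along(nodes), function(i) {
    node <- nodes[[i]]
    label <- xml2::xml_attr(node, "PartOfGroup")
    if (is.na(label) || !nzchar(label)) label <- xml2::xml_attr(node, "Name")
    coords <- xml2::xml_find_all(node, ".//Coordinate")
    if (length(coords) == 0)
      sil_data_error(sprintf("Annotation %d has no Coordinate elements", i))
    ord <- suppressWarnings(as.integer(xml2::xml_attr(coords, "Order")))
    x <- suppressWarnings(as.numeric(xml2::xml_attr(coords, "X")))
    y <- suppressWarnings(as.numeric(xml2::xml_attr(coords, "Y")))
    if (anyNA(ord) || anyNA(x) || anyNA(y))
      sil_data_error(sprintf(
        "Annotation %d has a Coordinate missing Order/X/Y", i
      ))
    o <- order(ord)
    list(label = label, points = cbind(x = x[o], y = y[o]))
  })
  annotation_set(polygons, source_format = "asap_xml")
}

# Assembled as text: node-by-node DOM insertion is quadratic in xml2 and
# traced contours run to thousands of vertices per polygon.
write_asap_xml <- function(a, path) {
  groups <- unique(vapply(a$polygons, `[[`, "", "label"))
  ann_chunks <- vapply(seq_along(a$polygons), function(i) {
    p <- a$polygons[[i]]
    coords <- sprintf(
      '      <Coordinate Order="%d" X="%s" Y="%s"/>',
      seq_len(nrow(p$points)) - 1,
      format(p$points[, 1], digits = 17, trim = TRUE, scientific = FALSE),
      format(p$points[, 2], digits = 17, trim = TRUE, scientific = FALSE)
    )
    paste0(
      sprintf(
        '    <Annotation Name="Annotation %d" Type="Polygon" PartOfGroup="%s" Color="#F4FA58">\n',
        i - 1, p$label
      ),
      "      <Coordinates>\n",
      paste(coords, collapse = "\n"), "\n",
      "      </Coordinates>\n",
      "    </Annotation>"
    )
  }, character(1))
  group_chunks <- sprintf(
    '    <Group Name="%s" PartOfGroup="None" Color="#64FE2E"/>', groups
  )
  xml <- paste0(
    '<?xml version="1.0"?>\n<ASAP_Annotations>\n  <Annotations>\n',
    paste(ann_chunks, collapse = "\n"),
    "\n  </Annotations>\n  <AnnotationGroups>\n",
    paste(group_chunks, collapse = "\n"),
    "\n  </AnnotationGroups>\n</ASAP_Annotations>\n"
  )
  # validate the emitted document before writing
  xml2::read_xml(xml)
  writeLines(xml, path)
  invisible(path)
}

read_geojson <- function(path) {
  js <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) sil_data_error(sprintf(
      "malformed GeoJSON in %s: %s", path, conditionMessage(e)
    ))
  )
  feats <- js$features %||% sil_data_error("GeoJSON has no 'features' member")
  polygons <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    geom <- f$geometry %||% sil_data_error(sprintf("feature %d has no geometry", i))
    if (!identical(geom$type, "Polygon"))
      sil_data_error(sprintf(
        "feature %d: geometry type '%s' is not Polygon", i, geom$type %||% "?"
      ))
    ring <- geom$coordinates[[1]]
    pts <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    # GeoJSON rings repeat the first vertex; drop the closure
    if (nrow(pts) >= 2 && all(pts[1, ] == pts[nrow(pts), ]))
      pts <- pts[-nrow(pts), , drop = FALSE]
    if (nrow(pts) < 3)
      sil_data_error(sprintf("feature %d: polygon has fewer than 3 vertices", i))
    label <- f$properties$classification$name %||%
      f$properties$classification %||% "other"
    if (is.list(label)) label <- label$name %||% "other"
    colnames(pts) <- c("x", "y")
    list(label = label, points = pts)
  })
  annotation_set(polygons, source_format = "geojson")
}

write_geojson <- function(a, path) {
  feats <- lapply(a$polygons, function(p) {
    ring <- rbind(p$points, p$points[1, , drop = FALSE])
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) {
          c(ring[j, 1], ring[j, 2])
        }))
      ),
      properties = list(classification = list(name = p$label))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
}

#' Rasterize polygon annotations into a mask
#'
#' A pixel is set to 1 iff its centre lies inside any polygon of the
#' requested label, under the even-odd rule. Pixel centres are at integer
#' coordinates (pixel `[r, c]` has centre `(c - 1, r - 1)`).
#'
#' @param a an [annotation_set()].
#' @param label label to rasterize.
#' @param shape integer `c(height, width)`.
#' @return integer mask matrix.
#' @export
rasterize_annotations <- function(a, label, shape) {
  if (any(shape < 1)) sil_data_error("shape must be positive")
  present <- unique(vapply(a$polygons, `[[`, "", "label"))
  sel <- vapply(a$polygons, function(p) p$label == label, logical(1))
  if (!label %in% present && length(a$polygons) > 0)
    sil_data_error(sprintf(
      "label '%s' not present; available: %s",
      label, paste(present, collapse = ", ")
    ))
  out <- matrix(0L, shape[1], shape[2])
  if (!any(sel)) return(out)
  g <- expand.grid(y = seq_len(shape[1]) - 1, x = seq_len(shape[2]) - 1)
  for (p in a$polygons[sel]) {
    inside <- cpp_points_in_polygon(g$x, g$y, p$points)
    out[inside] <- 1L
  }
  out
}
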