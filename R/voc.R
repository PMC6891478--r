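#' Labeled images and Pascal-VOC XML annotations
#'
#' A `labeled_image` couples an `[H, W, 3]` raster with a data frame of
#' annotations: continuous 0-based pixel boxes (`x_min`, `y_min`, `x_max`,
#' `y_max`), a class `label`, and optional acquisition tags (`height_tag`,
#' flying height in m; `stage_tag`, growth stage). On disk, annotations use
#' the Pascal-VOC XML dialect produced by the labelImg tool: 1-based
#' inclusive integer pixel corners. A continuous box `[x0, x1)` maps to
#' `xmin = floor(x0) + 1`, `xmax = ceiling(x1)`, which round-trips exactly
#' for integer-valued boxes.
#'
#' @name voc
NULL

.empty_annotations <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' Construct a labeled image
#'
#' @param image `[H, W, 3]` numeric array
#' @param annotations data frame with columns `x_min`, `y_min`, `x_max`,
#'   `y_max`, `label` (optional extra columns are carried along); `NULL`
#'   means no objects
#' @param height_tag,stage_tag acquisition metadata (flying height in m,
#'   growth stage), stored as attributes on the object
#' @return object of class `labeled_image`
#' @export
labeled_image <- function(image, annotations = NULL,
                          height_tag = NA_real_, stage_tag = NA_character_) {
  .check_image(image)
  if (is.null(annotations) || nrow(annotations) == 0L) {
    annotations <- .empty_annotations()
  } else {
    req <- c("x_min", "y_min", "x_max", "y_max", "label")
    if (!all(req %in% names(annotations)))
      stop("annotations need columns: ", paste(req, collapse = ", "))
    d <- dim(image)
    m <- clip_box(as.matrix(annotations[, c("x_min", "y_min", "x_max", "y_max")]),
                  x_max = d[2], y_max = d[1])
    m <- .box_mat(m)
    annotations[, c("x_min", "y_min", "x_max", "y_max")] <- m
    validate_box(m)
  }
  structure(list(image = image, annotations = annotations,
                 height_tag = height_tag, stage_tag = stage_tag),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_image> %d x %d px, %d object(s)\n",
              d[2], d[1], nrow(x$annotations)))
  invisible(x)
}

#' Write annotations as Pascal-VOC XML
#'
#' @param limg a `labeled_image` (its raster is only used for the `<size>`
#'   element), or a list with `annotations` and image dimensions
#' @param path output XML path
#' @param image_filename value of the `<filename>` element
#' @export
write_voc_xml <- function(limg, path, image_filename = basename(path)) {
  stopifnot(inherits(limg, "labeled_image"))
  d <- dim(limg$image)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", image_filename)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(d[2]))
  xml2::xml_add_child(sz, "height", as.character(d[1]))
  xml2::xml_add_child(sz, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  ann <- limg$annotations
  for (i in seq_len(nrow(ann))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", ann$label[i])
    xml2::xml_add_child(ob, "pose", "Unspecified")
    xml2::xml_add_child(ob, "truncated", "0")
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(floor(ann$x_min[i]) + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(floor(ann$y_min[i]) + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(ceiling(ann$x_max[i])))
    xml2::xml_add_child(bb, "ymax", as.character(ceiling(ann$y_max[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Pascal-VOC XML annotation file
#'
#' @param path XML path
#' @return list with `filename`, `width`, `height`, and `annotations`
#'   (continuous 0-based boxes, see [voc])
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  num <- function(node, sel) as.numeric(xml2::xml_text(xml2::xml_find_first(node, sel)))
  width <- num(doc, ".//size/width")
  height <- num(doc, ".//size/height")
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs)) {
    ann <- data.frame(
      x_min = vapply(objs, num, 0, sel = ".//bndbox/xmin") - 1,
      y_min = vapply(objs, num, 0, sel = ".//bndbox/ymin") - 1,
      x_max = vapply(objs, num, 0, sel = ".//bndbox/xmax"),
      y_max = vapply(objs, num, 0, sel = ".//bndbox/ymax"),
      label = vapply(objs, function(o)
        xml2::xml_text(xml2::xml_find_first(o, ".//name")), ""),
      stringsAsFactors = FALSE)
  } else {
    ann <- .empty_annotations()
  }
  list(filename = xml2::xml_text(xml2::xml_find_first(doc, ".//filename")),
       width = width, height = height, annotations = ann)
}
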