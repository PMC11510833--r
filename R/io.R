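# Annotation and image I/O.
#
# Two coordinate conventions cross here and nowhere else: label files store
# YOLO center-format boxes normalized to [0, 1]; everything internal uses
# continuous pixel corner coordinates with the origin at the top-left.

#' Read / write YOLO-format label files
#'
#' One `class cx cy w h` line per object, all but `class` normalized to the
#' unit square.  Round trips are exact to 6 decimals; an empty (or absent)
#' file is an empty annotation.
#'
#' @param path label file path.
#' @param labels data frame with columns class_id, cx, cy, w, h.
#' @return `read_yolo_labels`: data frame with columns class_id (integer),
#'   cx, cy, w, h.
#' @export
read_yolo_labels <- function(path) {
  empty <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) != 5L) {
      stop(sprintf("%s line %d: expected 5 fields, got %d", path, i, length(tok)))
    }
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v))) stop(sprintf("%s line %d: non-numeric field", path, i))
    if (v[1] < 0 || v[1] != round(v[1])) {
      stop(sprintf("%s line %d: class id must be a non-negative integer", path, i))
    }
    if (any(v[2:5] < 0 | v[2:5] > 1)) {
      stop(sprintf("%s line %d: coordinates outside [0, 1]", path, i))
    }
    if (v[4] <= 0 || v[5] <= 0) {
      stop(sprintf("%s line %d: box width/height must be positive", path, i))
    }
    data.frame(class_id = as.integer(v[1]), cx = v[2], cy = v[3], w = v[4], h = v[5])
  })
  do.call(rbind, rows)
}

#' @rdname read_yolo_labels
#' @export
write_yolo_labels <- function(labels, path) {
  if (is.null(labels) || nrow(labels) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("class_id", "cx", "cy", "w", "h") %in% names(labels)))
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id,
                     labels$cx, labels$cy, labels$w, labels$h), path)
  invisible(path)
}

#' Convert between normalized center boxes and pixel corner boxes
#'
#' @param labels data frame from [read_yolo_labels()].
#' @param width,height image size in pixels.
#' @return `yolo_to_corners`: list with `boxes` (G x 4 corner matrix, pixels)
#'   and `cls` (0-based classes); `corners_to_yolo`: a labels data frame,
#'   clamped to the unit square.
#' @export
yolo_to_corners <- function(labels, width, height) {
  if (nrow(labels) == 0L) {
    return(list(boxes = matrix(numeric(0), 0, 4), cls = integer(0)))
  }
  list(boxes = cbind((labels$cx - labels$w / 2) * width,
                     (labels$cy - labels$h / 2) * height,
                     (labels$cx + labels$w / 2) * width,
                     (labels$cy + labels$h / 2) * height),
       cls = labels$class_id)
}

#' @rdname yolo_to_corners
#' @param boxes G x 4 corner matrix in pixels.
#' @param cls 0-based class vector.
#' @export
corners_to_yolo <- function(boxes, cls, width, height) {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    return(data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  b <- cbind(pmax(boxes[, 1], 0), pmax(boxes[, 2], 0),
             pmin(boxes[, 3], width), pmin(boxes[, 4], height))
  data.frame(class_id = as.integer(cls),
             cx = (b[, 1] + b[, 3]) / 2 / width,
             cy = (b[, 2] + b[, 4]) / 2 / height,
             w = (b[, 3] - b[, 1]) / width,
             h = (b[, 4] - b[, 2]) / height)
}

#' Read a VOC-layout XML annotation
#'
#' Parses the `<object>` entries of a PASCAL-VOC annotation file.
#'
#' @param path XML file.
#' @param class_map optional character vector of class names; when given,
#'   `class_id` is the 0-based index into it (unknown names error).
#' @return data frame: name, class_id (or NA without `class_map`),
#'   x1, y1, x2, y2 (pixels), plus image width/height attributes.
#' @export
read_voc_xml <- function(path, class_map = NULL) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, ".//size")
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  rows <- lapply(objs, function(o) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    bb <- xml2::xml_find_first(o, "./bndbox")
    gv <- function(t) as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", t))))
    cid <- if (is.null(class_map)) NA_integer_ else {
      i <- match(nm, class_map)
      if (is.na(i)) stop("unknown class name in ", path, ": ", nm)
      i - 1L
    }
    data.frame(name = nm, class_id = cid, x1 = gv("xmin"), y1 = gv("ymin"),
               x2 = gv("xmax"), y2 = gv("ymax"))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(name = character(0), class_id = integer(0), x1 = numeric(0),
               y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  }
  attr(out, "width") <- w
  attr(out, "height") <- h
  out
}

#' Read / write images as PNG
#'
#' Images are H x W x 3 arrays of values in `[0, 1]` (8-bit resolution).
#'
#' @param x image array.
#' @param path file path.
#' @return `read_image`: the array.
#' @export
write_image <- function(x, path) {
  png::writePNG(x, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Build a training sample from an image and its YOLO labels
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param labels data frame from [read_yolo_labels()].
#' @return list(image, boxes, cls) in pixel corner convention.
#' @export
sample_from_yolo <- function(image, labels) {
  d <- dim(image)
  cc <- yolo_to_corners(labels, d[2], d[1])
  list(image = image, boxes = cc$boxes, cls = cc$cls)
}

#' Read a dataset directory via its YAML descriptor
#'
#' The layout matches the YOLO convention written by [generate_dataset()]:
#' a `data.yaml` with `names` and relative `train`/`val` image directories,
#' each with a sibling `labels/<split>` directory of `.txt` files.
#'
#' @param yaml_path path to the dataset YAML.
#' @param split `"train"` or `"val"`.
#' @return list of samples (see [sample_from_yolo()]).
#' @export
load_dataset <- function(yaml_path, split = c("train", "val")) {
  split <- match.arg(split)
  if (!file.exists(yaml_path)) stop("dataset yaml not found: ", yaml_path)
  y <- yaml::read_yaml(yaml_path)
  root <- dirname(yaml_path)
  img_dir <- file.path(root, y[[split]])
  if (!dir.exists(img_dir)) stop("image directory not found: ", img_dir)
  lab_dir <- file.path(root, "labels", split)
  imgs <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  lapply(imgs, function(f) {
    lab <- file.path(lab_dir, sub("\\.png$", ".txt", basename(f)))
    labels <- if (file.exists(lab)) read_yolo_labels(lab) else
      data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                 w = numeric(0), h = numeric(0))
    sample_from_yolo(read_image(f), labels)
  })
}

#' Write / read a model configuration as YAML
#'
#' @param cfg an `ev_config`.
#' @param path file path.
#' @return `read_model_yaml`: the `ev_config`.
#' @export
write_model_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "ev_config"))
  keep <- c("scale", "mgefa", "p6", "lska", "nc", "imgsz", "reg_max",
            "lska_k", "lse_grid", "lse_k", "seed")
  yaml::write_yaml(unclass(cfg)[keep], path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  if (!file.exists(path)) stop("model yaml not found: ", path)
  do.call(model_config, yaml::read_yaml(path))
}
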