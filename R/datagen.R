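# Synthetic weed scenes.
#
# The generator emulates the structure of field weed-detection imagery:
# a textured soil/foliage background, many small lobed plant blobs with
# class-specific shape and hue, partial occlusion between neighbouring
# plants, and exact bounding boxes recorded from each blob's own painted
# extent before later paints may cover it.

#' Scene generator parameters
#'
#' @param image_size edge length in pixels (square scenes).
#' @param n_classes number of object classes (2-20).
#' @param objects_per_image inclusive integer range.
#' @param scale_range object diameter as a fraction of the image edge,
#'   sampled log-uniformly so small targets dominate.  The default keeps
#'   even the smallest objects at 1.3+ cells of a stride-8 detection grid,
#'   the regime of field weed imagery (sub-resolution objects can be forced
#'   by lowering the minimum).
#' @param occlusion_rate probability that an object is deliberately placed
#'   overlapping an earlier one (its later neighbours then partially cover
#'   it).
#' @param lobe_amp amplitude of the lobed boundary modulation.
#' @param bg_cells background texture coarseness (noise grid cells per edge).
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(image_size = 64, n_classes = 3,
                         objects_per_image = c(2, 5),
                         scale_range = c(0.16, 0.35),
                         occlusion_rate = 0.3,
                         lobe_amp = 0.25, bg_cells = 8) {
  stopifnot(image_size >= 16, n_classes >= 2, n_classes <= 20,
            length(objects_per_image) == 2L,
            objects_per_image[1] >= 1,
            objects_per_image[2] >= objects_per_image[1],
            scale_range[1] > 0, scale_range[2] >= scale_range[1],
            scale_range[2] <= 0.5,
            occlusion_rate >= 0, occlusion_rate <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 objects_per_image = as.integer(objects_per_image),
                 scale_range = scale_range, occlusion_rate = occlusion_rate,
                 lobe_amp = lobe_amp, bg_cells = as.integer(bg_cells)),
            class = "scene_params")
}

# per-class appearance: lobe count, base hue, saturation -- fixed mapping so
# a class looks the same in every scene
class_style <- function(cid) {
  list(lobes = 3L + (cid %% 5L),
       hue = (0.22 + 0.61 * cid / 7) %% 1,
       sat = 0.45 + 0.1 * ((cid * 3L) %% 4L) / 3)
}

# bilinear upsample of a coarse noise grid to size s x s
bg_noise <- function(s, cells) {
  g <- matrix(stats::rnorm((cells + 1)^2), cells + 1)
  u <- (seq_len(s) - 0.5) / s * cells + 0.5
  i0 <- pmin(pmax(floor(u), 1), cells); f <- pmin(pmax(u - i0, 0), 1)
  a <- g[i0, i0, drop = FALSE]
  b <- g[i0 + 1, i0, drop = FALSE]
  cc <- g[i0, i0 + 1, drop = FALSE]
  d <- g[i0 + 1, i0 + 1, drop = FALSE]
  fa <- matrix(f, s, s); fb <- matrix(f, s, s, byrow = TRUE)
  a * (1 - fa) * (1 - fb) + b * fa * (1 - fb) + cc * (1 - fa) * fb + d * fa * fb
}

#' Generate one synthetic weed scene
#'
#' @param params a [scene_params()].
#' @param seed integer seed; identical seeds give identical samples.
#' @return list: `image` (H x W x 3, values on the 8-bit grid in `[0, 1]`),
#'   `boxes` (G x 4 pixel corners, pre-occlusion extents), `cls` (0-based),
#'   `labels` (normalized YOLO rows), `occluded` (logical per object).
#' @export
generate_scene <- function(params = scene_params(), seed = 0) {
  stopifnot(inherits(params, "scene_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  s <- params$image_size
  # soil background: brownish base + low-frequency noise + foliage patches
  n1 <- bg_noise(s, params$bg_cells)
  img <- array(0, c(s, s, 3))
  img[, , 1] <- 0.32 + 0.05 * n1
  img[, , 2] <- 0.26 + 0.06 * n1
  img[, , 3] <- 0.17 + 0.03 * n1
  xs <- matrix(seq_len(s) - 0.5, s, s, byrow = TRUE)   # x along columns
  ys <- matrix(seq_len(s) - 0.5, s, s)                 # y along rows
  for (k in seq_len(3L + (seed %% 3L))) {              # dark foliage ellipses
    cx <- stats::runif(1, 0, s); cy <- stats::runif(1, 0, s)
    rx <- stats::runif(1, 0.1, 0.3) * s; ry <- stats::runif(1, 0.1, 0.3) * s
    m <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 < 1
    for (ch in 1:3) img[, , ch][m] <- img[, , ch][m] * 0.8 + c(0.10, 0.16, 0.07)[ch] * 0.2
  }
  obj_rng <- seq.int(params$objects_per_image[1], params$objects_per_image[2])
  n_obj <- if (length(obj_rng) == 1L) obj_rng else sample(obj_rng, 1)
  boxes <- NULL; cls <- integer(0); occluded <- logical(0)
  placed <- 0L
  for (o in seq_len(n_obj)) {
    r <- exp(stats::runif(1, log(params$scale_range[1]), log(params$scale_range[2]))) * s / 2
    want_occl <- placed > 0L && stats::runif(1) < params$occlusion_rate
    ok <- FALSE
    for (try in seq_len(40L)) {
      if (want_occl) {
        j <- sample.int(placed, 1)
        pcx <- (boxes[j, 1] + boxes[j, 3]) / 2
        pcy <- (boxes[j, 2] + boxes[j, 4]) / 2
        pr <- (boxes[j, 3] - boxes[j, 1]) / 2
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- pcx + cos(ang) * (pr + r) * 0.7
        cy <- pcy + sin(ang) * (pr + r) * 0.7
      } else {
        cx <- stats::runif(1, r, s - r)
        cy <- stats::runif(1, r, s - r)
      }
      if (cx < r / 2 || cx > s - r / 2 || cy < r / 2 || cy > s - r / 2) next
      cand <- c(cx - r, cy - r, cx + r, cy + r)
      if (!want_occl && placed > 0L) {
        ious <- suppressWarnings(box_iou(matrix(cand, 1), boxes))
        if (max(ious) > 0.25) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      warning(sprintf("scene %d: could not place object %d of %d; emitting fewer",
                      seed, o, n_obj))
      next
    }
    cid <- sample.int(params$n_classes, 1) - 1L
    sty <- class_style(cid)
    phi <- stats::runif(1, 0, 2 * pi)
    theta <- atan2(ys - cy, xs - cx)
    rad <- r / (1 + params$lobe_amp) * (1 + params$lobe_amp * cos(sty$lobes * theta + phi))
    m <- (xs - cx)^2 + (ys - cy)^2 <= rad^2
    if (!any(m)) next
    # paint: class hue with radial shading and speckle
    base <- grDevices::hsv(sty$hue, sty$sat, 1)
    rgbv <- grDevices::col2rgb(base)[, 1] / 255
    shade <- 0.55 + 0.45 * sqrt(pmax(1 - ((xs - cx)^2 + (ys - cy)^2) / r^2, 0))
    spec <- 1 + 0.08 * matrix(stats::rnorm(s * s), s, s)
    for (ch in 1:3) {
      v <- rgbv[ch] * shade * spec
      img[, , ch][m] <- pmin(pmax(v[m], 0), 1)
    }
    # exact painted extent (pre-occlusion): tight bounds of the mask
    rows <- range(which(rowSums(m) > 0)); colsr <- range(which(colSums(m) > 0))
    bx <- c(colsr[1] - 1, rows[1] - 1, colsr[2], rows[2])
    # overlap with previously painted objects marks THEM occluded later;
    # the occlusion flag here records deliberate overlap placement
    boxes <- rbind(boxes, bx)
    cls <- c(cls, cid)
    occluded <- c(occluded, want_occl)
    placed <- placed + 1L
  }
  if (is.null(boxes)) boxes <- matrix(numeric(0), 0, 4)
  rownames(boxes) <- NULL
  img <- round(img * 255) / 255                        # 8-bit grid, PNG-exact
  labels <- corners_to_yolo(boxes, cls, s, s)
  list(image = img, boxes = boxes, cls = cls, labels = labels, occluded = occluded)
}

#' Write a synthetic dataset to disk
#'
#' Creates `images/{train,val}` PNGs, `labels/{train,val}` YOLO text files
#' and a `data.yaml` listing class names and split directories.
#'
#' @param params a [scene_params()].
#' @param n_train,n_val split sizes.
#' @param out_dir output directory.
#' @param seed base seed; image i of a split uses `seed + i` offsets.
#' @param force overwrite a non-empty existing directory.
#' @return the dataset YAML path, invisibly.
#' @export
generate_dataset <- function(params = scene_params(), n_train = 16, n_val = 4,
                             out_dir, seed = 0, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ", out_dir)
  }
  offs <- list(train = 0L, val = 100000L)
  ns <- list(train = n_train, val = n_val)
  for (split in c("train", "val")) {
    dir.create(file.path(out_dir, "images", split), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", split), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(ns[[split]])) {
      sc <- generate_scene(params, seed = seed + offs[[split]] + i)
      nm <- sprintf("%s_%04d", split, i)
      write_image(sc$image, file.path(out_dir, "images", split, paste0(nm, ".png")))
      write_yolo_labels(sc$labels, file.path(out_dir, "labels", split, paste0(nm, ".txt")))
    }
  }
  ypath <- file.path(out_dir, "data.yaml")
  yaml::write_yaml(list(names = paste0("weed_", seq_len(params$n_classes) - 1L),
                        nc = params$n_classes,
                        train = "images/train", val = "images/val"),
                   ypath)
  invisible(ypath)
}

# ---------------------------------------------------------------------------
# Augmentation: crop/scale, flips, colour jitter.

#' Augmentation parameters
#'
#' @param hflip,vflip flip probabilities.
#' @param scale_range uniform zoom factor range (crop back to original size).
#' @param brightness,contrast,saturation,hue maximal jitter amplitudes.
#' @param min_box_px minimum surviving box side after cropping, pixels.
#' @param min_area_frac minimum surviving fraction of a box's area.
#' @return a list of class `augment_params`.
#' @export
augment_params <- function(hflip = 0.5, vflip = 0.2, scale_range = c(0.8, 1.2),
                           brightness = 0.2, contrast = 0.2, saturation = 0.3,
                           hue = 0.03, min_box_px = 2, min_area_frac = 0.25) {
  structure(as.list(environment()), class = "augment_params")
}

#' Augment a sample
#'
#' Geometric transforms (zoom-crop via nearest-neighbour resampling,
#' horizontal/vertical flips) move boxes together with pixels; boxes are
#' clipped to the crop and dropped when smaller than `min_box_px` a side or
#' below `min_area_frac` of their original area.  Colour jitter rescales
#' brightness/contrast in RGB and saturation/hue in HSV.  The same seed
#' always produces the same output.
#'
#' @param sample list(image, boxes, cls) in pixel corners.
#' @param params an [augment_params()].
#' @param seed integer seed.
#' @return an augmented sample; `attr(, "n_dropped")` counts removed boxes.
#' @export
augment <- function(sample, params = augment_params(), seed = 0) {
  stopifnot(inherits(params, "augment_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  img <- sample$image
  boxes <- sample$boxes
  cls <- sample$cls
  d <- dim(img)
  H <- d[1]; W <- d[2]
  areas0 <- if (nrow(boxes)) (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2]) else numeric(0)
  # zoom and crop back to the original frame
  sc <- stats::runif(1, params$scale_range[1], params$scale_range[2])
  Hs <- max(round(H * sc), 8L); Ws <- max(round(W * sc), 8L)
  ri <- pmin(pmax(ceiling(seq_len(Hs) / sc), 1L), H)
  ci <- pmin(pmax(ceiling(seq_len(Ws) / sc), 1L), W)
  big <- img[ri, ci, , drop = FALSE]
  offy <- if (Hs > H) sample.int(Hs - H + 1L, 1) - 1L else 0L
  offx <- if (Ws > W) sample.int(Ws - W + 1L, 1) - 1L else 0L
  out <- array(0, c(H, W, 3))
  cp_h <- min(H, Hs); cp_w <- min(W, Ws)
  out[seq_len(cp_h), seq_len(cp_w), ] <-
    big[offy + seq_len(cp_h), offx + seq_len(cp_w), , drop = FALSE]
  if (nrow(boxes)) {
    sx <- Ws / W; sy <- Hs / H
    boxes <- cbind(boxes[, 1] * sx - offx, boxes[, 2] * sy - offy,
                   boxes[, 3] * sx - offx, boxes[, 4] * sy - offy)
    boxes <- cbind(pmax(boxes[, 1], 0), pmax(boxes[, 2], 0),
                   pmin(boxes[, 3], W), pmin(boxes[, 4], H))
  }
  img <- out
  # flips
  if (stats::runif(1) < params$hflip) {
    img <- img[, rev(seq_len(W)), , drop = FALSE]
    if (nrow(boxes)) boxes <- cbind(W - boxes[, 3], boxes[, 2], W - boxes[, 1], boxes[, 4])
  }
  if (stats::runif(1) < params$vflip) {
    img <- img[rev(seq_len(H)), , , drop = FALSE]
    if (nrow(boxes)) boxes <- cbind(boxes[, 1], H - boxes[, 4], boxes[, 3], H - boxes[, 2])
  }
  # colour jitter
  img <- img * (1 + stats::runif(1, -params$contrast, params$contrast))
  img <- img + stats::runif(1, -params$brightness, params$brightness)
  img <- pmin(pmax(img, 0), 1)
  if (params$saturation > 0 || params$hue > 0) {
    m <- matrix(aperm(img, c(3, 1, 2)), 3)
    hsvm <- grDevices::rgb2hsv(m, maxColorValue = 1)
    hsvm[1, ] <- (hsvm[1, ] + stats::runif(1, -params$hue, params$hue)) %% 1
    hsvm[2, ] <- pmin(pmax(hsvm[2, ] * (1 + stats::runif(1, -params$saturation,
                                                         params$saturation)), 0), 1)
    rgbm <- grDevices::col2rgb(grDevices::hsv(hsvm[1, ], hsvm[2, ], hsvm[3, ])) / 255
    img <- aperm(array(rgbm, c(3, H, W)), c(2, 3, 1))
  }
  keep <- seq_len(nrow(boxes))
  if (nrow(boxes)) {
    wpx <- boxes[, 3] - boxes[, 1]; hpx <- boxes[, 4] - boxes[, 2]
    area <- wpx * hpx
    keep <- which(wpx >= params$min_box_px & hpx >= params$min_box_px &
                    area >= params$min_area_frac * areas0 * (Ws / W) * (Hs / H))
  }
  res <- list(image = img, boxes = boxes[keep, , drop = FALSE], cls = cls[keep])
  attr(res, "n_dropped") <- nrow(sample$boxes) - length(keep)
  res
}
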