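#' Two-channel ratiometric image container
#'
#' @param red 2-D numeric matrix, F590 (red) channel intensities (>= 0).
#' @param green 2-D numeric matrix, F520 (green) channel, same shape.
#' @param pixel_size Pixel edge length in micrometres (default 1).
#' @return Object of class `ratio_image`.
#' @export
ratio_image <- function(red, green, pixel_size = 1) {
  if (!is.matrix(red) || !is.matrix(green) || !all(dim(red) == dim(green))) {
    abort("red and green must be matrices of identical shape",
          class = "mmpscreen_invalid_input")
  }
  if (any(red < 0) || any(green < 0)) {
    abort("intensities must be >= 0", class = "mmpscreen_invalid_input")
  }
  structure(list(red = red, green = green, pixel_size = pixel_size),
            class = "ratio_image")
}

#' 8-connected component labeling of a binary mask
#'
#' Labels 8-connected foreground components (the ImageJ convention),
#' discarding components smaller than `min_area` pixels. Component labels
#' are assigned in raster order of each component's first pixel.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param min_area Minimum component size in pixels.
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, min_area = 1) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  id_of <- integer(nr * nc)
  id_of[fg] <- seq_along(fg)
  ri <- ((fg - 1L) %% nr) + 1L
  ci <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- ri + off[1]; c2 <- ci + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      edges <- c(edges, rbind(id_of[fg[ok][hit]], id_of[nb[hit]]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep <- sizes[comp] >= min_area
  # renumber surviving components by first (raster-order) pixel
  comp_kept <- comp[keep]
  first_px <- tapply(fg[keep], comp_kept, min)
  new_id <- integer(max(comp))
  new_id[as.integer(names(sort(first_px)))] <- seq_along(first_px)
  lab[fg[keep]] <- new_id[comp_kept]
  lab
}

#' Threshold-based cell segmentation of a two-channel image
#'
#' Thresholds the summed-channel intensity (Otsu by default, or a fixed
#' cutoff) and labels 8-connected foreground components of at least
#' `min_area` pixels as cells.
#'
#' @param image A [ratio_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity cutoff when `method = "fixed"`.
#' @param min_area Minimum cell area in pixels (default 50).
#' @return Integer label matrix (0 = background).
#' @export
segment_cells <- function(image, method = c("otsu", "fixed"),
                          fixed_threshold = NULL, min_area = 50) {
  method <- match.arg(method)
  total <- image$red + image$green
  if (max(total) == 0) {
    warn("no foreground signal: zero cells segmented")
    return(matrix(0L, nrow(total), ncol(total)))
  }
  thr <- if (method == "otsu") {
    scaled <- total / max(total)
    EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * max(total)
  } else {
    if (is.null(fixed_threshold)) {
      abort("fixed_threshold required for method = 'fixed'",
            class = "mmpscreen_invalid_input")
    }
    fixed_threshold
  }
  mask <- total > thr
  lab <- label_components(mask, min_area = min_area)
  if (max(lab) == 0) warn("no foreground components above min_area")
  lab
}

#' Per-cell F590/F520 ratio and image mean
#'
#' For each labeled cell the ratio is computed as mean(red) / mean(green)
#' over the cell's pixels (ratio of means, robust to near-zero green
#' pixels); the image summary is the unweighted mean of per-cell ratios,
#' mirroring per-image averaging of confirmatory confocal fields. Cells
#' whose green mean is not positive are excluded with a message.
#'
#' @param image A [ratio_image()].
#' @param labels Integer label matrix aligned with the image.
#' @return Object of class `cell_segmentation`: `labels`, `n_cells`,
#'   `per_cell` (tibble `label`, `area`, `ratio`), `image_mean`.
#' @export
per_cell_ratio <- function(image, labels) {
  if (!all(dim(labels) == dim(image$red))) {
    abort("labels not aligned with image", class = "mmpscreen_invalid_input")
  }
  ids <- sort(unique(labels[labels > 0]))
  rows <- purrr::map(ids, function(id) {
    px <- labels == id
    g <- mean(image$green[px])
    if (!is.finite(g) || g <= 0) {
      inform(sprintf("cell %d excluded: non-positive green mean", id))
      return(NULL)
    }
    tibble(label = id, area = sum(px), ratio = mean(image$red[px]) / g)
  })
  per_cell <- bind_rows(rows)
  structure(list(
    labels = labels,
    n_cells = nrow(per_cell),
    per_cell = per_cell,
    image_mean = if (nrow(per_cell)) mean(per_cell$ratio) else NA_real_
  ), class = "cell_segmentation")
}

#' Mitochondrial morphometry from a binary mask
#'
#' Labels 8-connected objects of at least `min_area` pixels and computes,
#' per object: area (pixel count), perimeter (boundary polygon length from
#' Moore-neighbor tracing through pixel centers, diagonal steps weighted
#' sqrt(2)), major/minor axis lengths (4 * sqrt of the eigenvalues of the
#' second central moment matrix of the pixel set, with the 1/12
#' finite-pixel term so that one-pixel-wide objects keep a positive minor
#' axis), aspect ratio AR = major/minor, and form factor
#' FF = perimeter^2 / (4 pi area). Under these definitions a circle has
#' FF = 1 and elongated or complex outlines have larger FF, so
#' mitochondrial fragmentation lowers both AR and FF.
#'
#' @param mask Logical or 0/1 matrix.
#' @param min_area Minimum object size in pixels (default 4).
#' @param pixel_size Pixel edge length in micrometres (default 1); areas
#'   in micrometres^2 are reported alongside pixel units.
#' @return Tibble with one row per object: `label`, `area`, `area_um2`,
#'   `perimeter`, `major_axis`, `minor_axis`, `aspect_ratio`,
#'   `form_factor`.
#' @export
label_mitochondria <- function(mask, min_area = 4, pixel_size = 1) {
  lab <- label_components(mask, min_area = min_area)
  ids <- seq_len(max(lab))
  if (length(ids) == 0) {
    return(tibble(label = integer(), area = integer(), area_um2 = numeric(),
                  perimeter = numeric(), major_axis = numeric(),
                  minor_axis = numeric(), aspect_ratio = numeric(),
                  form_factor = numeric()))
  }
  purrr::map_dfr(ids, function(id) {
    px <- which(lab == id)
    r <- ((px - 1L) %% nrow(lab)) + 1L
    c <- ((px - 1L) %/% nrow(lab)) + 1L
    ax <- moment_axes(r, c)
    per <- trace_perimeter(lab == id)
    area <- length(px)
    tibble(label = id, area = area, area_um2 = area * pixel_size^2,
           perimeter = per,
           major_axis = ax$major, minor_axis = ax$minor,
           aspect_ratio = ax$major / ax$minor,
           form_factor = per^2 / (4 * pi * area))
  })
}

# Axis lengths from second central moments of the pixel set. The 1/12
# per-axis term is the variance of a unit pixel, keeping minor axes of
# single-pixel-wide objects positive.
moment_axes <- function(r, c) {
  mu20 <- mean((r - mean(r))^2) + 1 / 12
  mu02 <- mean((c - mean(c))^2) + 1 / 12
  mu11 <- mean((r - mean(r)) * (c - mean(c)))
  tr <- mu20 + mu02
  det_root <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  lambda <- c((tr + det_root) / 2, (tr - det_root) / 2)
  list(major = 4 * sqrt(lambda[1]), minor = 4 * sqrt(lambda[2]))
}

# Moore-neighbor boundary tracing; returns the closed polygon length
# through boundary pixel centers (steps of 1 or sqrt(2)). The walk is a
# deterministic function of the (pixel, backtrack-direction) state, so the
# closed boundary is the cycle between the first repeated state. Single
# pixels use the unit-square convention P = 4.
trace_perimeter <- function(obj) {
  px <- which(obj)
  if (length(px) == 1) return(4)
  nr <- nrow(obj)
  m <- matrix(FALSE, nr + 2, ncol(obj) + 2) # 1-pixel pad
  m[2:(nr + 1), 2:(ncol(obj) + 1)] <- obj
  start_r <- ((px[1] - 1L) %% nr) + 2L
  start_c <- ((px[1] - 1L) %/% nr) + 2L
  # Moore neighborhood, clockwise from W (image coords: rows grow down)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  steps <- sqrt(dr^2 + dc^2)
  cur_r <- start_r; cur_c <- start_c
  b <- 1L # W neighbor of the raster-order first pixel is background
  total <- 0
  corners <- 0L
  last_move <- NA_integer_
  len_at <- new.env(parent = emptyenv())
  assign(paste(cur_r, cur_c, b), c(0, 0), envir = len_at)
  repeat {
    idx <- NA_integer_
    for (k in 1:8) {
      cand <- ((b + k - 2L) %% 8L) + 1L
      if (m[cur_r + dr[cand], cur_c + dc[cand]]) { idx <- cand; break }
    }
    if (is.na(idx)) return(4) # no foreground neighbor (defensive)
    prev_idx <- ((b + k - 3L) %% 8L) + 1L # last background checked
    r2 <- cur_r + dr[idx]; c2 <- cur_c + dc[idx]
    total <- total + steps[idx]
    if (!is.na(last_move) && idx != last_move) corners <- corners + 1L
    last_move <- idx
    b <- which(dr == cur_r + dr[prev_idx] - r2 &
               dc == cur_c + dc[prev_idx] - c2)
    cur_r <- r2; cur_c <- c2
    key <- paste(cur_r, cur_c, b)
    if (exists(key, envir = len_at, inherits = FALSE)) {
      st <- get(key, envir = len_at)
      # corner correction: a polygon through pixel centers overshoots a
      # smooth boundary at every direction change (Vossepoel-Smeulders
      # corner term); 0.091 per corner restores near-unbiased lengths for
      # smooth outlines while leaving straight-edged shapes almost exact
      return(max(total - st[1] - 0.091 * (corners - st[2]), 1))
    }
    assign(key, c(total, corners), envir = len_at)
  }
}

#' Summary statistics over a set of mitochondrial objects
#'
#' @param objects Tibble from [label_mitochondria()].
#' @return List with `mean_ar`, `mean_ff`, `n_objects`.
#' @export
morphology_summary <- function(objects) {
  if (nrow(objects) == 0) {
    abort("no objects: morphology summary undefined",
          class = "mmpscreen_undefined_summary")
  }
  list(mean_ar = mean(objects$aspect_ratio),
       mean_ff = mean(objects$form_factor),
       n_objects = nrow(objects))
}

#' Read a two-channel ratio image from TIFF
#'
#' Accepts either a single two-page TIFF (page 1 = red/F590, page 2 =
#' green/F520) or two single-channel TIFF paths.
#'
#' @param red_path Path to the red-channel (or two-page) TIFF.
#' @param green_path Optional path to the green-channel TIFF.
#' @param pixel_size Micrometres per pixel.
#' @return A [ratio_image()].
#' @export
read_ratio_tiff <- function(red_path, green_path = NULL, pixel_size = 1) {
  if (is.null(green_path)) {
    pages <- tiff::readTIFF(red_path, all = TRUE)
    if (length(pages) < 2) {
      abort("two-page TIFF expected when green_path is missing",
            class = "mmpscreen_parse_error")
    }
    ratio_image(pages[[1]], pages[[2]], pixel_size)
  } else {
    ratio_image(tiff::readTIFF(red_path), tiff::readTIFF(green_path),
                pixel_size)
  }
}

#' Write a two-channel ratio image as a two-page TIFF
#'
#' Both channels are stored as 32-bit floats rescaled by their joint
#' maximum into [0, 1] (the storage contract of the TIFF writer). The
#' common rescaling leaves every ratiometric quantity unchanged.
#'
#' @param image A [ratio_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_tiff <- function(image, path) {
  s <- max(image$red, image$green, 1e-12)
  tiff::writeTIFF(list(image$red / s, image$green / s), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Read a binary mask TIFF
#'
#' @param path Path to the mask TIFF; any positive pixel is foreground.
#' @return Logical matrix.
#' @export
read_mask_tiff <- function(path) {
  tiff::readTIFF(path) > 0
}
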