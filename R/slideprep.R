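# Slide preprocessing: tissue segmentation (a deterministic saturation /
# Otsu stand-in for a trained pixel classifier), control-region exclusion,
# grid tessellation into fixed-size tiles, and the capped random tile
# sampler used during training and validation.

#' Tissue mask container
#'
#' A binary grid at a stated downsample factor: grid cell (r, c) covers the
#' full-resolution pixel block
#' `[(c-1)*downsample, c*downsample) x [(r-1)*downsample, r*downsample)`.
#'
#' @param grid binary (0/1 or logical) matrix.
#' @param downsample positive integer downsample factor.
#' @return object of class `tissue_mask`.
#' @export
tissue_mask <- function(grid, downsample = 1L) {
  if (!is.matrix(grid)) stopf("grid must be a matrix")
  if (!all(grid %in% c(0, 1))) stopf("grid values must be 0/1")
  if (!is_count(downsample) || downsample < 1) stopf("downsample must be a positive integer")
  structure(list(grid = matrix(as.integer(grid), nrow(grid)),
                 downsample = as.integer(downsample)),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("Tissue mask: %d x %d grid at downsample %d (%.1f%% tissue)\n",
              nrow(x$grid), ncol(x$grid), x$downsample, 100 * mean(x$grid)))
  invisible(x)
}

slide_dims <- function(mask) dim(mask$grid) * mask$downsample

#' Segment tissue from a slide image
#'
#' Deterministic stand-in for a trained pixel classifier: tissue is where
#' the HSV saturation channel exceeds an Otsu-chosen threshold, followed by
#' removal of small connected components. On a degenerate (near-constant)
#' saturation channel a fixed threshold of 0.05 is used, so uniform white
#' images yield an empty mask and uniformly stained images a full one.
#'
#' @param image RGB array (height x width x 3, values in `[0, 1]`).
#' @param downsample store the mask at this downsample factor (block
#'   majority vote).
#' @param min_object_px connected components smaller than this many
#'   full-resolution pixels are removed.
#' @return a [tissue_mask()].
#' @export
segment_tissue <- function(image, downsample = 1L, min_object_px = 64L) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) stopf("image must be RGB")
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  sat <- ifelse(mx > 1e-8, (mx - mn) / mx, 0)
  thr <- if (diff(range(sat)) < 0.02) 0.05 else
    EBImage::otsu(sat, range = c(0, 1), levels = 256)
  bin <- sat > thr
  if (any(bin) && min_object_px > 0) {
    lab <- EBImage::bwlabel(bin)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    bin <- matrix(lab %in% keep, nrow(bin))
  }
  if (downsample == 1L) return(tissue_mask(bin * 1L, 1L))
  h <- nrow(bin); w <- ncol(bin)
  gh <- ceiling(h / downsample); gw <- ceiling(w / downsample)
  grid <- matrix(0L, gh, gw)
  for (r in seq_len(gh)) {
    rr <- ((r - 1) * downsample + 1):min(r * downsample, h)
    for (c in seq_len(gw)) {
      cc <- ((c - 1) * downsample + 1):min(c * downsample, w)
      grid[r, c] <- as.integer(mean(bin[rr, cc]) >= 0.5)
    }
  }
  tissue_mask(grid, downsample)
}

#' Exclude regions (e.g. control-tissue cores) from a tissue mask
#'
#' Zeroes the mask inside each region. Any grid cell whose pixel block
#' intersects a region is cleared (conservative exclusion). The operation is
#' idempotent, and applying regions sequentially equals applying their
#' union.
#'
#' @param mask a [tissue_mask()].
#' @param regions data.frame/matrix with columns `x0`, `y0`, `width`,
#'   `height` in full-resolution 0-based pixel coordinates; may have zero
#'   rows.
#' @return the modified `tissue_mask`.
#' @export
exclude_regions <- function(mask, regions) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (is.null(regions) || NROW(regions) == 0) return(mask)
  regions <- as.matrix(as.data.frame(regions)[, c("x0", "y0", "width", "height")])
  dims <- slide_dims(mask)  # (H, W)
  ds <- mask$downsample
  for (i in seq_len(nrow(regions))) {
    b <- regions[i, ]
    if (b["x0"] < 0 || b["y0"] < 0 ||
        b["x0"] + b["width"] > dims[2] || b["y0"] + b["height"] > dims[1]) {
      stopf("region %d outside slide bounds", i)
    }
    r0 <- floor(b["y0"] / ds) + 1
    r1 <- ceiling((b["y0"] + b["height"]) / ds)
    c0 <- floor(b["x0"] / ds) + 1
    c1 <- ceiling((b["x0"] + b["width"]) / ds)
    mask$grid[r0:r1, c0:c1] <- 0L
  }
  mask
}

integral_image <- function(m) {
  cs <- apply(m, 2, cumsum)
  t(apply(rbind(0, cs), 1, function(r) c(0, cumsum(r))))
}

block_sum <- function(I, r0, r1, c0, c1) {
  # sum of m[r0:r1, c0:c1] given integral image I (1-padded)
  I[r1 + 1, c1 + 1] - I[r0, c1 + 1] - I[r1 + 1, c0] + I[r0, c0]
}

#' Tessellate a tissue mask into fixed-size tiles
#'
#' Lays a non-overlapping grid of `tile_size`-pixel tiles anchored at the
#' slide origin (0, 0) with stride `tile_size`; partial edge tiles are
#' dropped. A tile is kept iff the fraction of its pixels inside the mask is
#' at least `min_coverage`. Coordinates are 0-based and half-open, matching
#' the heatmap-rendering convention.
#'
#' @param mask a [tissue_mask()].
#' @param tile_size tile edge in full-resolution pixels (default 224, the
#'   tile size used at x10 magnification, about 1 micron per pixel).
#' @param min_coverage minimum masked-pixel fraction in `(0, 1]`
#'   (default 0.5).
#' @return data.frame of tile boxes (`x0`, `y0`, `width`, `height`) with
#'   attribute `level = "10x"`.
#' @export
tessellate <- function(mask, tile_size = 224L, min_coverage = 0.5) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (tile_size < 1) stopf("tile_size must be >= 1")
  if (!(min_coverage > 0 && min_coverage <= 1)) stopf("min_coverage must be in (0, 1]")
  dims <- slide_dims(mask)
  if (dims[1] < tile_size || dims[2] < tile_size) stopf("mask smaller than one tile")
  ds <- mask$downsample
  grid <- mask$grid
  if (ds > 1) {
    if (prod(dim(grid)) * ds^2 > 6.4e7) {
      stopf("mask too large to expand; store it at a finer downsample")
    }
    grid <- grid[rep(seq_len(nrow(grid)), each = ds),
                 rep(seq_len(ncol(grid)), each = ds)]
    grid <- grid[seq_len(dims[1]), seq_len(dims[2])]
  }
  I <- integral_image(grid)
  n_tx <- floor(dims[2] / tile_size)
  n_ty <- floor(dims[1] / tile_size)
  area <- tile_size^2
  out <- list()
  for (ty in seq_len(n_ty) - 1L) {
    for (tx in seq_len(n_tx) - 1L) {
      s <- block_sum(I, ty * tile_size + 1, (ty + 1) * tile_size,
                     tx * tile_size + 1, (tx + 1) * tile_size)
      if (s / area >= min_coverage) {
        out[[length(out) + 1L]] <- c(tx * tile_size, ty * tile_size)
      }
    }
  }
  boxes <- if (length(out)) {
    do.call(rbind, out)
  } else {
    matrix(integer(0), 0, 2)
  }
  res <- data.frame(x0 = boxes[, 1], y0 = boxes[, 2],
                    width = rep(as.integer(tile_size), nrow(boxes)),
                    height = rep(as.integer(tile_size), nrow(boxes)))
  attr(res, "level") <- "10x"
  res
}

#' Capped random tile sampling
#'
#' During training and validation at most `max_n` tiles per slide are used:
#' if the slide has `n_tiles <= max_n` tiles all indices are returned,
#' otherwise a uniform random subset of size `max_n` without replacement.
#' In `"test"` mode all tiles are always used, enforcing the full-tile
#' inference contract by flag rather than caller discipline.
#'
#' @param n_tiles number of tiles available (>= 1).
#' @param max_n cap (default 500).
#' @param seed optional integer seed making the draw reproducible per
#'   (seed, epoch, case).
#' @param mode `"train"` (capped) or `"test"` (all tiles).
#' @return sorted integer index vector.
#' @export
sample_tiles <- function(n_tiles, max_n = 500L, seed = NULL,
                         mode = c("train", "test")) {
  mode <- match.arg(mode)
  if (!is_count(n_tiles) || n_tiles < 1) stopf("n_tiles must be >= 1")
  if (!is_count(max_n) || max_n < 1) stopf("max_n must be >= 1")
  if (mode == "test" || n_tiles <= max_n) return(seq_len(n_tiles))
  with_seed(seed, sort(sample.int(n_tiles, max_n)))
}
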