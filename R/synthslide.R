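# Synthetic slide rendering: small H&E-like / IHC-like image pairs with a
# ground-truth tissue mask, used to exercise the full image path
# (segmentation -> tessellation -> encoding) without real slides. No attempt
# is made to emulate real histology texture statistics.

slide_palette <- list(
  he = list(tissue = c(0.82, 0.58, 0.72), signal = c(0.55, 0.25, 0.50)),
  ihc = list(tissue = c(0.72, 0.58, 0.45), signal = c(0.45, 0.25, 0.10))
)

rect_blob <- function(x0, y0, width, height) {
  list(type = "rect", x0 = x0, y0 = y0, width = width, height = height)
}

ellipse_blob <- function(cx, cy, rx, ry) {
  list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry)
}

blob_mask <- function(blob, h, w) {
  # pixel (row r, col c) has 0-based centre (x, y) = (c - 0.5, r - 0.5)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  if (blob$type == "rect") {
    (xs >= blob$x0) & (xs < blob$x0 + blob$width) &
      (ys >= blob$y0) & (ys < blob$y0 + blob$height)
  } else {
    ((xs - blob$cx) / blob$rx)^2 + ((ys - blob$cy) / blob$ry)^2 <= 1
  }
}

#' Render a synthetic H&E/IHC slide pair
#'
#' Paints tissue blobs on a white background for both stain modalities and
#' overlays a distinct high-frequency texture on "signal" tiles (tiles a
#' positive slide would carry biomarker-associated morphology on). A
#' ground-truth binary tissue mask is returned alongside, so segmentation
#' quality can be scored.
#'
#' @param dims image (height, width) in pixels; must hold at least one tile.
#' @param blobs optional list of [rect_blob()] / [ellipse_blob()] specs; when
#'   `NULL`, `n_blobs` random ellipses are placed.
#' @param n_blobs number of random tissue blobs when `blobs` is `NULL`.
#'   `n_blobs = 0` gives an all-white slide with an empty mask.
#' @param tile_size tile edge in pixels (default 224).
#' @param positive logical; plant signal-tile texture?
#' @param signal_fraction fraction of tissue tiles receiving signal texture.
#' @param seed integer seed; identical arguments reproduce identical pixels.
#' @return object of class `synthetic_slide`: list with RGB arrays `he`,
#'   `ihc` (height x width x 3 in `[0, 1]`), binary `mask`, binary `signal`
#'   (pixel map of signal tiles), and `signal_tiles` (tile boxes).
#' @export
render_synthetic_slide <- function(dims = c(896, 896), blobs = NULL,
                                   n_blobs = 3, tile_size = 224L,
                                   positive = TRUE, signal_fraction = 0.3,
                                   seed = 1L) {
  h <- dims[1]; w <- dims[2]
  if (h < tile_size || w < tile_size) stopf("dims smaller than one tile")
  with_seed(seed, {
    if (is.null(blobs)) {
      blobs <- replicate(n_blobs, {
        ellipse_blob(cx = stats::runif(1, 0.15, 0.85) * w,
                     cy = stats::runif(1, 0.15, 0.85) * h,
                     rx = stats::runif(1, 0.12, 0.3) * w,
                     ry = stats::runif(1, 0.12, 0.3) * h)
      }, simplify = FALSE)
    }
    mask <- matrix(FALSE, h, w)
    for (b in blobs) mask <- mask | blob_mask(b, h, w)

    # signal tiles: grid tiles with >= 50% tissue
    n_tx <- floor(w / tile_size); n_ty <- floor(h / tile_size)
    tiles <- expand.grid(tx = seq_len(n_tx) - 1L, ty = seq_len(n_ty) - 1L)
    cover <- mapply(function(tx, ty) {
      mean(mask[ty * tile_size + seq_len(tile_size),
                tx * tile_size + seq_len(tile_size)])
    }, tiles$tx, tiles$ty)
    tissue_tiles <- which(cover >= 0.5)
    sig_tiles <- integer(0)
    if (positive && length(tissue_tiles) > 0) {
      n_sig <- max(1L, round(signal_fraction * length(tissue_tiles)))
      sig_tiles <- sort(sample(tissue_tiles, n_sig))
    }
    signal <- matrix(FALSE, h, w)
    checker <- outer(seq_len(tile_size), seq_len(tile_size),
                     function(r, c) ((r - 1) %/% 8 + (c - 1) %/% 8) %% 2 == 0)
    for (k in sig_tiles) {
      rr <- tiles$ty[k] * tile_size + seq_len(tile_size)
      cc <- tiles$tx[k] * tile_size + seq_len(tile_size)
      signal[rr, cc] <- mask[rr, cc]
    }

    render <- function(pal) {
      img <- array(1, dim = c(h, w, 3))
      speckle <- matrix(stats::rnorm(h * w, 0, 0.03), h, w)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- pal$tissue[ch] + speckle[mask]
        img[, , ch] <- plane
      }
      for (k in sig_tiles) {
        rr <- tiles$ty[k] * tile_size + seq_len(tile_size)
        cc <- tiles$tx[k] * tile_size + seq_len(tile_size)
        sub_mask <- mask[rr, cc]
        for (ch in 1:3) {
          plane <- img[rr, cc, ch]
          target <- pal$signal[ch] + 0.12 * (checker - 0.5)
          plane[sub_mask] <- target[sub_mask]
          img[rr, cc, ch] <- plane
        }
      }
      pmin(pmax(img, 0), 1)
    }

    sig_boxes <- if (length(sig_tiles)) {
      cbind(x0 = tiles$tx[sig_tiles] * tile_size,
            y0 = tiles$ty[sig_tiles] * tile_size,
            width = tile_size, height = tile_size)
    } else {
      matrix(integer(0), 0, 4, dimnames = list(NULL, c("x0", "y0", "width", "height")))
    }
    structure(list(he = render(slide_palette$he),
                   ihc = render(slide_palette$ihc),
                   mask = mask * 1L, signal = signal * 1L,
                   signal_tiles = sig_boxes, tile_size = tile_size),
              class = "synthetic_slide")
  })
}

#' Write a synthetic slide pair to PNG files
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisibly, the written paths.
#' @export
write_slide_png <- function(slide, dir, stem = "slide") {
  stopifnot(inherits(slide, "synthetic_slide"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(stem, c("_he.png", "_ihc.png", "_mask.png")))
  png::writePNG(slide$he, paths[1])
  png::writePNG(slide$ihc, paths[2])
  png::writePNG(slide$mask, paths[3])
  invisible(paths)
}

#' Cut a slide image into tile images
#'
#' @param image RGB array.
#' @param tile_boxes data.frame or matrix with columns x0, y0, width, height
#'   (0-based pixel coordinates).
#' @return list of tile arrays in box order.
#' @export
extract_tiles <- function(image, tile_boxes) {
  boxes <- as.matrix(tile_boxes[, c("x0", "y0", "width", "height")])
  lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    image[b["y0"] + seq_len(b["height"]), b["x0"] + seq_len(b["width"]), ,
          drop = FALSE]
  })
}
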