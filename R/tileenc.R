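# Tile-encoder contract and embedding-bag container. The encoder is a
# pluggable function mapping tile images to fixed-width embedding rows; any
# external pretrained histopathology encoder with the same contract can be
# dropped in. The package ships a deterministic toy encoder (handcrafted
# colour/texture statistics under a fixed random projection) so the pipeline
# runs at desk scale without downloaded weights.

#' Embedding bag: the multiple-instance unit
#'
#' A per-slide `N x width` matrix of tile embeddings with aligned tile
#' coordinates, the stain modality, and scanner/site metadata.
#'
#' @param case_id case identifier.
#' @param modality `"HE"` or `"IHC"`.
#' @param embeddings numeric matrix, one row per tile, all values finite.
#' @param tile_boxes matrix/data.frame with columns x0, y0, width, height,
#'   one row per tile.
#' @param scanner,site categorical metadata.
#' @return object of class `embedding_bag`.
#' @export
embedding_bag <- function(case_id, modality = c("HE", "IHC"), embeddings,
                          tile_boxes, scanner = NA_character_,
                          site = NA_character_) {
  modality <- match.arg(modality)
  if (!is.matrix(embeddings) || nrow(embeddings) < 1) {
    stopf("embeddings must be a matrix with at least one row")
  }
  if (!all(is.finite(embeddings))) stopf("embeddings must be finite")
  boxes <- as.matrix(as.data.frame(tile_boxes)[, c("x0", "y0", "width", "height")])
  if (nrow(boxes) != nrow(embeddings)) {
    stopf("tile_boxes rows (%d) must match embedding rows (%d)",
          nrow(boxes), nrow(embeddings))
  }
  structure(list(case_id = case_id, modality = modality,
                 embeddings = embeddings, tile_boxes = boxes,
                 scanner = scanner, site = site),
            class = "embedding_bag")
}

#' @export
print.embedding_bag <- function(x, ...) {
  cat(sprintf("Embedding bag %s [%s]: %d tiles x %d dims (scanner %s, site %s)\n",
              x$case_id, x$modality, nrow(x$embeddings), ncol(x$embeddings),
              x$scanner, x$site))
  invisible(x)
}

validate_bag <- function(bag, width = NULL) {
  if (!inherits(bag, "embedding_bag")) stopf("not an embedding_bag")
  if (is.null(bag$embeddings) || is.null(bag$tile_boxes)) {
    stopf("bag missing embeddings or tile_boxes")
  }
  if (nrow(bag$embeddings) < 1) stopf("empty bag")
  if (nrow(bag$embeddings) != nrow(bag$tile_boxes)) {
    stopf("bag schema error: %d embedding rows vs %d tile boxes",
          nrow(bag$embeddings), nrow(bag$tile_boxes))
  }
  if (!all(is.finite(bag$embeddings))) stopf("non-finite values in bag")
  if (!is.null(width) && ncol(bag$embeddings) != width) {
    stopf("bag width %d does not match expected %d", ncol(bag$embeddings), width)
  }
  invisible(bag)
}

#' Save / load an embedding bag
#'
#' Bags are serialized with base-R RDS; [load_bag()] re-validates the schema
#' (row/box alignment, finiteness, optional width) so a corrupt file errors
#' rather than yielding a malformed bag. [write_bag_csv()] exports the same
#' content as two plain CSV files for interchange.
#'
#' @param bag an `embedding_bag`.
#' @param path file path.
#' @param width expected embedding width to enforce on load (optional).
#' @return `load_bag` returns the validated bag.
#' @export
save_bag <- function(bag, path) {
  validate_bag(bag)
  saveRDS(bag, path)
  invisible(path)
}

#' @rdname save_bag
#' @export
load_bag <- function(path, width = NULL) {
  bag <- readRDS(path)
  validate_bag(bag, width)
  bag
}

#' @rdname save_bag
#' @param dir directory for the CSV export.
#' @export
write_bag_csv <- function(bag, dir) {
  validate_bag(bag)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(bag$case_id, "_", bag$modality))
  utils::write.csv(as.data.frame(bag$embeddings),
                   paste0(stem, "_embeddings.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bag$tile_boxes),
                   paste0(stem, "_boxes.csv"), row.names = FALSE)
  invisible(stem)
}

# Handcrafted per-tile statistics: per-channel 8-bin histograms, means, sds,
# gradient energy, and a grey-level second moment. 34 features total.
tile_features <- function(tile) {
  feats <- numeric(0)
  for (ch in 1:3) {
    plane <- pmin(pmax(tile[, , ch], 0), 1)
    feats <- c(feats,
               as.numeric(graphics::hist(plane, breaks = seq(0, 1, length.out = 9),
                                         plot = FALSE)$counts) / length(plane),
               mean(plane), stats::sd(plane),
               mean(abs(diff(plane))) + mean(abs(t(diff(t(plane))))))
  }
  grey <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
  feats <- c(feats, mean((grey - mean(grey))^2))
  feats
}

#' Deterministic toy tile encoder
#'
#' Computes handcrafted colour and texture statistics per tile and projects
#' them to `dim` dimensions with a fixed seeded Gaussian random matrix. The
#' encoder is deterministic, separates the synthetic tissue/signal textures
#' linearly, and honours the encoder contract (fixed output width, row order
#' preserved). It is a desk-scale default, not a learned representation.
#'
#' @param dim output embedding width (default 768).
#' @param projection_seed seed of the fixed projection matrix.
#' @return a function `f(tiles)` mapping a list of RGB tile arrays to an
#'   `N x dim` matrix.
#' @export
toy_tile_encoder <- function(dim = 768L, projection_seed = 768L) {
  n_feat <- 34L
  P <- with_seed(projection_seed,
                 matrix(stats::rnorm(n_feat * dim, 0, 1 / sqrt(n_feat)),
                        n_feat, dim))
  function(tiles) {
    feats <- t(vapply(tiles, tile_features, numeric(n_feat)))
    feats %*% P
  }
}

#' Encode tile images into an embedding bag
#'
#' @param tiles list of RGB tile arrays, all of identical square geometry.
#' @param tile_boxes tile boxes aligned with `tiles`.
#' @param case_id,modality,scanner,site bag metadata.
#' @param encoder a function mapping a list of tiles to an `N x width`
#'   matrix (default [toy_tile_encoder()]).
#' @return an [embedding_bag()] with one row per tile, order preserved.
#' @export
encode_tiles <- function(tiles, tile_boxes, case_id = "case",
                         modality = c("HE", "IHC"),
                         encoder = toy_tile_encoder(),
                         scanner = NA_character_, site = NA_character_) {
  modality <- match.arg(modality)
  if (length(tiles) < 1) stopf("no tiles to encode")
  dims <- vapply(tiles, function(t) dim(t)[1:2], numeric(2))
  if (any(dims != dims[1, 1])) stopf("all tiles must share the same square geometry")
  emb <- encoder(tiles)
  if (!is.matrix(emb) || nrow(emb) != length(tiles)) {
    stopf("encoder must return one row per tile")
  }
  if (!all(is.finite(emb))) stopf("encoder returned non-finite values")
  embedding_bag(case_id, modality, emb, tile_boxes, scanner, site)
}
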