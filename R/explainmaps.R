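# Explainability: attention rollout over the recorded self-attention
# tensors, per-tile classification scores from single-tile forward passes,
# contribution (attention x classification) maps, and heatmap rendering
# back onto slide coordinates.

#' Attention rollout
#'
#' Attributes the class-token output to input tiles by averaging each
#' layer's heads to a single row-stochastic matrix and recursively
#' multiplying the layer matrices in order. The class-token row of the
#' product, restricted to tile columns and renormalised to sum to one, is
#' the per-tile attention score. With a single layer this reduces to the
#' class-token attention row itself. If the class token retains essentially
#' all mass (e.g. identity attention), uniform scores are returned with a
#' warning.
#'
#' @param per_layer_attention list over layers of `heads x tokens x tokens`
#'   arrays (token 1 is the class token), as recorded in a `forward_trace`.
#' @param tol tolerance for the row-stochasticity check.
#' @return numeric vector of per-tile scores summing to 1.
#' @export
attention_rollout <- function(per_layer_attention, tol = 1e-4) {
  if (length(per_layer_attention) == 0) stopf("no attention recorded")
  R <- NULL
  for (A in per_layer_attention) {
    M <- apply(A, c(2, 3), mean)  # head average
    if (any(abs(rowSums(M) - 1) > tol) || any(M < -tol)) {
      stopf("attention rows must be stochastic")
    }
    R <- if (is.null(R)) M else M %*% R
  }
  if (any(abs(rowSums(R) - 1) > 1e-6)) {
    stopf("rollout product lost row-stochasticity")
  }
  tile_mass <- R[1, -1]
  if (sum(tile_mass) < 1e-8) {
    warning("class token retained all attention mass; returning uniform scores")
    return(rep(1 / length(tile_mass), length(tile_mass)))
  }
  tile_mass / sum(tile_mass)
}

#' Per-tile classification scores
#'
#' Scores each tile by running it alone through the trained model in the
#' bag's modality mode: the output probability of a single-tile bag is the
#' tile's classification score.
#'
#' @param object a `duonet` or `duonet_fit`.
#' @param bag an [embedding_bag()].
#' @return numeric vector of probabilities, one per tile.
#' @export
per_tile_classification <- function(object, bag) {
  model <- if (inherits(object, "duonet_fit")) object$model else object
  validate_bag(bag, width = model$config$embed_dim_in)
  mode <- if (bag$modality == "HE") "HE_ONLY" else "IHC_ONLY"
  X <- bag$embeddings
  vapply(seq_len(nrow(X)), function(i) {
    row <- X[i, , drop = FALSE]
    if (mode == "HE_ONLY") {
      duonet_forward(model, he = row, mode = mode)$probability
    } else {
      duonet_forward(model, ihc = row, mode = mode)$probability
    }
  }, numeric(1))
}

# Display normalisation: percentile clipping then min-max to [0, 1].
# Constant vectors normalise to zero with a flag instead of NaN.
norm01 <- function(x, clip = c(0.01, 0.99)) {
  q <- stats::quantile(x, clip, names = FALSE)
  x <- pmin(pmax(x, q[1]), q[2])
  rng <- diff(range(x))
  if (rng < 1e-12) {
    structure(rep(0, length(x)), constant = TRUE)
  } else {
    structure((x - min(x)) / rng, constant = FALSE)
  }
}

#' Contribution map: attention x classification
#'
#' The raw contribution of a tile is the elementwise product of its
#' attention-rollout score and its single-tile classification score. For
#' display, each channel (attention, classification, contribution) is
#' independently normalised to `[0, 1]` by min-max after clipping at the
#' 1st/99th percentile; constant channels map to zero and are flagged.
#'
#' @param attention_scores raw per-tile attention (e.g. from
#'   [attention_rollout()]).
#' @param classification_scores per-tile probabilities (same length).
#' @param tile_boxes aligned tile boxes.
#' @param case_id,modality metadata.
#' @param clip clipping percentiles for display normalisation.
#' @return object of class `attention_map`: data.frame with raw and
#'   display-normalised channels, plus tile coordinates; constant-channel
#'   flags are kept in the `"constant"` attribute.
#' @export
contribution_map <- function(attention_scores, classification_scores,
                             tile_boxes, case_id = NA_character_,
                             modality = NA_character_, clip = c(0.01, 0.99)) {
  if (length(attention_scores) != length(classification_scores)) {
    stopf("attention and classification score lengths differ")
  }
  boxes <- as.data.frame(tile_boxes)[, c("x0", "y0", "width", "height")]
  if (nrow(boxes) != length(attention_scores)) {
    stopf("tile_boxes must align with scores")
  }
  raw <- attention_scores * classification_scores
  a <- norm01(attention_scores, clip)
  c_ <- norm01(classification_scores, clip)
  k <- norm01(raw, clip)
  out <- data.frame(boxes,
                    attention_raw = attention_scores,
                    classification_raw = classification_scores,
                    contribution_raw = raw,
                    attention = as.numeric(a),
                    classification = as.numeric(c_),
                    contribution = as.numeric(k))
  structure(out, class = c("attention_map", "data.frame"),
            case_id = case_id, modality = modality,
            constant = c(attention = attr(a, "constant"),
                         classification = attr(c_, "constant"),
                         contribution = attr(k, "constant")))
}

# Perceptually ordered low-purple to high-yellow ramp (viridis anchors).
heat_ramp <- grDevices::colorRamp(
  c("#440154", "#3B528B", "#21918C", "#5EC962", "#FDE725"))

#' Render a heatmap PNG from an attention map
#'
#' Paints each tile box with its (display-normalised) score under a
#' yellow-high / purple-low colormap on a white background and writes a
#' PNG. Tile boxes are 0-based, half-open pixel rectangles; the
#' tessellation invariant guarantees disjointness, and overlapping boxes
#' are reported as an error.
#'
#' @param map an [contribution_map()] result (or compatible data.frame).
#' @param slide_dims (height, width) of the canvas in pixels.
#' @param file output PNG path.
#' @param channel which score channel to paint.
#' @param scale optional integer downscale factor for the canvas.
#' @return invisibly, the file path.
#' @export
render_heatmap <- function(map, slide_dims, file,
                           channel = c("contribution", "attention",
                                       "classification"),
                           scale = 1L) {
  channel <- match.arg(channel)
  h <- ceiling(slide_dims[1] / scale)
  w <- ceiling(slide_dims[2] / scale)
  img <- array(1, dim = c(h, w, 3))
  if (nrow(map) == 0) {
    warning("empty attention map; writing blank canvas")
  } else {
    if (any(map$x0 + map$width > slide_dims[2]) ||
        any(map$y0 + map$height > slide_dims[1])) {
      stopf("tile boxes outside slide dims")
    }
    painted <- matrix(FALSE, h, w)
    cols <- heat_ramp(pmin(pmax(map[[channel]], 0), 1)) / 255
    for (i in seq_len(nrow(map))) {
      rr <- (floor(map$y0[i] / scale) + 1):min(h, ceiling((map$y0[i] + map$height[i]) / scale))
      cc <- (floor(map$x0[i] / scale) + 1):min(w, ceiling((map$x0[i] + map$width[i]) / scale))
      if (any(painted[rr, cc])) stopf("overlapping tile boxes in heatmap")
      painted[rr, cc] <- TRUE
      for (ch in 1:3) img[rr, cc, ch] <- cols[i, ch]
    }
  }
  png::writePNG(img, file)
  invisible(file)
}

#' Full explanation of one case
#'
#' Runs a forward pass, extracts per-branch attention rollout, computes
#' single-tile classification scores and assembles contribution maps for
#' each modality present.
#'
#' @param object a `duonet` or `duonet_fit`.
#' @param case a cohort case (with `he` / `ihc` bags).
#' @param mode modality mode.
#' @return named list of `attention_map`s (one per branch used).
#' @export
explain_case <- function(object, case, mode = "DUET") {
  model <- if (inherits(object, "duonet_fit")) object$model else object
  b <- case_bags(case, mode)
  tr <- duonet_forward(model, he = b$he, ihc = b$ihc, mode = mode)
  out <- list()
  for (mdl in tr$branch_kept) {
    bag <- if (mdl == "HE") case$he else case$ihc
    att <- attention_rollout(tr$attention[[mdl]])
    cls <- per_tile_classification(model, bag)
    out[[mdl]] <- contribution_map(att, cls, bag$tile_boxes,
                                   case_id = case$case_id, modality = mdl)
  }
  out
}
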