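uniform_attn <- function(n_heads, n) {
  A <- array(1 / n, dim = c(n_heads, n, n))
  A
}

test_that("attention rollout matches hand-computed matrix products", {
  # two layers of uniform attention over (class + 2 tiles): tiles get 1/2 each
  layers <- list(uniform_attn(2, 3), uniform_attn(2, 3))
  expect_equal(attention_rollout(layers), c(0.5, 0.5))

  # a single layer reduces to the class-token attention row
  A <- array(0, dim = c(1, 3, 3))
  A[1, 1, ] <- c(0, 0.3, 0.7)
  A[1, 2, ] <- c(0.2, 0.5, 0.3)
  A[1, 3, ] <- c(0.1, 0.1, 0.8)
  expect_equal(attention_rollout(list(A)), c(0.3, 0.7))

  # heads are averaged before multiplication
  B <- array(0, dim = c(2, 3, 3))
  B[1, , ] <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))
  B[2, , ] <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  M <- (B[1, , ] + B[2, , ]) / 2
  expect_equal(attention_rollout(list(B)), M[1, -1] / sum(M[1, -1]))

  # identity attention: all mass stays on the class token -> uniform fallback
  I3 <- array(0, dim = c(1, 3, 3))
  for (i in 1:3) I3[1, i, i] <- 1
  expect_warning(r <- attention_rollout(list(I3)), "uniform")
  expect_equal(r, c(0.5, 0.5))

  # non-stochastic rows are rejected
  bad <- uniform_attn(1, 3); bad[1, 1, 1] <- 0.9
  expect_error(attention_rollout(list(bad)), "stochastic")
})

test_that("rollout of model-recorded attention is a probability vector", {
  model <- duonet_init(tiny_model_config(), seed = 61)
  X <- matrix(rnorm(60), 5, 12)
  tr <- duonet_forward(model, he = X, mode = "HE_ONLY")
  r <- attention_rollout(tr$attention$HE)
  expect_length(r, 5)
  expect_equal(sum(r), 1)
  expect_true(all(r >= 0))
})

test_that("single-tile classification scores are probabilities and respect multiplicity", {
  model <- duonet_init(tiny_model_config(), seed = 67)
  row <- matrix(rnorm(12), 1, 12)
  emb <- row[rep(1, 4), , drop = FALSE]
  boxes <- data.frame(x0 = 224 * (0:3), y0 = 0, width = 224, height = 224)
  bag <- embedding_bag("c", "HE", emb, boxes)
  sc <- per_tile_classification(model, bag)
  expect_length(sc, 4)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(sc == sc[1]))
})

test_that("contribution maps multiply channels and survive degenerate inputs", {
  boxes <- data.frame(x0 = c(0, 224), y0 = 0, width = 224, height = 224)
  m <- contribution_map(c(0.2, 0.8), c(0.5, 0.5), boxes)
  expect_equal(m$contribution_raw, c(0.1, 0.4))
  expect_equal(m$attention, c(0, 1))

  z <- contribution_map(c(0, 0), c(0.3, 0.9), boxes)
  expect_equal(z$contribution_raw, c(0, 0))
  expect_true(attr(z, "constant")["contribution"])
  expect_true(all(z$contribution == 0))
  expect_false(any(is.nan(z$contribution)))

  expect_error(contribution_map(c(0.1), c(0.2, 0.3), boxes), "lengths")
})

test_that("heatmaps paint tiles with the yellow-high / purple-low ramp", {
  tdir <- withr::local_tempdir()
  boxes <- data.frame(x0 = c(0, 16), y0 = c(0, 0), width = 16, height = 16)
  m <- contribution_map(c(1, 1), c(1, 0), boxes)
  f <- file.path(tdir, "hm.png")
  render_heatmap(m, c(16, 32), f, channel = "classification")
  img <- png::readPNG(f)
  ramp <- duetmil:::heat_ramp(c(1, 0)) / 255
  expect_equal(img[8, 8, 1:3], ramp[1, ], tolerance = 0.01)   # high: yellow
  expect_equal(img[8, 24, 1:3], ramp[2, ], tolerance = 0.01)  # low: purple

  # checkerboard scores give a checkerboard image
  grid_boxes <- expand.grid(x0 = c(0, 16), y0 = c(0, 16))
  grid_boxes$width <- 16; grid_boxes$height <- 16
  sc <- with(grid_boxes, as.numeric((x0 / 16 + y0 / 16) %% 2 == 0))
  m2 <- contribution_map(rep(1, 4), sc, grid_boxes)
  f2 <- file.path(tdir, "checker.png")
  render_heatmap(m2, c(32, 32), f2, channel = "classification")
  img2 <- png::readPNG(f2)
  expect_equal(img2[8, 8, 1:3], ramp[1, ], tolerance = 0.01)
  expect_equal(img2[8, 24, 1:3], ramp[2, ], tolerance = 0.01)
  expect_equal(img2[24, 24, 1:3], ramp[1, ], tolerance = 0.01)

  # empty maps warn and write a blank canvas
  empty <- m[0, ]
  f3 <- file.path(tdir, "blank.png")
  expect_warning(render_heatmap(empty, c(16, 16), f3), "empty")
  expect_true(all(png::readPNG(f3) == 1))

  # out-of-bounds tiles are rejected
  expect_error(render_heatmap(m, c(16, 16), f), "outside")
})

test_that("trained models score planted signal tiles higher than background", {
  fx <- trained_explain_fixture()
  pos_ids <- fx$split$test_ids[
    vapply(fx$cohort$cases[fx$split$test_ids], `[[`, numeric(1), "status") == 1]
  checked <- 0; higher_cls <- 0; higher_att <- 0
  for (id in pos_ids) {
    case <- fx$cohort$cases[[id]]
    if (!any(case$signal_tiles_he) || all(case$signal_tiles_he)) next
    maps <- explain_case(fx$fit, case)
    sig <- case$signal_tiles_he
    checked <- checked + 1
    higher_cls <- higher_cls +
      (mean(maps$HE$classification_raw[sig]) >
         mean(maps$HE$classification_raw[!sig]))
    higher_att <- higher_att +
      (mean(maps$HE$attention_raw[sig]) > mean(maps$HE$attention_raw[!sig]))
    expect_equal(maps$HE$contribution_raw,
                 maps$HE$attention_raw * maps$HE$classification_raw)
  }
  expect_gte(checked, 5)
  # single-tile classification localises the witness tiles reliably;
  # rollout attention trends the same way but is a weaker localiser
  # (quantified in the acceptance suite)
  expect_gte(higher_cls / checked, 0.9)
  expect_gt(higher_att / checked, 0.5)
})
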