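set.seed(99)
tiny_bags <- function(n_he = 4, n_ihc = 5, d = 12) {
  list(he = matrix(rnorm(n_he * d), n_he, d),
       ihc = matrix(rnorm(n_ihc * d), n_ihc, d))
}

test_that("analytic gradients match finite differences", {
  cfg <- tiny_model_config()
  model <- duonet_init(cfg, seed = 3)
  b <- tiny_bags(3, 4)
  tr <- duonet_forward(model, b$he, b$ihc, cache = TRUE)
  bk <- duetmil:::duonet_backward(model, tr, y = 1)
  flat <- duetmil:::tree_flatten(model$params)
  gflat <- duetmil:::tree_flatten(bk$grads)
  loss_at <- function(params) {
    m2 <- model; m2$params <- params
    duetmil:::bce_loss(duonet_forward(m2, b$he, b$ihc)$logit, 1)
  }
  poke <- function(tree, path, j, d_) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    rec <- function(t, parts) {
      if (length(parts) == 0) { t[j] <- t[j] + d_; return(t) }
      key <- parts[1]
      kk <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
      t[[kk]] <- rec(t[[kk]], parts[-1]); t
    }
    rec(tree, parts)
  }
  eps <- 1e-5
  set.seed(4)
  for (nm in names(flat)) {
    j <- sample(length(flat[[nm]]), 1)
    num <- (loss_at(poke(model$params, nm, j, eps)) -
            loss_at(poke(model$params, nm, j, -eps))) / (2 * eps)
    expect_equal(gflat[[nm]][j], num, tolerance = 1e-4,
                 label = sprintf("grad of %s", nm))
  }
})

test_that("tile order does not change the prediction", {
  model <- duonet_init(tiny_model_config(), seed = 7)
  b <- tiny_bags(8, 6)
  p0 <- duonet_forward(model, b$he, b$ihc)$probability
  set.seed(11)
  for (i in 1:100) {
    p <- duonet_forward(model, b$he[sample(8), ], b$ihc[sample(6), ])$probability
    expect_lt(abs(p - p0), 1e-5)
  }
})

test_that("single-modality mode ignores the other bag entirely", {
  model <- duonet_init(tiny_model_config(), seed = 7)
  b <- tiny_bags()
  p1 <- duonet_forward(model, he = b$he, mode = "HE_ONLY")$probability
  p2 <- duonet_forward(model, he = b$he, ihc = b$ihc * 100,
                       mode = "HE_ONLY")$probability
  expect_identical(p1, p2)
  expect_error(duonet_forward(model, he = b$he, mode = "DUET"), "requires")
  bad <- b$he; bad[1, 1] <- NaN
  expect_error(duonet_forward(model, he = bad, mode = "HE_ONLY"), "NaN")
})

test_that("attention over repeated identical tiles is near-invariant to multiplicity", {
  # exact invariance does not hold with a class token in the softmax
  # denominator (the token/tile balance shifts with N); the deviation stays
  # tiny because tile tokens remain identical and dominate the average
  model <- duonet_init(tiny_model_config(), seed = 5)
  row <- matrix(rnorm(12), 1, 12)
  many <- row[rep(1, 7), , drop = FALSE]
  p1 <- duonet_forward(model, he = row, mode = "HE_ONLY")$probability
  p7 <- duonet_forward(model, he = many, mode = "HE_ONLY")$probability
  expect_equal(p7, p1, tolerance = 1e-4)
})

test_that("attention rows are stochastic at every layer and head", {
  model <- duonet_init(tiny_model_config(), seed = 13)
  b <- tiny_bags(6, 5)
  tr <- duonet_forward(model, b$he, b$ihc)
  for (mdl in c("HE", "IHC")) {
    for (A in tr$attention[[mdl]]) {
      for (h in seq_len(dim(A)[1])) {
        M <- A[h, , ]
        expect_true(all(M >= 0))
        expect_equal(rowSums(M), rep(1, nrow(M)), tolerance = 1e-5)
      }
    }
  }
  expect_equal(tr$probability, plogis(tr$logit))
})

test_that("the trunk is shared: both branches produce identical features for the same bag", {
  model <- duonet_init(tiny_model_config(), seed = 17)
  X <- tiny_bags()$he
  f_he <- duetmil:::trunk_forward(model$params$trunk, X,
                                  model$config$n_heads)$feat
  tr_he <- duonet_forward(model, he = X, mode = "HE_ONLY", cache = TRUE)
  tr_ihc <- duonet_forward(model, ihc = X, mode = "IHC_ONLY", cache = TRUE)
  # same trunk output lands in the HE block vs the IHC block of the head input
  m <- model$config$model_dim
  expect_equal(tr_he$cache$z[1:m], f_he)
  expect_equal(tr_ihc$cache$z[m + 1:m], f_he)
  expect_equal(tr_he$cache$z[m + 1:m], rep(0, m))
})

test_that("branch dropout keeps the contract and the empirical rate", {
  expect_identical(branch_dropout_mask("HE", p = 0.9), "HE")
  expect_error(branch_dropout_mask(character(0)), "non-empty")
  set.seed(2024)
  n <- 10000
  kept <- replicate(n, branch_dropout_mask(c("HE", "IHC"), p = 0.3),
                    simplify = FALSE)
  sizes <- lengths(kept)
  drop_rate <- mean(sizes == 1)
  expect_lt(abs(drop_rate - 0.3), 0.015)
  dropped_he <- mean(vapply(kept[sizes == 1], identical, logical(1), "IHC"))
  expect_lt(abs(dropped_he - 0.5), 0.03)
  expect_true(all(sizes >= 1))
})

test_that("gradients reach kept branches and only kept branches", {
  model <- duonet_init(tiny_model_config(), seed = 23)
  b <- tiny_bags()
  tr <- duonet_forward(model, b$he, b$ihc, cache = TRUE)
  bk <- duetmil:::duonet_backward(model, tr, 1)
  expect_gt(sum(abs(bk$dX$HE)), 0)
  expect_gt(sum(abs(bk$dX$IHC)), 0)

  tr_drop <- duonet_forward(model, b$he, b$ihc, keep = "HE", cache = TRUE)
  bk_drop <- duetmil:::duonet_backward(model, tr_drop, 1)
  expect_gt(sum(abs(bk_drop$dX$HE)), 0)
  expect_null(bk_drop$dX$IHC)
  # gradients must not depend on the dropped bag's content
  tr_drop2 <- duonet_forward(model, b$he, b$ihc * 5, keep = "HE", cache = TRUE)
  bk_drop2 <- duetmil:::duonet_backward(model, tr_drop2, 1)
  expect_identical(duetmil:::tree_flatten(bk_drop$grads),
                   duetmil:::tree_flatten(bk_drop2$grads))
})

test_that("parameter counts follow the sharing arithmetic", {
  cfg <- tiny_model_config()
  m1 <- duonet_init(cfg, seed = 1)
  m2 <- duonet_init(cfg, seed = 99)
  pc <- count_parameters(m1)
  expect_identical(pc, count_parameters(m2))  # counts depend on config only

  # head ingests the concatenation of both branch features
  expect_equal(nrow(m1$params$head$Wh1), 2 * cfg$model_dim)

  # doubling n_layers adds exactly one more block of per-layer parameters
  cfg4 <- tiny_model_config(n_layers = 4L)
  pc4 <- count_parameters(duonet_init(cfg4, seed = 1))
  per_layer <- (pc4$trunk - pc$trunk) / 2
  non_layer <- pc$trunk - 2 * per_layer
  expect_equal(pc4$trunk, non_layer + 4 * per_layer)
  expect_identical(pc$head, pc4$head)

  # initialisation is seed-deterministic
  expect_identical(duetmil:::tree_flatten(m1$params),
                   duetmil:::tree_flatten(duonet_init(cfg, seed = 1)$params))
})

test_that("configuration invariants are enforced", {
  expect_error(duonet_config(model_dim = 10, n_heads = 4), "divisible")
  expect_error(duonet_config(n_layers = 0), "n_layers")
  expect_error(duonet_config(p_branch_dropout = 1), "0, 1")
})
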