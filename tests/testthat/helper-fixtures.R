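# Shared fixtures. Small-dimension configurations keep unit tests fast; the
# cached trained fixture is built once per test run and reused by the
# explainability and survival tests.

tiny_synth_config <- function(n_cases = 60, seed = 42,
                              tiles_per_slide_range = c(4L, 8L), ...) {
  synth_config(n_cases = n_cases,
               tiles_per_slide_range = tiles_per_slide_range,
               d_sig = 2, effect_he = c(3, 3), effect_ihc = c(3, 3),
               embed_dim = 12, seed = seed, ...)
}

tiny_model_config <- function(n_layers = 2L, model_dim = 8L,
                              mlp_hidden = 6L, ...) {
  duonet_config(embed_dim_in = 12L, model_dim = model_dim,
                n_layers = n_layers, n_heads = 2L,
                mlp_hidden = mlp_hidden, ...)
}

# study-scale configuration used by the end-to-end synthetic experiments
study_model_config <- function() {
  duonet_config(model_dim = 64L, n_heads = 4L, mlp_hidden = 64L)
}

study_train_config <- function(seed = 1L) {
  train_config(learning_rate = 1e-3, epochs = 10L, eval_every = 200L,
               seed = seed)
}

# sparse-witness conditions for the explainability study: a small fraction
# of clearly recognisable signal tiles, so instance selection matters
explain_synth_config <- function(seed = 314) {
  synth_config(seed = seed, signal_fraction = 0.1, d_sig = 8,
               effect_he = rep(3, 8), effect_ihc = rep(3, 8))
}

.fixture_env <- new.env(parent = emptyenv())

train_one_fold <- function(cohort, seed) {
  labels <- vapply(cohort$cases, `[[`, numeric(1), "status")
  splits <- make_folds(names(cohort$cases), k = 5, seed = seed,
                       labels = labels)
  fit <- train_fold(cohort, splits[[1]], study_model_config(),
                    study_train_config(seed = seed))
  list(cohort = cohort, split = splits[[1]], fit = fit)
}

# One trained fold on the default (complementary-signal) study cohort,
# cached per test run; used by the survival-stratification checks.
trained_study_fixture <- function() {
  if (!exists("study", envir = .fixture_env)) {
    assign("study", train_one_fold(generate_cohort(synth_config(seed = 314)),
                                   seed = 314),
           envir = .fixture_env)
  }
  get("study", envir = .fixture_env)
}

# One trained fold on the sparse-witness cohort, cached per test run; used
# by the explainability checks.
trained_explain_fixture <- function() {
  if (!exists("explain", envir = .fixture_env)) {
    assign("explain", train_one_fold(generate_cohort(explain_synth_config()),
                                     seed = 314),
           envir = .fixture_env)
  }
  get("explain", envir = .fixture_env)
}

# brute-force pairwise-concordance AUROC oracle (ties count one half)
auroc_brute <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

random_prediction_set <- function(n, tie_prone = TRUE) {
  p <- if (tie_prone) round(runif(n), 1) else runif(n)
  y <- c(0, 1, rbinom(n - 2, 1, 0.5))[sample(n)]
  list(p = p, y = y)
}
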