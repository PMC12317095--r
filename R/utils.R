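#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state; restores the caller's stream so that
# seeded helpers never perturb global reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Fans one master seed out into independent, reproducible per-stage seeds.
#' The same (master, stage) pair always yields the same seed; different stage
#' names decorrelate the streams. Result is a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. `"simulate"`), or an
#'   integer index (e.g. an epoch number).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master))
  if (is.character(stage)) {
    codes <- utf8ToInt(stage)
    h <- 0
    for (ch in codes) h <- (h * 131 + ch) %% 2147483647
  } else {
    h <- as.double(stage) %% 2147483647
  }
  s <- (as.double(master) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h * 69621 + 12345) %% 2147483646)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 0

is_prob <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
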