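#' @importFrom stats rnorm runif median predict approx sd setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# Label palette codes shared by masks, PNG export and samplers.
OCT_LABEL_CODES <- c(outside = 0L, healthy = 1L, CME = 2L, DRT = 3L,
                     SRD = 4L, uncertainty = 5L)

#' Class names used by the pipeline
#'
#' `oct_classes()` returns the four diagnostic target classes; with
#' `with_uncertainty = TRUE` the expert "uncertainty" label is appended
#' (the fifth label present in masks and window samples, but never a
#' classifier target in the fine-grained stage).
#'
#' @param with_uncertainty include the uncertainty label.
#' @return character vector of class names.
#' @export
oct_classes <- function(with_uncertainty = FALSE) {
  cls <- c("healthy", "CME", "DRT", "SRD")
  if (with_uncertainty) c(cls, "uncertainty") else cls
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive reproducible sub-seeds (kept below 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Reflect indices across grid borders without duplicating the border pixel
#'
#' Maps arbitrary (possibly out-of-range) 1-based indices onto `1..n` by
#' mirror reflection about the first and last element, excluding repetition
#' of the border sample itself (the "reflect-101" convention): for `n = 5`
#' the index sequence `0, -1, -2` maps to `2, 3, 4`.
#'
#' @param idx integer vector of 1-based indices, any range.
#' @param n grid extent (>= 1).
#' @return integer vector of indices in `1..n`.
#' @export
reflect_index <- function(idx, n) {
  if (n < 1L) stop("grid extent must be >= 1")
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  m <- ((idx - 1L) %% period + period) %% period
  m <- ifelse(m > (n - 1L), period - m, m)
  as.integer(m + 1L)
}
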