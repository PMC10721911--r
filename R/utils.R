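#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded package functions do not disturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-seed from a master seed
#'
#' Fans a single master seed out to reproducible, distinct sub-seeds for the
#' independent random stages of an analysis (data split, network
#' initialization, bootstrap, simulation), so each stage can be re-run in
#' isolation.
#'
#' @param master integer master seed.
#' @param label character tag naming the stage.
#' @param index optional integer (e.g. replicate number) folded into the seed.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  s <- (as.double(master) * 2654435761 + h * 40503 + as.double(index) * 97) %%
    2147483647
  as.integer(s)
}

# round to nearest integer and clamp into [lo, hi]
clamp_round <- function(x, lo, hi) {
  pmin(pmax(round(x), lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stratified index split used by the data split and CV folds
stratified_sample <- function(strata, fraction) {
  idx_train <- integer(0)
  for (s in unique(strata)) {
    ids <- which(strata == s)
    n_tr <- round(fraction * length(ids))
    # keep both partitions non-empty per stratum when the stratum allows it
    if (length(ids) >= 2) {
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
    } else {
      n_tr <- length(ids)
    }
    idx_train <- c(idx_train, sample(ids, n_tr))
  }
  sort(idx_train)
}
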