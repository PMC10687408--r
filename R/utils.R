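#' @importFrom rlang .data
#' @importFrom stats quantile rnorm runif rgeom sd coef lm predict setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# Linear-interpolation quantile (type 7), no names, NA-tolerant.
q_lin <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE, na.rm = TRUE)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library calls never perturb user code.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("invalid parameter: `%s` must be finite", what), call. = FALSE)
  }
  invisible(x)
}

# rbind a list of tibbles that may be empty
bind_rows_safe <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0) return(tibble::tibble())
  dplyr::bind_rows(lst)
}
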