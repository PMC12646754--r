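#' @importFrom rlang abort warn .data
#' @importFrom stats quantile sd rnorm runif rlnorm rpois qnorm pnorm uniroot
#'   predict dist median
NULL

# stop with a classed condition so callers can distinguish failure modes
fc_abort <- function(msg, class) {
  abort(msg, class = c(class, "firecanopy_error"))
}

# signal that a metric is undefined on this input (distinct from an error):
# returns NA_real_ after emitting a classed warning that callers can muffle
fc_undefined <- function(msg) {
  warn(msg, class = "firecanopy_undefined_metric")
  NA_real_
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_number(x) || x < lower || x > upper) {
    fc_abort(
      sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
      "firecanopy_bad_argument"
    )
  }
  invisible(x)
}

# evaluate expr with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
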