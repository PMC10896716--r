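#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## weekly accounting basis <-> daily / monthly
DAYS_PER_WEEK <- 7
WEEKS_PER_MONTH <- (365.25 / 12) / 7

stop_ed <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ed("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stop_ed("`%s` must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lower = min)
  if (x != round(x)) stop_ed("`%s` must be an integer, got %g", name, x)
  invisible(as.integer(x))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Keeps derived seeds within the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#'
#' @param seed master integer seed
#' @param k stream index (>= 0)
#' @return an integer seed
#' @keywords internal
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * (k + 1)) %% 2147483647) + 1L
}

## run `expr` under a seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## symmetric projection with zero row/column sums (double-centering)
center_symmetric <- function(M) {
  M <- (M + t(M)) / 2
  J <- nrow(M)
  H <- diag(J) - matrix(1 / J, J, J)
  H %*% M %*% H
}

## row medians ignoring NA, for summary tables
med <- function(x) stats::median(x, na.rm = TRUE)
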