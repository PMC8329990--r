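# Internal helpers shared across modules.

# Seed the RNG for the duration of the calling function and restore the
# caller's RNG state on exit (same contract as stats::simulate).
local_seed <- function(seed, envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  restore <- function() {
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
  do.call(on.exit, list(substitute(restore(), list(restore = restore)),
                        add = TRUE), envir = envir)
  invisible(seed)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  }
  if (integerish && x != round(x)) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  check_scalar(x, name, lower = 0, upper = 1)
}

#' Parameterize a lognormal distribution by its mean and coefficient of
#' variation
#'
#' Convenience for specifying copy-number or size distributions on the natural
#' scale used in the lab (mean copies per vesicle, CV across vesicles) rather
#' than the log-scale `meanlog`/`sdlog` pair.
#'
#' @param mean Desired distribution mean (> 0).
#' @param cv Desired coefficient of variation (>= 0).
#' @return A list with elements `meanlog` and `sdlog`.
#' @examples
#' p <- lognormal_params(mean = 70, cv = 0.5)
#' exp(p$meanlog + p$sdlog^2 / 2)  # 70
#' @export
lognormal_params <- function(mean, cv) {
  check_scalar(mean, "mean", lower = 0, strict_lower = TRUE)
  check_scalar(cv, "cv", lower = 0)
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
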