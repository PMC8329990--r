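# Rank-based multi-group comparisons and cross-method correlation.

as_grouped <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  lens <- lengths(groups)
  if (any(lens < 1L)) stop("every group needs >= 1 observation",
                           call. = FALSE)
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric comparison of k groups on pooled midranks with the standard
#' tie correction; the p value comes from the chi-square approximation with
#' k - 1 degrees of freedom.  Computed by [stats::kruskal.test()]; when all
#' observations are identical the statistic is defined as 0 with p = 1.
#'
#' @param groups Either a named list of numeric vectors, or a data frame with
#'   `group` and `value` columns.
#' @return A list with `H`, `df`, `p_value`, `n`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2), b = c(3, 4)))$H  # 2.4
#' @export
kruskal_wallis <- function(groups) {
  g <- as_grouped(groups)
  n <- sum(lengths(g))
  if (n < 3L) stop("need at least 3 observations in total", call. = FALSE)
  pooled <- unlist(g, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(list(H = 0, df = length(g) - 1L, p_value = 1, n = n))
  }
  kt <- kruskal.test(g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = n)
}

#' Dunn's post-hoc test for pairwise group comparisons
#'
#' Follows a Kruskal-Wallis test: for each pair (i, j), the rank-mean
#' difference is standardized as
#' z_ij = (Rbar_i - Rbar_j) / sqrt(S2 * (1/n_i + 1/n_j)) with the
#' tie-corrected variance S2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1));
#' two-sided p values come from the normal distribution and are adjusted
#' family-wise by Bonferroni over all pairs (the classical form of the
#' procedure).
#'
#' @inheritParams kruskal_wallis
#' @return A data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups) {
  g <- as_grouped(groups)
  labs <- names(g)
  if (is.null(labs)) labs <- paste0("group", seq_along(g))
  k <- length(g)
  pooled <- unlist(g, use.names = FALSE)
  n_i <- lengths(g)
  N <- length(pooled)
  r <- rank(pooled)  # midranks
  idx <- rep(seq_len(k), n_i)
  rbar <- as.numeric(tapply(r, idx, mean))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se <- sqrt(s2 * (1 / n_i[i] + 1 / n_i[j]))
    z[c] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[c] <- 2 * pnorm(-abs(z[c]))
  }
  data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
             z = z, p_unadjusted = p,
             p_adjusted = p.adjust(p, method = "bonferroni"),
             stringsAsFactors = FALSE)
}

#' Normalize per-condition values to a control condition
#'
#' Divides every condition's value by the control's value, so the control
#' maps to 1 and other conditions become fold changes over control.  A
#' negative control still divides (sign preserved) but is flagged.
#'
#' @param values Named numeric vector, one value per condition.
#' @param control Name of the control condition (must be present, non-zero).
#' @param method Optional method name recorded on the result.
#' @return An object of class `method_vector`: a list with `method`,
#'   `values` (named, control = 1), `control`, `negative_control_flag`.
#' @export
normalize_to_control <- function(values, control, method = "method") {
  if (is.null(names(values)) || !(control %in% names(values))) {
    stop("'values' must be named and include the control condition",
         call. = FALSE)
  }
  ctrl <- values[[control]]
  if (!is.finite(ctrl) || ctrl == 0) {
    stop("control value must be non-zero", call. = FALSE)
  }
  structure(list(method = method, values = values / ctrl, control = control,
                 negative_control_flag = ctrl < 0),
            class = "method_vector")
}

#' @export
print.method_vector <- function(x, ...) {
  cat(sprintf("Method '%s' (normalized to '%s'%s):\n", x$method, x$control,
              if (x$negative_control_flag) ", negative control flagged"
              else ""))
  print(round(x$values, 3))
  invisible(x)
}

#' Pearson correlation between two method vectors
#'
#' Correlates per-condition values from two measurement methods over their
#' shared, aligned conditions; reports the product-moment r and R^2 = r^2.
#' Zero variance in either vector leaves the correlation undefined.
#'
#' @param x,y `method_vector` objects (see [normalize_to_control()]) or named
#'   numeric vectors; conditions are aligned by name when names are present.
#' @return A list with `r`, `r_squared`, `n`, `defined`.
#' @export
correlate_methods <- function(x, y) {
  vx <- if (inherits(x, "method_vector")) x$values else x
  vy <- if (inherits(y, "method_vector")) y$values else y
  if (!is.null(names(vx)) && !is.null(names(vy))) {
    shared <- intersect(names(vx), names(vy))
    vx <- vx[shared]
    vy <- vy[shared]
  }
  if (length(vx) != length(vy) || length(vx) < 3L) {
    stop("need >= 3 aligned conditions", call. = FALSE)
  }
  if (sd(vx) == 0 || sd(vy) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_, n = length(vx),
                defined = FALSE))
  }
  r <- cor(vx, vy)
  list(r = r, r_squared = r^2, n = length(vx), defined = TRUE)
}
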