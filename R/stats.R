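#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-group comparison of distributions (nonparametric one-way
#' ANOVA), applied here to per-lesion pixel-intensity samples and to
#' per-lesion vascular densities grouped by organ. Pooled values receive
#' mid-ranks; the statistic is
#' `H = [12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)] / C` with the tie
#' correction `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie groups, and the
#' p-value is the upper chi-square tail on k - 1 degrees of freedom.
#'
#' When every pooled value is identical the tie correction degenerates to
#' C = 0; the result is then defined as H = 0, p = 1 and flagged
#' `"degenerate: all ties"`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each non-empty,
#'   pooled N >= k + 1).
#' @return An object of class `kw_result`: `H`, `df`, `p`, `k`, `N`,
#'   `tie_correction`, `flags`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group must contain at least 1 value")
  k <- length(groups)
  N <- sum(sizes)
  if (N < k + 1L) stop("pooled sample size must be at least k + 1")
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) stop("missing values are not allowed")
  r <- rank(pooled)  # mid-ranks for ties
  grp <- rep(seq_len(k), sizes)
  Rsum <- vapply(split(r, grp), sum, 0)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    return(structure(list(H = 0, df = k - 1L, p = 1, k = k, N = N,
                          tie_correction = 0,
                          flags = "degenerate: all ties"),
                     class = "kw_result"))
  }
  H <- (12 / (N * (N + 1)) * sum(Rsum^2 / sizes) - 3 * (N + 1)) / C
  H <- max(H, 0)
  structure(list(H = H, df = k - 1L,
                 p = stats::pchisq(H, df = k - 1L, lower.tail = FALSE),
                 k = k, N = N, tie_correction = C, flags = character(0)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (k = %d, N = %d, C = %.4f)%s\n",
              x$H, x$df, x$p, x$k, x$N, x$tie_correction,
              if (length(x$flags) && nzchar(x$flags[1L]))
                paste0(" [", paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Seeded subsampling of a pixel sample
#'
#' Bounds the per-lesion sample entering rank tests: groups at or below
#' `n_max` are returned unchanged; larger groups are subsampled uniformly
#' without replacement under the given seed (deterministic, and the caller's
#' RNG state is untouched). The default cap of 10^4 pixels per lesion keeps
#' rank tests fast and avoids the practical degeneracy of p-values computed
#' from millions of pixels.
#'
#' @param values Numeric vector (e.g. ROI pixel intensities).
#' @param n_max Maximum sample size (>= 1).
#' @param seed Integer seed for the subsample.
#' @return Numeric vector of length `min(length(values), n_max)`.
#' @export
subsample_pixels <- function(values, n_max = 10000L, seed = 1L) {
  if (n_max < 1L) stop("`n_max` must be >= 1")
  n <- length(values)
  if (n <= n_max) return(values)
  with_seed(seed, values[sample.int(n, n_max)])
}

#' Five-number boxplot summaries with 1.5 IQR whiskers
#'
#' Quartiles use linear interpolation (quantile type 7); whiskers extend to
#' the most extreme observations within `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`;
#' points beyond the whiskers are counted as outliers.
#'
#' @param groups Named list of non-empty numeric vectors.
#' @return Data frame with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
boxplot_summary <- function(groups) {
  if (!is.list(groups) || !length(groups)) stop("`groups` must be a non-empty list")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (!length(v)) stop(sprintf("group '%s' is empty", g))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    lo_lim <- q[1L] - 1.5 * iqr
    hi_lim <- q[3L] + 1.5 * iqr
    inside <- v[v >= lo_lim & v <= hi_lim]
    data.frame(group = g, n = length(v), min = min(v), q1 = q[1L],
               median = q[2L], q3 = q[3L], max = max(v),
               whisker_lo = min(inside), whisker_hi = max(inside),
               n_outliers = sum(v < lo_lim | v > hi_lim),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
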