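#' Mean intensity over a region mask
#'
#' Arithmetic mean of the raw (unstretched) voxel intensities under the
#' mask. Display-only histogram stretching must never feed this.
#'
#' @param v a `stem_volume`.
#' @param m a nonempty `stem_mask` on the same grid.
#' @return numeric scalar.
#' @export
region_mean <- function(v, m) {
  if (!all(vol_dim(v) == dim(m$data)))
    stop("mask and volume grids differ")
  if (!any(m$data)) stop("empty region mask")
  mean(v$data[m$data])
}

#' Normalize a region mean by the anterior-commissure mean
#'
#' @param region_mean mean region intensity (0-255 scale).
#' @param ac_mean mean anterior-commissure intensity (> 0).
#' @return dimensionless ratio.
#' @export
normalize_by_ac <- function(region_mean, ac_mean) {
  if (any(ac_mean <= 0)) stop("AC mean intensity must be positive")
  region_mean / ac_mean
}

#' Spearman rank correlation (midranks for ties)
#'
#' Pearson correlation of average ranks; ties receive midranks, which the
#' tied ages in an 8-subject series make observable.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined: zero rank variance")
  stats::cor(rx, ry)
}

#' Two-sided p-value for Spearman's rho (t approximation)
#'
#' Transforms rho to `t = rho * sqrt((n - 2) / (1 - rho^2))` and takes the
#' two-sided tail of Student's t with `n - 2` degrees of freedom.
#'
#' @param rho Spearman correlation (|rho| <= 1).
#' @param n number of pairs (>= 3).
#' @return two-sided p in `(0, 1]`; for |rho| = 1 returns 0 with attribute
#'   `exact = TRUE`.
#' @export
spearman_p_tapprox <- function(rho, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(rho) > 1 + 1e-12) stop("|rho| must be <= 1")
  if (abs(rho) >= 1) return(structure(0, exact = TRUE))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Exact permutation p-value for Spearman's rho
#'
#' Enumerates all n! permutations (n <= 8) and reports the two-sided tail
#' `P(|rho_perm| >= |rho_obs|)`. Non-default alternative to
#' [spearman_p_tapprox()].
#'
#' @param x,y numeric vectors (3 <= n <= 8).
#' @return exact two-sided p.
#' @export
spearman_p_exact <- function(x, y) {
  n <- length(x)
  if (n < 3L || n > 8L) stop("exact enumeration supports 3 <= n <= 8")
  obs <- abs(spearman_rho(x, y))
  rx <- rank(x); ry <- rank(y)
  perms <- all_permutations(n)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Ordinary least-squares regression of y on x
#'
#' Wraps [stats::lm()]; reports slope, intercept, r-squared and the
#' two-sided p of the slope's t statistic (n - 2 df).
#'
#' @param x,y numeric vectors (n >= 3, x non-constant).
#' @return A `stem_regression` list: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "stem_regression")
}

#' @export
print.stem_regression <- function(x, ...) {
  cat(sprintf("<stem_regression> slope %.4g, intercept %.4g, r^2 %.4g, p %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Age correlation analysis over a region-statistics table
#'
#' For each region, computes Spearman's rho between age and the normalized
#' intensity ratio with the t-approximation p-value, and flags per-region
#' significance at `alpha` without multiplicity correction (a Holm option
#' exists but is off by default). Regions with fewer than 3 subjects are
#' skipped with a warning.
#'
#' @param table data.frame with columns `subject`, `age_years`, `region`,
#'   `ratio` (as produced by [make_age_series()]).
#' @param regions region labels to analyse (default: all present).
#' @param alpha per-region significance level (default 0.05).
#' @param adjust `"none"` (default, matching per-region reporting) or
#'   `"holm"`.
#' @return data.frame: `region`, `n`, `rho`, `df`, `t`, `p`, `significant`.
#' @export
age_analysis <- function(table, regions = NULL, alpha = 0.05,
                         adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  regions <- regions %||% unique(table$region)
  rows <- lapply(regions, function(rg) {
    sub <- table[table$region == rg, , drop = FALSE]
    if (nrow(sub) < 3L) {
      warning("region '", rg, "' has < 3 subjects; skipped", call. = FALSE)
      return(NULL)
    }
    rho <- spearman_rho(sub$age_years, sub$ratio)
    n <- nrow(sub)
    data.frame(region = rg, n = n, rho = rho, df = n - 2,
               t = if (abs(rho) < 1) rho * sqrt((n - 2) / (1 - rho^2))
                   else sign(rho) * Inf,
               p = as.numeric(spearman_p_tapprox(rho, n)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  padj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$significant <- padj < alpha
  rownames(out) <- NULL
  out
}

#' Display-only histogram stretch to the 0-255 range
#'
#' Linearly maps the intensity range onto 0-255 for QC rendering. Never
#' feed the result into statistics; [region_mean()] uses raw intensities.
#'
#' @param v a `stem_volume`.
#' @return A `stem_volume` with stretched intensities.
#' @export
stretch_intensity <- function(v) {
  r <- range(v$data)
  if (diff(r) == 0) return(v)
  out <- v
  out$data <- (v$data - r[1]) / diff(r) * 255
  out
}

#' Write a region-statistics table / overlap results as CSV
#'
#' @param x data.frame or list of `stem_overlap`.
#' @param path CSV output path.
#' @export
write_stats_csv <- function(x, path) {
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, logical(1),
                                                    "stem_overlap")))
    x <- do.call(rbind, lapply(x, function(o)
      data.frame(label_a = o$label_a, label_b = o$label_b,
                 n_intersection = o$n_intersection, n_union = o$n_union,
                 jaccard_pct = o$jaccard_pct,
                 frac_of_a_pct = o$frac_of_a_pct,
                 frac_of_b_pct = o$frac_of_b_pct)))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
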