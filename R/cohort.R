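#' @include AllClasses.R
NULL

#' Axis-symmetric dual regression
#'
#' Fits three lines through the centroid of a scatter: the ordinary
#' least-squares regression of Y on X (slope cov(x,y)/var(x)); the
#' ordinate projection of the X-on-Y regression, whose slope in Y-on-X
#' coordinates is var(y)/cov(x,y); and the mean regression line, taken as
#' the geometric mean of the two — the standardized major axis, slope
#' sign(cov) * sd(y)/sd(x). The squared correlation
#' r2 = cov^2/(var(x) var(y)) is invariant under swapping the axes, and
#' the SMA slope always lies between the other two in absolute value.
#'
#' @param x,y paired finite numeric vectors (>= 3 points, each with
#'   nonzero variance).
#' @return a [RegressionResult-class]. With zero covariance the X-on-Y
#'   projection and the mean line are undefined (NA, flagged).
#' @examples
#' r <- dualRegression(c(0, 1, 2, 3), c(0, 1, 0, 1))
#' r@slopeYX    # 0.2
#' r@r2         # 0.2
#' @export
dualRegression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite points")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("zero variance in x or y")
  cxy <- stats::cov(x, y)
  mx <- mean(x); my <- mean(y)
  slopeYX <- cxy / vx
  r2 <- cxy^2 / (vx * vy)
  flags <- character()
  if (cxy == 0) {
    slopeXYInv <- slopeMean <- NA_real_
    flags <- "zero-covariance"
  } else {
    slopeXYInv <- vy / cxy
    slopeMean <- sign(cxy) * sqrt(vy / vx)
  }
  intercept <- function(s) if (is.na(s)) NA_real_ else my - s * mx
  new("RegressionResult",
      slopeYX = slopeYX, interceptYX = intercept(slopeYX),
      slopeXYInv = slopeXYInv, interceptXYInv = intercept(slopeXYInv),
      slopeMean = slopeMean, interceptMean = intercept(slopeMean),
      r2 = r2, n = as.integer(n), flags = flags)
}

#' Group medians, IQRs and ratio-of-medians contrasts
#'
#' Summarizes one metric per isolation method as median with
#' interquartile range, and contrasts the non-reference methods against
#' the reference by the ratio of group medians, with seeded bootstrap
#' percentile confidence intervals.
#'
#' @param records data.frame with `method` and the metric column.
#' @param metric name of the metric column.
#' @param ref reference method for the ratios (default `"DC"`).
#' @param nBoot bootstrap resamples for the ratio CI.
#' @param conf confidence level.
#' @param seed optional integer seed for the bootstrap.
#' @return list with `summary` (per-method median, q25, q75, n) and
#'   `ratios` (per non-reference method: ratio of medians, CI bounds).
#' @export
summarizeGroups <- function(records, metric, ref = "DC", nBoot = 2000,
                            conf = 0.95, seed = NULL) {
  stopifnot(is.data.frame(records), metric %in% names(records),
            "method" %in% names(records))
  doBoot <- function() {
    methods <- unique(records$method)
    vals <- lapply(methods, function(m) {
      v <- records[[metric]][records$method == m]
      v <- v[!is.na(v)]
      if (!length(v)) stop("empty method group: ", m)
      v
    })
    names(vals) <- methods
    summary <- do.call(rbind, lapply(methods, function(m) {
      q <- stats::quantile(vals[[m]], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(method = m, n = length(vals[[m]]), median = q[2],
                 q25 = q[1], q75 = q[3], stringsAsFactors = FALSE)
    }))
    if (!(ref %in% methods)) stop("reference method absent: ", ref)
    alpha <- (1 - conf) / 2
    others <- setdiff(methods, ref)
    ratios <- do.call(rbind, lapply(others, function(m) {
      rat <- stats::median(vals[[m]]) / stats::median(vals[[ref]])
      bs <- replicate(nBoot, {
        stats::median(sample(vals[[m]], replace = TRUE)) /
          stats::median(sample(vals[[ref]], replace = TRUE))
      })
      ci <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE)
      data.frame(comparison = paste0(m, "/", ref), ratio = rat,
                 ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
    }))
    list(summary = summary, ratios = ratios, metric = metric)
  }
  if (is.null(seed)) doBoot() else withr::with_seed(as.integer(seed), doBoot())
}

#' Paired and groupwise significance tests
#'
#' Thin glue around the standard routines: the Wilcoxon matched-pairs
#' signed-rank test for two methods paired by donor, and one-way ANOVA
#' across methods with Tukey multiple comparisons. Donors missing one of
#' the compared methods are dropped with a message.
#'
#' @param records data.frame with `donor_id`, `method` and the metric.
#' @param metric metric column name.
#' @param test `"wilcoxon"` (paired, two methods) or `"anova"` (one-way
#'   across all methods, with Tukey HSD).
#' @param methods for `"wilcoxon"`, the two methods to pair.
#' @return for `"wilcoxon"`: list(statistic, p_value, n_pairs, dropped);
#'   for `"anova"`: list(f_value, p_value, tukey, n).
#' @export
pairedCompare <- function(records, metric, test = c("wilcoxon", "anova"),
                          methods = c("DC", "PA")) {
  test <- match.arg(test)
  stopifnot(metric %in% names(records))
  v <- records[[metric]]
  if (all(is.na(v)) || stats::var(v, na.rm = TRUE) == 0)
    stop("metric is constant or empty; test undefined")
  if (test == "wilcoxon") {
    a <- records[records$method == methods[1], c("donor_id", metric)]
    b <- records[records$method == methods[2], c("donor_id", metric)]
    common <- intersect(a$donor_id, b$donor_id)
    dropped <- length(unique(c(a$donor_id, b$donor_id))) - length(common)
    if (dropped > 0)
      message(dropped, " unpaired donor(s) dropped")
    if (length(common) < 5)
      warning("fewer than 5 donor pairs; test power is minimal")
    xa <- a[[metric]][match(common, a$donor_id)]
    xb <- b[[metric]][match(common, b$donor_id)]
    if (all(xa == xb))   # no nonzero differences: nothing to rank
      return(list(statistic = 0, p_value = 1, n_pairs = length(common),
                  dropped = dropped))
    wt <- stats::wilcox.test(xa, xb, paired = TRUE, exact = FALSE)
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_pairs = length(common), dropped = dropped)
  } else {
    fit <- stats::aov(stats::as.formula(paste(metric, "~ method")),
                      data = records)
    sm <- summary(fit)[[1]]
    list(f_value = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
         tukey = stats::TukeyHSD(fit)$method, n = nrow(records))
  }
}
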