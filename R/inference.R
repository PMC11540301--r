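# Statistical machinery: OLS with F tests, encoding classification,
# resampling comparison, ANCOVA/ANOVA with Tukey HSD, shuffle-bootstrap
# null band and significant-run detection.

#' Ordinary least squares with an F test of the slope
#'
#' Closed-form simple regression on all finite (x, y) pairs; significance
#' of the slope is assessed with an F test on (1, n - 2) degrees of
#' freedom.
#'
#' @param x,y numeric vectors (NaN/NA pairs dropped).
#' @return list of class `"axonav_fit"`: `slope`, `intercept`, `F_stat`,
#'   `p_value`, `n_points`, `dof_resid`, `se_slope`.
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need >= 3 finite points, got %d", n)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stopf("zero variance in x")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  dof <- n - 2L
  mse <- rss / dof
  Fst <- if (mse > 0) (tss - rss) / mse else if (tss > rss) Inf else 0
  p <- stats::pf(Fst, 1, dof, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, F_stat = Fst,
                 p_value = p, n_points = n, dof_resid = dof,
                 se_slope = sqrt(mse / sxx)),
            class = "axonav_fit")
}

#' Classify per-ROI regression fits by sign and significance
#'
#' @param fits list of [fit_linear()] results (one per ROI).
#' @param alpha significance level, default 0.05.
#' @return list with `counts` (positive, negative, ns) and `class` (per-ROI
#'   label).
#' @export
classify_roi_fits <- function(fits, alpha = 0.05) {
  cls <- vapply(fits, function(f) {
    if (f$p_value < alpha && f$slope > 0) "positive"
    else if (f$p_value < alpha && f$slope < 0) "negative"
    else "ns"
  }, character(1))
  list(counts = c(positive = sum(cls == "positive"),
                  negative = sum(cls == "negative"),
                  ns = sum(cls == "ns")),
       class = cls)
}

#' Monte-Carlo resampling comparison of two populations' regressions
#'
#' The larger population is resampled `n_reps` times at the smaller
#' population's size (`subsample_n` ROIs drawn without replacement); each
#' draw pools the ROIs' points and fits one regression.  A reference fit is
#' "contained" when both its slope and intercept fall inside the per-axis
#' 2.5-97.5 percentile box of the resampled cloud.
#'
#' @param roi_points list, one element per ROI, each a data.frame/list with
#'   `x` and `y`.
#' @param subsample_n ROIs per draw (must be < number of ROIs).
#' @param reference_fit a [fit_linear()] result to test for containment
#'   (optional).
#' @param n_reps resamples, default 1000.
#' @param seed RNG seed.
#' @return list of class `"axonav_resample"`: `slopes`, `intercepts`,
#'   `slope_ci`, `intercept_ci`, `contained` (NA if no reference).
#' @export
resample_comparison <- function(roi_points, subsample_n, reference_fit = NULL,
                                n_reps = 1000L, seed = 1L) {
  n_roi <- length(roi_points)
  if (subsample_n >= n_roi)
    stopf("subsample_n (%d) must be smaller than the population (%d)",
          subsample_n, n_roi)
  slopes <- numeric(n_reps); intercepts <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      pick <- sample.int(n_roi, subsample_n)
      x <- unlist(lapply(roi_points[pick], function(p) p$x))
      y <- unlist(lapply(roi_points[pick], function(p) p$y))
      f <- fit_linear(x, y)
      slopes[r] <- f$slope; intercepts[r] <- f$intercept
    }
  })
  s_ci <- stats::quantile(slopes, c(0.025, 0.975), names = FALSE)
  i_ci <- stats::quantile(intercepts, c(0.025, 0.975), names = FALSE)
  contained <- NA
  if (!is.null(reference_fit)) {
    contained <- reference_fit$slope >= s_ci[1] && reference_fit$slope <= s_ci[2] &&
      reference_fit$intercept >= i_ci[1] && reference_fit$intercept <= i_ci[2]
  }
  structure(list(slopes = slopes, intercepts = intercepts,
                 slope_ci = s_ci, intercept_ci = i_ci,
                 subsample_n = subsample_n, n_reps = n_reps,
                 contained = contained),
            class = "axonav_resample")
}

# least-squares RSS for an explicit design matrix
.design_rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' One-way ANCOVA on slopes with Tukey HSD post hoc
#'
#' Omnibus: F test of the group-by-covariate interaction in
#' `y ~ group + x + group:x` against the common-slope model.  Pairwise:
#' slope differences between groups tested with the studentized-range
#' distribution (Tukey HSD) using the full model's residual variance and
#' each group's own `Sxx`.
#'
#' @param groups named list, one element per group, each with `x` and `y`.
#' @return list of class `"axonav_group_comparison"` with `kind`,
#'   `F_stat`, `p_value`, `df`, `slopes` and `pairwise` (data.frame:
#'   group_a, group_b, estimate, adjusted_p).
#' @export
ancova_slopes <- function(groups) {
  g <- length(groups)
  if (g < 2L) stopf("need >= 2 groups")
  labels <- names(groups) %||% paste0("g", seq_len(g))
  for (i in seq_len(g)) {
    ok <- is.finite(groups[[i]]$x) & is.finite(groups[[i]]$y)
    groups[[i]]$x <- groups[[i]]$x[ok]; groups[[i]]$y <- groups[[i]]$y[ok]
    if (length(groups[[i]]$x) < 3L)
      stopf("group '%s' has < 3 finite points", labels[i])
    if (stats::var(groups[[i]]$x) == 0)
      stopf("group '%s' has zero covariate variance", labels[i])
  }
  x <- unlist(lapply(groups, `[[`, "x"))
  y <- unlist(lapply(groups, `[[`, "y"))
  gid <- factor(rep(labels, vapply(groups, function(p) length(p$x), integer(1))),
                levels = labels)
  n <- length(y)
  G <- stats::model.matrix(~ gid)                 # intercept + g-1 dummies
  X_full <- cbind(G, G * x)                        # separate slopes
  X_red <- cbind(G, x)                             # common slope
  rss_full <- .design_rss(X_full, y)
  rss_red <- .design_rss(X_red, y)
  df_full <- n - 2L * g
  Fst <- ((rss_red - rss_full) / (g - 1L)) / (rss_full / df_full)
  p <- stats::pf(Fst, g - 1L, df_full, lower.tail = FALSE)

  s2 <- rss_full / df_full
  slopes <- vapply(groups, function(p) fit_linear(p$x, p$y)$slope, numeric(1))
  sxx <- vapply(groups, function(p) sum((p$x - mean(p$x))^2), numeric(1))
  pairs <- utils::combn(g, 2)
  pw <- data.frame(group_a = labels[pairs[1, ]], group_b = labels[pairs[2, ]],
                   estimate = slopes[pairs[1, ]] - slopes[pairs[2, ]],
                   adjusted_p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(s2 * (1 / sxx[i] + 1 / sxx[j]))
    q <- abs(slopes[i] - slopes[j]) / (se / sqrt(2))
    pw$adjusted_p[k] <- stats::ptukey(q, g, df_full, lower.tail = FALSE)
  }
  structure(list(kind = "ancova_slopes", F_stat = Fst, p_value = p,
                 df = c(g - 1L, df_full), slopes = slopes, pairwise = pw),
            class = "axonav_group_comparison")
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Textbook between/within decomposition across groups (e.g. laps) with
#' studentized-range pairwise tests.  Groups with fewer than `min_n`
#' observations are dropped with a log line.
#'
#' @param values numeric observations.
#' @param group group label per observation (e.g. lap id).
#' @param reference optional reference group; pairwise rows against it are
#'   marked in `vs_reference`.
#' @param min_n minimum observations per group, default 2.
#' @return `axonav_group_comparison` with `kind = "anova_means"`.
#' @export
anova_tukey <- function(values, group, reference = NULL, min_n = 2L) {
  group <- as.character(group)
  tab <- table(group)
  drop <- names(tab)[tab < min_n]
  if (length(drop)) {
    log_msg("inference", "dropping groups with too few observations",
            c(groups = paste(drop, collapse = ",")))
    keep <- !group %in% drop
    values <- values[keep]; group <- group[keep]
  }
  labels <- unique(group)
  g <- length(labels)
  if (g < 2L) stopf("need >= 2 groups with >= %d observations", min_n)
  n <- length(values)
  gm <- mean(values)
  means <- vapply(labels, function(l) mean(values[group == l]), numeric(1))
  ns <- vapply(labels, function(l) sum(group == l), numeric(1))
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((values - means[match(group, labels)])^2)
  df_b <- g - 1L; df_w <- n - g
  msw <- ss_w / df_w
  Fst <- if (msw > 0) (ss_b / df_b) / msw else if (ss_b > 0) Inf else 0
  p <- stats::pf(Fst, df_b, df_w, lower.tail = FALSE)

  pairs <- utils::combn(g, 2)
  pw <- data.frame(group_a = labels[pairs[1, ]], group_b = labels[pairs[2, ]],
                   estimate = means[pairs[1, ]] - means[pairs[2, ]],
                   adjusted_p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
    q <- if (se > 0) abs(means[i] - means[j]) / (se / sqrt(2)) else
      if (means[i] != means[j]) Inf else 0
    pw$adjusted_p[k] <- stats::ptukey(q, g, df_w, lower.tail = FALSE)
  }
  pw$vs_reference <- if (!is.null(reference))
    pw$group_a == as.character(reference) | pw$group_b == as.character(reference)
  else NA
  structure(list(kind = "anova_means", F_stat = Fst, p_value = p,
                 df = c(df_b, df_w), means = means, n_per_group = ns,
                 pairwise = pw),
            class = "axonav_group_comparison")
}

#' Shuffle-bootstrap null band for population activity
#'
#' Builds the null distribution of the population mean: each shuffled trace
#' is an independent circular rotation of one ROI's full-session trace by a
#' uniform random offset of at least `min_shift_s` (preserving marginal
#' distribution and autocorrelation); each of `n_subsample_reps` replicates
#' draws `subsample_n` (ROI, rotation) traces from a pool of
#' `n_shuffles` pre-drawn rotations per ROI and averages them.  The
#' baseline mean and 95% CI are pointwise percentiles (2.5/97.5) across
#' replicates.  An optional `bin_fun` (e.g. 50-frame or lap binning) is
#' applied to every replicate mean before summarising, yielding the binned
#' baseline variants.
#'
#' @param traces matrix ROI x frames of mean-normalised activity.
#' @param subsample_n traces per replicate (at most the number of ROIs).
#' @param n_shuffles rotations drawn per ROI, default 1000.
#' @param n_subsample_reps replicates, default 1000.
#' @param frame_rate_hz sampling rate (for the minimum shift).
#' @param min_shift_s minimum rotation in seconds, default 30.
#' @param bin_fun optional function applied to each replicate's mean trace.
#' @param keep_reps when `TRUE` the replicate x point matrix is returned as
#'   `$reps` (useful for deriving further binned summaries without redrawing).
#' @param seed RNG seed.
#' @return list of class `"axonav_shuffle_baseline"`: `mean`, `ci_lo`,
#'   `ci_hi` (per point), plus the parameters.
#' @export
shuffle_baseline <- function(traces, subsample_n, n_shuffles = 1000L,
                             n_subsample_reps = 1000L, frame_rate_hz = 30,
                             min_shift_s = 30, bin_fun = NULL,
                             keep_reps = FALSE, seed = 1L) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  n_roi <- nrow(traces); n_t <- ncol(traces)
  if (subsample_n > n_roi)
    stopf("subsample_n (%d) exceeds available traces (%d)", subsample_n, n_roi)
  min_shift <- round(min_shift_s * frame_rate_hz)
  if (2L * min_shift >= n_t)
    stopf("traces too short for a %g s minimum rotation", min_shift_s)
  reps <- NULL
  with_seed(seed, {
    # pre-draw the rotation pool: n_shuffles offsets per ROI
    offsets <- matrix(floor(stats::runif(n_roi * n_shuffles, min_shift,
                                         n_t - min_shift + 1)),
                      nrow = n_roi)
    idx_base <- seq_len(n_t)
    for (r in seq_len(n_subsample_reps)) {
      pick <- sample.int(n_roi, subsample_n)
      acc <- numeric(n_t)
      for (i in pick) {
        o <- offsets[i, sample.int(n_shuffles, 1L)]
        rot <- ((idx_base - 1L + o) %% n_t) + 1L
        acc <- acc + traces[i, rot]
      }
      mtrace <- acc / subsample_n
      if (!is.null(bin_fun)) mtrace <- bin_fun(mtrace)
      if (is.null(reps)) reps <- matrix(NA_real_, n_subsample_reps, length(mtrace))
      reps[r, ] <- mtrace
    }
  })
  structure(list(
    mean = colMeans(reps),
    ci_lo = apply(reps, 2, stats::quantile, probs = 0.025, names = FALSE),
    ci_hi = apply(reps, 2, stats::quantile, probs = 0.975, names = FALSE),
    n_shuffles = n_shuffles, n_subsample_reps = n_subsample_reps,
    subsample_n = subsample_n,
    reps = if (keep_reps) reps else NULL),
    class = "axonav_shuffle_baseline")
}

#' Epochs where a series exceeds the null band
#'
#' Maximal runs of consecutive points strictly above the baseline's upper
#' 95% limit, kept when at least `min_run` long (2 for frame-resolution
#' series; 1 for lap or 50-frame bins, where a single bin already spans
#' many frames).
#'
#' @param series observed population series (same length as the baseline).
#' @param baseline an `axonav_shuffle_baseline`.
#' @param min_run minimum run length, default 2.
#' @param frame_rate_hz when given, segment durations are also reported in
#'   seconds (`frames / frame_rate_hz`).
#' @return list of class `"axonav_runs"`: `segments` data.frame with
#'   half-open `[start, end)` 0-based indices, `length`, and `duration_s`.
#' @export
detect_significant_runs <- function(series, baseline, min_run = 2L,
                                    frame_rate_hz = NULL) {
  if (length(series) != length(baseline$ci_hi))
    stopf("series length (%d) != baseline length (%d)", length(series),
          length(baseline$ci_hi))
  above <- series > baseline$ci_hi
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  seg <- data.frame(start = starts[keep] - 1L, end = ends[keep],
                    length = r$lengths[keep])
  seg$duration_s <- if (!is.null(frame_rate_hz)) seg$length / frame_rate_hz
                    else rep(NA_real_, nrow(seg))
  structure(list(segments = seg, min_run = min_run), class = "axonav_runs")
}
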