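#' Normalise intensity values to a control group
#'
#' Divides every value by the mean of the control group, so the control
#' maps to mean 1 and other genotypes are expressed as fold changes
#' relative to it — the normalisation used for per-Z-disc fluorescence
#' comparisons.
#'
#' @param values Numeric vector to normalise.
#' @param control_values Numeric vector of control-group values; must be
#'   non-empty with a positive mean.
#' @return `values / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0L)
    stop("`control_values` must be non-empty")
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be positive")
  values / m
}

#' BiFC signal-to-background ratios
#'
#' Bimolecular fluorescence complementation readout: each sample's
#' Z-disc profile peak divided by the off-disc background level. Ratios
#' near 1 indicate no complementation (signal at the noise floor); an
#' interaction shows as ratios well above 1. With one background value
#' per sample the division is pairwise; with a pooled background vector
#' every peak is divided by the pooled mean.
#'
#' @param zdisc_peak_values Per-sample peak intensities.
#' @param background_values Per-sample backgrounds (same length) or a
#'   pooled background sample.
#' @return Numeric vector of per-sample ratios.
#' @export
bifc_signal <- function(zdisc_peak_values, background_values) {
  if (length(background_values) == 0L)
    stop("`background_values` must be non-empty")
  if (length(background_values) == length(zdisc_peak_values)) {
    if (any(background_values <= 0)) stop("background values must be > 0")
    return(zdisc_peak_values / background_values)
  }
  m <- mean(background_values)
  if (!is.finite(m) || m <= 0) stop("background mean must be positive")
  zdisc_peak_values / m
}

# log-probability of a contingency table under fixed margins
log_table_prob <- function(x) {
  sum(lgamma(rowSums(x) + 1)) + sum(lgamma(colSums(x) + 1)) -
    lgamma(sum(x) + 1) - sum(lgamma(x + 1))
}

validate_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts))
    stop("contingency table must contain non-negative integers")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate margins: every row and column must have a positive sum")
  storage.mode(counts) <- "double"
  counts
}

# Enumerate all tables with the given margins, applying f(table, logp).
enumerate_margin_tables <- function(rs, cs, f) {
  R <- length(rs); C <- length(cs)
  tab <- matrix(0, R, C)
  rec_row <- function(r, cs_left) {
    if (r == R) {
      tab[R, ] <<- cs_left
      f(tab)
      return(invisible())
    }
    fill_row <- function(j, left, cs_left) {
      if (j == C) {
        if (left <= cs_left[C]) {
          tab[r, C] <<- left
          cs2 <- cs_left; cs2[C] <- cs2[C] - left
          rec_row(r + 1L, cs2)
        }
        return(invisible())
      }
      for (x in 0:min(left, cs_left[j])) {
        tab[r, j] <<- x
        cs2 <- cs_left; cs2[j] <- cs2[j] - x
        fill_row(j + 1L, left - x, cs2)
      }
    }
    fill_row(1L, rs[r], cs_left)
  }
  rec_row(1L, cs)
}

#' Fisher's exact test for count data
#'
#' Two-sided exact test of independence for an R x C contingency table
#' of counts (size categories x genotypes, aggregate-positive tile
#' counts, ...). For 2 x 2 tables the p-value is the sum of
#' hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one. Larger tables with
#' total `N <= exact_limit` are handled by full enumeration over tables
#' with the observed margins; beyond that a seeded Monte-Carlo estimate
#' over `mc_replicates` random tables (via [stats::r2dtable()]) is
#' returned together with its standard error.
#'
#' @param counts Integer matrix (or table) of counts; no all-zero row
#'   or column.
#' @param exact_limit Largest total count enumerated exactly for R x C
#'   tables (default 200).
#' @param mc_replicates Monte-Carlo replicates beyond the exact limit.
#' @param seed Seed for the Monte-Carlo draw.
#' @return An object of class `zq_test_result`: list with `method`,
#'   `p_value`, `statistic` (NA for exact tests), `df` (NA),
#'   `mc_replicates`, `mc_se`, `seed`.
#' @export
fisher_exact <- function(counts, exact_limit = 200, mc_replicates = 1e5,
                         seed = 1L) {
  x <- validate_contingency(counts)
  n <- sum(x)
  lp_obs <- log_table_prob(x)
  tol <- 1e-7                      # relative slack for fp-equal probabilities
  if (nrow(x) == 2 && ncol(x) == 2) {
    k <- 0:min(rowSums(x)[1], colSums(x)[1])
    lp <- vapply(k, function(a) {
      t <- matrix(c(a, rowSums(x)[1] - a, colSums(x)[1] - a,
                    n - rowSums(x)[1] - colSums(x)[1] + a), 2, 2)
      if (any(t < 0)) -Inf else log_table_prob(t)
    }, numeric(1))
    p <- sum(exp(lp[lp <= lp_obs + tol]))
    return(test_result("Fisher's exact test for count data (2x2)",
                       p_value = min(1, p)))
  }
  if (n <= exact_limit) {
    acc <- new.env(); acc$p <- 0
    enumerate_margin_tables(rowSums(x), colSums(x), function(tab) {
      lp <- log_table_prob(tab)
      if (lp <= lp_obs + tol) acc$p <- acc$p + exp(lp)
    })
    return(test_result("Fisher's exact test for count data (enumeration)",
                       p_value = min(1, acc$p)))
  }
  hits <- with_local_seed(seed, {
    tabs <- stats::r2dtable(mc_replicates, rowSums(x), colSums(x))
    sum(vapply(tabs, log_table_prob, numeric(1)) <= lp_obs + tol)
  })
  p <- (hits + 1) / (mc_replicates + 1)
  test_result("Fisher's exact test for count data (Monte-Carlo)",
              p_value = p, mc_replicates = mc_replicates,
              mc_se = sqrt(p * (1 - p) / mc_replicates), seed = seed)
}

test_result <- function(method, p_value, statistic = NA_real_,
                        df = NA_real_, mc_replicates = NA_integer_,
                        mc_se = NA_real_, seed = NA_integer_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, mc_replicates = mc_replicates,
                 mc_se = mc_se, seed = seed),
            class = "zq_test_result")
}

#' @export
print.zq_test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic))
    cat(sprintf("  t = %.4g, df = %.4g\n", x$statistic, x$df))
  cat(sprintf("  p = %.4g%s\n", x$p_value,
              if (!is.na(x$mc_se))
                sprintf(" (MC se %.2g, B = %d, seed %d)",
                        x$mc_se, x$mc_replicates, x$seed) else ""))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees
#' of freedom, the test used for comparing relative fluorescence
#' intensities, BiFC ratios and aggregate-frequency estimates between
#' groups: `t = (mean(a) - mean(b)) / sqrt(var(a)/na + var(b)/nb)`,
#' two-sided p from the t distribution.
#'
#' @param a,b Numeric vectors, each of length >= 2; at least one group
#'   must have positive variance.
#' @return A `zq_test_result` with `statistic`, `df` and `p_value`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("both groups have zero variance: t is undefined")
  sa <- va / length(a); sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  test_result("Welch's two-sample t-test", p_value = p, statistic = t,
              df = df)
}
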