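# Independent oracles used across tests. These deliberately share no
# code with the package implementations they check.

# Exhaustive scan for the smallest iterative-intermeans fixed point on a
# 256-bin histogram: the smallest t (bin index) with both sides occupied
# and t == floor((mean(bins <= t) + mean(bins > t)) / 2).
oracle_intermeans <- function(counts) {
  levels <- 0:255
  occ <- which(counts > 0) - 1L
  for (t in occ[1]:(occ[length(occ)] - 1L)) {
    lo <- 0:t; hi <- (t + 1):255
    mu_lo <- sum(levels[lo + 1] * counts[lo + 1]) / sum(counts[lo + 1])
    mu_hi <- sum(levels[hi + 1] * counts[hi + 1]) / sum(counts[hi + 1])
    if (t == floor((mu_lo + mu_hi) / 2)) return(t)
  }
  NA_integer_
}

# Two-sided Fisher p for a 2x2 table by direct enumeration over the
# free cell, using factorial arithmetic only.
oracle_fisher_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob_a <- function(a) {
    b <- rs[1] - a; c <- cs[1] - a; d <- n - rs[1] - cs[1] + a
    if (min(b, c, d) < 0) return(0)
    exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
          sum(lfactorial(c(a, b, c, d))))
  }
  p_obs <- prob_a(tab[1, 1])
  ps <- vapply(0:min(rs[1], cs[1]), prob_a, numeric(1))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Brute-force connected-component count by breadth-first flood fill.
oracle_component_count <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (eight) expand.grid(dr = -1:1, dc = -1:1)
          else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  n <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs$dr[k]; c <- p[2] + offs$dc[k]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  n
}

# A small noise- and blur-free longitudinal field whose geometry is
# forced by construction (used by several suites).
clean_field_params <- function(...) {
  longitudinal_params(psf_sigma_um = 0,
                      noise = noise_params(poisson_gain = 0,
                                           gaussian_sd = 0, seed = 1L),
                      ...)
}

# Match truth bands to particles by nearest centroid; errors if the
# matching is not one-to-one.
match_truth_particles <- function(truth, particles) {
  bands <- truth[truth$object_kind == "zdisc", ]
  idx <- vapply(seq_len(nrow(bands)), function(i) {
    d2 <- (particles$centroid_x_px - bands$centre_x_px[i])^2 +
      (particles$centroid_y_px - bands$centre_y_px[i])^2
    which.min(d2)
  }, integer(1))
  stopifnot(!anyDuplicated(idx))
  list(truth = bands, particle_idx = idx)
}
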