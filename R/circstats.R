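# Circular statistics: vector strength, circular mean +/- S.E.M., the
# Jammalamadaka-SenGupta circular correlation, and the paired second-order
# Hotelling test for circular data (Zar's formulation).

#' Construct an angle sample
#'
#' Angles are reduced modulo 2*pi onto `[0, 2*pi)`. `n` is the number of
#' stimulus repetitions that produced the reset angles.
#'
#' @param angles numeric vector of angles in radians.
#' @return object of class `angle_sample`.
#' @export
angle_sample <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 1) stop("angle_sample needs at least one angle")
  check_finite(angles, "angles")
  angles <- angles %% (2 * pi)
  structure(list(angles = angles, n = length(angles)), class = "angle_sample")
}

#' Construct a paired angle sample
#'
#' Used for paired comparisons such as reset phases evoked by normal- versus
#' reversed-polarity stimuli. The paired Hotelling test needs `n_pairs >= 3`.
#'
#' @param angles_a,angles_b equal-length numeric vectors of angles (radians).
#' @return object of class `paired_angle_sample`.
#' @export
paired_angle_sample <- function(angles_a, angles_b) {
  a <- as.numeric(angles_a); b <- as.numeric(angles_b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  check_finite(a, "angles_a"); check_finite(b, "angles_b")
  structure(list(angles_a = a %% (2 * pi), angles_b = b %% (2 * pi),
                 n_pairs = length(a)),
            class = "paired_angle_sample")
}

as_angles <- function(x) {
  if (inherits(x, "angle_sample")) x$angles else angle_sample(x)$angles
}

#' Vector strength of a set of phases
#'
#' \deqn{r = \sqrt{(\sum \cos\phi / n)^2 + (\sum \sin\phi / n)^2}}
#'
#' equals 1 when all angles are identical across stimulus repetitions and 0
#' when the angles carry no phase preference.
#'
#' @param sample an [angle_sample()] or numeric vector of radians.
#' @return list with `r` (in `[0, 1]`) and `mean_angle` (radians, the angle
#'   of the resultant vector; `NA` when `r` is numerically 0).
#' @export
vector_strength <- function(sample) {
  a <- as_angles(sample)
  n <- length(a)
  C <- sum(cos(a)) / n
  S <- sum(sin(a)) / n
  r <- sqrt(C^2 + S^2)
  mean_angle <- if (r < 1e-14) NA_real_ else atan2(S, C) %% (2 * pi)
  list(r = min(r, 1), mean_angle = mean_angle)
}

#' Circular correlation coefficient (sine-product estimator)
#'
#' Jammalamadaka-SenGupta estimator
#' \deqn{r_{cc} = \frac{\sum \sin(\alpha_i - \bar\alpha)\sin(\beta_i - \bar\beta)}
#'   {\sqrt{\sum \sin^2(\alpha_i - \bar\alpha) \sum \sin^2(\beta_i - \bar\beta)}}}
#' with circular means \eqn{\bar\alpha, \bar\beta}.
#'
#' When a sample's circular mean is undefined (resultant length numerically
#' zero, e.g. angles evenly spaced on the circle), the estimator falls back
#' to the equivalent mean-free pairwise form
#' \eqn{\sum_{i<j} \sin(\alpha_i-\alpha_j)\sin(\beta_i-\beta_j)} over the
#' analogous normalizer.
#'
#' @param a,b equal-length angle vectors or [angle_sample()] objects.
#' @return correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(a, b) {
  a <- as_angles(a); b <- as_angles(b)
  if (length(a) != length(b)) stop("samples must have equal length")
  if (length(a) < 2) stop("need at least two angles per sample")
  n <- length(a)
  Ra <- sqrt(sum(sin(a))^2 + sum(cos(a))^2)
  Rb <- sqrt(sum(sin(b))^2 + sum(cos(b))^2)
  if (Ra < 1e-8 * n || Rb < 1e-8 * n) {
    da <- outer(a, a, `-`); db <- outer(b, b, `-`)
    lower <- lower.tri(da)
    sa <- sin(da[lower]); sb <- sin(db[lower])
    va <- sum(sa^2); vb <- sum(sb^2)
    if (va <= .Machine$double.eps * n)
      stop("degenerate sample 'a': zero circular variance")
    if (vb <= .Machine$double.eps * n)
      stop("degenerate sample 'b': zero circular variance")
    return(max(-1, min(1, sum(sa * sb) / sqrt(va * vb))))
  }
  ma <- atan2(sum(sin(a)), sum(cos(a)))
  mb <- atan2(sum(sin(b)), sum(cos(b)))
  sa <- sin(a - ma); sb <- sin(b - mb)
  va <- sum(sa^2); vb <- sum(sb^2)
  if (va <= .Machine$double.eps * length(a))
    stop("degenerate sample 'a': zero circular variance")
  if (vb <= .Machine$double.eps * length(b))
    stop("degenerate sample 'b': zero circular variance")
  r <- sum(sa * sb) / sqrt(va * vb)
  max(-1, min(1, r))
}

#' Paired second-order Hotelling test for circular data
#'
#' Tests whether two paired sets of angles share a common mean direction by
#' testing whether the mean of the per-pair rectangular difference vectors
#' \eqn{(X_j, Y_j) = (\cos a_j - \cos b_j,\; \sin a_j - \sin b_j)} is the
#' origin. With \eqn{\bar X, \bar Y} the means and \eqn{x = X - \bar X},
#' \eqn{y = Y - \bar Y}:
#' \deqn{F = \frac{n(n-2)}{2} \cdot
#'   \frac{\bar X^2 \sum y^2 - 2 \bar X \bar Y \sum xy + \bar Y^2 \sum x^2}
#'        {\sum x^2 \sum y^2 - (\sum xy)^2}}
#' referred to the F distribution with (2, n - 2) degrees of freedom.
#'
#' @param sample a [paired_angle_sample()].
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `F_crit`, `p_value`, `significant`, `df`.
#' @export
hotelling_paired <- function(sample, alpha = 0.05) {
  if (!inherits(sample, "paired_angle_sample"))
    stop("sample must be a paired_angle_sample")
  n <- sample$n_pairs
  if (n < 3) stop("hotelling_paired needs at least 3 pairs (df = n - 2)")
  X <- cos(sample$angles_a) - cos(sample$angles_b)
  Y <- sin(sample$angles_a) - sin(sample$angles_b)
  Xb <- mean(X); Yb <- mean(Y)
  x <- X - Xb; y <- Y - Yb
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  denom <- sxx * syy - sxy^2
  if (denom <= 0) {
    # difference vectors perfectly collinear or identical; F degenerates
    Fstat <- if (Xb == 0 && Yb == 0) 0 else Inf
  } else {
    Fstat <- (n * (n - 2) / 2) * (Xb^2 * syy - 2 * Xb * Yb * sxy + Yb^2 * sxx) / denom
  }
  F_crit <- qf(1 - alpha, 2, n - 2)
  list(F = Fstat, F_crit = F_crit,
       p_value = pf(Fstat, 2, n - 2, lower.tail = FALSE),
       significant = Fstat > F_crit, df = c(2, n - 2))
}

#' Circular mean and angular standard error
#'
#' The angular S.E.M. is the circular standard deviation
#' \eqn{\sqrt{-2 \ln r}} divided by \eqn{\sqrt{n}}; a dispersion-based
#' convention chosen because no formula is standard for "angular S.E.M."
#'
#' @param sample an [angle_sample()] or numeric vector of radians.
#' @return list with `mean` (radians in `[0, 2*pi)`) and `sem` (radians).
#' @export
circular_mean_sem <- function(sample) {
  a <- as_angles(sample)
  n <- length(a)
  if (n < 2) stop("circular_mean_sem needs n >= 2")
  vs <- vector_strength(a)
  if (vs$r < 1e-14) stop("mean direction undefined: vector strength is 0")
  r <- min(vs$r, 1)
  list(mean = vs$mean_angle, sem = sqrt(-2 * log(r)) / sqrt(n))
}
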