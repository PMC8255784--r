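#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A one-row tibble: exact fractions (`sensitivity`, `specificity`),
#'   two-decimal presentations (`sensitivity_2dp`, `specificity_2dp`, rounded
#'   half-up), and the counts. Undefined denominators yield `NA`.
#' @export
#' @examples
#' sensitivity_specificity(tp = 12, fn = 2, tn = 19, fp = 4)
sensitivity_specificity <- function(tp, fp, tn, fn) {
  stopifnot_msg(all(c(tp, fp, tn, fn) >= 0), "counts must be non-negative")
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    sensitivity = se, specificity = sp,
    sensitivity_2dp = round_half_up(se, 2),
    specificity_2dp = round_half_up(sp, 2),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Quadrant thresholds for the AAPE x IEIN classifier
#'
#' The published classifier places arrhythmia-free animals in the
#' bottom-left quadrant below arbitrary thresholds of 1.975 (AAPE) and 670
#' (IEIN sigma). Those numbers are specific to one entropy parameterization;
#' they are shipped as defaults for reproducing the rule, not as calibrated
#' values for other configurations.
#'
#' @param aape_threshold AAPE cut (default 1.975).
#' @param iein_threshold IEIN sigma cut (default 670).
#' @return A list of class `quadrant_thresholds`.
#' @export
quadrant_thresholds <- function(aape_threshold = 1.975, iein_threshold = 670) {
  stopifnot_msg(is.finite(aape_threshold) && is.finite(iein_threshold),
                "thresholds must be finite")
  structure(list(aape_threshold = aape_threshold,
                 iein_threshold = iein_threshold),
            class = "quadrant_thresholds")
}

#' Bottom-left-quadrant low-risk call
#'
#' An animal is flagged low risk when its AAPE and IEIN sigma both fall
#' strictly below their thresholds (the bottom-left quadrant). Missing
#' entropy values return `NA`: such animals are excluded from stratification.
#'
#' @param aape,iein_sigma Entropy values (vectorized).
#' @param thresholds A [quadrant_thresholds()].
#' @return Logical vector (NA where input is missing).
#' @export
#' @examples
#' quadrant_low_risk(1.5, 500)   # TRUE
#' quadrant_low_risk(1.975, 500) # FALSE: strict comparison
quadrant_low_risk <- function(aape, iein_sigma,
                              thresholds = quadrant_thresholds()) {
  aape < thresholds$aape_threshold & iein_sigma < thresholds$iein_threshold
}

#' Midpoint threshold calibration
#'
#' Chooses a classification threshold on training data so every positive-class
#' value falls strictly below it: the midpoint between the positive-class
#' maximum and the smallest negative-class value above it (or a small margin
#' above the positive maximum when the classes overlap).
#'
#' @param values Numeric scores (lower = more likely positive class).
#' @param positive Logical vector: TRUE for the class that must fall below
#'   the threshold.
#' @return The threshold.
#' @export
choose_threshold <- function(values, positive) {
  stopifnot_msg(any(positive) && any(!positive),
                "both classes must be present")
  hi <- max(values[positive])
  above <- values[!positive][values[!positive] > hi]
  if (length(above) > 0) (hi + min(above)) / 2 else hi * (1 + 1e-6) + 1e-9
}

#' Two-sample proportion test
#'
#' Pooled-proportion z test of `k1/n1` vs `k2/n2`, two-sided normal p value,
#' without continuity correction by default (a corrected variant is
#' available). Identical proportions give z = 0, p = 1.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @param correct Apply the continuity correction (default FALSE).
#' @return A one-row tibble of class `prop_test_result`: `z`, `p_value`,
#'   `p1`, `p2`, and the counts.
#' @export
#' @examples
#' two_sample_proportion_test(10, 12, 2, 11) # z ~ 3.12, p ~ 0.0018
two_sample_proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot_msg(n1 >= 1 && n2 >= 1, "group sizes must be at least 1")
  stopifnot_msg(k1 >= 0 && k1 <= n1 && k2 >= 0 && k2 <= n2,
                "counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  num <- p1 - p2
  if (correct) {
    cc <- (1 / n1 + 1 / n2) / 2
    num <- sign(num) * max(abs(num) - cc, 0)
  }
  z <- if (se == 0) 0 else num / se
  out <- tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)),
                        p1 = p1, p2 = p2, k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  class(out) <- c("prop_test_result", class(out))
  out
}

#' Grubbs test for a single outlier
#'
#' G = max |x - mean| / sd compared against the t-based critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`. At most one outlier per pass; set
#' `iterate = TRUE` to repeat on the reduced sample until no outlier remains.
#' Zero-variance samples contain no outlier.
#'
#' @param values Numeric sample (n >= 3).
#' @param alpha Significance level (default 0.05).
#' @param iterate Repeat passes (default FALSE).
#' @return A tibble of flagged outliers (possibly empty): `index`, `value`,
#'   `g`, `g_critical`.
#' @export
#' @examples
#' grubbs_test(c(10, 10.1, 9.9, 25))
grubbs_test <- function(values, alpha = 0.05, iterate = FALSE) {
  stopifnot_msg(length(values) >= 3, "need at least 3 values")
  empty <- tibble::tibble(index = integer(), value = numeric(),
                          g = numeric(), g_critical = numeric())
  active <- seq_along(values)
  out <- empty
  repeat {
    x <- values[active]
    n <- length(x)
    if (n < 3) break
    s <- sd(x)
    if (s == 0) break
    g <- abs(x - mean(x)) / s
    i <- which.max(g)
    tcrit <- qt(1 - alpha / (2 * n), n - 2)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g[i] <= gcrit) break
    out <- dplyr::bind_rows(out, tibble::tibble(
      index = active[i], value = x[i], g = g[i], g_critical = gcrit))
    if (!iterate) break
    active <- active[-i]
  }
  out
}

#' Friedewald LDL cholesterol
#'
#' LDL = TC - HDL - TAG / 2.2, all in mmol/L. Negative results are returned
#' with a warning: the formula is not valid at high triglyceride levels.
#'
#' @param tc,hdl,tag Total cholesterol, HDL cholesterol and triglycerides in
#'   mmol/L (vectorized, all >= 0).
#' @return LDL cholesterol in mmol/L.
#' @export
#' @examples
#' friedewald_ldl(1.65, 1.1, 0.36) # ~0.386 -> 0.39 at 2 decimals
friedewald_ldl <- function(tc, hdl, tag) {
  stopifnot_msg(all(c(tc, hdl, tag) >= 0, na.rm = TRUE),
                "lipid inputs must be non-negative")
  ldl <- tc - hdl - tag / 2.2
  if (any(ldl < 0, na.rm = TRUE)) {
    warn("negative LDL estimate: outside the validity range of the formula")
  }
  ldl
}
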