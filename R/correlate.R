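#' Pearson product-moment correlation
#'
#' Thin, contract-checked wrapper around the definitional formula: equal
#' lengths of at least 3 and both vectors nonconstant; constant input
#' yields `NA` (reported missing) rather than an error mid-table.
#'
#' @param x,y numeric vectors.
#' @return Coefficient in `[-1, 1]`, or `NA` for constant input.
#' @export
pearson <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3, "need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlate per-condition texture means with observer AUC
#'
#' Mirrors a three-column correlation report: per feature, the Pearson
#' coefficient over the unfiltered ("noisy") arm, over the Wiener-filtered
#' arm, and over the pooled arms (the combined column pools the
#' 2 x length(subset) condition points, not the average of the two per-arm
#' coefficients). Correlations use condition means only.
#'
#' @param features data frame with columns `P`, `filtered` (logical),
#'   `feature`, `mean` (per-condition feature means).
#' @param aucs data frame with columns `P`, `filtered`, `auc`.
#' @param subset the projection numbers to correlate over (default the
#'   five observer-study values 3, 7, 11, 25, 45).
#' @param threshold highlight threshold on `|r|` (default 0.85).
#' @return A `correlation_table` data frame: `feature`, `r_noisy`,
#'   `r_filtered`, `r_combined`, `highlighted`.
#' @export
correlate_conditions <- function(features, aucs,
                                 subset = c(3, 7, 11, 25, 45),
                                 threshold = 0.85) {
  need_f <- c("P", "filtered", "feature", "mean")
  need_a <- c("P", "filtered", "auc")
  .assert(all(need_f %in% names(features)),
          paste("features needs columns:", paste(need_f, collapse = ", ")))
  .assert(all(need_a %in% names(aucs)),
          paste("aucs needs columns:", paste(need_a, collapse = ", ")))
  for (arm in c(FALSE, TRUE)) {
    have <- unique(aucs$P[aucs$filtered == arm])
    miss <- setdiff(subset, have)
    .assert(length(miss) == 0,
            paste0("missing AUC conditions (filtered=", arm, "): ",
                   paste(miss, collapse = ", ")))
  }
  feats <- unique(features$feature)
  rows <- lapply(feats, function(f) {
    get_arm <- function(arm) {
      fsub <- features[features$feature == f & features$filtered == arm &
                         features$P %in% subset, ]
      asub <- aucs[aucs$filtered == arm & aucs$P %in% subset, ]
      .assert(all(subset %in% fsub$P),
              paste0("missing feature conditions for ", f))
      m <- fsub$mean[match(subset, fsub$P)]
      a <- asub$auc[match(subset, asub$P)]
      list(m = m, a = a)
    }
    noisy <- get_arm(FALSE); filt <- get_arm(TRUE)
    data.frame(feature = f,
               r_noisy = pearson(noisy$m, noisy$a),
               r_filtered = pearson(filt$m, filt$a),
               r_combined = pearson(c(noisy$m, filt$m), c(noisy$a, filt$a)))
  })
  tab <- do.call(rbind, rows)
  tab$highlighted <- tab$feature %in% highlight_features(tab, threshold)
  class(tab) <- c("correlation_table", "data.frame")
  attr(tab, "threshold") <- threshold
  tab
}

#' Features highly correlated in all three columns
#'
#' A feature is highlighted when `|r| >= threshold` in the noisy, filtered
#' and combined columns simultaneously. Comparison happens at printed
#' 4-decimal precision, and with `>=` rather than `>`: a coefficient that
#' prints as exactly 0.8500 counts as highly correlated.
#'
#' @param table data frame with `feature`, `r_noisy`, `r_filtered`,
#'   `r_combined`.
#' @param threshold absolute-correlation threshold (default 0.85).
#' @return Character vector of feature names, in table order.
#' @export
highlight_features <- function(table, threshold = 0.85) {
  cols <- c("r_noisy", "r_filtered", "r_combined")
  .assert(all(c("feature", cols) %in% names(table)),
          "table must have feature, r_noisy, r_filtered, r_combined")
  ok <- rep(TRUE, nrow(table))
  for (cl in cols) {
    r <- round(abs(table[[cl]]), 4)
    ok <- ok & !is.na(r) & r >= threshold
  }
  table$feature[ok]
}

#' Classify the concavity of a feature-versus-P curve
#'
#' Least-squares parabola in the projection number; the sign of the
#' quadratic coefficient gives the label. The curvature is called
#' indeterminate when its peak-to-edge effect `|a| * (range(P)/2)^2` is
#' below `rel_tol` times the observed value range (or when the values are
#' constant).
#'
#' @param values feature means at increasing `P`.
#' @param P projection numbers (same length, >= 4 points).
#' @param rel_tol relative curvature tolerance (default 0.01).
#' @return `"concave-up"`, `"concave-down"`, or `"indeterminate"`.
#' @export
classify_concavity <- function(values, P, rel_tol = 0.01) {
  .assert(length(values) == length(P), "values and P must match")
  .assert(length(values) >= 4, "need at least 4 points to classify concavity")
  rng <- diff(range(values))
  if (rng == 0) return("indeterminate")
  fit <- stats::lm(values ~ P + I(P^2))
  a <- stats::coef(fit)[["I(P^2)"]]
  effect <- abs(a) * (diff(range(P)) / 2)^2
  if (!is.finite(a) || effect < rel_tol * rng) return("indeterminate")
  if (a > 0) "concave-up" else "concave-down"
}

#' Published worked-example correlation matrix
#'
#' The 13 x 3 reference matrix of Pearson coefficients between texture
#' features and observer AUC shipped with the package for the worked
#' example and its tests (values as printed in the source report, at their
#' printed precision).
#'
#' @return Data frame with `feature`, `display`, `r_noisy`, `r_filtered`,
#'   `r_combined`.
#' @export
reference_correlation_table <- function() {
  path <- system.file("extdata", "reference_correlations.csv",
                      package = "tomotex", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
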