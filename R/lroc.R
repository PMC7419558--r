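#' Build training and test session lists
#'
#' Seeded shuffle of the manifest rows for one condition into disjoint
#' training and test image lists.
#'
#' @param manifest data frame with one row per image; must contain a
#'   logical `truth` column.
#' @param n_train,n_test session sizes (defaults 18 and 54).
#' @param seed integer RNG seed.
#' @return List with `train` and `test` data frames and the
#'   lesion-present/absent `mixture` of the test set.
#' @export
build_sessions <- function(manifest, n_train = 18L, n_test = 54L, seed = 1L) {
  .assert(is.data.frame(manifest) && "truth" %in% names(manifest),
          "manifest must be a data frame with a truth column")
  n_train <- as.integer(n_train); n_test <- as.integer(n_test)
  .assert(nrow(manifest) >= n_train + n_test,
          sprintf("insufficient images: have %d, need %d",
                  nrow(manifest), n_train + n_test))
  set.seed(as.integer(seed))
  ord <- sample.int(nrow(manifest))
  train <- manifest[ord[seq_len(n_train)], , drop = FALSE]
  test <- manifest[ord[n_train + seq_len(n_test)], , drop = FALSE]
  list(train = train, test = test,
       mixture = c(present = sum(test$truth), absent = sum(!test$truth)))
}

#' Score a localization attempt
#'
#' Correct iff the Euclidean distance between the marked point and the true
#' centre is `<= radius` (a mark exactly at the radius counts as correct).
#'
#' @param marked numeric length-2 marked location (row, col), pixels.
#' @param true_center numeric length-2 true centre.
#' @param radius acceptance radius in pixels (default 15).
#' @return Logical.
#' @export
score_localization <- function(marked, true_center, radius = 15) {
  .assert(length(marked) == 2 && length(true_center) == 2,
          "marked and true_center must be length-2 points")
  sqrt(sum((marked - true_center)^2)) <= radius
}

#' Localization-corrected AUC via the Wilcoxon statistic
#'
#' `AUC = (1 / (N_p * N_a)) * sum over (present p, absent a) pairs of
#' c_p * [I(r_p > r_a) + 0.5 * I(r_p = r_a)]`, where `c_p = 1` iff trial
#' `p` was correctly localized. Ties in the rating contribute one half, as
#' in the Wilcoxon rank-sum statistic. Equivalent to exhaustive pair
#' counting, computed here from rating tallies.
#'
#' @param trials data frame with columns `truth` (logical), `rating`
#'   (integers), and `correct_loc` (logical; only consulted on present
#'   trials).
#' @return A `study_result`: list with `auc`, `n_present`, `n_absent`,
#'   `loc_fraction` (fraction of present trials correctly localized).
#' @export
lroc_auc <- function(trials) {
  .assert(is.data.frame(trials) &&
            all(c("truth", "rating", "correct_loc") %in% names(trials)),
          "trials needs columns truth, rating, correct_loc")
  pres <- trials[trials$truth, , drop = FALSE]
  abs_ <- trials[!trials$truth, , drop = FALSE]
  .assert(nrow(pres) >= 1 && nrow(abs_) >= 1,
          "need at least one present and one absent trial")
  ra <- abs_$rating
  num <- 0
  for (k in seq_len(nrow(pres))) {
    if (!isTRUE(pres$correct_loc[k])) next
    num <- num + sum(pres$rating[k] > ra) + 0.5 * sum(pres$rating[k] == ra)
  }
  structure(list(auc = num / (nrow(pres) * nrow(abs_)),
                 n_present = nrow(pres), n_absent = nrow(abs_),
                 loc_fraction = mean(pres$correct_loc)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("LROC result: AUC = %.4f (%d present, %d absent, %.0f%% localized)\n",
              x$auc, x$n_present, x$n_absent, 100 * x$loc_fraction))
  invisible(x)
}

#' Parametric synthetic observer
#'
#' Stand-in for human readers so the pipeline can be exercised end to end.
#' Each test trial draws a latent score `z + detectability * truth` with
#' `z ~ N(0, 1)`, thresholded into ratings 1-4 at the empirical quartiles
#' of the session's latent scores (an observer spreading their confidence
#' scale over what they actually see). A present trial is "perceived" when
#' its latent score exceeds the session median; perceived trials mark the
#' true centre plus isotropic Gaussian error of SD `loc_error_scale`
#' (clamped to the image), while absent or missed trials guess uniformly
#' over `guess_area`. All random draws are made up front per trial, so a
#' fixed seed yields common random numbers across `detectability` values.
#'
#' @param session data frame of test trials: `truth` (logical), and for
#'   present trials `center_row`, `center_col` (pixels).
#' @param detectability latent-score separation (>= 0, finite).
#' @param loc_error_scale SD of the localization error for perceived
#'   trials, pixels (>= 0).
#' @param guess_area logical matrix (e.g. the breast mask): support of the
#'   uniform guess; must be nonempty.
#' @param seed integer RNG seed.
#' @return Data frame of trial records: `truth`, `rating` (1-4),
#'   `marked_row`, `marked_col`, `correct_loc`, `perceived`.
#' @export
simulate_observer <- function(session, detectability, loc_error_scale,
                              guess_area, seed = 1L) {
  .assert(is.finite(detectability) && detectability >= 0,
          "detectability must be finite and >= 0")
  .assert(loc_error_scale >= 0, "loc_error_scale must be >= 0")
  .assert(is.matrix(guess_area) && any(guess_area),
          "guess_area must be a nonempty logical matrix")
  n <- nrow(session)
  .assert(n >= 1, "empty session")
  set.seed(as.integer(seed))
  z <- rnorm(n)
  gx <- rnorm(n); gy <- rnorm(n)
  cells <- which(guess_area, arr.ind = TRUE)
  guess_ix <- sample.int(nrow(cells), n, replace = TRUE)

  latent <- z + detectability * as.numeric(session$truth)
  cuts <- stats::quantile(latent, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  rating <- findInterval(latent, cuts) + 1L
  perceived <- session$truth & latent > cuts[2]

  mr <- cells[guess_ix, 1]
  mc <- cells[guess_ix, 2]
  if (any(perceived)) {
    pr <- which(perceived)
    mr[pr] <- pmin(pmax(session$center_row[pr] + loc_error_scale * gx[pr], 1),
                   nrow(guess_area))
    mc[pr] <- pmin(pmax(session$center_col[pr] + loc_error_scale * gy[pr], 1),
                   ncol(guess_area))
  }
  correct <- rep(NA, n)
  for (k in which(session$truth)) {
    correct[k] <- score_localization(
      c(mr[k], mc[k]), c(session$center_row[k], session$center_col[k]))
  }
  data.frame(truth = session$truth, rating = rating,
             marked_row = mr, marked_col = mc,
             correct_loc = correct, perceived = perceived)
}

#' Expected AUC of the synthetic observer at a given detectability
#'
#' Monte Carlo estimate over synthetic sessions, usable to invert the
#' AUC-detectability relationship (parameter recovery).
#'
#' @param detectability scalar >= 0.
#' @param n_trials total trials per session (half present).
#' @param guess_area logical matrix for the uniform guess.
#' @param loc_error_scale localization error SD, pixels.
#' @param seed integer RNG seed.
#' @param center optional true centre (defaults to the guess-area centre).
#' @return Scalar AUC estimate.
#' @export
observer_auc <- function(detectability, n_trials = 2000L, guess_area,
                         loc_error_scale = 2, seed = 1L, center = NULL) {
  if (is.null(center)) center <- dim(guess_area) / 2
  n_p <- n_trials %/% 2L
  session <- data.frame(truth = rep(c(TRUE, FALSE), c(n_p, n_trials - n_p)),
                        center_row = center[1], center_col = center[2])
  trials <- simulate_observer(session, detectability, loc_error_scale,
                              guess_area, seed = seed)
  lroc_auc(trials)$auc
}

#' Recover detectability from an observed AUC
#'
#' Builds a monotone AUC-vs-detectability curve by Monte Carlo with common
#' random numbers and inverts it by linear interpolation.
#'
#' @param auc observed AUC in (0, 1).
#' @param grid detectability grid for the curve.
#' @inheritParams observer_auc
#' @return Estimated detectability (clamped to the grid range).
#' @export
estimate_detectability <- function(auc, grid = seq(0, 6, by = 0.25),
                                   n_trials = 2000L, guess_area,
                                   loc_error_scale = 2, seed = 1L) {
  curve <- vapply(grid, observer_auc, numeric(1), n_trials = n_trials,
                  guess_area = guess_area, loc_error_scale = loc_error_scale,
                  seed = seed)
  curve <- cummax(curve)    # enforce monotonicity against MC jitter
  if (auc <= curve[1]) return(grid[1])
  if (auc >= curve[length(curve)]) return(grid[length(grid)])
  stats::approx(curve, grid, xout = auc, ties = "ordered")$y
}
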