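# Single-trial classification: per-fixation feature vectors, balanced
# linear-SVM 5-fold cross-validation, exact binomial above-chance test.

#' Feature-set specification
#'
#' Defines which blocks are concatenated into the per-fixation feature
#' vector: `SRP` (all EEG channel voltages over the feature interval),
#' `EOG` (HEOG/VEOG voltages over the same interval), `FIXDUR` (fixation
#' duration), `PUPIL` (pupil size), `EYE` (both scalars), `ALL`
#' (SRP + both scalars), `SRP+EOG`.
#'
#' @param id one of `"SRP"`, `"EOG"`, `"FIXDUR"`, `"PUPIL"`, `"EYE"`,
#'   `"ALL"`, `"SRP+EOG"`.
#' @param interval seconds within the epoch (default 0.25-1.0 after the
#'   saccade velocity peak).
#' @return object of class `srp_feature_spec` with logical block switches.
#' @export
feature_set_spec <- function(id = c("SRP", "EOG", "FIXDUR", "PUPIL", "EYE",
                                    "ALL", "SRP+EOG"),
                             interval = c(0.25, 1.0)) {
  id <- match.arg(id)
  blocks <- switch(id,
    "SRP" = c(srp = TRUE, eog = FALSE, fixdur = FALSE, pupil = FALSE),
    "EOG" = c(srp = FALSE, eog = TRUE, fixdur = FALSE, pupil = FALSE),
    "FIXDUR" = c(srp = FALSE, eog = FALSE, fixdur = TRUE, pupil = FALSE),
    "PUPIL" = c(srp = FALSE, eog = FALSE, fixdur = FALSE, pupil = TRUE),
    "EYE" = c(srp = FALSE, eog = FALSE, fixdur = TRUE, pupil = TRUE),
    "ALL" = c(srp = TRUE, eog = FALSE, fixdur = TRUE, pupil = TRUE),
    "SRP+EOG" = c(srp = TRUE, eog = TRUE, fixdur = FALSE, pupil = FALSE))
  structure(list(id = id, blocks = blocks, interval = interval),
            class = "srp_feature_spec")
}

#' Build the observation x feature matrix for a contrast
#'
#' Joins retained epochs with eye features on the event id and concatenates
#' the blocks requested by the spec. Voltage blocks cover the feature
#' interval (192 samples per channel at 256 Hz for 250-1000 ms). Rows with
#' missing eye features are dropped when the spec needs them (count
#' attached as attribute `n_dropped`).
#'
#' @param epochs an `srp_epochs` (already outlier-rejected).
#' @param eye_features a [fixation_features()] table (or `NULL` when the
#'   spec uses no eye block).
#' @param spec a [feature_set_spec()].
#' @param contrast `"target_vs_nontarget"` or `"hit_vs_miss"`.
#' @return list with `x` (matrix), `y` (factor with the positive class
#'   first: `target` / `hit`), `event` (event ids).
#' @export
build_feature_matrix <- function(epochs, eye_features = NULL,
                                 spec = feature_set_spec("SRP"),
                                 contrast = c("target_vs_nontarget",
                                              "hit_vs_miss")) {
  contrast <- match.arg(contrast)
  lab <- epochs$labels
  if (contrast == "target_vs_nontarget") {
    keep <- rep(TRUE, nrow(lab))
    y <- factor(ifelse(lab$is_target, "target", "nontarget"),
                levels = c("target", "nontarget"))
  } else {
    keep <- lab$is_target
    y <- factor(ifelse(lab$hit[keep] %in% TRUE, "hit", "miss"),
                levels = c("hit", "miss"))
  }
  idx <- which(keep)
  if (length(idx) == 0) stop("no epochs left for this contrast")
  si <- which(epochs$times >= spec$interval[1] &
              epochs$times < spec$interval[2])
  blocks <- list()
  if (spec$blocks[["srp"]]) {
    ch <- setdiff(epochs$channels, c("HEOG", "VEOG"))
    ci <- match(ch, epochs$channels)
    blocks$srp <- matrix(epochs$data[idx, ci, si],
                         nrow = length(idx))
  }
  if (spec$blocks[["eog"]]) {
    ci <- match(c("HEOG", "VEOG"), epochs$channels)
    if (anyNA(ci)) stop("HEOG/VEOG channels absent from the epoch set")
    blocks$eog <- matrix(epochs$data[idx, ci, si], nrow = length(idx))
  }
  need_eye <- spec$blocks[["fixdur"]] || spec$blocks[["pupil"]]
  if (need_eye) {
    if (is.null(eye_features)) stop("eye features required by this spec")
    m <- match(lab$event[idx], eye_features$event)
    if (spec$blocks[["fixdur"]])
      blocks$fixdur <- matrix(eye_features$fixation_duration_ms[m], ncol = 1)
    if (spec$blocks[["pupil"]])
      blocks$pupil <- matrix(eye_features$pupil_mm[m], ncol = 1)
  }
  x <- do.call(cbind, blocks)
  y <- y[seq_along(idx)]
  ok <- stats::complete.cases(x)
  n_dropped <- sum(!ok)
  x <- x[ok, , drop = FALSE]
  out <- list(x = x, y = droplevels(y[ok]), event = lab$event[idx][ok])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Subsample the majority class to balance a training fold
#'
#' @param labels factor (two classes) of the training observations.
#' @param seed optional integer; `NULL` (the default) draws from the
#'   current RNG stream, as done inside [train_eval_svm_cv()].
#' @return integer indices into `labels` keeping all minority-class and a
#'   random without-replacement subset of majority-class observations.
#' @export
subsample_majority <- function(labels, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  tab <- table(labels)
  if (length(tab) < 2 || any(tab == 0))
    stop("both classes must be present in the training fold")
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[minority] == tab[majority]) return(seq_along(labels))
  min_idx <- which(labels == minority)
  maj_idx <- which(labels == majority)
  sort(c(min_idx, sample(maj_idx, length(min_idx))))
}

# Stratified fold assignment (values 1..folds, one per observation).
.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Balanced linear-SVM cross-validation
#'
#' Stratified k-fold cross-validation: per fold, features are standardized
#' with the training fold's mean/SD (zero-SD features set to 0), the
#' training majority class is subsampled to the minority count, a linear
#' SVM is fitted and the untouched test fold predicted. Accuracy pools
#' correct predictions over folds; an exact one-sided binomial test
#' assesses above-chance performance.
#'
#' @param x observations x features matrix.
#' @param y two-level factor.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling fold assignment and subsampling.
#' @param cost SVM regularization constant (default 1).
#' @param alpha significance level for the above-chance flag.
#' @return object of class `srp_classification`: `accuracy` (pooled),
#'   `fold_accuracy`, `fold_n`, `fold_correct`, `fold_id` (per-observation
#'   fold assignment), `n_test`, `n_correct`, `binomial_p`,
#'   `above_chance`, `folds_used`, `seed`.
#' @export
train_eval_svm_cv <- function(x, y, folds = 5, seed = 1L, cost = 1,
                              alpha = 0.05) {
  stopifnot(is.matrix(x), nrow(x) == length(y), nlevels(y) == 2)
  if (min(table(y)) < folds)
    stop("need at least `folds` observations per class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold_id <- .stratified_folds(y, folds)
  n_correct <- 0L; n_test <- 0L
  fold_acc <- rep(NA_real_, folds); fold_n <- integer(folds)
  fold_correct <- integer(folds)
  used <- 0L
  for (k in seq_len(folds)) {
    tr <- fold_id != k; te <- !tr
    if (length(unique(y[tr])) < 2 || !any(te)) next
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    scale_fold <- function(m) {
      z <- sweep(m, 2, mu)
      z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
      z[, sdv == 0] <- 0
      z
    }
    xtr <- scale_fold(x[tr, , drop = FALSE])
    ytr <- y[tr]
    bal <- subsample_majority(ytr)
    fit <- e1071::svm(x = xtr[bal, , drop = FALSE], y = droplevels(ytr[bal]),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, scale_fold(x[te, , drop = FALSE]))
    correct <- sum(as.character(pred) == as.character(y[te]))
    fold_acc[k] <- correct / sum(te)
    fold_n[k] <- sum(te)
    fold_correct[k] <- correct
    n_correct <- n_correct + correct
    n_test <- n_test + sum(te)
    used <- used + 1L
  }
  if (n_test == 0) stop("no usable folds")
  bt <- binomial_above_chance(n_correct, n_test, alpha)
  structure(list(accuracy = n_correct / n_test, fold_accuracy = fold_acc,
                 fold_n = fold_n, fold_correct = fold_correct,
                 fold_id = fold_id, n_test = n_test, n_correct = n_correct,
                 binomial_p = bt$p, above_chance = bt$flag,
                 folds_used = used, seed = seed),
            class = "srp_classification")
}

#' Exact one-sided binomial above-chance test
#'
#' Tail probability `P(X >= n_correct)` for `X ~ Binomial(n_total, 0.5)`.
#'
#' @param n_correct,n_total counts with `0 <= n_correct <= n_total`.
#' @param alpha significance level.
#' @return list `p`, `flag` (`p < alpha`).
#' @export
binomial_above_chance <- function(n_correct, n_total, alpha = 0.05) {
  stopifnot(n_correct >= 0, n_correct <= n_total)
  p <- pbinom(n_correct - 1, n_total, 0.5, lower.tail = FALSE)
  list(p = p, flag = p < alpha)
}

#' Classification grid over contrasts, feature sets and loads
#'
#' Reproduces the study's comparison structure: target vs non-target for
#' both load conditions; hit vs miss only where the session has at least
#' `min_miss` misses (in practice the high-load condition).
#'
#' @param sessions named list (`low`, `high`) of per-session data, each a
#'   list with `epochs` (outlier-rejected `srp_epochs`) and
#'   `eye_features`.
#' @param feature_ids feature-set ids to evaluate.
#' @param folds,cost,alpha passed to [train_eval_svm_cv()].
#' @param min_miss minimum misses for a hit/miss cell.
#' @param seed integer seed.
#' @return data.frame with one row per grid cell: `load`, `contrast`,
#'   `feature_set`, `accuracy`, `n_test`, `binomial_p`, `above_chance`,
#'   `available` (FALSE cells carry NA results).
#' @export
comparison_grid <- function(sessions,
                            feature_ids = c("SRP", "FIXDUR", "PUPIL",
                                            "EYE", "ALL"),
                            folds = 5, cost = 1, alpha = 0.05,
                            min_miss = 10, seed = 1L) {
  rows <- list()
  cell_seed <- 0L
  for (load in names(sessions)) {
    ses <- sessions[[load]]
    n_miss <- sum(ses$epochs$labels$is_target &
                  !(ses$epochs$labels$hit %in% TRUE))
    for (contrast in c("target_vs_nontarget", "hit_vs_miss")) {
      if (contrast == "hit_vs_miss" && n_miss < min_miss) {
        for (fid in feature_ids)
          rows[[length(rows) + 1L]] <- data.frame(
            load = load, contrast = contrast, feature_set = fid,
            accuracy = NA_real_, n_test = NA_integer_,
            binomial_p = NA_real_, above_chance = NA,
            available = FALSE)
        next
      }
      for (fid in feature_ids) {
        cell_seed <- cell_seed + 1L
        fm <- build_feature_matrix(ses$epochs, ses$eye_features,
                                   feature_set_spec(fid), contrast)
        res <- tryCatch(
          train_eval_svm_cv(fm$x, fm$y, folds = folds,
                            seed = as.integer(seed) + cell_seed,
                            cost = cost, alpha = alpha),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- if (is.null(res)) data.frame(
          load = load, contrast = contrast, feature_set = fid,
          accuracy = NA_real_, n_test = NA_integer_,
          binomial_p = NA_real_, above_chance = NA, available = FALSE)
        else data.frame(
          load = load, contrast = contrast, feature_set = fid,
          accuracy = res$accuracy, n_test = res$n_test,
          binomial_p = res$binomial_p, above_chance = res$above_chance,
          available = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
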