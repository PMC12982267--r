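#' Cross-validation fold assignment
#'
#' Three modes: `"random"` assigns records uniformly to `k` folds;
#' `"spatial_block"` tiles the record extent into `block_size_m` squares and
#' randomly allocates whole blocks to folds, so no test record shares a
#' block with a training record of its fold (spatially blocked CV; test
#' folds may be unbalanced); `"random_split"` draws `k` independent
#' stratified 75/25 train/test splits — the repeated-split reading of a
#' "10-fold CV allocating 75% and 25%" protocol, kept available alongside
#' the k-fold default.
#'
#' @param records data.frame with `x`, `y` (and optionally `response` for
#'   stratified splits).
#' @param mode `"random"`, `"spatial_block"` or `"random_split"`.
#' @param k number of folds / repeats (default 10).
#' @param block_size_m spatial block edge length (m), default 5000.
#' @param train_fraction training fraction for `"random_split"` (default 0.75).
#' @param seed integer seed (recorded in the assignment).
#' @return object of class `FoldAssignment`: `fold` (per-record id, NA in
#'   split mode), `test_sets` (list of test row indices), `block` (per-record
#'   block id in spatial mode), plus the parameters.
#' @export
make_folds <- function(records, mode = c("random", "spatial_block",
                                         "random_split"),
                       k = 10, block_size_m = 5000, train_fraction = 0.75,
                       seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(records)
  fold <- rep(NA_integer_, n)
  block <- NULL
  set.seed(split_seed(seed, 31))
  if (mode == "random") {
    if (n < k) stop("fewer records than folds")
    fold <- sample(rep(seq_len(k), length.out = n))
    test_sets <- split(seq_len(n), fold)
  } else if (mode == "spatial_block") {
    bx <- floor((records$x - min(records$x)) / block_size_m)
    by <- floor((records$y - min(records$y)) / block_size_m)
    block <- paste(bx, by, sep = "_")
    ub <- unique(block)
    if (length(ub) < k)
      stop(sprintf(
        "only %d non-empty spatial blocks for %d folds; use smaller blocks",
        length(ub), k))
    bf <- sample(rep(seq_len(k), length.out = length(ub)))
    fold <- bf[match(block, ub)]
    test_sets <- split(seq_len(n), fold)
  } else {
    strata <- if ("response" %in% names(records)) records$response else
      rep(0, n)
    test_sets <- lapply(seq_len(k), function(r) {
      te <- integer(0)
      for (s in unique(strata)) {
        rows <- which(strata == s)
        n_te <- max(1L, round((1 - train_fraction) * length(rows)))
        te <- c(te, sample(rows, n_te))
      }
      sort(te)
    })
  }
  structure(list(mode = mode, k = k, block_size_m = block_size_m,
                 train_fraction = train_fraction, fold = fold,
                 test_sets = test_sets, block = block, seed = seed),
            class = "FoldAssignment")
}

#' Area under the ROC curve for presence vs background scores
#'
#' The rank-statistic formulation: the probability that a randomly chosen
#' presence outscores a randomly chosen background point, ties counted 1/2.
#' Equivalent to the Mann-Whitney U statistic scaled to \[0, 1\], and
#' invariant under strictly monotone transforms of the scores.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("both score sets must be non-empty")
  if (anyNA(presence_scores) || anyNA(background_scores))
    stop("scores contain NA/NaN")
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Continuous Boyce index
#'
#' Slides `n_classes` overlapping windows of width `window_width` across the
#' \[0, 1\] suitability range; in each window the predicted-to-expected ratio
#' P/E = (fraction of presences) / (fraction of the landscape) is computed,
#' windows with zero expected fraction are skipped, and the index is the
#' Spearman correlation between P/E and the window midpoint. 1 means
#' presences concentrate monotonically in high-suitability classes, 0 no
#' better than random, -1 the reverse.
#'
#' @param presence_scores suitability at presence points.
#' @param landscape_scores suitability over the evaluation landscape.
#' @param n_classes number of windows (default 101).
#' @param window_width window width on the suitability scale (default 0.1).
#' @return Boyce index in \[-1, 1\].
#' @export
boyce_index <- function(presence_scores, landscape_scores, n_classes = 101,
                        window_width = 0.1) {
  landscape_scores <- landscape_scores[is.finite(landscape_scores)]
  if (length(unique(landscape_scores)) < 2)
    stop("landscape scores are degenerate")
  if (!any(presence_scores >= 0 & presence_scores <= 1))
    stop("no presence score falls in the [0, 1] suitability range")
  mids <- seq(window_width / 2, 1 - window_width / 2, length.out = n_classes)
  pe <- rep(NA_real_, n_classes)
  for (i in seq_len(n_classes)) {
    lo <- mids[i] - window_width / 2
    hi <- mids[i] + window_width / 2
    e <- mean(landscape_scores >= lo & landscape_scores <= hi)
    if (e == 0) next
    p <- mean(presence_scores >= lo & presence_scores <= hi)
    pe[i] <- p / e
  }
  keep <- is.finite(pe)
  if (sum(keep) < 2) stop("fewer than 2 usable suitability windows")
  if (stats::sd(pe[keep]) == 0) return(0)
  stats::cor(pe[keep], mids[keep], method = "spearman")
}

#' TSS curve and threshold selection (maxSSS, MDT)
#'
#' Sweeps classification thresholds (predictions >= threshold are positive)
#' and reports sensitivity, specificity and the true skill statistic
#' TSS = sensitivity + specificity - 1 at each; `maxSSS` is the threshold
#' maximising sensitivity + specificity and `MDT` the one minimising
#' |sensitivity - specificity|, ties broken toward the smaller threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 observed labels.
#' @param threshold_grid candidate thresholds; default the unique scores
#'   plus the regular grid 0.00, 0.01, ..., 1.00.
#' @return list with `curve` (data.frame threshold/sensitivity/specificity/
#'   tss), `max_sss` (threshold), `mdt` (threshold), `tss_at_max_sss`.
#' @export
tss_curve <- function(scores, labels, threshold_grid = NULL) {
  if (length(unique(labels)) < 2)
    stop("labels contain a single class")
  if (anyNA(scores)) stop("scores contain NA")
  if (is.null(threshold_grid))
    threshold_grid <- sort(unique(c(scores, seq(0, 1, by = 0.01))))
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  sens <- vapply(threshold_grid, function(t) sum(scores[pos] >= t) / np,
                 numeric(1))
  spec <- vapply(threshold_grid, function(t) sum(scores[!pos] < t) / nn,
                 numeric(1))
  tss <- sens + spec - 1
  curve <- data.frame(threshold = threshold_grid, sensitivity = sens,
                      specificity = spec, tss = tss)
  i_max <- which.max(sens + spec)                       # first = smallest
  i_mdt <- which.min(abs(sens - spec))
  list(curve = curve, max_sss = threshold_grid[i_max],
       mdt = threshold_grid[i_mdt], tss_at_max_sss = tss[i_max])
}

#' Cross-validated performance of a suitability model
#'
#' For each fold, refits the model on the training rows at the smoothing
#' parameters selected by the all-data fit, scores the test rows, and
#' computes AUC (test presences vs test background), the continuous Boyce
#' index (test presences against all test scores as the landscape) and TSS
#' at the fold's maxSSS threshold. Folds whose test set contains a single
#' class are skipped with a warning. Reported coefficients remain those of
#' the all-data fit.
#'
#' @param frame model frame (see [assemble_model_frame()]).
#' @param folds a `FoldAssignment` over the frame rows.
#' @param model optional prefitted all-data `SuitabilityModel`; fitted here
#'   (with selection) if NULL.
#' @param ... passed to [fit_model()] for the all-data fit.
#' @return object of class `MetricReport`: `per_fold` data.frame, `summary`
#'   (mean ± sd per metric), `model`, `skipped_folds`, `seed`.
#' @export
cross_validate <- function(frame, folds, model = NULL, ...) {
  if (is.null(model)) model <- fit_model(frame, ...)
  fixed <- list(lambdas = model$lambdas, lambda_stars = model$lambda_stars)
  rows <- list(); skipped <- integer(0)
  for (f in seq_along(folds$test_sets)) {
    te <- folds$test_sets[[f]]
    tr <- setdiff(seq_len(nrow(frame)), te)
    ytest <- frame$response[te]
    if (length(unique(ytest)) < 2 || length(unique(frame$response[tr])) < 2) {
      warning(sprintf("fold %d has a single-class train or test set; skipped", f))
      skipped <- c(skipped, f)
      next
    }
    fm <- fit_model(frame[tr, , drop = FALSE],
                    predictors = names(model$terms),
                    spatial_rank = if (is.null(model$spatial)) 0 else
                      model$spatial$K,
                    fixed = fixed, species = model$species)
    sc <- predict(fm, frame[te, , drop = FALSE], type = "response")
    a <- auc(sc[ytest == 1], sc[ytest == 0])
    b <- boyce_index(sc[ytest == 1], sc)
    ts <- tss_curve(sc, ytest)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, n_test = length(te), auc = a, boyce = b,
      tss = ts$tss_at_max_sss, threshold = ts$max_sss)
  }
  if (!length(rows)) stop("no usable fold")
  per_fold <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("auc", "boyce", "tss"),
    mean = c(mean(per_fold$auc), mean(per_fold$boyce), mean(per_fold$tss)),
    sd = c(stats::sd(per_fold$auc), stats::sd(per_fold$boyce),
           stats::sd(per_fold$tss)))
  structure(list(per_fold = per_fold, summary = summ, model = model,
                 skipped_folds = skipped, mode = folds$mode,
                 seed = folds$seed),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("MetricReport (%s CV, %d folds%s):\n", x$mode,
              nrow(x$per_fold),
              if (length(x$skipped_folds))
                sprintf(", %d skipped", length(x$skipped_folds)) else ""))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-6s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}
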