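#' Area under the ROC curve from two score sets
#'
#' Mann-Whitney form: the mean over all (positive, negative) pairs of 1 if
#' the positive outscores the negative, 0.5 on a tie, 0 otherwise. This
#' equals the area under the threshold-sweep ROC curve with trapezoidal
#' interpolation through ties.
#'
#' @param pos_scores,neg_scores nonempty numeric vectors.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_from_scores(c(0.9, 0.4), c(0.8, 0.3, 0.1))  # 5/6
#' @export
auc_from_scores <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("empty score list")
  }
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Threshold-sweep ROC curve
#'
#' Sweeps the decision threshold over all observed score values (descending)
#' and records the false and true positive rates at each.
#'
#' @inheritParams auc_from_scores
#' @return A `data.frame` with columns `FPR`, `TPR`, starting at (0, 0) and
#'   ending at (1, 1), non-decreasing in both coordinates.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("empty score list")
  }
  th <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg_scores >= t), numeric(1))
  data.frame(FPR = c(0, fpr, 1), TPR = c(0, tpr, 1))
}

# Per-positive normalized exceedance ranks -> pooled step-curve ROC.
# e_i is the fraction of that run's candidates outscoring positive i (ties
# half); thresholding on e gives TPR as the fraction of positives recovered.
pooled_roc <- function(e) {
  e <- sort(e)
  n <- length(e)
  data.frame(FPR = c(0, e, 1), TPR = c(0, seq_len(n) / n, 1))
}

mask_pairs <- function(dataset, pairs) {
  A <- dataset$adjacency
  A[pairs] <- 0L
  association_dataset(A, dataset$disease_names, dataset$microbe_names)
}

default_score_fun <- function(...) {
  params <- list(...)
  function(dataset) {
    do.call(predict_associations, c(list(dataset = dataset), params))$scores
  }
}

#' Leave-one-out cross-validation of association prediction
#'
#' Each known association is masked in turn; the entire pipeline (kernels,
#' node weights, normalization, recommendation, propagation) is re-run on
#' the masked adjacency, and the held-out pair's score is ranked against the
#' scores of all candidate pairs — the pairs unknown in the original
#' adjacency. The reported AUC is the mean over held-out positives of the
#' pairwise (Mann-Whitney) statistic of the positive against its run's
#' candidates; the ROC curve pools the per-positive normalized ranks.
#'
#' @param dataset an [association_dataset()] with at least 2 known
#'   associations.
#' @param ... pipeline parameters forwarded to [predict_associations()].
#' @param score_fun optional function `dataset -> score matrix` replacing
#'   the default pipeline (used for controls and protocol tests).
#' @return A list of class `md_cv_result` with `auc`, `roc_points`,
#'   `per_positive_ranks` (disease, microbe, rank, n_candidates) and
#'   `n_runs`.
#' @export
loocv <- function(dataset, ..., score_fun = NULL) {
  stopifnot(inherits(dataset, "association_dataset"))
  A0 <- dataset$adjacency
  if (sum(A0) < 2L) stop("need at least 2 known associations for LOOCV")
  if (is.null(score_fun)) score_fun <- default_score_fun(...)
  positives <- which(A0 == 1L, arr.ind = TRUE)
  cand_mask <- A0 == 0L
  u <- numeric(nrow(positives))
  ranks <- numeric(nrow(positives))
  n_cand <- sum(cand_mask)
  for (t in seq_len(nrow(positives))) {
    sc <- score_fun(mask_pairs(dataset, positives[t, , drop = FALSE]))
    pos <- sc[positives[t, 1L], positives[t, 2L]]
    cand <- sc[cand_mask]
    u[t] <- auc_from_scores(pos, cand)
    ranks[t] <- 1 + sum(cand > pos) + 0.5 * sum(cand == pos)
  }
  structure(
    list(method = "loocv",
         auc = mean(u),
         roc_points = pooled_roc(1 - u),
         per_positive_ranks = data.frame(
           disease = dataset$disease_names[positives[, 1L]],
           microbe = dataset$microbe_names[positives[, 2L]],
           rank = ranks,
           n_candidates = n_cand,
           stringsAsFactors = FALSE),
         n_runs = nrow(positives)),
    class = "md_cv_result"
  )
}

#' Repeated k-fold cross-validation of association prediction
#'
#' Per repeat, the known associations are shuffled with a repeat-specific
#' seed (spawned deterministically from `seed`) and split into `folds`
#' near-equal groups (the first `nnz %% folds` groups get one extra pair).
#' Each group is masked in turn, the full pipeline is re-run, and every
#' held-out positive is ranked against the candidate pairs (unknown in the
#' original adjacency). A repeat's AUC pools the per-positive statistics of
#' all its folds; the summary is the mean and standard deviation over
#' repeats.
#'
#' @inheritParams loocv
#' @param folds number of folds (default 5).
#' @param repeats number of random re-partitions (default 100).
#' @param seed master seed controlling all randomness.
#' @return A list of class `md_cv_result` with `auc` (= `mean_auc`),
#'   `auc_per_repeat`, `mean_auc`, `sd_auc`, pooled `roc_points` and `seed`.
#' @export
kfold_cv <- function(dataset, folds = 5, repeats = 100, seed = 1, ...,
                     score_fun = NULL) {
  stopifnot(inherits(dataset, "association_dataset"), folds >= 2)
  A0 <- dataset$adjacency
  nnz <- sum(A0)
  if (nnz < folds) stop("fewer known associations than folds")
  if (is.null(score_fun)) score_fun <- default_score_fun(...)
  positives <- which(A0 == 1L, arr.ind = TRUE)
  cand_mask <- A0 == 0L
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max, repeats)
  sizes <- rep(nnz %/% folds, folds) + (seq_len(folds) <= nnz %% folds)
  fold_id <- rep(seq_len(folds), times = sizes)
  auc_per_repeat <- numeric(repeats)
  e_all <- list()
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    perm <- sample.int(nnz)
    u <- numeric(nnz)
    for (f in seq_len(folds)) {
      idx <- perm[fold_id == f]
      held <- positives[idx, , drop = FALSE]
      sc <- score_fun(mask_pairs(dataset, held))
      cand <- sc[cand_mask]
      u[idx] <- vapply(seq_len(nrow(held)), function(h) {
        auc_from_scores(sc[held[h, 1L], held[h, 2L]], cand)
      }, numeric(1))
    }
    auc_per_repeat[r] <- mean(u)
    e_all[[r]] <- 1 - u
  }
  structure(
    list(method = "kfold",
         folds = folds, repeats = repeats, seed = seed,
         auc = mean(auc_per_repeat),
         auc_per_repeat = auc_per_repeat,
         mean_auc = mean(auc_per_repeat),
         sd_auc = stats::sd(auc_per_repeat),
         roc_points = pooled_roc(unlist(e_all))),
    class = "md_cv_result"
  )
}

#' @export
print.md_cv_result <- function(x, ...) {
  if (x$method == "loocv") {
    cat(sprintf("LOOCV over %d associations: AUC %.4f\n", x$n_runs, x$auc))
  } else {
    cat(sprintf("%d-fold CV x %d repeats (seed %d): AUC %.4f +/- %.4f\n",
                x$folds, x$repeats, x$seed, x$mean_auc,
                ifelse(is.na(x$sd_auc), 0, x$sd_auc)))
  }
  invisible(x)
}

#' Cross-validated performance across propagation lengths
#'
#' Re-runs cross-validation for each value of the walk length `n` and
#' tabulates the resulting AUCs, mirroring the usual parameter study that
#' motivates the default `n = 2`.
#'
#' @inheritParams kfold_cv
#' @param n_values integer vector of propagation lengths to evaluate.
#' @param cv `"loocv"` or `"kfold"`.
#' @return A `data.frame` with one row per `n`: `n`, `auc`, and for k-fold
#'   also `sd_auc`.
#' @export
parameter_study <- function(dataset, n_values = c(2, 3, 4),
                            cv = c("loocv", "kfold"),
                            folds = 5, repeats = 10, seed = 1, ...) {
  cv <- match.arg(cv)
  rows <- lapply(n_values, function(n) {
    if (cv == "loocv") {
      res <- loocv(dataset, n = n, ...)
      data.frame(n = n, auc = res$auc, sd_auc = NA_real_)
    } else {
      res <- kfold_cv(dataset, folds = folds, repeats = repeats, seed = seed,
                      n = n, ...)
      data.frame(n = n, auc = res$mean_auc, sd_auc = res$sd_auc)
    }
  })
  do.call(rbind, rows)
}
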