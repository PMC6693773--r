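#' Exact Wilcoxon rank-sum test (mid-rank ties)
#'
#' Two-sided two-sample rank-sum test. For combined sample sizes up to 25 the
#' exact conditional null distribution of the first sample's rank sum over all
#' equally likely group assignments is computed by convolution over the
#' observed (mid-)rank multiset, so ties are handled exactly. Larger samples
#' fall back to the tie-corrected normal approximation (flagged in the
#' result). The two-sided p-value is the doubled smaller tail,
#' min(1, 2 min(P(W <= w), P(W >= w))).
#'
#' @param x,y numeric samples, both non-empty.
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (anyNA(c(x, y))) stop("wilcoxon_rank_sum: missing values not allowed")
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L) {
    warning("wilcoxon_rank_sum: all values tied across both samples; p = 1")
    return(list(statistic = sum(rank(all_v)[seq_along(x)]), p_value = 1,
                method = "degenerate"))
  }
  r <- rank(all_v)
  m <- length(x); n <- length(all_v)
  w <- sum(r[seq_len(m)])
  if (n <= 25) {
    # doubled ranks are integers; count size-m subsets by sum
    r2 <- as.integer(round(2 * r))
    S <- sum(r2)
    # dp[c + 1, s + 1] = number of size-c subsets with doubled-rank sum s
    dp <- matrix(0, m + 1, S + 1)
    dp[1, 1] <- 1
    processed <- 0L
    for (g in r2) {
      processed <- processed + 1L
      for (cc in seq(min(m, processed), 1L)) {
        nz <- which(dp[cc, ] > 0)
        if (length(nz)) {
          dp[cc + 1L, nz + g] <- dp[cc + 1L, nz + g] + dp[cc, nz]
        }
      }
    }
    probs <- dp[m + 1, ] / choose(n, m)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(S + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = w, p_value = p, method = "exact")
  } else {
    mu <- m * (n + 1) / 2
    tie_tab <- table(all_v)
    sig2 <- m * (n - m) / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                  (n * (n - 1)))
    z <- (w - mu) / sqrt(sig2)
    list(statistic = w, p_value = 2 * stats::pnorm(-abs(z)),
         method = "normal-approximation")
  }
}

#' Exact Wilcoxon signed-rank test (mid-rank ties)
#'
#' Two-sided paired test on a vector of differences. Zero differences are
#' dropped (with a note in the result); the exact null distribution over all
#' sign assignments of the observed |difference| mid-ranks is computed by
#' convolution for up to 25 non-zero differences, with the tie-corrected
#' normal approximation beyond. Two-sided p is the doubled smaller tail.
#'
#' @param d numeric vector of paired differences (>= 5 non-zero values).
#' @return list with `statistic` (positive-rank sum), `p_value`, `n_nonzero`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(d) {
  if (anyNA(d)) stop("wilcoxon_signed_rank: missing values not allowed")
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("wilcoxon_signed_rank: all differences zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate"))
  }
  if (length(nz) < 5L) {
    stop("wilcoxon_signed_rank: need at least 5 non-zero differences")
  }
  n <- length(nz)
  r <- rank(abs(nz))
  w_pos <- sum(r[nz > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    S <- sum(r2)
    dp <- numeric(S + 1)
    dp[1] <- 1
    for (g in r2) {
      shifted <- c(numeric(g), dp[seq_len(S + 1 - g)])
      dp <- dp + shifted
    }
    probs <- dp / 2^n
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(S + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = w_pos, p_value = p, n_nonzero = n, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(nz))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu) / sqrt(sig2)
    list(statistic = w_pos, p_value = 2 * stats::pnorm(-abs(z)),
         n_nonzero = n, method = "normal-approximation")
  }
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the product-moment correlation of the mid-ranks, which equals
#' 1 - 6 sum(d^2) / (n (n^2 - 1)) when there are no ties and is the standard
#' tie-corrected form otherwise. The two-sided p-value is exact (full
#' permutation enumeration of one rank vector) for n <= 8 and uses the
#' t-approximation t = rho sqrt((n-2)/(1-rho^2)) for larger n.
#'
#' @param x,y equal-length numeric samples, n >= 3, non-constant.
#' @return list with `rho`, `p_value`, `method`.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("spearman_rank: missing values not allowed")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("spearman_rank: undefined for constant input")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (n <= 8) {
    perms <- permutations_of(n)
    ry_mat <- matrix(ry[perms], nrow = nrow(perms))
    rhos <- as.numeric(stats::cor(rx, t(ry_mat)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, method = "exact-permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
         method = "t-approximation")
  }
}

# all permutations of 1..n as a matrix (n! rows), n <= 8
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Single-predictor logistic regression trained by gradient descent
#'
#' Fits logit(Pr(y = 1)) = beta0 + beta1 W by full-batch gradient descent on
#' the average negative log-likelihood, starting from beta = 0 with the
#' predictor z-scored (the standardization is stored and applied at
#' prediction time). Converges when the gradient infinity-norm drops below
#' `tol`. Under perfect separation the coefficients are capped at `cap` and a
#' warning is raised.
#'
#' @param w numeric predictor values.
#' @param y labels in {0, 1}; both classes must be present.
#' @param predictor_name label stored in the model.
#' @param max_iter,tol,cap gradient-descent controls.
#' @return a `logistic_model`.
#' @export
fit_logistic_gd <- function(w, y, predictor_name = "predictor",
                            max_iter = 50000L, tol = 1e-8, cap = 30) {
  stopifnot(length(w) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("fit_logistic_gd: both classes must be present in the training data")
  }
  mu <- mean(w)
  sd_w <- stats::sd(w)
  if (!is.finite(sd_w) || sd_w < 1e-12) sd_w <- 1
  z <- (w - mu) / sd_w
  fit <- .logit_gd(z, as.numeric(y), as.integer(max_iter), tol, cap)
  if (fit[5] > 0) {
    warning("fit_logistic_gd: perfect separation; coefficients capped at ", cap)
  }
  structure(list(beta0 = fit[1], beta1 = fit[2],
                 predictor_name = predictor_name,
                 standardization = c(mean = mu, sd = sd_w),
                 iterations = as.integer(fit[3]),
                 converged = fit[4] > 0, capped = fit[5] > 0),
            class = "logistic_model")
}

#' @export
coef.logistic_model <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  z <- (newdata - object$standardization["mean"]) / object$standardization["sd"]
  unname(stats::plogis(object$beta0 + object$beta1 * z))
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf(paste0("Logistic model (%s): beta0 = %.4f, beta1 = %.4f ",
                     "(standardized scale)%s\n"),
              x$predictor_name, x$beta0, x$beta1,
              if (x$capped) " [separation-capped]" else ""))
  invisible(x)
}

#' Confusion counts
#' @param tp,tn,fp,fn non-negative counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP + TN) / total, sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP). A metric whose denominator is zero (no
#' positives, or no negatives) is reported as NULL, never as zero.
#'
#' @param counts a `confusion_counts` object.
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_confusion <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NULL,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NULL))
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted half, which
#' equals trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels labels in {0, 1}; both classes required.
#' @return list with `points` (data.frame fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("roc_auc: AUC undefined with a single class")
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(diff(sc) != 0, TRUE)   # step after each distinct threshold
  tpr <- cumsum(lab) / npos
  fpr <- cumsum(1 - lab) / nneg
  pts <- data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
  list(points = pts, auc = auc)
}

#' Repeated stratified 5-fold cross-validation of the logistic predictor
#'
#' For each repeat: the labelled participants are partitioned into `k` folds
#' (stratified as far as the class counts allow, random within class), the
#' logistic model is trained on each set of k-1 folds and the held-out fold
#' is predicted at probability threshold 0.5 (p >= 0.5 -> positive). All
#' held-out predictions of the repeat are pooled into one confusion table and
#' one ROC; accuracy, sensitivity, specificity and AUC are averaged over
#' repeats. Training folds containing a single class are skipped and logged.
#' Partitions are drawn on the id-sorted participants, so results are
#' invariant to row order given the seed.
#'
#' @param predictor column name of the predictor in `data` (or "sex", which is
#'   coded numerically M = 0, F = 1).
#' @param data a `cohort` or data.frame; only rows with group BG/WG are used,
#'   with BG the positive class (y = 1).
#' @param k folds.
#' @param repeats repetitions with fresh random partitions.
#' @param seed RNG seed (required for reproducibility).
#' @param threshold probability threshold for the positive call.
#' @return a `cv_result`: mean `accuracy`, `sensitivity`, `specificity`,
#'   `auc`, `n_repeats`, `per_repeat` records, `seed`, `skipped_folds` count.
#' @export
cross_validate <- function(predictor, data, k = 5, repeats = 200, seed = 1,
                           threshold = 0.5) {
  df <- as.data.frame(data)
  df <- df[df$group %in% c("BG", "WG"), , drop = FALSE]
  if (nrow(df) < k) stop("cross_validate: fewer participants than folds")
  df <- df[order(df$id), , drop = FALSE]
  w <- if (predictor == "sex") ifelse(df$sex == "F", 1, 0) else df[[predictor]]
  if (is.null(w)) stop("cross_validate: unknown predictor '", predictor, "'")
  if (anyNA(w)) stop("cross_validate: predictor '", predictor, "' has missing values")
  y <- as.numeric(df$group == "BG")
  n <- length(y)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  per_repeat <- vector("list", repeats)
  skipped <- 0L
  for (rep_i in seq_len(repeats)) {
    folds <- integer(n)
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    pred_prob <- rep(NA_real_, n)
    for (fold in seq_len(k)) {
      test <- which(folds == fold)
      train <- which(folds != fold)
      if (length(test) == 0L) next
      if (length(unique(y[train])) < 2L) {
        skipped <- skipped + 1L
        next
      }
      fit <- suppressWarnings(
        fit_logistic_gd(w[train], y[train], predictor))
      pred_prob[test] <- predict(fit, w[test])
    }
    use <- !is.na(pred_prob)
    yhat <- as.numeric(pred_prob[use] >= threshold)
    cc <- confusion_counts(tp = sum(yhat == 1 & y[use] == 1),
                           tn = sum(yhat == 0 & y[use] == 0),
                           fp = sum(yhat == 1 & y[use] == 0),
                           fn = sum(yhat == 0 & y[use] == 1))
    metrics <- evaluate_confusion(cc)
    auc <- roc_auc(pred_prob[use], y[use])$auc
    per_repeat[[rep_i]] <- data.frame(
      repeat_id = rep_i,
      accuracy = metrics$accuracy,
      sensitivity = if (is.null(metrics$sensitivity)) NA_real_ else metrics$sensitivity,
      specificity = if (is.null(metrics$specificity)) NA_real_ else metrics$specificity,
      auc = auc)
  }
  per_repeat <- do.call(rbind, per_repeat)
  structure(list(
    accuracy = mean(per_repeat$accuracy),
    sensitivity = mean(per_repeat$sensitivity, na.rm = TRUE),
    specificity = mean(per_repeat$specificity, na.rm = TRUE),
    auc = mean(per_repeat$auc),
    n_repeats = repeats, per_repeat = per_repeat, seed = seed,
    predictor = predictor, skipped_folds = skipped),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("Repeated 5-fold CV (%s, %d repeats, seed %d):\n",
                     "  accuracy %.4f  sensitivity %.4f  specificity %.4f  ",
                     "AUC %.4f\n"),
              x$predictor, x$n_repeats, x$seed, x$accuracy, x$sensitivity,
              x$specificity, x$auc))
  if (x$skipped_folds > 0) {
    cat(sprintf("  (%d single-class training folds skipped)\n",
                x$skipped_folds))
  }
  invisible(x)
}
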