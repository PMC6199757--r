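#' Confusion-matrix counts
#'
#' @param tp,fp,tn,fn nonnegative integer counts; the positive class is AMD.
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  counts <- as.integer(counts)
  names(counts) <- c("tp", "fp", "tn", "fn")
  structure(as.list(counts), class = "confusion_matrix")
}

undef <- function(what) {
  warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
  NA_real_
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`.  A zero denominator yields
#' `NA` with a warning rather than a silent 0.
#'
#' @param cm a [confusion_matrix] (or list with `tp`, `fp`, `tn`, `fn`).
#' @return Named list: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else undef("sensitivity"),
    specificity = if (tn + fp > 0) tn / (tn + fp) else undef("specificity"),
    accuracy = if (tp + fp + tn + fn > 0) (tp + tn) / (tp + fp + tn + fn)
               else undef("accuracy"))
}

#' Cohen's kappa of a binary confusion matrix
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' observed agreement `p_o` equal to the accuracy and the expected
#' agreement `p_e` from the marginal products.
#'
#' @inheritParams confusion_metrics
#' @return Kappa in `[-1, 1]`, or `NA` with a warning when `p_e = 1`.
#' @export
cohen_kappa <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  n <- tp + fp + tn + fn
  if (n == 0) return(undef("kappa"))
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) / n) * ((tp + fp) / n) + ((tn + fp) / n) * ((tn + fn) / n)
  if (1 - p_e == 0) return(undef("kappa"))
  (p_o - p_e) / (1 - p_e)
}

#' Area under the ROC curve (rank estimator)
#'
#' Mann-Whitney estimate: the probability that a random positive case
#' outscores a random negative one, with ties counted one half.
#'
#' @param scores continuous decision values, larger meaning more AMD-like.
#' @param labels class labels; `positive` marks the positive class.
#' @param positive positive-class label (default `"AMD"`).
#' @return AUROC in `[0, 1]`, or `NA` with a warning if one class is
#'   absent.
#' @export
auroc <- function(scores, labels, positive = "AMD") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: one class absent", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class '%s' has %d case(s), fewer than k = %d folds",
                   cl, length(idx), k), call. = FALSE)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

feature_matrix <- function(table) {
  fcols <- grep("^f_\\d+$", names(table), value = TRUE)
  if (!length(fcols)) stop("no f_NNN feature columns found", call. = FALSE)
  as.matrix(table[fcols])
}

#' Repeated stratified k-fold SVM evaluation
#'
#' The central evaluation of the pipeline: for each repetition a fresh
#' stratified k-fold split is drawn; within each fold, features are
#' z-scored with the training split's mean and SD only (no test-set
#' leakage), an SVM is fitted and the held-out split scored with its
#' continuous decision values.  The out-of-fold predictions of one
#' repetition are pooled into a single confusion matrix and AUROC, and the
#' per-repetition metrics are aggregated as mean, SD, and the rows of the
#' best-accuracy and best-kappa repetitions.
#'
#' @param table feature data frame (one arrangement) with `label` and
#'   `f_NNN` columns, or a plain numeric matrix plus `labels`.
#' @param labels class labels, required when `table` is a matrix.
#' @param k folds (default 5, so each test fold holds 20% of cases).
#' @param repetitions number of repeated splits.
#' @param kernel,cost,gamma SVM settings passed to [e1071::svm()]
#'   (defaults: RBF kernel, `cost = 1`, `gamma = 1/p`).
#' @param seed RNG seed; the whole evaluation is deterministic given it.
#' @param positive positive-class label (default `"AMD"`).
#' @return An object of class `amd_eval` with components `protocol`,
#'   `per_repetition`, `per_fold`, `aggregates` and `scores`.
#' @export
svm_repeated_cv <- function(table, labels = NULL, k = 5, repetitions = 10,
                            kernel = "radial", cost = 1, gamma = NULL,
                            seed = 1L, positive = "AMD") {
  if (is.data.frame(table)) {
    if (!is.null(table$arrangement) &&
        length(unique(table$arrangement)) > 1)
      stop("feature table mixes arrangements; evaluate one at a time",
           call. = FALSE)
    x <- feature_matrix(table)
    labels <- table$label
  } else {
    x <- as.matrix(table)
    if (is.null(labels)) stop("labels required with a matrix input", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(unique(labels)) != 2)
    stop("exactly two classes required", call. = FALSE)
  if (!positive %in% labels)
    stop(sprintf("positive class '%s' absent from labels", positive),
         call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  ylev <- c(setdiff(unique(labels), positive), positive)
  y <- factor(labels, levels = ylev)

  per_rep <- vector("list", repetitions)
  per_fold <- vector("list", repetitions)
  scores_all <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(seed + r * 1000003L)
    fold <- stratified_folds(labels, k)
    score <- numeric(length(labels))
    pred <- character(length(labels))
    fold_rows <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      if (length(unique(labels[tr])) < 2)
        stop("a class is absent from a training split", call. = FALSE)
      mu <- colMeans(x[tr, , drop = FALSE])
      sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      xs_tr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
      xs_te <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sg, "/")
      fit <- e1071::svm(xs_tr, y[tr], kernel = kernel, cost = cost,
                        gamma = gamma, scale = FALSE)
      p <- stats::predict(fit, xs_te, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      # orient decision values so larger means more positive-class-like
      sgn <- if (strsplit(colnames(dv), "/")[[1]][1] == positive) 1 else -1
      score[te] <- sgn * as.numeric(dv)
      pred[te] <- as.character(p)
      cmte <- list(tp = sum(pred[te] == positive & labels[te] == positive),
                   fp = sum(pred[te] == positive & labels[te] != positive),
                   tn = sum(pred[te] != positive & labels[te] != positive),
                   fn = sum(pred[te] != positive & labels[te] == positive))
      fold_rows[[f]] <- data.frame(repetition = r, fold = f,
                                   tp = cmte$tp, fp = cmte$fp,
                                   tn = cmte$tn, fn = cmte$fn)
    }
    cm <- confusion_matrix(sum(pred == positive & labels == positive),
                           sum(pred == positive & labels != positive),
                           sum(pred != positive & labels != positive),
                           sum(pred != positive & labels == positive))
    met <- confusion_metrics(cm)
    per_rep[[r]] <- data.frame(
      repetition = r, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      sensitivity = met$sensitivity, specificity = met$specificity,
      accuracy = met$accuracy,
      auroc = auroc(score, labels, positive = positive),
      kappa = cohen_kappa(cm))
    per_fold[[r]] <- do.call(rbind, fold_rows)
    scores_all[[r]] <- score
  }
  reps <- do.call(rbind, per_rep)

  metrics <- c("sensitivity", "specificity", "accuracy", "auroc", "kappa")
  i_acc <- which.max(reps$accuracy)
  i_kap <- which.max(reps$kappa)
  aggregates <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reps[[m]]), 0),
    std = vapply(metrics, function(m) stats::sd(reps[[m]]), 0),
    max_acc = vapply(metrics, function(m) reps[[m]][i_acc], 0),
    max_kappa = vapply(metrics, function(m) reps[[m]][i_kap], 0),
    row.names = NULL)

  structure(list(
    protocol = list(k = k, repetitions = repetitions, seed = seed,
                    kernel = kernel, cost = cost, gamma = gamma,
                    positive = positive, n_cases = length(labels),
                    n_positive = sum(labels == positive),
                    n_negative = sum(labels != positive),
                    standardization = "per-fold z-score (training split only)"),
    per_repetition = reps,
    per_fold = do.call(rbind, per_fold),
    aggregates = aggregates,
    scores = scores_all),
    class = "amd_eval")
}

#' @export
print.amd_eval <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("SVM evaluation: %d-fold x %d repetitions, %d cases (%d %s / %d other)\n",
              p$k, p$repetitions, p$n_cases, p$n_positive, p$positive,
              p$n_negative))
  a <- x$aggregates
  fmt <- function(m, col) {
    v <- a[[col]][a$metric == m]
    if (m %in% c("sensitivity", "specificity", "accuracy"))
      sprintf("%6.1f", 100 * v) else sprintf("%6.3f", v)
  }
  rows <- c(Average = "mean", Std = "std", `Max acc` = "max_acc",
            `Max kappa` = "max_kappa")
  cat(sprintf("  %-10s %8s %8s %8s %8s %8s\n", "", "Sens(%)", "Spec(%)",
              "Acc(%)", "AUROC", "Kappa"))
  for (rn in names(rows))
    cat(sprintf("  %-10s %8s %8s %8s %8s %8s\n", rn,
                fmt("sensitivity", rows[rn]), fmt("specificity", rows[rn]),
                fmt("accuracy", rows[rn]), fmt("auroc", rows[rn]),
                fmt("kappa", rows[rn])))
  invisible(x)
}

#' @export
summary.amd_eval <- function(object, ...) {
  print(object)
  invisible(object$aggregates)
}

#' @export
as.data.frame.amd_eval <- function(x, ...) x$per_repetition

#' Distribution of per-repetition metrics
#'
#' Boxplots of sensitivity, specificity, accuracy, AUROC and kappa across
#' repetitions.
#'
#' @param x an `amd_eval`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.amd_eval <- function(x, ...) {
  m <- x$per_repetition[c("sensitivity", "specificity", "accuracy",
                          "auroc", "kappa")]
  graphics::boxplot(m, ylab = "metric value", ...)
  invisible(x)
}
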