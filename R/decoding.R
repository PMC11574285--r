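# Decode group identity (neurotransmitter / neighborhood / class) from
# boolean receptor-detection profiles. Accuracy is estimated by stratified
# K-fold cross-validation of a random forest; the confusion matrix and
# per-class report come from out-of-fold predictions; attribution is
# computed on one forest fitted to the full data via Monte-Carlo
# permutation Shapley sampling.

#' Decoder specification
#'
#' Hyperparameters of the tree-ensemble decoder and its evaluation
#' protocol: 200 trees of maximum depth 10 with balanced class weights,
#' 5-fold stratified cross-validation, and a class-weight-balanced sample
#' of at most 10,000 rows for attribution.
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth.
#' @param n_splits Stratified CV folds (>= 2).
#' @param seed Integer seed controlling fold assignment, training and
#'   attribution sampling.
#' @param attribution_sample Maximum rows used for attribution.
#' @param n_permutations Monte-Carlo permutations per row in the Shapley
#'   estimator.
#' @return A `decoder_spec` list.
#' @export
decoder_spec <- function(n_trees = 200, max_depth = 10, n_splits = 5,
                         seed = 1L, attribution_sample = 10000,
                         n_permutations = 8) {
  stopifnot(is_count(n_trees), is_count(max_depth),
            is_count(n_splits), n_splits >= 2,
            is_count(attribution_sample), is_count(n_permutations))
  structure(
    list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
         n_splits = as.integer(n_splits), seed = as.integer(seed),
         attribution_sample = as.integer(attribution_sample),
         n_permutations = as.integer(n_permutations)),
    class = "decoder_spec"
  )
}

#' Build the feature table for decoding
#'
#' Features are the boolean detection states of the family genes; the
#' label is the cell's value of the target metadata column. Rows with a
#' missing label are dropped with a logged count. Feature column order is
#' the mask's gene order.
#'
#' @param mask Detection mask with cell-label rownames.
#' @param cells Cell table.
#' @param target_level Metadata column to decode.
#' @return List with `features` (logical matrix) and `labels` (factor).
#' @export
make_feature_table <- function(mask, cells, target_level) {
  labels <- group_vector(mask, cells, target_level)
  keep <- !is.na(labels)
  if (any(!keep)) {
    message(sprintf("dropped %d cells with missing %s label",
                    sum(!keep), target_level))
  }
  list(features = mask[keep, , drop = FALSE],
       labels = factor(labels[keep]))
}

#' Analytic chance level of a label set
#'
#' Uniform-guessing chance level of balanced accuracy: 100 divided by the
#' number of distinct labels.
#'
#' @param labels Vector of labels (NAs ignored).
#' @return Percent (scalar).
#' @export
#' @examples
#' chance_level(rep(letters[1:10], 3)) # 10
chance_level <- function(labels) {
  k <- length(unique(labels[!is.na(labels)]))
  stopifnot(k >= 1)
  100 / k
}

#' Balanced accuracy (mean per-class recall)
#'
#' @param truth,pred Factors/vectors of equal length.
#' @return Fraction in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, pred) {
  lev <- unique(as.character(truth))
  recalls <- vapply(lev, function(cl) {
    mean(as.character(pred)[truth == cl] == cl)
  }, numeric(1))
  mean(recalls)
}

# Stratified fold assignment: within each class, shuffle indices and deal
# them round-robin over a randomly rotated fold order.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(factor(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  fold
}

balanced_class_weights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

fit_forest <- function(x, y, spec, probability = FALSE, seed_offset = 0) {
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = spec$n_trees, max.depth = spec$max_depth,
    class.weights = unname(balanced_class_weights(y)[levels(y)]),
    probability = probability,
    seed = derive_seed(spec$seed, 500 + seed_offset),
    num.threads = 1
  )
}

drop_small_classes <- function(features, labels, n_splits) {
  tab <- table(labels)
  small <- names(tab)[tab < n_splits]
  if (length(small) > 0) {
    warning("dropping classes with fewer members than n_splits: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !labels %in% small
    features <- features[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  list(features = features, labels = labels)
}

#' Cross-validated decoding of group identity
#'
#' Stratified K-fold cross-validation of a random forest (see
#' [decoder_spec()]). Per-fold balanced accuracies are averaged for the
#' headline number; out-of-fold predictions feed the true-label-normalized
#' confusion matrix and the per-class precision/recall/F1 report. Classes
#' with fewer members than the number of folds are dropped with a warning
#' (never silently merged). Fixed seed makes folds and training
#' reproducible.
#'
#' @param features Logical/numeric cells x genes matrix.
#' @param labels Factor of group labels (one per row).
#' @param spec A [decoder_spec()].
#' @return A `decoding_result` list: `mean_balanced_accuracy`, `per_fold`,
#'   `chance_level` (percent), `confusion` (rows sum to 1), `per_class`
#'   tibble, `predictions` (out-of-fold), `labels`.
#' @export
run_decoder <- function(features, labels, spec = decoder_spec()) {
  labels <- factor(labels)
  kept <- drop_small_classes(features, labels, spec$n_splits)
  features <- kept$features
  labels <- kept$labels
  if (nlevels(labels) < 2) stop("need >= 2 classes after filtering", call. = FALSE)

  fold <- stratified_folds(labels, spec$n_splits, derive_seed(spec$seed, 400))
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  per_fold <- numeric(spec$n_splits)
  for (f in seq_len(spec$n_splits)) {
    tr <- fold != f
    fit <- fit_forest(features[tr, , drop = FALSE], labels[tr], spec,
                      seed_offset = f)
    p <- predict(fit, data = as.data.frame(features[!tr, , drop = FALSE]),
                 num.threads = 1)$predictions
    pred[!tr] <- p
    per_fold[f] <- balanced_accuracy(labels[!tr], p)
  }

  conf <- table(truth = labels, predicted = pred)
  conf_norm <- conf / rowSums(conf)
  per_class <- tibble::tibble(
    class = levels(labels),
    precision = vapply(levels(labels), function(cl) {
      denom <- sum(pred == cl, na.rm = TRUE)
      if (denom == 0) NA_real_ else sum(pred == cl & labels == cl) / denom
    }, numeric(1)),
    recall = vapply(levels(labels), function(cl) {
      sum(pred == cl & labels == cl) / sum(labels == cl)
    }, numeric(1))
  )
  per_class$f1 <- with(per_class, ifelse(
    is.na(precision) | (precision + recall) == 0, NA_real_,
    2 * precision * recall / (precision + recall)))

  structure(
    list(
      mean_balanced_accuracy = mean(per_fold),
      per_fold = per_fold,
      chance_level = chance_level(labels),
      confusion = as.matrix(conf_norm),
      per_class = per_class,
      predictions = pred,
      labels = labels
    ),
    class = "decoding_result"
  )
}

#' Linear baseline decoders
#'
#' Multinomial logistic regression and linear discriminant analysis run
#' under the identical stratified-CV protocol, for comparison with the
#' forest (linear models underperform it on real receptor profiles).
#'
#' @inheritParams run_decoder
#' @return Tibble `model`, `mean_balanced_accuracy`.
#' @export
run_baselines <- function(features, labels, spec = decoder_spec()) {
  labels <- factor(labels)
  kept <- drop_small_classes(features, labels, spec$n_splits)
  features <- kept$features
  labels <- kept$labels
  fold <- stratified_folds(labels, spec$n_splits, derive_seed(spec$seed, 400))
  x <- as.data.frame(features + 0)

  cv_accuracy <- function(fit_fun, predict_fun) {
    accs <- numeric(spec$n_splits)
    for (f in seq_len(spec$n_splits)) {
      tr <- fold != f
      # fitting draws initial weights from the RNG, and prediction breaks
      # exact probability ties randomly; pin both to the decoder seed
      pred <- tryCatch(
        withr::with_seed(derive_seed(spec$seed, 700 + f), {
          fit <- fit_fun(x[tr, , drop = FALSE], labels[tr])
          predict_fun(fit, x[!tr, , drop = FALSE])
        }),
        error = function(e) NULL)
      if (is.null(pred)) return(NA_real_)
      accs[f] <- balanced_accuracy(labels[!tr], pred)
    }
    mean(accs)
  }

  logistic <- cv_accuracy(
    function(xd, y) nnet::multinom(y ~ ., data = cbind(y = y, xd),
                                   trace = FALSE, maxit = 200, MaxNWts = 5000),
    function(fit, xd) predict(fit, newdata = xd))
  lda <- cv_accuracy(
    function(xd, y) MASS::lda(xd, grouping = y),
    function(fit, xd) predict(fit, xd)$class)

  tibble::tibble(model = c("logistic", "lda"),
                 mean_balanced_accuracy = c(logistic, lda))
}

# Class-weight-balanced sample for attribution: per-class quota of
# attribution_sample / K, capped at class size (sampling never inflates a
# class beyond its members).
attribution_rows <- function(labels, spec) {
  k <- nlevels(labels)
  quota <- max(1L, spec$attribution_sample %/% k)
  unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) <= quota) idx else sample(idx, quota)
  }), use.names = FALSE)
}

#' Per-class attribution matrix (Monte-Carlo Shapley)
#'
#' Trains one probability forest on the full feature table (separate from
#' the CV loop used for accuracy) and estimates, for every class and
#' gene, the mean absolute Shapley contribution of the gene's detection
#' state to the predicted class probability. Contributions are estimated
#' by permutation chain sampling: for each sampled row, a random feature
#' ordering is walked from a random background row towards the row of
#' interest, and the change in predicted probability when a feature's
#' value is switched in is its contribution for that permutation
#' (contributions telescope to `f(x) - f(background)` exactly). A feature
#' constant across all cells contributes exactly 0. The sample is
#' class-weight balanced and capped at `attribution_sample` rows.
#'
#' @inheritParams run_decoder
#' @return Class x gene matrix of mean absolute attributions (>= 0).
#' @export
attribution_matrix <- function(features, labels, spec = decoder_spec()) {
  labels <- factor(labels)
  m <- ncol(features)
  fit <- fit_forest(features, labels, spec, probability = TRUE,
                    seed_offset = 99)
  k <- nlevels(labels)
  withr::with_seed(derive_seed(spec$seed, 600), {
    rows <- attribution_rows(labels, spec)
    s <- length(rows)
    x <- features[rows, , drop = FALSE] + 0
    abs_phi <- array(0, dim = c(s, m, k))
    for (b in seq_len(spec$n_permutations)) {
      perm <- sample.int(m)
      bg <- features[sample.int(nrow(features), s, replace = TRUE), ,
                     drop = FALSE] + 0
      # chain of hybrids: position t has features perm[1..t] from x,
      # the rest from the background row
      chain <- matrix(0, nrow = s * (m + 1), ncol = m)
      cur <- bg
      chain[seq_len(s), ] <- cur
      for (t in seq_len(m)) {
        cur[, perm[t]] <- x[, perm[t]]
        chain[t * s + seq_len(s), ] <- cur
      }
      colnames(chain) <- colnames(features)
      probs <- predict(fit, data = as.data.frame(chain),
                       num.threads = 1)$predictions
      for (t in seq_len(m)) {
        d <- probs[t * s + seq_len(s), , drop = FALSE] -
          probs[(t - 1) * s + seq_len(s), , drop = FALSE]
        abs_phi[, perm[t], ] <- abs_phi[, perm[t], ] + d
      }
      if (b == 1) class_names <- colnames(probs)
    }
  })
  phi <- abs_phi / spec$n_permutations
  out <- matrix(0, nrow = k, ncol = m,
                dimnames = list(class_names, colnames(features)))
  for (ki in seq_len(k)) {
    out[ki, ] <- colMeans(abs(phi[, , ki, drop = FALSE])[, , 1, drop = TRUE])
  }
  out[levels(labels), , drop = FALSE]
}
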