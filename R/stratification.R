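#' Classifier configuration for grey-zone stratification
#'
#' The classifier is deliberately a pluggable standard component: L1
#' feature selection followed by a cross-validated binary classifier.
#' `l1_strength` is the inverse regularization strength C of the selection
#' step (converted internally to a lasso penalty `lambda = 1 / (n C)`).
#' Available models: `"ridge_logistic"` (default; ridge-penalized logistic
#' regression with CV-chosen penalty) and `"lda"` (linear discriminant
#' analysis) as the second model for cross-model concordance checks.
#'
#' @param l1_strength inverse L1 regularization strength (C), positive.
#' @param split_ratio training fraction of the stratified split.
#' @param cv_folds folds for the downstream model's cross-validation.
#' @param oversample_k SMOTE neighbor count.
#' @param seed seed controlling split, oversampling and fitting.
#' @param model `"ridge_logistic"` or `"lda"`.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(l1_strength = 0.1, split_ratio = 0.7, cv_folds = 5,
                            oversample_k = 5, seed = 42,
                            model = c("ridge_logistic", "lda")) {
  stopifnot(l1_strength > 0, split_ratio > 0, split_ratio < 1, cv_folds >= 2,
            oversample_k >= 1)
  structure(list(l1_strength = l1_strength, split_ratio = split_ratio,
                 cv_folds = cv_folds, oversample_k = oversample_k,
                 seed = seed, model = match.arg(model)),
            class = "classifier_spec")
}

#' Stratified train/test split
#'
#' Splits sample ids into train and test preserving the per-label
#' proportions within rounding (`round(ratio * n)` per label). Disjoint and
#' exhaustive; deterministic under a fixed seed.
#'
#' @param metadata data frame with `sample_id` and `condition` columns.
#' @param ratio training fraction.
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors.
#' @export
stratified_split <- function(metadata, ratio = 0.7, seed = 42) {
  stopifnot(is.data.frame(metadata), ratio > 0, ratio < 1)
  labs <- split(as.character(metadata$sample_id), metadata$condition)
  if (length(labs) < 2) abort("both labels must be present")
  if (any(lengths(labs) < 2))
    abort("label(s) with fewer than 2 samples: ",
          fmt_ids(names(labs)[lengths(labs) < 2]))
  with_seed(seed, {
    train <- unlist(lapply(labs, function(ids)
      sample(ids, round(ratio * length(ids)))), use.names = FALSE)
  })
  list(train = train,
       test = setdiff(as.character(metadata$sample_id), train))
}

#' SMOTE minority oversampling
#'
#' Synthetic minority points are convex combinations `x + u (x_nn - x)`,
#' `u ~ Uniform(0, 1)`, with `x_nn` one of the `k` nearest minority
#' neighbors (Euclidean). Classes are returned exactly balanced; already
#' balanced input is returned unchanged. Synthetic points never leave the
#' convex hull of the minority class.
#'
#' @param features numeric matrix (samples x features).
#' @param labels vector with two classes.
#' @param k neighbor count (minority class must have >= k + 1 samples).
#' @param seed RNG seed.
#' @return list with balanced `features` and `labels`.
#' @export
oversample_minority <- function(features, labels, k = 5, seed = 42) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  tab <- table(labels)
  if (length(tab) != 2) abort("need exactly two classes")
  if (tab[1] == tab[2]) return(list(features = features, labels = labels))
  minority <- names(tab)[which.min(tab)]
  x_min <- features[labels == minority, , drop = FALSE]
  n_min <- nrow(x_min)
  if (n_min < k + 1)
    abort("minority class has ", n_min, " samples; needs k + 1 = ", k + 1,
          " — use a smaller k")
  n_syn <- max(tab) - n_min
  d <- as.matrix(dist(x_min))
  diag(d) <- Inf
  ord <- apply(d, 1L, function(r) order(r)[seq_len(k)])
  nn_idx <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  syn <- with_seed(seed, {
    base <- sample.int(n_min, n_syn, replace = TRUE)
    pick <- nn_idx[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    x_min[base, , drop = FALSE] +
      u * (x_min[pick, , drop = FALSE] - x_min[base, , drop = FALSE])
  })
  rownames(syn) <- sprintf("syn_%04d", seq_len(n_syn))
  list(features = rbind(features, syn),
       labels = c(labels, rep(minority, n_syn)))
}

#' Fit the pluggable classifier and predict test probabilities
#'
#' Pipeline: standardize on training statistics, SMOTE-balance the training
#' set when imbalanced, select features by L1-penalized logistic
#' regression (features with zero coefficient dropped; an empty selection
#' is an error reporting `l1_strength`), then fit the configured model on
#' the surviving features and return predicted case probabilities for the
#' test samples.
#'
#' @param spec a [classifier_spec()].
#' @param train_x,test_x numeric matrices (samples x features) with sample
#'   ids as rownames.
#' @param train_y,test_y labels (`"case"` / `"control"`).
#' @param oversample apply SMOTE when classes are imbalanced.
#' @return a `prediction_set`: data frame (sample_id, probability, label,
#'   model_id).
#' @export
fit_predict <- function(spec, train_x, train_y, test_x, test_y,
                        oversample = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"),
            is.matrix(train_x), is.matrix(test_x),
            nrow(train_x) == length(train_y), nrow(test_x) == length(test_y))
  keep <- apply(train_x, 2L, sd) > 0
  if (!any(keep)) abort("all features are constant on the training set")
  mu <- colMeans(train_x[, keep, drop = FALSE])
  sg <- apply(train_x[, keep, drop = FALSE], 2L, sd)
  xtr <- sweep(sweep(train_x[, keep, drop = FALSE], 2L, mu), 2L, sg, "/")
  xte <- sweep(sweep(test_x[, keep, drop = FALSE], 2L, mu), 2L, sg, "/")
  ytr <- as.character(train_y)

  if (oversample && length(unique(table(ytr))) > 1) {
    bal <- oversample_minority(xtr, ytr, k = spec$oversample_k,
                               seed = derive_seed(spec$seed, 1))
    xtr <- bal$features; ytr <- bal$labels
  }
  yy <- factor(ytr, levels = c("control", "case"))

  lambda_l1 <- 1 / (nrow(xtr) * spec$l1_strength)
  sel <- with_seed(derive_seed(spec$seed, 2), {
    fit <- glmnet::glmnet(xtr, yy, family = "binomial", alpha = 1,
                          lambda = lambda_l1, standardize = FALSE)
    which(as.numeric(coef(fit))[-1L] != 0)
  })
  if (length(sel) == 0)
    abort("no features survive L1 selection at l1_strength = ",
          spec$l1_strength)
  xtr_s <- xtr[, sel, drop = FALSE]
  xte_s <- xte[, sel, drop = FALSE]

  prob <- with_seed(derive_seed(spec$seed, 3), {
    if (spec$model == "lda") {
      fit <- MASS::lda(xtr_s, grouping = yy)
      predict(fit, xte_s)$posterior[, "case"]
    } else if (ncol(xtr_s) >= 2) {
      cvfit <- glmnet::cv.glmnet(xtr_s, yy, family = "binomial", alpha = 0,
                                 nfolds = spec$cv_folds)
      as.numeric(predict(cvfit, xte_s, s = "lambda.min", type = "response"))
    } else {
      df <- data.frame(y = yy, x = xtr_s[, 1L])
      fit <- stats::glm(y ~ x, data = df, family = stats::binomial())
      as.numeric(predict(fit, data.frame(x = xte_s[, 1L]), type = "response"))
    }
  })
  ids <- rownames(test_x)
  if (is.null(ids)) ids <- sprintf("sample_%04d", seq_len(nrow(test_x)))
  structure(data.frame(sample_id = ids, probability = unname(prob),
                       label = as.character(test_y), model_id = spec$model,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with half-credit for ties, so any strictly
#' monotone transform of the probabilities leaves it unchanged.
#'
#' @param preds a `prediction_set` (both labels present).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(preds) {
  y <- preds$label == "case"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both labels must be present")
  r <- rank(preds$probability)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assign clear / grey / unassigned zones
#'
#' Operational rule (probability of case P plus clinical label):
#' grey iff `0.4 <= P <= 0.6` (label-agnostic); `Clear_GDM` iff `P >= 0.7`
#' and clinically case; `Clear_NonGDM` iff `P <= 0.3` and clinically
#' control; everything else — the gaps (0.3, 0.4) and (0.6, 0.7) and
#' label-discordant extremes — is `unassigned`. With `strict = TRUE` the
#' clear thresholds become exclusive (`P > 0.7` / `P < 0.3`).
#'
#' @param preds a `prediction_set`.
#' @param strict use strict clear-zone inequalities.
#' @return a `zone_assignment`: data frame (sample_id, zone).
#' @export
assign_zones <- function(preds, strict = FALSE) {
  p <- preds$probability
  lab <- preds$label
  clear_case <- if (strict) p > 0.7 else p >= 0.7
  clear_ctrl <- if (strict) p < 0.3 else p <= 0.3
  zone <- ifelse(p >= 0.4 & p <= 0.6, "grey",
          ifelse(clear_case & lab == "case", "Clear_GDM",
          ifelse(clear_ctrl & lab == "control", "Clear_NonGDM", "unassigned")))
  structure(data.frame(sample_id = preds$sample_id, zone = zone,
                       stringsAsFactors = FALSE),
            class = c("zone_assignment", "data.frame"))
}

#' Misclassification rate per probability bin
#'
#' Bins must partition `[0, 1]` (`bin_edges` strictly increasing from 0 to
#' 1); bins are left-closed, the last also right-closed. A sample is called
#' case iff `P >= 0.5`; the error rate is the fraction of calls that
#' mismatch the clinical label. Empty bins get `n = 0` and `NA` rate.
#'
#' @param preds a `prediction_set`.
#' @param bin_edges increasing numeric vector from 0 to 1.
#' @return data frame: bin, lower, upper, n, error_rate.
#' @export
bin_misclassification <- function(preds, bin_edges = seq(0, 1, by = 0.1)) {
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 1)
    abort("bin_edges must increase strictly from 0 to 1 (no overlap, no gaps)")
  p <- preds$probability
  bin <- findInterval(p, bin_edges, rightmost.closed = TRUE)
  wrong <- (p >= 0.5) != (preds$label == "case")
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin = sprintf("[%.2g,%.2g%s", bin_edges[-length(bin_edges)],
                                  bin_edges[-1L],
                                  c(rep(")", nb - 1L), "]")),
                    lower = bin_edges[-length(bin_edges)],
                    upper = bin_edges[-1L],
                    n = tabulate(bin, nbins = nb))
  out$error_rate <- vapply(seq_len(nb), function(b)
    if (out$n[b] == 0) NA_real_ else mean(wrong[bin == b]), numeric(1))
  out
}

#' Grey-zone concordance between two models
#'
#' Overlap of the grey-zone sample sets of two zone assignments over the
#' same sample universe: intersection size and Jaccard index (1 when both
#' grey sets are empty, i.e. identical).
#'
#' @param za,zb `zone_assignment`s on the same samples.
#' @return list: `n_intersection`, `jaccard`, `n_a`, `n_b`.
#' @export
zone_concordance <- function(za, zb) {
  if (!setequal(za$sample_id, zb$sample_id))
    abort("zone assignments cover different sample universes")
  ga <- za$sample_id[za$zone == "grey"]
  gb <- zb$sample_id[zb$zone == "grey"]
  u <- union(ga, gb)
  list(n_intersection = length(intersect(ga, gb)),
       jaccard = if (length(u) == 0) 1 else length(intersect(ga, gb)) / length(u),
       n_a = length(ga), n_b = length(gb))
}
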