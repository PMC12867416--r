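meta_of <- function(n_case, n_control) {
  data.frame(sample_id = sprintf("s%03d", seq_len(n_case + n_control)),
             condition = rep(c("case", "control"), c(n_case, n_control)),
             stringsAsFactors = FALSE)
}

test_that("stratified_split preserves label proportions and is seeded", {
  sp <- stratified_split(meta_of(70, 70), ratio = 0.7, seed = 1)
  meta <- meta_of(70, 70)
  lab <- setNames(meta$condition, meta$sample_id)
  expect_equal(sum(lab[sp$train] == "case"), 49)
  expect_equal(sum(lab[sp$train] == "control"), 49)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), meta$sample_id)
  # same seed, same split
  expect_identical(sp, stratified_split(meta_of(70, 70), 0.7, seed = 1))
  # rounding rule: 10 cases at 0.7 -> 7 train, 3 test
  sp2 <- stratified_split(meta_of(10, 100), 0.7, seed = 2)
  lab2 <- setNames(meta_of(10, 100)$condition, meta_of(10, 100)$sample_id)
  expect_equal(sum(lab2[sp2$test] == "case"), 3)
  expect_error(stratified_split(meta_of(1, 50)), "fewer than 2")
})

test_that("SMOTE balances classes with convex-combination synthesis", {
  set.seed(41)
  x <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("r%02d", 1:20), c("f1", "f2")))
  y <- rep(c("case", "control"), c(6, 14))
  bal <- oversample_minority(x, y, k = 3, seed = 1)
  expect_equal(unname(table(bal$labels)["case"]),
               unname(table(bal$labels)["control"]))
  # synthetic points stay inside the minority bounding box (convex hull prop.)
  syn <- bal$features[grepl("^syn", rownames(bal$features)), , drop = FALSE]
  mins <- apply(x[y == "case", ], 2, min); maxs <- apply(x[y == "case", ], 2, max)
  expect_true(all(t(syn) >= mins - 1e-12 & t(syn) <= maxs + 1e-12))
  # already balanced input is returned unchanged
  same <- oversample_minority(x[1:12, ], rep(c("case", "control"), each = 6))
  expect_identical(same$features, x[1:12, ])
  # 1-D minority {0, 1} with k = 1: synthetic values stay in [0, 1]
  x1 <- matrix(c(0, 1, rnorm(8, 10)), ncol = 1,
               dimnames = list(sprintf("q%02d", 1:10), "f"))
  y1 <- rep(c("case", "control"), c(2, 8))
  b1 <- oversample_minority(x1, y1, k = 1, seed = 2)
  syn1 <- b1$features[grepl("^syn", rownames(b1$features)), 1]
  expect_true(all(syn1 >= 0 & syn1 <= 1))
  expect_error(oversample_minority(x, y, k = 10), "smaller k")
})

test_that("auc matches pair counting, handles ties, and is rank-invariant", {
  preds <- data.frame(sample_id = letters[1:4],
                      probability = c(0.9, 0.4, 0.6, 0.2),
                      label = c("case", "case", "control", "control"))
  expect_equal(auc(preds), 0.75)  # 3 of 4 pairs concordant
  # probabilities equal to the labels: perfect
  perfect <- data.frame(sample_id = 1:4, probability = c(1, 1, 0, 0),
                        label = c("case", "case", "control", "control"))
  expect_equal(auc(perfect), 1)
  # all tied: 0.5 by half-credit
  flat <- transform(perfect, probability = 0.5)
  expect_equal(auc(flat), 0.5)
  # strictly monotone transform leaves AUC unchanged
  trans <- transform(preds, probability = plogis(5 * probability - 2))
  expect_equal(auc(trans), auc(preds))
  expect_error(auc(transform(preds, label = "case")), "both labels")
})

test_that("fit_predict separates, nulls out, and finds planted signal", {
  set.seed(42)
  # perfectly separable
  n <- 60
  x <- rbind(matrix(rnorm(n * 3, 3), n), matrix(rnorm(n * 3, -3), n))
  colnames(x) <- paste0("f", 1:3)
  rownames(x) <- sprintf("s%03d", 1:(2 * n))
  y <- rep(c("case", "control"), each = n)
  idx <- c(1:40, 61:100)
  spec <- classifier_spec(seed = 7)
  preds <- fit_predict(spec, x[idx, ], y[idx], x[-idx, ], y[-idx])
  expect_equal(auc(preds), 1)
  # permuted labels: AUC near 0.5 on average over seeds. The default L1
  # penalty correctly empties the selection when there is no signal, so a
  # weak penalty is used here to exercise the downstream null behavior.
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    yp <- sample(y)
    p <- fit_predict(classifier_spec(l1_strength = 10, seed = s),
                     x[idx, ], yp[idx], x[-idx, ], yp[-idx])
    auc(p)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
  # no features surviving an absurdly strong penalty is a clear error
  expect_error(fit_predict(classifier_spec(l1_strength = 1e-8, seed = 1),
                           x[idx, ], y[idx], x[-idx, ], y[-idx]),
               "l1_strength")
})

test_that("planted guild shift is learnable at moderate n", {
  guilds <- guild_spec(8, rho_intra_case = 0.6, abundance_log_shift = 0.9)
  cohort <- cohort_spec(150, 150, n_noise_otus = 22, seed = 43)
  sim <- generate_cohort(guilds, cohort)
  clr <- clr_transform(sim$table)
  meta <- sim$metadata
  sp <- stratified_split(meta, 0.7, seed = 1)
  lab <- setNames(meta$condition, meta$sample_id)
  for (model in c("ridge_logistic", "lda")) {
    preds <- fit_predict(classifier_spec(seed = 1, model = model),
                         clr[sp$train, ], lab[sp$train],
                         clr[sp$test, ], lab[sp$test])
    expect_gt(auc(preds), 0.6)
  }
})

test_that("assign_zones follows the rule table including gaps and discordance", {
  cases <- expand.grid(p = c(0.25, 0.35, 0.45, 0.55, 0.65, 0.75),
                       label = c("case", "control"),
                       stringsAsFactors = FALSE)
  preds <- data.frame(sample_id = seq_len(nrow(cases)),
                      probability = cases$p, label = cases$label)
  z <- assign_zones(preds)$zone
  want <- ifelse(cases$p >= 0.4 & cases$p <= 0.6, "grey",
          ifelse(cases$p >= 0.7 & cases$label == "case", "Clear_GDM",
          ifelse(cases$p <= 0.3 & cases$label == "control", "Clear_NonGDM",
                 "unassigned")))
  expect_identical(z, want)
  # boundary behavior: inclusive by default, exclusive when strict
  edge <- data.frame(sample_id = 1:2, probability = c(0.7, 0.3),
                     label = c("case", "control"))
  expect_identical(assign_zones(edge)$zone, c("Clear_GDM", "Clear_NonGDM"))
  expect_identical(assign_zones(edge, strict = TRUE)$zone,
                   c("unassigned", "unassigned"))
})

test_that("bin_misclassification counts errors per probability bin", {
  # 5 of 6 wrong in one bin reproduces the 83.3% reporting style
  preds <- data.frame(sample_id = 1:6, probability = rep(0.55, 6),
                      label = c(rep("control", 5), "case"))
  bins <- bin_misclassification(preds)
  row <- bins[bins$lower == 0.5, ]
  expect_equal(row$n, 6)
  expect_equal(row$error_rate, 5 / 6, tolerance = 1e-12)
  expect_true(all(bins$n[bins$lower != 0.5] == 0))
  expect_true(all(is.na(bins$error_rate[bins$n == 0])))
  # all correct: zero error everywhere occupied
  good <- data.frame(sample_id = 1:4, probability = c(0.9, 0.8, 0.1, 0.2),
                     label = c("case", "case", "control", "control"))
  b2 <- bin_misclassification(good)
  expect_true(all(b2$error_rate[b2$n > 0] == 0))
  # random predictions vs direct counting oracle
  set.seed(44)
  rp <- data.frame(sample_id = 1:200, probability = runif(200),
                   label = sample(c("case", "control"), 200, TRUE))
  b3 <- bin_misclassification(rp, bin_edges = c(0, 0.5, 1))
  wrong <- (rp$probability >= 0.5) != (rp$label == "case")
  expect_equal(b3$error_rate[1], mean(wrong[rp$probability < 0.5]))
  expect_equal(b3$error_rate[2], mean(wrong[rp$probability >= 0.5]))
  expect_error(bin_misclassification(rp, c(0, 0.6, 0.4, 1)), "increase")
})

test_that("zone_concordance measures grey-set overlap", {
  za <- assign_zones(data.frame(sample_id = 1:4,
                                probability = c(0.5, 0.45, 0.9, 0.1),
                                label = c("case", "control", "case", "control")))
  expect_equal(zone_concordance(za, za)$jaccard, 1)
  zb <- za; zb$zone <- c("unassigned", "unassigned", "grey", "grey")
  cc <- zone_concordance(za, zb)
  expect_equal(cc$n_intersection, 0)
  expect_equal(cc$jaccard, 0)
  zc <- za; zc$sample_id <- 5:8
  expect_error(zone_concordance(za, zc), "universe")
})

test_that("cross-model grey zones overlap on transitional cohorts", {
  guilds <- guild_spec(8, rho_intra_case = 0.6, abundance_log_shift = 1.2)
  cohort <- cohort_spec(120, 120, n_grey = 60, n_noise_otus = 22, seed = 45)
  sim <- generate_cohort(guilds, cohort)
  clr <- clr_transform(sim$table)
  meta <- sim$metadata
  sp <- stratified_split(meta, 0.7, seed = 2)
  lab <- setNames(meta$condition, meta$sample_id)
  mk <- function(model) {
    assign_zones(fit_predict(classifier_spec(seed = 2, model = model),
                             clr[sp$train, ], lab[sp$train],
                             clr[sp$test, ], lab[sp$test]))
  }
  za <- mk("ridge_logistic"); zb <- mk("lda")
  cc <- zone_concordance(za, zb)
  expect_gt(cc$n_a, 0)  # a transitional cohort does produce a grey zone
  expect_gt(cc$jaccard, 0)
})
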