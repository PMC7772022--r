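test_that("stratified split uses per-class floor rounding", {
  tab <- fx_class_table(89, 48)
  sp <- split_cohort(tab, split_spec(base_seed = 9), run = 1)
  expect_equal(sum(sp$train$group == "fractured"), 62)   # floor(0.7 * 89)
  expect_equal(sum(sp$train$group == "control"), 33)     # floor(0.7 * 48)
  expect_equal(nrow(sp$train), 95)
  expect_equal(nrow(sp$test), 42)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  tab$subject_id)
  ## same base seed + run index reproduces the split
  sp2 <- split_cohort(tab, split_spec(base_seed = 9), run = 1)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  expect_error(split_cohort(tab[tab$group == "control", ]), "both classes")
})

test_that("SMOTE fills both classes to the target with convex synthetics", {
  tab <- fx_class_table(89, 48)
  sp <- split_cohort(tab, split_spec(base_seed = 1), run = 1)
  aug <- smote_augment(sp$train, smote_spec(seed = 5),
                       features = c("f1", "f2", "f3", "f4"))
  expect_equal(nrow(aug), 400)
  expect_equal(sum(aug$group == "fractured"), 200)
  expect_equal(sum(aug$group == "control"), 200)
  ## originals preserved verbatim
  expect_true(all(sp$train$subject_id %in% aug$subject_id[!aug$synthetic]))
  ## synthetic points stay inside each class's bounding box (convexity)
  for (g in c("fractured", "control")) {
    orig <- sp$train[sp$train$group == g, c("f1", "f2", "f3", "f4")]
    syn <- aug[aug$synthetic & aug$group == g, c("f1", "f2", "f3", "f4")]
    for (f in names(orig)) {
      expect_true(all(syn[[f]] >= min(orig[[f]]) - 1e-12))
      expect_true(all(syn[[f]] <= max(orig[[f]]) + 1e-12))
    }
  }
  ## a class of identical duplicated points only reproduces itself
  dup <- data.frame(group = rep(c("a", "b"), each = 8),
                    f1 = rep(c(1, 5), each = 8), f2 = rep(c(2, -1), each = 8))
  aug2 <- smote_augment(dup, smote_spec(target_per_class = 20, seed = 2),
                        features = c("f1", "f2"))
  expect_true(all(aug2$f1[aug2$group == "a"] == 1))
  expect_true(all(aug2$f2[aug2$group == "b"] == -1))
  expect_error(smote_augment(sp$train, smote_spec(target_per_class = 10)),
               "below existing")
})

test_that("evaluation metrics follow their confusion definitions", {
  ## fabricate predictions through a threshold-free check of the formulas
  mk <- function(truth, pred) {
    tp <- sum(pred == "fractured" & truth == "fractured")
    fn <- sum(pred == "control" & truth == "fractured")
    tn <- sum(pred == "control" & truth == "control")
    fp <- sum(pred == "fractured" & truth == "control")
    c(Se = tp / (tp + fn), Sp = tn / (tn + fp),
      Acc = (tp + tn) / length(truth))
  }
  truth <- rep(c("fractured", "control"), c(10, 10))
  pred <- c(rep("fractured", 9), "control",          # TP 9, FN 1
            rep("fractured", 2), rep("control", 8))  # FP 2, TN 8
  m <- mk(truth, pred)
  expect_equal(unname(m), c(0.9, 0.8, 0.85))
  ## and the package evaluator agrees on a trained model
  tab <- fx_class_table(40, 40, gap = 6, seed = 2)   # near-separable
  sp <- split_cohort(tab, split_spec(base_seed = 3), run = 1)
  mod <- train_model(model_spec("LR"), sp$train, c("f1", "f2"))
  ev <- evaluate_model(mod, sp$test)
  expect_equal(ev$Acc,
               (ev$confusion["TP"] + ev$confusion["TN"]) / nrow(sp$test),
               ignore_attr = TRUE)
  expect_gte(ev$Acc, 0.9)
})

test_that("every model family separates well-separated blobs", {
  tab <- fx_class_table(30, 30, gap = 8, seed = 4)
  feats <- c("f1", "f2")
  for (spec in list(model_spec("LR"), model_spec("SVM", kernel = "linear"),
                    model_spec("SVM", kernel = "gaussian"),
                    model_spec("SVM", kernel = "bayesian"),
                    model_spec("DT"),
                    model_spec("RF", trees = 100))) {
    mod <- train_model(spec, tab, feats)
    pred <- predict(mod, tab)
    expect_gte(mean(pred == tab$group), 0.97)
  }
  one_class <- tab[tab$group == "fractured", ]
  expect_error(train_model(model_spec("LR"), one_class, feats), "single class")
})

test_that("kernel contrast on XOR data: linear fails, Gaussian succeeds", {
  set.seed(8)
  n <- 400
  x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
  tab <- data.frame(group = ifelse(x1 * x2 > 0, "fractured", "control"),
                    f1 = x1, f2 = x2)
  sp <- split_cohort(tab, split_spec(base_seed = 6), run = 1)
  lin <- train_model(model_spec("SVM", kernel = "linear"), sp$train,
                     c("f1", "f2"))
  gau <- train_model(model_spec("SVM", kernel = "gaussian"), sp$train,
                     c("f1", "f2"))
  acc <- function(m) mean(predict(m, sp$test) == sp$test$group)
  expect_lt(acc(lin), 0.65)
  expect_gt(acc(gau), 0.9)
})

test_that("benchmark bookkeeping: row counts, single-run RF, determinism", {
  tab <- fx_class_table(30, 20, gap = 2, seed = 10)
  feats <- list(two = c("f1", "f2"), four = c("f1", "f2", "f3", "f4"))
  models <- list(LR = model_spec("LR"),
                 RF = model_spec("RF", trees = 50))
  rep1 <- benchmark(tab, feats, models,
                    split_spec(n_runs = 3, base_seed = 21),
                    smote_spec(target_per_class = 40))
  expect_equal(nrow(rep1$summary), length(feats) * length(models))
  rf_rows <- rep1$summary[rep1$summary$model == "RF", ]
  expect_true(all(rf_rows$n_runs == 1))
  expect_equal(rf_rows$Acc_mean, rf_rows$Acc_best)
  lr_rows <- rep1$summary[rep1$summary$model == "LR", ]
  expect_true(all(lr_rows$n_runs == 3))
  ## n_runs = 1 collapses mean and best
  rep_one <- benchmark(tab, feats["two"], models["LR"],
                       split_spec(n_runs = 1, base_seed = 21),
                       smote_spec(target_per_class = 40))
  expect_equal(rep_one$summary$Se_mean, rep_one$summary$Se_best)
  ## bit-for-bit reproducibility from the base seed
  rep2 <- benchmark(tab, feats, models,
                    split_spec(n_runs = 3, base_seed = 21),
                    smote_spec(target_per_class = 40))
  expect_identical(rep1$summary, rep2$summary)
})
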