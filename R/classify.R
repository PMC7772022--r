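#' Split specification for repeated hold-out evaluation
#'
#' @param train_fraction fraction of each class assigned to training
#' @param stratified keep class proportions (always TRUE in this design;
#'   recorded for the report)
#' @param n_runs number of independent split/train/test cycles
#' @param base_seed seed from which per-run split seeds are derived
#' @return object of class `split_spec`
#' @export
split_spec <- function(train_fraction = 0.70, stratified = TRUE,
                       n_runs = 1000, base_seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_runs >= 1)
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 n_runs = n_runs, base_seed = base_seed),
            class = "split_spec")
}

#' SMOTE specification
#'
#' @param target_per_class training rows per class after augmentation
#' @param k number of same-class nearest neighbours
#' @param seed sampling seed
#' @return object of class `smote_spec`
#' @export
smote_spec <- function(target_per_class = 200, k = 5, seed = 1) {
  stopifnot(k >= 1, target_per_class >= 1)
  structure(list(target_per_class = target_per_class, k = k, seed = seed),
            class = "smote_spec")
}

#' Classifier specification
#'
#' Families: `"LR"` (logistic regression), `"SVM"` (with kernel
#' `"linear"`, `"sigmoid"`, `"gaussian"` or `"bayesian"`), `"DT"`
#' (decision tree, Gini splitting) and `"RF"` (random forest).
#' `posterior_probability` requests classification by thresholding a
#' calibrated class posterior ("posterior probability regions") instead
#' of the raw decision value. The `"bayesian"` kernel is a Gaussian
#' process classifier with a squared-exponential kernel, which natively
#' yields posteriors and is therefore always probabilistic.
#'
#' @param family one of LR, SVM, DT, RF
#' @param kernel SVM kernel (SVM only)
#' @param posterior_probability classify by calibrated posterior
#' @param threshold posterior decision threshold
#' @param trees number of random-forest trees
#' @param max_depth random-forest depth cap
#' @param cost SVM soft-margin cost
#' @param label optional display label
#' @return object of class `model_spec`
#' @export
model_spec <- function(family = c("LR", "SVM", "DT", "RF"),
                       kernel = NULL, posterior_probability = FALSE,
                       threshold = 0.5, trees = 1000, max_depth = 12,
                       cost = 1, label = NULL) {
  family <- match.arg(family)
  if (!is.null(kernel)) {
    if (family != "SVM") stop("kernel is only meaningful for SVM")
    kernel <- match.arg(kernel, c("linear", "sigmoid", "gaussian", "bayesian"))
    if (kernel == "bayesian") posterior_probability <- TRUE
  } else if (family == "SVM") kernel <- "linear"
  stopifnot(trees >= 1, threshold > 0, threshold < 1)
  if (is.null(label)) {
    label <- family
    if (family == "SVM") label <- paste0("SVM-", kernel)
    if (posterior_probability) label <- paste0(label, "+PPR")
  }
  structure(list(family = family, kernel = kernel,
                 posterior_probability = posterior_probability,
                 threshold = threshold, trees = trees, max_depth = max_depth,
                 cost = cost, label = label),
            class = "model_spec")
}

#' The model battery of the benchmark
#'
#' Logistic regression, seven SVM variants (linear, sigmoid and Gaussian
#' kernels each with and without posterior-probability classification,
#' plus the Bayesian/Gaussian-process kernel), a Gini decision tree and a
#' 1000-tree random forest.
#'
#' @param trees random-forest tree count
#' @param max_depth random-forest depth cap
#' @return named list of [model_spec()] objects
#' @export
default_model_battery <- function(trees = 1000, max_depth = 12) {
  specs <- list(
    model_spec("LR"),
    model_spec("SVM", kernel = "linear"),
    model_spec("SVM", kernel = "linear", posterior_probability = TRUE),
    model_spec("SVM", kernel = "sigmoid"),
    model_spec("SVM", kernel = "sigmoid", posterior_probability = TRUE),
    model_spec("SVM", kernel = "gaussian"),
    model_spec("SVM", kernel = "gaussian", posterior_probability = TRUE),
    model_spec("SVM", kernel = "bayesian"),
    model_spec("DT"),
    model_spec("RF", trees = trees, max_depth = max_depth)
  )
  names(specs) <- vapply(specs, function(s) s$label, character(1))
  specs
}

#' Stratified train/test split
#'
#' Per class, `floor(train_fraction * class size)` rows go to training
#' and the remainder to test, sampled with a seed derived from the base
#' seed and the run index.
#'
#' @param table data frame with a `group` column (levels `fractured`,
#'   `control`)
#' @param spec a [split_spec()]
#' @param run run index (>= 1)
#' @return list with data frames `train`, `test`
#' @export
split_cohort <- function(table, spec = split_spec(), run = 1) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  groups <- unique(as.character(table$group))
  if (length(groups) < 2) stop("both classes must be present")
  if (any(table(table$group) < 2)) stop("each class needs at least 2 members")
  seed <- derive_seed(spec$base_seed, 101, run)
  tr_idx <- with_seed(seed, {
    unlist(lapply(groups, function(g) {
      idx <- which(table$group == g)
      sample(idx, floor(spec$train_fraction * length(idx)))
    }))
  })
  list(train = table[sort(tr_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), tr_idx), , drop = FALSE])
}

#' SMOTE augmentation of a training table
#'
#' Synthetic minority (here: both-class) oversampling: each synthetic
#' point is `x + lambda * (x_nn - x)` with `lambda ~ U(0, 1)` and `x_nn`
#' one of the `k` nearest same-class neighbours under Euclidean distance
#' on per-feature z-scored coordinates. Original rows are preserved and
#' tagged `synthetic = FALSE`. Each class is filled up to
#' `target_per_class` rows independently; the test set is never touched.
#'
#' @param train training data frame with `group` and numeric feature
#'   columns
#' @param spec a [smote_spec()]
#' @param features feature column names (default: all numeric columns
#'   except provenance columns)
#' @return augmented data frame with a logical `synthetic` column
#' @export
smote_augment <- function(train, spec = smote_spec(), features = NULL) {
  stopifnot(is.data.frame(train), "group" %in% names(train))
  if (is.null(features)) {
    num <- vapply(train, is.numeric, logical(1))
    features <- setdiff(names(train)[num], c("synthetic"))
  }
  counts <- table(train$group)
  if (any(spec$target_per_class < counts))
    stop("target per class below existing class size")
  ## z-scored coordinates for the neighbour metric
  X <- as.matrix(train[, features, drop = FALSE])
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  out <- train
  out$synthetic <- FALSE
  add <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  for (g in names(counts)) {
    idx <- which(train$group == g)
    need <- spec$target_per_class - length(idx)
    if (need <= 0) next
    k <- spec$k
    if (length(idx) <= k) {
      warning("class '", g, "' smaller than k+1; k reduced")
      k <- length(idx) - 1
    }
    if (k < 1) stop("class '", g, "' too small for SMOTE")
    D <- as.matrix(stats::dist(Z[idx, , drop = FALSE]))
    diag(D) <- Inf
    nn <- do.call(rbind, lapply(seq_len(nrow(D)),
                                function(r) order(D[r, ])[seq_len(k)]))
    base <- sample(seq_along(idx), need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
    lam <- stats::runif(need)
    Xnew <- X[idx[base], , drop = FALSE] +
      lam * (X[idx[pick], , drop = FALSE] - X[idx[base], , drop = FALSE])
    new <- train[idx[base], , drop = FALSE]
    new[, features] <- Xnew
    new$synthetic <- TRUE
    if ("subject_id" %in% names(new))
      new$subject_id <- sprintf("%s_smote%03d", g, seq_len(need))
    add[[g]] <- new
  }
  res <- rbind(out, do.call(rbind, add))
  rownames(res) <- NULL
  res
}

## internal: fit + predict machinery -----------------------------------------

prep_xy <- function(data, features) {
  x <- as.matrix(data[, features, drop = FALSE])
  y <- factor(as.character(data$group), levels = c("control", "fractured"))
  list(x = x, y = y)
}

#' Train a classifier
#'
#' The positive class is `fractured` (coded 1). Probabilistic variants
#' classify by thresholding the fractured-class posterior; SVM
#' posteriors use Platt-style sigmoid calibration, the Bayesian kernel is
#' a Gaussian process classifier and is inherently probabilistic.
#'
#' @param spec a [model_spec()]
#' @param train training data frame with `group` and feature columns
#' @param features feature column names
#' @return object of class `sidefall_model`
#' @export
train_model <- function(spec, train, features) {
  d <- prep_xy(train, features)
  if (nlevels(droplevels(d$y)) < 2) stop("training data contain a single class")
  fit <- switch(spec$family,
    LR = {
      df <- data.frame(d$x, y = as.integer(d$y == "fractured"))
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    SVM = {
      if (spec$kernel == "bayesian") {
        fit <- NULL
        utils::capture.output(
          fit <- kernlab::gausspr(x = d$x, y = d$y, kernel = "rbfdot"))
        fit
      } else {
        ktype <- c(linear = "linear", sigmoid = "sigmoid",
                   gaussian = "radial")[spec$kernel]
        e1071::svm(x = d$x, y = d$y, kernel = unname(ktype), cost = spec$cost,
                   probability = spec$posterior_probability, scale = TRUE)
      }
    },
    DT = {
      df <- data.frame(d$x, y = d$y)
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = "gini"))
    },
    RF = {
      df <- data.frame(d$x, y = d$y)
      ranger::ranger(y ~ ., data = df, num.trees = spec$trees,
                     max.depth = spec$max_depth, probability = TRUE,
                     num.threads = 1, seed = 1)
    }
  )
  structure(list(spec = spec, fit = fit, features = features),
            class = "sidefall_model")
}

#' Predict class labels
#'
#' @param object a `sidefall_model`
#' @param newdata data frame with the model's feature columns
#' @param ... unused
#' @return factor with levels `control`, `fractured`
#' @export
predict.sidefall_model <- function(object, newdata, ...) {
  spec <- object$spec
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  lv <- c("control", "fractured")
  lab <- switch(spec$family,
    LR = {
      p <- stats::predict(object$fit, newdata = as.data.frame(x),
                          type = "response")
      ifelse(p >= spec$threshold, "fractured", "control")
    },
    SVM = {
      if (spec$kernel == "bayesian") {
        p <- kernlab::predict(object$fit, x, type = "probabilities")
        colnames(p) <- object$fit@lev
        p <- p[, , drop = FALSE]
        ifelse(p[, "fractured"] >= spec$threshold, "fractured", "control")
      } else if (spec$posterior_probability) {
        pr <- stats::predict(object$fit, x, probability = TRUE)
        p <- attr(pr, "probabilities")[, "fractured"]
        ifelse(p >= spec$threshold, "fractured", "control")
      } else {
        as.character(stats::predict(object$fit, x))
      }
    },
    DT = {
      p <- stats::predict(object$fit, as.data.frame(x), type = "prob")[, "fractured"]
      ifelse(p >= spec$threshold, "fractured", "control")
    },
    RF = {
      p <- stats::predict(object$fit, data = as.data.frame(x),
                          num.threads = 1)$predictions[, "fractured"]
      ifelse(p >= spec$threshold, "fractured", "control")
    }
  )
  factor(lab, levels = lv)
}

#' Sensitivity, specificity and accuracy on a test set
#'
#' Fractured is the positive class: `Se = TP/(TP+FN)`,
#' `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/n`. If a class is absent from the
#' test set the corresponding metric is `NA` and `flagged` is TRUE.
#'
#' @param model a trained `sidefall_model`
#' @param test test data frame with `group` and feature columns
#' @return list with `Se`, `Sp`, `Acc`, `confusion` (TP, FP, TN, FN),
#'   `flagged`
#' @export
evaluate_model <- function(model, test) {
  stopifnot(nrow(test) > 0)
  truth <- factor(as.character(test$group), levels = c("control", "fractured"))
  pred <- predict(model, test)
  tp <- sum(pred == "fractured" & truth == "fractured")
  fn <- sum(pred == "control" & truth == "fractured")
  tn <- sum(pred == "control" & truth == "control")
  fp <- sum(pred == "fractured" & truth == "control")
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(Se = se, Sp = sp, Acc = (tp + tn) / length(truth),
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       flagged = is.na(se) || is.na(sp))
}

#' Benchmark a model battery over repeated splits
#'
#' For LR, SVM and DT models: `n_runs` independent
#' split -> SMOTE -> train -> evaluate cycles, reporting mean, SD and
#' best of each metric. The random forest is treated as self-averaging:
#' a single seeded run is reported (mean = best, SD = NA). Each feature
#' set in `feature_sets` is evaluated for each model. SMOTE rows never
#' reach a test set: augmentation is applied strictly after the split.
#'
#' @param table attribute data frame with `group` plus attribute columns
#' @param feature_sets named list of character vectors
#' @param models named list of [model_spec()]s
#' @param split a [split_spec()]
#' @param smote a [smote_spec()]; its seed is re-derived per run
#' @return object of class `eval_report`: data frame `summary` plus
#'   per-run metric records in `runs`
#' @export
benchmark <- function(table, feature_sets, models = default_model_battery(),
                      split = split_spec(), smote = smote_spec()) {
  stopifnot(length(feature_sets) > 0, !is.null(names(feature_sets)))
  summ <- list(); runs <- list()
  for (fs_name in names(feature_sets)) {
    feats <- feature_sets[[fs_name]]
    missing <- setdiff(feats, names(table))
    if (length(missing)) stop("missing features: ", paste(missing, collapse = ", "))
    for (m_name in names(models)) {
      spec <- models[[m_name]]
      n_runs <- if (spec$family == "RF") 1L else split$n_runs
      met <- matrix(NA_real_, n_runs, 3,
                    dimnames = list(NULL, c("Se", "Sp", "Acc")))
      for (r in seq_len(n_runs)) {
        sp <- split_cohort(table, split, run = r)
        sm <- smote
        sm$seed <- derive_seed(split$base_seed, 202, r)
        tr <- smote_augment(sp$train, sm, features = feats)
        mod <- train_model(spec, tr, feats)
        ev <- evaluate_model(mod, sp$test)
        met[r, ] <- c(ev$Se, ev$Sp, ev$Acc)
      }
      key <- paste(m_name, fs_name, sep = " | ")
      runs[[key]] <- met
      summ[[key]] <- data.frame(
        model = m_name, feature_set = fs_name, n_runs = n_runs,
        Se_mean = mean(met[, "Se"], na.rm = TRUE),
        Se_sd = if (n_runs > 1) stats::sd(met[, "Se"], na.rm = TRUE) else NA_real_,
        Se_best = max(met[, "Se"], na.rm = TRUE),
        Sp_mean = mean(met[, "Sp"], na.rm = TRUE),
        Sp_sd = if (n_runs > 1) stats::sd(met[, "Sp"], na.rm = TRUE) else NA_real_,
        Sp_best = max(met[, "Sp"], na.rm = TRUE),
        Acc_mean = mean(met[, "Acc"], na.rm = TRUE),
        Acc_sd = if (n_runs > 1) stats::sd(met[, "Acc"], na.rm = TRUE) else NA_real_,
        Acc_best = max(met[, "Acc"], na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
                 runs = runs, split = split, smote = smote),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Classifier benchmark (", nrow(x$summary), " model x feature-set rows)\n",
      sep = "")
  df <- x$summary
  df[, -(1:3)] <- round(df[, -(1:3)], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
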