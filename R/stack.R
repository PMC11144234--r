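#' Stacking ensemble configuration
#'
#' @param folds Cross-fit folds for the out-of-fold meta features (>= 2).
#' @param seed RNG seed governing fold assignment and every base learner.
#' @param include_latlon Include latitude/longitude as features (off by
#'   default: they index location, not soil quality).
#' @param rf_trees Random-forest tree count.
#' @return An object of class `stack_config`.
#' @export
stack_config <- function(folds = 5, seed = 1, include_latlon = FALSE,
                         rf_trees = 200) {
  if (folds < 2) abort_config("'folds' must be >= 2")
  structure(list(folds = folds, seed = seed, include_latlon = include_latlon,
                 rf_trees = rf_trees), class = "stack_config")
}

soil_numeric_cols <- function(cfg) {
  base <- c("ph", "nitrogen", "organic_carbon", "bulk_density")
  if (cfg$include_latlon) c("latitude", "longitude", base) else base
}

check_soil_table <- function(table, cfg, need_label = TRUE) {
  need <- c(soil_numeric_cols(cfg), "soil_group", if (need_label) "label")
  miss <- setdiff(need, names(table))
  if (length(miss))
    abort_input(sprintf("soil table is missing columns: %s",
                        paste(miss, collapse = ", ")))
  if (anyNA(table[need]))
    abort_input("soil table contains missing values; clean before fitting")
  if (any(table$ph < 0 | table$ph > 14)) abort_input("pH outside [0, 14]")
  invisible(need)
}

# Design matrix: standardized numerics + one-hot soil group (training
# vocabulary; unseen levels map to the all-zero row and are flagged).
soil_design <- function(table, prep) {
  X <- as.matrix(table[prep$num_cols])
  X <- sweep(sweep(X, 2, prep$center, "-"), 2, prep$scale, "/")
  g <- as.character(table$soil_group)
  unknown <- !(g %in% prep$levels)
  oh <- matrix(0, nrow(table), length(prep$levels),
               dimnames = list(NULL, paste0("soil_", prep$levels)))
  for (lv in prep$levels) oh[g == lv, paste0("soil_", lv)] <- 1
  list(X = cbind(X, oh), unknown = unknown)
}

# Aliased (rank-deficient) coefficients from glm.fit come back NA; treat
# them as 0 so the full one-hot encoding stays usable.
glm_coefs <- function(fit) { cf <- fit$coefficients; cf[is.na(cf)] <- 0; cf }

base_learner_specs <- function(cfg) {
  list(
    logistic = list(
      fit = function(X, y) glm_coefs(suppressWarnings(
        stats::glm.fit(cbind(1, X), y, family = stats::binomial()))),
      prob = function(fit, X) as.numeric(sigmoid(cbind(1, X) %*% fit))),
    svm = list(
      fit = function(X, y) {
        m <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                        scale = FALSE)
        dv <- attr(stats::predict(m, X, decision.values = TRUE),
                   "decision.values")[, 1]
        # deterministic Platt scaling on the training decision values
        platt <- glm_coefs(suppressWarnings(
          stats::glm.fit(cbind(1, dv), y, family = stats::binomial())))
        list(svm = m, platt = platt)
      },
      prob = function(fit, X) {
        dv <- attr(stats::predict(fit$svm, X, decision.values = TRUE),
                   "decision.values")[, 1]
        as.numeric(sigmoid(fit$platt[1] + fit$platt[2] * dv))
      }),
    tree = list(
      fit = function(X, y) rpart::rpart(y ~ ., data = data.frame(y = factor(y), X),
                                        method = "class"),
      prob = function(fit, X) stats::predict(fit, data.frame(X))[, "1"]),
    forest = list(
      fit = function(X, y) randomForest::randomForest(X, factor(y, levels = c(0, 1))),
      prob = function(fit, X) stats::predict(fit, X, type = "prob")[, "1"]),
    bayes = list(
      fit = function(X, y) e1071::naiveBayes(data.frame(X), factor(y, levels = c(0, 1))),
      prob = function(fit, X) stats::predict(fit, data.frame(X), type = "raw")[, "1"])
  )
}

#' Fit a stacking ensemble for regrowth possibility
#'
#' Five base learners (logistic regression, radial SVM, decision tree,
#' random forest, naive Bayes) are cross-fit on seeded stratified folds; a
#' logistic-regression generalizer (meta-model) is then fit on the
#' out-of-fold probability features only, so no base prediction used for
#' meta training ever saw its own label. Base learners are finally refit on
#' the full table for prediction. Numeric features are standardized and the
#' soil group one-hot encoded.
#'
#' @param table Soil table (data frame) with a binary `label` column.
#' @param cfg A `stack_config`.
#' @return An object of class `stack_model`.
#' @export
fit_stack <- function(table, cfg = stack_config()) {
  check_soil_table(table, cfg)
  y <- as.integer(table$label)
  if (length(unique(y)) < 2) abort_input("both classes must be present")
  n <- nrow(table)
  if (n < 10 * cfg$folds)
    abort_input(sprintf("need at least %d rows for %d folds", 10 * cfg$folds, cfg$folds))
  set.seed(cfg$seed)
  num_cols <- soil_numeric_cols(cfg)
  prep <- list(num_cols = num_cols,
               center = colMeans(as.matrix(table[num_cols])),
               scale = apply(as.matrix(table[num_cols]), 2, stats::sd),
               levels = sort(unique(as.character(table$soil_group))))
  prep$scale[prep$scale == 0] <- 1
  des <- soil_design(table, prep)

  # stratified fold assignment
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(cfg$folds), length(idx)))
  }

  specs <- base_learner_specs(cfg)
  oof <- matrix(NA_real_, n, length(specs),
                dimnames = list(NULL, names(specs)))
  for (f in seq_len(cfg$folds)) {
    tr <- fold != f; te <- !tr
    for (s in names(specs)) {
      set.seed(cfg$seed + 1000 * f + match(s, names(specs)))
      fit <- specs[[s]]$fit(des$X[tr, , drop = FALSE], y[tr])
      oof[te, s] <- specs[[s]]$prob(fit, des$X[te, , drop = FALSE])
    }
  }
  meta <- glm_coefs(suppressWarnings(
    stats::glm.fit(cbind(1, oof), y, family = stats::binomial())))
  base_fits <- list()
  for (s in names(specs)) {
    set.seed(cfg$seed + match(s, names(specs)))
    base_fits[[s]] <- specs[[s]]$fit(des$X, y)
  }
  structure(list(base = base_fits, meta = meta, prep = prep,
                 cfg = cfg, oof = oof, y = y),
            class = "stack_model")
}

stack_prob <- function(model, X) {
  specs <- base_learner_specs(model$cfg)
  feats <- vapply(names(specs),
                  function(s) specs[[s]]$prob(model$base[[s]], X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) feats <- matrix(feats, 1)
  as.numeric(sigmoid(cbind(1, feats) %*% model$meta))
}

#' Predict regrowth possibility for soil records
#'
#' @param model A fitted `stack_model`.
#' @param records Data frame of soil records (label column not required).
#' @return Data frame with columns `label` (`"possible"`/`"not possible"`),
#'   `probability` (of regrowth), and `unknown_soil_group` flagging records
#'   whose soil group was outside the training vocabulary (still predicted,
#'   via the zero-encoded group).
#' @export
predict_regrowth <- function(model, records) {
  check_soil_table(records, model$cfg, need_label = FALSE)
  des <- soil_design(records, model$prep)
  p <- stack_prob(model, des$X)
  data.frame(label = ifelse(p >= 0.5, "possible", "not possible"),
             probability = p, unknown_soil_group = des$unknown,
             stringsAsFactors = FALSE)
}

#' Classifier performance metrics
#'
#' Standard precision, recall, F1 = 2PR/(P+R), and accuracy for binary
#' labels. Zero-division cases return 0 with a warning.
#'
#' @param y_true,y_pred Binary vectors (0/1 or logical) of equal length.
#' @return Named list: precision, recall, f1, accuracy.
#' @export
evaluate_classifier <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort_input("lengths differ")
  m <- change_metrics(as.logical(y_true), as.logical(y_pred))
  m[c("precision", "recall", "f1", "accuracy")]
}

#' Held-out evaluation of the stack against its base learners
#'
#' Fits the stack on a training split and reports held-out accuracy of the
#' ensemble and of each base learner refit on the same split.
#'
#' @param table Labelled soil table.
#' @param cfg A `stack_config`.
#' @param holdout Fraction held out (seeded split).
#' @return List: `stack_accuracy`, `base_accuracy` (named), `model`, plus
#'   the held-out indices.
#' @export
stack_holdout_eval <- function(table, cfg = stack_config(), holdout = 0.25) {
  set.seed(cfg$seed)
  n <- nrow(table)
  te <- sort(sample.int(n, round(holdout * n)))
  tr_tab <- table[-te, , drop = FALSE]
  te_tab <- table[te, , drop = FALSE]
  model <- fit_stack(tr_tab, cfg)
  pred <- predict_regrowth(model, te_tab)
  yte <- as.integer(te_tab$label)
  stack_acc <- mean((pred$probability >= 0.5) == (yte == 1))
  des_tr <- soil_design(tr_tab, model$prep)
  des_te <- soil_design(te_tab, model$prep)
  specs <- base_learner_specs(cfg)
  base_acc <- vapply(names(specs), function(s) {
    set.seed(cfg$seed + match(s, names(specs)))
    fit <- specs[[s]]$fit(des_tr$X, as.integer(tr_tab$label))
    mean((specs[[s]]$prob(fit, des_te$X) >= 0.5) == (yte == 1))
  }, numeric(1))
  list(stack_accuracy = stack_acc, base_accuracy = base_acc, model = model,
       holdout_index = te)
}

#' Save / load a stacking model
#'
#' The archive is a directory holding a JSON manifest describing the
#' configuration plus the fitted model serialized with [saveRDS()] (the
#' tree/forest base learners have no practical plain-text form).
#'
#' @param model A `stack_model`.
#' @param dir Destination directory.
#' @export
save_stack <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(folds = model$cfg$folds, seed = model$cfg$seed,
                            include_latlon = model$cfg$include_latlon,
                            levels = model$prep$levels),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_stack
#' @export
load_stack <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) abort_format(sprintf("no stack model at %s", dir))
  readRDS(f)
}
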