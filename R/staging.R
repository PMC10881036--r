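#' Build the channel-by-frequency feature table
#'
#' Flattens each epoch's 15 x 145 dB spectrum into 2175 features (channel-
#' major: `ch01_f001 ... ch15_f145`) with `fly_id`, `label`, and epoch
#' start clock attached. Epoch order is preserved fly by fly.
#'
#' @param spectra list of `spectral_matrix` (one per fly) or a single one.
#' @param meta optional data.frame of extra per-epoch columns (row-bound in
#'   the same order).
#' @return data.frame with metadata columns first, then 2175 features.
#' @export
build_feature_table <- function(spectra, meta = NULL) {
  if (inherits(spectra, "spectral_matrix")) spectra <- list(spectra)
  grid <- feature_freq_grid()
  blocks <- list()
  for (sm in spectra) {
    if (length(sm$freq_grid) != length(grid) ||
        max(abs(sm$freq_grid - grid)) > 1e-9) {
      stop("frequency grid mismatch across flies")
    }
    dims <- dim(sm$power_db)
    # epochs x channels x freqs, flattened channel-major (within a channel,
    # the 145 frequency bins are contiguous)
    feat <- matrix(aperm(sm$power_db, c(1, 3, 2)), nrow = dims[1])
    df <- as.data.frame(feat)
    names(df) <- feature_names(dims[2], dims[3])
    df <- cbind(data.frame(fly_id = sm$fly_id, label = sm$label,
                           clock_s = sm$start_s), df)
    blocks[[length(blocks) + 1]] <- df
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (!is.null(meta)) out <- cbind(out[, 1:3], meta, out[, -(1:3)])
  if (anyNA(out[, feature_cols(out)])) {
    stop("feature table contains missing values")
  }
  out
}

feature_names <- function(n_ch, n_f) {
  as.vector(vapply(seq_len(n_ch), function(ch) {
    sprintf("ch%02d_f%03d", ch, seq_len(n_f))
  }, character(n_f)))
}

feature_cols <- function(table) grep("^ch[0-9]+_f[0-9]+$", names(table))

#' Classifier performance metrics
#'
#' Precision (TP/(TP+FP)), recall (TP/(TP+FN)), and F1 (harmonic mean) per
#' class, overall accuracy, ROC AUC (binary from scores; macro one-vs-rest
#' for multiclass), and the row-normalized confusion matrix.
#'
#' @param y_true,y_pred factors or characters of equal length.
#' @param scores optional: for binary problems a numeric vector of scores
#'   for the second class level; for multiclass a matrix of per-class
#'   probabilities (columns named by class).
#' @return a `classifier_report` list.
#' @export
classifier_metrics <- function(y_true, y_pred, scores = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- sort(unique(as.character(y_true)))
  y_pred <- as.character(y_pred)
  if (!all(y_pred %in% lev)) stop("prediction contains unseen label")
  y_true <- as.character(y_true)
  per_class <- t(vapply(lev, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    c(precision = precision, recall = recall, f1 = f1)
  }, numeric(3)))
  cm <- table(factor(y_true, lev), factor(y_pred, lev))
  cm_norm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.matrix(scores) || is.data.frame(scores)) {
      aucs <- vapply(lev, function(cl) {
        binary_auc(as.integer(y_true == cl), as.numeric(scores[, cl]))
      }, numeric(1))
      auc <- mean(aucs)
    } else if (length(lev) == 2) {
      auc <- binary_auc(as.integer(y_true == lev[2]), scores)
    }
  }
  out <- list(per_class = per_class, accuracy = mean(y_true == y_pred),
              roc_auc = auc, confusion = as.matrix(cm_norm), classes = lev)
  class(out) <- "classifier_report"
  out
}

## Rank-based AUC (equivalent to the Mann-Whitney statistic).
binary_auc <- function(y, s) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Seeded stratified 80/20 (or other fraction) split.
stratified_split <- function(y, train_frac = 0.8) {
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- max(1, round(length(idx) * (1 - train_frac)))
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

## Random downsampling of every class to the minority count.
downsample_balance <- function(idx, y) {
  n_min <- min(table(y[idx]))
  unlist(lapply(split(idx, y[idx]), function(i) {
    if (length(i) > n_min) sample(i, n_min) else i
  }), use.names = FALSE)
}

fit_scaler <- function(X) {
  list(center = colMeans(X), scale = pmax(apply(X, 2, stats::sd), 1e-12))
}
apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")
}

#' SMOTE oversampling
#'
#' Balances classes by synthesizing minority-class rows as random convex
#' combinations of a row and one of its k nearest within-class neighbors.
#'
#' @param X numeric matrix of features.
#' @param y class labels.
#' @param k neighborhood size.
#' @return list with balanced `X` and `y` (original rows first).
#' @export
smote_balance <- function(X, y, k = 5) {
  y <- as.character(y)
  tab <- table(y)
  n_max <- max(tab)
  add_X <- list(); add_y <- character(0)
  for (cl in names(tab)) {
    need <- n_max - tab[[cl]]
    if (need == 0) next
    Xi <- X[y == cl, , drop = FALSE]
    if (nrow(Xi) < 2) stop("class '", cl, "' too small for SMOTE")
    kk <- min(k, nrow(Xi) - 1)
    D <- as.matrix(stats::dist(Xi))
    diag(D) <- Inf
    nn <- t(apply(D, 1, function(r) order(r)[seq_len(kk)]))
    base <- sample.int(nrow(Xi), need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(kk, need, replace = TRUE))]
    u <- stats::runif(need)
    add_X[[length(add_X) + 1]] <-
      Xi[base, , drop = FALSE] + u * (Xi[pick, , drop = FALSE] -
                                        Xi[base, , drop = FALSE])
    add_y <- c(add_y, rep(cl, need))
  }
  if (length(add_X)) {
    X <- rbind(X, do.call(rbind, add_X))
    y <- c(y, add_y)
  }
  list(X = X, y = y)
}

#' Train the linear-SVM probability stager
#'
#' The two training classes (awake and midsleep by default) are balanced
#' by random downsampling, split 80/20 stratified, standardized on the
#' training rows only, and fit with a linear-kernel SVM with Platt-style
#' calibrated class probabilities. The whole recipe is repeated for five
#' independently seeded splits.
#'
#' @param table feature table from [build_feature_table()].
#' @param train_classes the two labels used for training.
#' @param seed base seed; iterations use `seed + 0..(n_iterations-1)`.
#' @param n_iterations number of independent split/fit repetitions.
#' @return a `staging_model`: list of per-iteration fits (`model`,
#'   `scaler`, `report`) plus `classes` and `positive` (the class whose
#'   probability is reported, the first of `train_classes`).
#' @export
train_probability_stager <- function(table,
                                     train_classes = c("awake", "midsleep"),
                                     seed = 1, n_iterations = 5) {
  stopifnot(length(train_classes) == 2)
  rows <- which(table$label %in% train_classes)
  if (min(table(table$label[rows])) < 10) {
    stop("a training class has fewer than 10 epochs")
  }
  X <- as.matrix(table[rows, feature_cols(table)])
  y <- factor(table$label[rows], levels = train_classes)
  iterations <- lapply(seq_len(n_iterations) - 1, function(it) {
    with_seed(seed + it, {
      bal <- downsample_balance(seq_along(y), y)
      sp <- stratified_split(y[bal])
      tr <- bal[sp$train]; te <- bal[sp$test]
      sc <- fit_scaler(X[tr, , drop = FALSE])
      fit <- e1071::svm(apply_scaler(X[tr, , drop = FALSE], sc), y[tr],
                        kernel = "linear", probability = TRUE, scale = FALSE)
      pr <- stats::predict(fit, apply_scaler(X[te, , drop = FALSE], sc),
                           probability = TRUE)
      probs <- attr(pr, "probabilities")
      rep <- classifier_metrics(y[te], pr,
                                scores = probs[, levels(y)[2]])
      list(model = fit, scaler = sc, report = rep)
    })
  })
  out <- list(iterations = iterations, classes = train_classes,
              positive = train_classes[1], seed = seed)
  class(out) <- "staging_model"
  out
}

#' Probe unseen epochs with a trained stager
#'
#' Applies each iteration's scaler and model to epochs whose labels were
#' never seen in training and returns the positive-class (awake)
#' probability per probe label and iteration.
#'
#' @param model a `staging_model`.
#' @param table feature table containing the probe epochs.
#' @param probe_labels labels to probe; defaults to every label present.
#' @return data.frame `label`, `iteration`, `mean_prob`, `n`; attribute
#'   `"per_epoch"` holds epoch-level probabilities of iteration 1.
#' @export
probe_unseen_epochs <- function(model, table,
                                probe_labels = unique(table$label)) {
  res <- list(); per_epoch <- NULL
  for (lab in probe_labels) {
    rows <- which(table$label == lab)
    if (!length(rows)) {
      warning("empty probe class: ", lab)
      next
    }
    X <- as.matrix(table[rows, feature_cols(table)])
    for (it in seq_along(model$iterations)) {
      fit <- model$iterations[[it]]
      pr <- stats::predict(fit$model, apply_scaler(X, fit$scaler),
                           probability = TRUE)
      p_pos <- attr(pr, "probabilities")[, model$positive]
      res[[length(res) + 1]] <- data.frame(
        label = lab, iteration = it, mean_prob = mean(p_pos),
        n = length(rows)
      )
      if (it == 1) {
        per_epoch <- rbind(per_epoch,
                           data.frame(label = lab, prob = as.numeric(p_pos)))
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "per_epoch") <- per_epoch
  out
}

#' Train the short- vs long-midsleep stager
#'
#' Midsleep epochs are labeled short (`< split_at` minutes) or long
#' (`>= split_at`) by their bout's midsleep duration, then fed through the
#' same recipe as [train_probability_stager()]. The table must carry a
#' `midsleep_min` column for midsleep rows.
#'
#' @param table feature table with a `midsleep_min` column.
#' @param split_at boundary in minutes (14; epochs at exactly 14 min are
#'   long).
#' @param seed,n_iterations as in [train_probability_stager()].
#' @return a `staging_model` with classes `short`/`long` (positive =
#'   short).
#' @export
train_midsleep_duration_stager <- function(table, split_at = 14, seed = 1,
                                           n_iterations = 5) {
  rows <- which(table$label == "midsleep")
  if (!length(rows)) stop("no midsleep epochs")
  sub <- table[rows, ]
  sub$label <- ifelse(sub$midsleep_min < split_at, "short", "long")
  if (length(unique(sub$label)) < 2) stop("both duration classes required")
  train_probability_stager(sub, train_classes = c("short", "long"),
                           seed = seed, n_iterations = n_iterations)
}

## Small documented hyperparameter grid; searched by out-of-bag error in a
## randomized stage followed by a grid stage around the randomized winner.
rf_grid <- function(n_features) {
  expand.grid(
    num.trees = c(200, 500),
    max.depth = c(0, 10, 20), # 0 = unlimited
    mtry = c(ceiling(sqrt(n_features)), ceiling(0.1 * n_features))
  )
}

tune_rf <- function(X, y, seed, n_random = 4) {
  grid <- rf_grid(ncol(X))
  # ties in OOB error go to the cheaper setting (fewer trees, smaller mtry,
  # shallower), so order the grid by cost up front
  grid <- grid[order(grid$num.trees, grid$mtry, grid$max.depth), ]
  cand <- sort(with_seed(seed, sample(nrow(grid), min(n_random, nrow(grid)))))
  oob <- function(i) {
    fit <- ranger::ranger(x = X, y = y, num.trees = grid$num.trees[i],
                          max.depth = grid$max.depth[i], mtry = grid$mtry[i],
                          seed = seed, num.threads = 1)
    fit$prediction.error
  }
  err_r <- vapply(cand, oob, numeric(1))
  best <- cand[which.min(err_r)]
  # grid stage: all settings sharing a coordinate with the randomized winner
  refine <- which(grid$num.trees == grid$num.trees[best] |
                    grid$max.depth == grid$max.depth[best] |
                    grid$mtry == grid$mtry[best])
  refine <- setdiff(refine, cand)
  err_g <- vapply(refine, oob, numeric(1))
  all_idx <- c(cand, refine); all_err <- c(err_r, err_g)
  ord <- order(all_idx)
  all_idx <- all_idx[ord]; all_err <- all_err[ord]
  grid[all_idx[which.min(all_err)], ]
}

#' Multiclass random-forest stager with permutation importance
#'
#' SMOTE-balances the classes (before the split by default, matching the
#' reference recipe; set `smote_before_split = FALSE` for the leakage-safe
#' variant), splits 80/20 stratified, standardizes on training rows, tunes
#' a random forest over a small randomized-then-grid hyperparameter search
#' (out-of-bag error), and reports per-class metrics, the normalized
#' confusion matrix, and held-out permutation feature importance (score
#' drop when one feature is shuffled; `importance_repeats` repeats per
#' split, averaged over the iterations).
#'
#' @param table feature table.
#' @param classes labels to include.
#' @param seed base seed; iteration i uses `seed + i - 1`.
#' @param n_iterations number of split/fit repetitions (hyperparameters
#'   are tuned once, on the first iteration's training data).
#' @param smote_before_split apply SMOTE to the full table (reference
#'   recipe) or to the training rows only.
#' @param importance compute the permutation-importance map (costly).
#' @param importance_repeats shuffles per feature per iteration.
#' @return an `rf_stager`: list with `reports` (per iteration),
#'   `mean_per_class` (classes x metrics, averaged over iterations),
#'   `confusion` (mean normalized), `importance` (channels x freqs matrix
#'   or NULL), `params`.
#' @export
train_rf_multiclass <- function(table, classes = unique(table$label),
                                seed = 1, n_iterations = 5,
                                smote_before_split = TRUE,
                                importance = TRUE,
                                importance_repeats = 5) {
  rows <- which(table$label %in% classes)
  if (min(table(table$label[rows])) < 6) {
    stop("a class has fewer than 6 epochs (SMOTE neighborhood)")
  }
  X0 <- as.matrix(table[rows, feature_cols(table)])
  y0 <- as.character(table$label[rows])
  n_ch <- length(unique(sub("_f[0-9]+$", "", colnames(X0))))
  n_f <- ncol(X0) / n_ch

  params <- NULL
  reports <- list(); conf <- 0
  imp_sum <- 0; imp_n <- 0
  for (it in seq_len(n_iterations)) {
    it_res <- with_seed(seed + it - 1, {
      if (smote_before_split) {
        sm <- smote_balance(X0, y0)
        X <- sm$X; y <- sm$y
        sp <- stratified_split(y)
        tr <- sp$train; te <- sp$test
      } else {
        sp <- stratified_split(y0)
        sm <- smote_balance(X0[sp$train, , drop = FALSE], y0[sp$train])
        X <- rbind(sm$X, X0[sp$test, , drop = FALSE])
        y <- c(sm$y, y0[sp$test])
        tr <- seq_len(nrow(sm$X)); te <- nrow(sm$X) + seq_along(sp$test)
      }
      sc <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
      Xte <- apply_scaler(X[te, , drop = FALSE], sc)
      ytr <- factor(y[tr]); yte <- factor(y[te], levels = levels(ytr))
      if (is.null(params)) params <- tune_rf(Xtr, ytr, seed)
      fit <- ranger::ranger(x = Xtr, y = ytr,
                            num.trees = params$num.trees,
                            max.depth = params$max.depth, mtry = params$mtry,
                            probability = TRUE, seed = seed + it - 1,
                            num.threads = 1)
      prob <- stats::predict(fit, Xte, num.threads = 1)$predictions
      pred <- colnames(prob)[max.col(prob)]
      rep <- classifier_metrics(as.character(yte), pred, scores = prob)
      rep$n_test <- length(te)
      imp <- if (importance) {
        # the map needs rank structure, not precise values: a stratified
        # subsample of held-out rows keeps the 2175-feature shuffle loop
        # affordable
        sub <- unlist(lapply(split(seq_along(yte), yte), function(i) {
          if (length(i) > 6) sample(i, 6) else i
        }), use.names = FALSE)
        permutation_importance(fit, Xte[sub, , drop = FALSE],
                               as.character(yte)[sub],
                               n_repeats = importance_repeats,
                               seed = seed + 100 + it)
      } else NULL
      list(report = rep, importance = imp)
    })
    reports[[it]] <- it_res$report
    conf <- conf + it_res$report$confusion
    if (!is.null(it_res$importance)) {
      imp_sum <- imp_sum + it_res$importance
      imp_n <- imp_n + 1
    }
  }
  per_class <- Reduce(`+`, lapply(reports, `[[`, "per_class")) / n_iterations
  imp_map <- if (imp_n > 0) {
    matrix(imp_sum / imp_n, nrow = n_ch, byrow = TRUE,
           dimnames = list(paste0("ch", seq_len(n_ch)), NULL))
  } else NULL
  out <- list(reports = reports, mean_per_class = per_class,
              confusion = conf / n_iterations, importance = imp_map,
              params = params, classes = sort(unique(y0)))
  class(out) <- "rf_stager"
  out
}

#' Held-out permutation feature importance
#'
#' Mean drop in model score when a single feature column is shuffled in
#' the held-out rows, over `n_repeats` shuffles. The default score is the
#' mean predicted probability of the true class, a soft scorer that stays
#' informative when hard accuracy saturates at 1 (highly redundant
#' features rarely flip a majority vote, so an accuracy drop would be
#' identically zero); `score = "accuracy"` uses the hard score.
#' Predictions for shuffled copies are batched in feature chunks for
#' speed.
#'
#' @param fit a fitted `ranger` probability forest.
#' @param X held-out feature matrix (already scaled as at fit time).
#' @param y held-out labels.
#' @param n_repeats shuffles per feature.
#' @param seed RNG seed.
#' @param chunk features per prediction batch.
#' @param score `"true_class_prob"` or `"accuracy"`.
#' @return numeric vector of importances, one per feature column.
#' @export
permutation_importance <- function(fit, X, y, n_repeats = 5, seed = 1,
                                   chunk = 300,
                                   score = c("true_class_prob", "accuracy")) {
  score <- match.arg(score)
  n <- nrow(X); p <- ncol(X)
  scorer <- function(prob, yy) {
    if (score == "accuracy") {
      mean(colnames(prob)[max.col(prob)] == yy)
    } else {
      mean(prob[cbind(seq_along(yy), match(yy, colnames(prob)))])
    }
  }
  base_prob <- stats::predict(fit, X, num.threads = 1)$predictions
  base_score <- scorer(base_prob, y)
  drop_sum <- numeric(p)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      perm <- sample.int(n)
      for (c0 in seq(1, p, by = chunk)) {
        cols <- c0:min(c0 + chunk - 1, p)
        big <- X[rep(seq_len(n), length(cols)), , drop = FALSE]
        for (j in seq_along(cols)) {
          rows_j <- (j - 1) * n + seq_len(n)
          big[rows_j, cols[j]] <- X[perm, cols[j]]
        }
        prob <- stats::predict(fit, big, num.threads = 1)$predictions
        scores <- vapply(seq_along(cols), function(j) {
          scorer(prob[(j - 1) * n + seq_len(n), , drop = FALSE], y)
        }, numeric(1))
        drop_sum[cols] <- drop_sum[cols] + (base_score - scores)
      }
    }
  })
  drop_sum / n_repeats
}
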