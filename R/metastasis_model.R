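#' Stratified train/test split of a bulk cohort
#'
#' Splits samples into train and test sets, stratified by the binary
#' metastasis label so both splits keep the cohort's class ratio (within one
#' sample per class).
#'
#' @param labels Character/factor vector of binary labels (e.g. NM/M),
#'   optionally named by sample.
#' @param train_frac Training fraction (default 0.8).
#' @param seed RNG seed.
#' @return Data.frame: sample, label, split ("train"/"test").
#' @export
split_cohort <- function(labels, train_frac = 0.8, seed = 1L) {
  lv <- unique(as.character(labels))
  if (length(lv) < 2) stop("cohort contains a single class")
  if (length(labels) < 10) stop("need at least 10 samples")
  ids <- names(labels) %||% as.character(seq_along(labels))
  split <- rep("test", length(labels))
  with_seed(seed, {
    for (l in lv) {
      idx <- which(labels == l)
      n_tr <- round(train_frac * length(idx))
      split[sample(idx, n_tr)] <- "train"
    }
  })
  data.frame(sample = ids, label = as.character(labels), split = split,
             stringsAsFactors = FALSE)
}

#' Empirical AUC (Mann-Whitney with tie correction)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counting one half: `U / (n1 * n0)` from midranks.
#'
#' @param scores Numeric predictions.
#' @param labels Binary labels; `positive` marks the positive class.
#' @param positive Positive class value (default the second sorted level).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("labels must contain exactly two classes")
  positive <- positive %||% lv[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Model Score: CV/test concordance-penalized performance
#'
#' `(cv + test) / 2 - lam * |cv - test|`. Rewards models whose
#' cross-validated and held-out AUCs are both high and close, penalizing the
#' optimism gap that flags overfitting; `lam = 0.8` is the reference weight.
#'
#' @param cv_auc,test_auc AUCs in \[0, 1\].
#' @param lam Divergence penalty weight (default 0.8).
#' @return The score (at most `max(cv_auc, test_auc)`).
#' @export
model_score <- function(cv_auc, test_auc, lam = 0.8) {
  if (any(c(cv_auc, test_auc) < 0 | c(cv_auc, test_auc) > 1))
    stop("AUC values must lie in [0, 1]")
  (cv_auc + test_auc) / 2 - lam * abs(cv_auc - test_auc)
}

#' Rank model evaluations by Model Score
#'
#' Descending Model Score; ties broken by higher test AUC, then model id.
#'
#' @param evals Data.frame with columns `model`, `cv_auc`, `test_auc`
#'   (and optionally `model_score`, recomputed if absent).
#' @param lam Passed to [model_score()].
#' @return The reordered data.frame with a `model_score` column.
#' @export
rank_models <- function(evals, lam = 0.8) {
  stopifnot(nrow(evals) >= 1)
  evals$model_score <- model_score(evals$cv_auc, evals$test_auc, lam)
  evals[order(-evals$model_score, -evals$test_auc, evals$model), ,
        drop = FALSE]
}

# ---- feature selection -------------------------------------------------

selector_lasso <- function(X, y, seed) {
  with_seed(seed, {
    fit <- glmnet::cv.glmnet(t(X), factor(y), family = "binomial",
                             nfolds = 5)
    co <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
    names(co)[co != 0]
  })
}

selector_forest <- function(X, y, seed, top_n = 35) {
  with_seed(seed, {
    df <- data.frame(t(X), y = factor(y), check.names = FALSE)
    fit <- ranger::ranger(y ~ ., data = df, num.trees = 500,
                          importance = "impurity",
                          seed = substream(seed, 7L))
    imp <- sort(fit$variable.importance, decreasing = TRUE)
    names(imp)[seq_len(min(top_n, length(imp)))]
  })
}

selector_auc <- function(X, y, seed, top_n = 35) {
  a <- apply(X, 1, function(x) abs(auc(x, y) - 0.5))
  names(sort(a, decreasing = TRUE))[seq_len(min(top_n, nrow(X)))]
}

#' Intersect feature selectors on a training cohort
#'
#' Runs each registered selector on the training expression/label pair and
#' keeps genes chosen by at least `min_selectors` of them — the
#' high-confidence candidate set for model training. Built-in selectors:
#' `lasso` (L1-penalized logistic path at the CV-optimal penalty),
#' `forest` (impurity importance of a random forest, top 35) and
#' `auc` (univariate rank-AUC filter, top 35).
#'
#' @param X Genes x samples training expression matrix (rownames = genes).
#' @param y Binary training labels.
#' @param selectors Character subset of the built-ins, or a named list of
#'   functions `f(X, y, seed)` returning gene ids.
#' @param min_selectors Minimum selecting methods (default 2).
#' @param seed RNG seed.
#' @return Character vector of selected genes; per-selector picks in
#'   `attr(, "by_selector")`.
#' @export
select_features <- function(X, y, selectors = c("lasso", "forest", "auc"),
                            min_selectors = 2, seed = 1L) {
  if (nrow(X) == 0) stop("empty candidate gene list")
  builtin <- list(lasso = selector_lasso, forest = selector_forest,
                  auc = selector_auc)
  if (is.character(selectors)) selectors <- builtin[selectors]
  if (length(selectors) < 2) stop("need at least 2 selectors")
  picks <- lapply(seq_along(selectors), function(i)
    selectors[[i]](X, y, substream(seed, i)))
  names(picks) <- names(selectors)
  tally <- table(unlist(lapply(picks, unique)))
  out <- names(tally)[tally >= min_selectors]
  attr(out, "by_selector") <- picks
  out
}

# ---- learner registry --------------------------------------------------

# Each learner returns a function(newX) -> numeric risk score.
learner_logistic <- function(X, y, seed) {
  df <- data.frame(t(X), y = as.integer(factor(y)) - 1L, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
  function(newX) {
    nd <- data.frame(t(newX), check.names = FALSE)
    unname(stats::predict(fit, newdata = nd, type = "link"))
  }
}

learner_ridge <- function(X, y, seed) {
  fit <- with_seed(seed,
    glmnet::cv.glmnet(t(X), factor(y), family = "binomial", alpha = 0,
                      nfolds = 5))
  function(newX)
    as.numeric(stats::predict(fit, newx = t(newX), s = "lambda.min"))
}

learner_forest <- function(X, y, seed) {
  df <- data.frame(t(X), y = factor(y), check.names = FALSE)
  fit <- ranger::ranger(y ~ ., data = df, num.trees = 500,
                        probability = TRUE, seed = seed)
  pos <- levels(factor(y))[2]
  function(newX) {
    nd <- data.frame(t(newX), check.names = FALSE)
    stats::predict(fit, data = nd)$predictions[, pos]
  }
}

default_learners <- function() {
  list(logistic = learner_logistic, ridge = learner_ridge,
       forest = learner_forest)
}

cv_auc <- function(X, y, learner, folds = 5, seed = 1L) {
  y <- as.character(y)
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (l in unique(y)) {
      idx <- sample(which(y == l))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    pred <- learner(X[, tr, drop = FALSE], y[tr], substream(seed, 100L + f))
    scores[!tr] <- pred(X[, !tr, drop = FALSE])
  }
  auc(scores, y)
}

#' Train, evaluate and rank candidate models
#'
#' For each learner in the registry: stratified 5-fold CV AUC on the
#' training split, test AUC on the held-out split, and the Model Score
#' combining the two. Returns the ranked evaluation table with the fitted
#' scorer of every learner attached.
#'
#' @param X Genes x samples expression matrix.
#' @param labels Binary labels aligned with columns.
#' @param split "train"/"test" assignment aligned with columns (e.g. from
#'   [split_cohort()]).
#' @param learners Named list of learner factories
#'   `f(X, y, seed) -> function(newX) -> score`; default registry has
#'   `logistic`, `ridge`, `forest`.
#' @param lam Model Score penalty weight.
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @return Ranked data.frame (`model`, `cv_auc`, `test_auc`, `model_score`)
#'   with fitted predictors in `attr(, "predictors")`.
#' @export
evaluate_models <- function(X, labels, split, learners = default_learners(),
                            lam = 0.8, folds = 5, seed = 1L) {
  stopifnot(ncol(X) == length(labels), length(split) == length(labels))
  tr <- split == "train"
  Xtr <- X[, tr, drop = FALSE]; ytr <- labels[tr]
  Xte <- X[, !tr, drop = FALSE]; yte <- labels[!tr]
  preds <- list()
  evals <- do.call(rbind, lapply(names(learners), function(nm) {
    cv <- cv_auc(Xtr, ytr, learners[[nm]], folds = folds,
                 seed = substream(seed, match(nm, names(learners))))
    fitted <- learners[[nm]](Xtr, ytr,
                             substream(seed, 50L + match(nm, names(learners))))
    preds[[nm]] <<- fitted
    te <- auc(fitted(Xte), yte)
    data.frame(model = nm, cv_auc = cv, test_auc = te,
               stringsAsFactors = FALSE)
  }))
  out <- rank_models(evals, lam = lam)
  attr(out, "predictors") <- preds
  out
}

#' Fit the logistic score model behind MPS/GMPS
#'
#' Maximum-likelihood logistic regression of the metastasis label on the
#' selected genes. If the fit shows separation (non-finite or exploding
#' coefficients), a lightly penalized ridge fit replaces it and the fallback
#' is recorded in the result.
#'
#' @param X Genes x samples training expression (rownames = genes).
#' @param y Binary labels.
#' @param genes Selected gene ids (must be rows of `X`).
#' @param scope `"cancer"` (MPS) or `"global"` (GMPS); metadata only.
#' @param positive Label value modelled as the event (default `"M"` when
#'   present, else the second sorted level).
#' @return Object of class `score_model`: `genes`, `coef`, `intercept`,
#'   `scope`, `positive`, `ridge_fallback`.
#' @export
fit_score_model <- function(X, y, genes, scope = c("cancer", "global"),
                            positive = NULL) {
  scope <- match.arg(scope)
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0) stop("genes absent from matrix: ",
                                paste(utils::head(missing, 5), collapse = ", "))
  if (length(unique(y)) != 2) stop("need both classes in training data")
  positive <- positive %||%
    (if ("M" %in% y) "M" else sort(unique(as.character(y)))[2])
  y_bin <- as.integer(y == positive)
  Xs <- X[genes, , drop = FALSE]
  df <- data.frame(t(Xs), y = y_bin, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
  co <- stats::coef(fit)
  fallback <- !all(is.finite(co)) || any(abs(co[-1]) > 50)
  if (fallback) {
    rf <- glmnet::glmnet(t(Xs), factor(y_bin), family = "binomial", alpha = 0,
                         lambda = 1e-3)
    co <- c(rf$a0, as.matrix(rf$beta)[, 1])
  }
  if (!all(is.finite(co))) stop("model did not converge even with ridge fallback")
  structure(list(genes = genes, coef = stats::setNames(unname(co[-1]), genes),
                 intercept = unname(co[1]), scope = scope,
                 positive = positive, ridge_fallback = fallback),
            class = "score_model")
}

#' Metastasis prediction score (MPS / GMPS)
#'
#' The fitted linear predictor `b0 + sum(b_i * x_i)` per sample. Genes
#' missing from the expression matrix are imputed at the cohort mean of the
#' model's available genes (a warning reports them); a monotone transform of
#' the fitted probability, so AUCs are unchanged.
#'
#' @param model A [fit_score_model()] object.
#' @param expression Genes x samples matrix.
#' @return Named per-sample score vector.
#' @export
compute_score <- function(model, expression) {
  stopifnot(inherits(model, "score_model"))
  present <- intersect(model$genes, rownames(expression))
  if (length(present) == 0) stop("no model gene present in expression")
  X <- expression[present, , drop = FALSE]
  score <- model$intercept + colSums(model$coef[present] * X)
  absent <- setdiff(model$genes, present)
  if (length(absent) > 0) {
    warning(length(absent), " model gene(s) absent; imputed at cohort mean")
    score <- score + sum(model$coef[absent] * mean(X))
  }
  score
}

#' Median split into High/Low risk
#'
#' Samples with score strictly above the median are High risk; ties at the
#' median (and below) are Low.
#'
#' @param scores Named per-sample numeric vector.
#' @return Data.frame: sample, score, risk.
#' @export
stratify_risk <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples")
  med <- stats::median(scores)
  data.frame(sample = names(scores) %||% as.character(seq_along(scores)),
             score = unname(scores),
             risk = ifelse(scores > med, "High", "Low"),
             stringsAsFactors = FALSE)
}
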