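# Problem-transformation multi-label classifiers (binary relevance, label
# powerset, RAkEL) over a random-forest base learner, RReliefF-style
# multi-label feature ranking, and the single-label (binary screening) mode.
#
# Every member model is fitted with the base-spec seed, so the RAkEL
# reductions (k = |L|, m = 1 -> LP; k = 1 with full coverage -> BR) hold
# exactly, score matrix for score matrix, at fixed seeds.

#' Base learner specification
#'
#' @param n_trees number of trees in the random forest (default 100).
#' @param mtry features sampled per split; `NULL` uses the ranger default
#'   (floor of sqrt(p)).
#' @param seed RNG seed for every member fit.
#' @return Object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(n_trees = 100, mtry = NULL, seed = 1) {
  stopifnot(n_trees >= 1)
  structure(list(kind = "random_forest", n_trees = as.integer(n_trees),
                 mtry = mtry, seed = as.integer(seed)),
            class = "base_learner_spec")
}

# Fit one probability classifier; degenerates to a constant scorer when the
# training response has a single class.
fit_base <- function(X, y, spec) {
  y <- droplevels(as.factor(y))
  lv <- levels(y)
  if (length(lv) < 2L) {
    warning("single-class training response; using constant scorer")
    return(list(type = "constant", levels = lv))
  }
  df <- as.data.frame(X)
  colnames(df) <- paste0("f", seq_len(ncol(df)))  # ranger-safe names
  fit <- ranger::ranger(
    x = df, y = y, probability = TRUE,
    num.trees = spec$n_trees,
    mtry = if (is.null(spec$mtry)) NULL else min(spec$mtry, ncol(df)),
    seed = spec$seed, num.threads = 1)
  list(type = "ranger", fit = fit, levels = lv)
}

predict_base <- function(model, X) {
  n <- nrow(X)
  if (model$type == "constant") {
    p <- matrix(1, n, 1, dimnames = list(NULL, model$levels))
    return(p)
  }
  df <- as.data.frame(X)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  p <- predict(model$fit, df, num.threads = 1)$predictions
  if (is.null(dim(p))) p <- matrix(p, nrow = n)
  p[, model$levels, drop = FALSE]
}

# Label powerset core shared by LP and the RAkEL members: multiclass over
# the labelset strings observed in training.
fit_powerset <- function(features, labels, base_spec) {
  keys <- apply(labels, 1, paste, collapse = "")
  classes <- sort(unique(keys))
  labelset <- do.call(rbind, lapply(strsplit(classes, ""), as.integer))
  colnames(labelset) <- colnames(labels)
  if (length(classes) < 2L) {
    warning("single distinct labelset; using constant scorer")
    member <- list(type = "constant", levels = classes)
  } else {
    member <- fit_base(features, factor(keys, levels = classes), base_spec)
  }
  list(member = member, classes = classes, labelset = labelset)
}

predict_powerset <- function(ps, features) {
  probs <- predict_base(ps$member, features)     # n x observed classes
  full <- matrix(0, nrow(features), length(ps$classes),
                 dimnames = list(NULL, ps$classes))
  full[, colnames(probs)] <- probs
  # marginal score per label: total probability of labelsets containing it
  full %*% ps$labelset
}

new_multilabel_model <- function(transformation, members, feature_names,
                                 label_names, base_spec, k = NULL, m = NULL,
                                 subsets = NULL, bins = NULL) {
  structure(list(transformation = transformation, members = members,
                 feature_names = feature_names, label_names = label_names,
                 base_spec = base_spec, k = k, m = m, subsets = subsets,
                 bins = bins),
            class = "multilabel_model")
}

#' @export
print.multilabel_model <- function(x, ...) {
  cat(sprintf("multilabel_model (%s): %d member(s), %d features, %d labels\n",
              x$transformation, length(x$members),
              length(x$feature_names), length(x$label_names)))
  invisible(x)
}

#' Fit a binary-relevance multi-label model
#'
#' One probabilistic binary classifier per label; the score for a label is
#' its member's positive-class probability. A label column with a single
#' observed class yields a constant scorer at that class's indicator.
#'
#' @param features matrix of neighborhood profiles (\{0,1,2,3\}).
#' @param labels binary label matrix, same rows.
#' @param base_spec a [base_learner_spec()].
#' @return A `multilabel_model` with `|L|` members.
#' @export
fit_br <- function(features, labels, base_spec = base_learner_spec()) {
  check_training(features, labels)
  members <- lapply(colnames(labels), function(l) {
    fit_powerset(features, labels[, l, drop = FALSE], base_spec)
  })
  names(members) <- colnames(labels)
  new_multilabel_model("BR", members, colnames(features), colnames(labels),
                       base_spec)
}

#' Fit a label-powerset multi-label model
#'
#' One multiclass classifier over the distinct labelsets observed in
#' training; the score for a label is the summed probability of the classes
#' whose labelset contains it.
#'
#' @inheritParams fit_br
#' @return A `multilabel_model` with a single member.
#' @export
fit_lp <- function(features, labels, base_spec = base_learner_spec()) {
  check_training(features, labels)
  members <- list(fit_powerset(features, labels, base_spec))
  new_multilabel_model("LP", members, colnames(features), colnames(labels),
                       base_spec)
}

#' Fit a RAkEL ensemble
#'
#' `m` distinct random label subsets of size `k` are drawn without
#' replacement (seeded); each member is a label-powerset model restricted to
#' its subset. The score for a label is the mean marginal score over the
#' members covering it; a label covered by no member scores 0 (with a
#' warning at fit time).
#'
#' @inheritParams fit_br
#' @param k label subset size (default 3).
#' @param m number of members; default `min(2|L|, choose(|L|, k))`.
#' @param seed seed for subset sampling (default: the base-spec seed).
#' @return A `multilabel_model` with `m` members.
#' @export
fit_rakel <- function(features, labels, base_spec = base_learner_spec(),
                      k = 3, m = NULL, seed = base_spec$seed) {
  check_training(features, labels)
  L <- ncol(labels)
  stopifnot(k >= 1, k <= L)
  n_subsets <- choose(L, k)
  if (is.null(m)) m <- min(2 * L, n_subsets)
  if (m > n_subsets) {
    stop(sprintf("m = %d exceeds the %d distinct %d-subsets of %d labels",
                 m, n_subsets, k, L))
  }
  set.seed(seed)
  subsets <- list()
  seen <- character(0)
  while (length(subsets) < m) {
    s <- sort(sample.int(L, k))
    key <- paste(s, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      subsets[[length(subsets) + 1L]] <- s
    }
  }
  covered <- sort(unique(unlist(subsets)))
  if (length(covered) < L) {
    warning("label(s) not covered by any RAkEL subset (score fixed at 0): ",
            paste(colnames(labels)[setdiff(seq_len(L), covered)],
                  collapse = ", "))
  }
  members <- lapply(subsets, function(s) {
    fit_powerset(features, labels[, s, drop = FALSE], base_spec)
  })
  new_multilabel_model("RAkEL", members, colnames(features), colnames(labels),
                       base_spec, k = k, m = m, subsets = subsets)
}

#' Fit a multi-label model by transformation name
#'
#' @inheritParams fit_rakel
#' @param transformation `"br"`, `"lp"` or `"rakel"`.
#' @return A `multilabel_model`.
#' @export
fit_multilabel <- function(features, labels,
                           transformation = c("rakel", "br", "lp"),
                           base_spec = base_learner_spec(), k = 3, m = NULL) {
  transformation <- match.arg(transformation)
  switch(transformation,
         br = fit_br(features, labels, base_spec),
         lp = fit_lp(features, labels, base_spec),
         rakel = fit_rakel(features, labels, base_spec, k = k, m = m))
}

check_training <- function(features, labels) {
  stopifnot(is.matrix(features), is.matrix(labels),
            nrow(features) == nrow(labels), nrow(features) >= 1,
            !is.null(colnames(labels)))
  if (length(features) && !all(features %in% 0:3)) {
    stop("feature values must be in {0,1,2,3}")
  }
  invisible(TRUE)
}

#' Predict label scores from a fitted multi-label model
#'
#' @param object a `multilabel_model`.
#' @param features profile matrix whose columns equal the model's feature
#'   registry (use [align_features()] first for raw profiles).
#' @param ... unused.
#' @return Matrix instances x labels with scores in `[0, 1]`, rows aligned
#'   to the input order.
#' @export
predict.multilabel_model <- function(object, features, ...) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  if (!identical(colnames(features), object$feature_names)) {
    stop("feature registry mismatch; align features to the training registry")
  }
  n <- nrow(features)
  L <- length(object$label_names)
  scores <- matrix(0, n, L, dimnames = list(rownames(features),
                                            object$label_names))
  if (n == 0L) return(scores)
  if (object$transformation == "LP") {
    return(predict_powerset(object$members[[1]], features))
  }
  counts <- numeric(L)
  for (i in seq_along(object$members)) {
    marg <- predict_powerset(object$members[[i]], features)
    idx <- match(colnames(marg), object$label_names)
    scores[, idx] <- scores[, idx] + marg
    counts[idx] <- counts[idx] + 1
  }
  covered <- counts > 0
  scores[, covered] <- sweep(scores[, covered, drop = FALSE], 2,
                             counts[covered], "/")
  scores
}

#' RReliefF-style multi-label feature ranking (RF-ML)
#'
#' For each sampled instance and its `k_nn` nearest neighbors under the
#' Manhattan distance on range-scaled features (values divided by 3), the
#' label dissimilarity `dL` (Hamming distance between label rows divided by
#' `|L|`) and the per-feature value difference `diff_f = |x_if - x_jf| / 3`
#' are accumulated into `N_dY`, `N_dF[f]` and `N_dYdF[f]`. The weight of
#' feature `f` is
#' `W[f] = N_dYdF[f] / N_dY - (N_dF[f] - N_dYdF[f]) / (M - N_dY)`
#' with `M` the total number of accumulated pairs: features whose
#' differences line up with label differences gain weight, features that
#' vary where labels agree lose it.
#'
#' @param features matrix in \{0,1,2,3\}.
#' @param labels binary label matrix.
#' @param k_nn neighbors per sampled instance (default 10; clamped to n-1).
#' @param n_sample number of instances sampled (default: all, in row order).
#' @param seed RNG seed for instance sampling.
#' @return data.frame `feature`, `weight`, sorted by weight descending with
#'   ties broken by feature id.
#' @export
rfml_rank_features <- function(features, labels, k_nn = 10,
                               n_sample = NULL, seed = 1) {
  stopifnot(nrow(features) >= 2, nrow(features) == nrow(labels))
  n <- nrow(features)
  p <- ncol(features)
  L <- ncol(labels)
  k <- min(k_nn, n - 1L)
  if (is.null(n_sample) || n_sample >= n) {
    idx <- seq_len(n)
  } else {
    set.seed(seed)
    idx <- sort(sample.int(n, n_sample))
  }
  Xs <- features / 3
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  dY <- as.matrix(stats::dist(labels, method = "manhattan")) / L
  N_dY <- 0
  N_dF <- numeric(p)
  N_dYdF <- numeric(p)
  M <- 0
  for (i in idx) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(D[i, others])][seq_len(k)]
    for (j in nb) {
      dl <- dY[i, j]
      df <- abs(Xs[i, ] - Xs[j, ])
      N_dY <- N_dY + dl
      N_dF <- N_dF + df
      N_dYdF <- N_dYdF + dl * df
      M <- M + 1
    }
  }
  if (N_dY == 0) {
    warning("all label rows identical among accumulated pairs; weights are 0")
    W <- numeric(p)
  } else {
    miss_term <- if (M - N_dY > 0) (N_dF - N_dYdF) / (M - N_dY) else 0
    W <- N_dYdF / N_dY - miss_term
  }
  out <- data.frame(feature = colnames(features), weight = unname(W),
                    stringsAsFactors = FALSE)
  out[order(-out$weight, out$feature), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Fit the single-label (binary screening) classifier
#'
#' The one-label special case of binary relevance: a probabilistic
#' photosynthetic / non-photosynthetic screen over neighborhood profiles.
#'
#' @param features profile matrix (\{0,1,2,3\}).
#' @param positive logical or 0/1 vector marking positive training rows.
#' @param base_spec a [base_learner_spec()].
#' @return Object of class `binary_mode_model`.
#' @export
binary_mode_fit <- function(features, positive,
                            base_spec = base_learner_spec()) {
  y <- matrix(as.integer(as.logical(positive)), ncol = 1,
              dimnames = list(NULL, "positive"))
  model <- fit_br(features, y, base_spec)
  structure(list(model = model), class = "binary_mode_model")
}

#' Score queries with the binary screening model
#'
#' Reports the positive-class probability and flags high-confidence
#' candidates at the screening threshold (default 0.8, the reporting rule
#' for "more than 80% probability"; use 0.5 for a plain decision rule).
#'
#' @param model a [binary_mode_fit()] result.
#' @param features aligned profile matrix.
#' @param flag_threshold probability above which a query is flagged
#'   (inclusive; default 0.8).
#' @return data.frame `score`, `flagged`.
#' @export
binary_mode_predict <- function(model, features, flag_threshold = 0.8) {
  s <- predict(model$model, features)[, 1]
  data.frame(score = s, flagged = s >= flag_threshold)
}
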