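# Per-lead one-vs-one multi-class RBF-SVM -------------------------------------
#
# Each ECG lead gets its own set of K(K-1)/2 pairwise soft-margin SVMs on the
# (p_st, p_pr) feature plane (ST on x, PR on y).  The quadratic dual of each
# pairwise problem is solved by libsvm (via e1071); this package owns the
# decision function, pairwise voting, and the fusion of per-lead decisions
# ("cross-matching") into the final per-minute label.  Features are mapped
# from percentages to [0, 1] before training so the RBF width sigma_rbf =
# 0.1 is on a sensible relative scale.

FEATURE_SCALE <- 100  # percent -> [0, 1]

#' Gaussian radial basis kernel
#'
#' `K(x, xi) = exp(-||x - xi||^2 / (2 sigma_rbf^2))`, in `(0, 1]`.
#'
#' @param x,xi numeric vectors of equal length.
#' @param sigma_rbf kernel width (> 0); default 0.1 on the `[0, 1]` feature
#'   scale.
#' @return scalar kernel value.
#' @export
rbf_kernel <- function(x, xi, sigma_rbf = 0.1) {
  if (sigma_rbf <= 0) stop("`sigma_rbf` must be > 0")
  exp(-sum((x - xi)^2) / (2 * sigma_rbf^2))
}

feature_matrix <- function(tab) {
  cbind(p_st = tab$p_st, p_pr = tab$p_pr) / FEATURE_SCALE
}

train_binary <- function(X, y, pos, neg, sigma_rbf, gamma_cost) {
  yf <- factor(y, levels = c(pos, neg))
  fit <- e1071::svm(x = X, y = yf, scale = FALSE, kernel = "radial",
                    gamma = 1 / (2 * sigma_rbf^2), cost = gamma_cost,
                    type = "C-classification")
  # libsvm orients the decision value by order of class appearance in the
  # training data: sum(coefs * K) - rho is positive for fit$labels[1]
  ord <- fit$levels[fit$labels]
  list(pos = ord[1], neg = ord[2],
       sv = unname(as.matrix(fit$SV)),
       coefs = as.numeric(fit$coefs),   # alpha_i * y_i
       b = -fit$rho,
       sigma_rbf = sigma_rbf, gamma_cost = gamma_cost)
}

#' Train the per-lead one-vs-one multi-class SVM
#'
#' For every lead present in the feature table, trains one binary RBF-SVM
#' per unordered pair of classes (K classes give K(K-1)/2 models per lead).
#' The trained structure is the scheme's per-lead decision model: the
#' boundaries that map an unknown segment's (p_st, p_pr) pair to a class.
#'
#' @param features a labelled [feature_table()] (no `NA` labels).
#' @param sigma_rbf RBF kernel width on the `[0, 1]` feature scale.
#' @param gamma_cost soft-margin cost (the box constraint on the dual
#'   coefficients).
#' @param seed integer seed (the dual solver is deterministic; the seed is
#'   kept for interface stability and future stochastic extensions).
#' @return an object of class `ischemia_model`.
#' @export
train_model <- function(features, sigma_rbf = 0.1, gamma_cost = 10,
                        seed = 1) {
  features <- feature_table(as.data.frame(features))
  if (any(is.na(features$label)))
    stop("training requires a label on every feature row")
  if (sigma_rbf <= 0) stop("`sigma_rbf` must be > 0")
  leads <- unique(features$lead_name)
  per_lead <- list()
  for (ld in leads) {
    tab <- features[features$lead_name == ld, ]
    classes <- sort(unique(tab$label))
    if (length(classes) < 2)
      stop("lead '", ld, "' has a single class; cannot train")
    cnt <- table(tab$label)
    if (any(cnt < 5))
      stop("lead '", ld, "' has fewer than 5 examples for class(es): ",
           paste(names(cnt)[cnt < 5], collapse = ", "))
    X <- feature_matrix(tab)
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    bins <- lapply(pairs, function(pr) {
      sel <- tab$label %in% pr
      train_binary(X[sel, , drop = FALSE], tab$label[sel],
                   pos = pr[1], neg = pr[2], sigma_rbf, gamma_cost)
    })
    per_lead[[ld]] <- list(classes = classes, binaries = bins)
  }
  structure(list(leads = per_lead, sigma_rbf = sigma_rbf,
                 gamma_cost = gamma_cost, feature_scale = FEATURE_SCALE,
                 seed = seed, version = 1L),
            class = "ischemia_model")
}

#' @export
print.ischemia_model <- function(x, ...) {
  cat(sprintf("<ischemia_model> %d lead(s), sigma_rbf = %g, cost = %g\n",
              length(x$leads), x$sigma_rbf, x$gamma_cost))
  for (ld in names(x$leads))
    cat(sprintf("  %s: classes {%s}, %d pairwise model(s)\n", ld,
                paste(x$leads[[ld]]$classes, collapse = ", "),
                length(x$leads[[ld]]$binaries)))
  invisible(x)
}

#' Decision value of one pairwise SVM
#'
#' `R(x) = sum_i W_i K(x, x_i) + b` over the support vectors, with
#' `W_i = alpha_i y_i`; `sign(R)` votes for the model's positive class.
#'
#' @param model_binary one element of `model$leads[[lead]]$binaries`.
#' @param x numeric feature pair on the `[0, 1]` scale.
#' @return scalar decision value `R`.
#' @export
decision_value <- function(model_binary, x) {
  if (is.null(model_binary$sv) || !length(model_binary$coefs))
    stop("untrained binary model")
  k <- apply(model_binary$sv, 1, function(svi)
    rbf_kernel(x, svi, model_binary$sigma_rbf))
  sum(model_binary$coefs * k) + model_binary$b
}

# one-vs-one vote for a single lead; ties broken by the largest summed
# absolute decision margin
vote_lead <- function(lead_model, x) {
  classes <- lead_model$classes
  votes <- stats::setNames(numeric(length(classes)), classes)
  margin <- stats::setNames(numeric(length(classes)), classes)
  for (bm in lead_model$binaries) {
    r <- decision_value(bm, x)
    winner <- if (r >= 0) bm$pos else bm$neg
    votes[winner] <- votes[winner] + 1
    margin[winner] <- margin[winner] + abs(r)
  }
  best <- which(votes == max(votes))
  if (length(best) > 1) best <- best[which.max(margin[best])]
  list(label = classes[best], votes = votes, margin = margin)
}

#' Classify feature rows and fuse per-lead decisions
#'
#' Every (record, segment) is classified per lead by majority vote over the
#' pairwise SVMs (ties broken by the larger summed `|R|` margin), then the
#' per-lead labels are fused across leads by majority vote with the same
#' margin tie-break -- the multi-lead "cross-matching" step.
#'
#' @param object an `ischemia_model`.
#' @param features a [feature_table()] whose leads are all known to the
#'   model.
#' @param ... unused.
#' @return data.frame with one row per (record_id, segment_index):
#'   fused `label`, `votes` string, plus per-lead labels in `lead_labels`.
#' @export
predict.ischemia_model <- function(object, features, ...) {
  features <- feature_table(as.data.frame(features))
  unknown <- setdiff(unique(features$lead_name), names(object$leads))
  if (length(unknown))
    stop("model has no lead(s) {", paste(unknown, collapse = ", "),
         "}; available: {", paste(names(object$leads), collapse = ", "), "}")
  X <- feature_matrix(features)
  per_row_label <- character(nrow(features))
  per_row_margin <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    v <- vote_lead(object$leads[[features$lead_name[i]]], X[i, ])
    per_row_label[i] <- v$label
    per_row_margin[i] <- max(v$margin)
  }
  key <- paste(features$record_id, features$segment_index, sep = "\r")
  out <- lapply(split(seq_len(nrow(features)), key), function(idx) {
    labs <- per_row_label[idx]
    tal <- tapply(rep(1, length(idx)), labs, sum)
    mar <- tapply(per_row_margin[idx], labs, sum)
    cand <- names(tal)[tal == max(tal)]
    fused <- if (length(cand) == 1) cand else cand[which.max(mar[cand])]
    data.frame(record_id = features$record_id[idx[1]],
               segment_index = features$segment_index[idx[1]],
               label = fused,
               truth = features$label[idx[1]],
               n_leads = length(idx),
               votes = paste(names(tal), tal, sep = ":", collapse = ";"),
               lead_labels = paste(features$lead_name[idx], labs,
                                   sep = "=", collapse = ";"))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$record_id, res$segment_index), ]
  rownames(res) <- NULL
  res
}

#' Classification metrics
#'
#' Multi-class confusion matrix plus binary-style accuracy, sensitivity and
#' specificity, where "positive" pools the non-normal classes (ischemia and
#' infarction).
#'
#' @param predicted,truth equal-length character vectors of class labels.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `confusion`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have the same length")
  lev <- sort(unique(c(predicted, truth)))
  confusion <- table(factor(truth, lev), factor(predicted, lev),
                     dnn = c("truth", "predicted"))
  pos_t <- truth != "normal"; pos_p <- predicted != "normal"
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p); fp <- sum(!pos_t & pos_p)
  list(accuracy = mean(predicted == truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = confusion)
}

#' Record-stratified k-fold cross-validation
#'
#' Records (never individual segments) are assigned to folds, stratified by
#' class label, so segments of one record can never appear in both a
#' training and a test fold.  Deterministic under the seed.
#'
#' @param features a labelled [feature_table()].
#' @param k number of folds.
#' @param seed integer seed for the fold shuffle.
#' @param sigma_rbf,gamma_cost passed to [train_model()].
#' @return list with `fold_assignment` (record -> fold), per-fold metrics in
#'   `folds`, and pooled `metrics` over all held-out segments.
#' @export
kfold_cv <- function(features, k = 10, seed = 1, sigma_rbf = 0.1,
                     gamma_cost = 10) {
  features <- feature_table(as.data.frame(features))
  if (k < 2) stop("`k` must be >= 2")
  recs <- unique(features[, c("record_id", "label")])
  if (nrow(recs) < k)
    stop("fewer records (", nrow(recs), ") than folds (", k, ")")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  fold <- stats::setNames(integer(nrow(recs)), recs$record_id)
  for (cl in unique(recs$label)) {
    ids <- sample(recs$record_id[recs$label == cl])
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  preds <- NULL
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- names(fold)[fold == f]
    tr <- features[!(features$record_id %in% test_ids), ]
    te <- features[features$record_id %in% test_ids, ]
    if (!nrow(te)) next
    mod <- train_model(tr, sigma_rbf = sigma_rbf, gamma_cost = gamma_cost,
                       seed = seed)
    p <- predict(mod, te)
    folds[[f]] <- evaluate_predictions(p$label, p$truth)
    preds <- rbind(preds, p)
  }
  list(fold_assignment = fold, folds = folds,
       metrics = evaluate_predictions(preds$label, preds$truth),
       predictions = preds)
}

#' Serialize / load a trained model as versioned JSON
#'
#' @param model an `ischemia_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `ischemia_model` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ischemia_model"))
  payload <- unclass(model)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (ld in names(m$leads)) {
    bl <- m$leads[[ld]]$binaries
    m$leads[[ld]]$binaries <- lapply(seq_along(bl$pos), function(i)
      list(pos = bl$pos[i], neg = bl$neg[i],
           sv = matrix(unlist(bl$sv[[i]]), ncol = 2,
                       dimnames = list(NULL, c("p_st", "p_pr"))),
           coefs = as.numeric(bl$coefs[[i]]), b = bl$b[i],
           sigma_rbf = bl$sigma_rbf[i], gamma_cost = bl$gamma_cost[i]))
  }
  class(m) <- "ischemia_model"
  m
}
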