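# one-vs-one multi-class RBF-SVM, decision fusion, metrics, CV

test_that("rbf_kernel matches its closed form", {
  expect_identical(rbf_kernel(c(1, 2), c(1, 2), 0.1), 1)
  s <- 0.3
  x <- c(0, 0); xi <- c(sqrt(2) * s, 0)   # ||x - xi||^2 = 2 s^2
  expect_equal(rbf_kernel(x, xi, s), exp(-1), tolerance = 1e-12)
  expect_error(rbf_kernel(c(0, 0), c(1, 1), 0), "sigma_rbf")
})

test_that("separable blobs are fit perfectly; training needs >= 2 classes", {
  ft <- blob_features(classes = c("normal", "ischemia"))
  m <- train_model(ft)
  p <- predict(m, ft)
  expect_identical(evaluate_predictions(p$label, p$truth)$accuracy, 1)

  one <- feature_table(as.data.frame(ft)[ft$label == "normal", ])
  expect_error(train_model(one), "single class")
  expect_error(train_model(ft, sigma_rbf = -1), "sigma_rbf")
})

test_that("K = 3 classes give exactly 3 pairwise models with valid duals", {
  ft <- blob_features(classes = c("normal", "ischemia", "infarction"))
  m <- train_model(ft, gamma_cost = 10)
  expect_length(m$leads[["I"]]$binaries, 3L)
  for (bm in m$leads[["I"]]$binaries) {
    alpha <- abs(bm$coefs)
    expect_true(all(alpha >= 0 & alpha <= 10 + 1e-9))
    expect_lt(abs(sum(bm$coefs)), 1e-6)
  }
})

test_that("duplicating every training point leaves the boundary unchanged", {
  ft <- blob_features(classes = c("normal", "ischemia"))
  dup <- as.data.frame(ft)
  dup2 <- dup; dup2$segment_index <- dup2$segment_index + 1000L
  m1 <- train_model(ft)
  m2 <- train_model(feature_table(rbind(dup, dup2)))
  grid <- feature_table(expand_probe_grid())
  expect_identical(predict(m1, grid)$label, predict(m2, grid)$label)
})

test_that("decision values behave like a kernel expansion", {
  ft <- blob_features(classes = c("normal", "ischemia"))
  m <- train_model(ft)
  bm <- m$leads[["I"]]$binaries[[1]]
  # far from every support vector the kernel vanishes and R -> b
  expect_equal(decision_value(bm, c(50, 50)), bm$b, tolerance = 1e-8)
  # free support vectors (0 < alpha < cost) sit on the margin |R| = 1
  free <- which(abs(bm$coefs) > 1e-6 & abs(bm$coefs) < m$gamma_cost - 1e-6)
  for (i in free) {
    expect_lt(abs(abs(decision_value(bm, bm$sv[i, ])) - 1), 0.05)
  }
  # empirical Lipschitz bound on a probe grid is finite
  g <- as.matrix(expand_probe_grid()[, c("p_st", "p_pr")]) / 100
  r <- apply(g, 1, function(x) decision_value(bm, x))
  d <- sqrt(rowSums((g[-1, ] - g[-nrow(g), ])^2))
  expect_true(all(is.finite(abs(diff(r)) / pmax(d, 1e-12))))
})

test_that("with K = 2 the one-vs-one machine equals a direct binary SVM", {
  ft <- blob_features(classes = c("normal", "ischemia"), sd = 6)
  m <- train_model(ft)
  expect_length(m$leads[["I"]]$binaries, 1L)
  X <- cbind(ft$p_st, ft$p_pr) / 100
  direct <- e1071::svm(x = X, y = factor(ft$label), scale = FALSE,
                       kernel = "radial", gamma = 1 / (2 * 0.1^2), cost = 10,
                       type = "C-classification")
  grid <- expand_probe_grid()
  gX <- as.matrix(grid[, c("p_st", "p_pr")]) / 100
  expect_identical(predict(m, feature_table(grid))$label,
                   unname(as.character(predict(direct, gX))))
})

test_that("lead fusion takes the majority across leads", {
  # hand-built pairwise models with a single support vector each: the
  # decision value at any probe is coef * K + b, so b's sign fixes the vote
  mk_lead <- function(pos_wins) {
    b <- if (pos_wins) 0.5 else -0.5
    list(classes = c("ischemia", "normal"),
         binaries = list(list(pos = "ischemia", neg = "normal",
                              sv = matrix(c(99, 99), 1), coefs = 1e-12,
                              b = b, sigma_rbf = 0.1, gamma_cost = 10)))
  }
  leads <- c("I", "II", "III", "V1", "V2", "V3", "V4")
  model <- structure(
    list(leads = setNames(lapply(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                   FALSE), mk_lead), leads),
         sigma_rbf = 0.1, gamma_cost = 10, feature_scale = 100, seed = 1,
         version = 1L),
    class = "ischemia_model")
  ft <- feature_table(data.frame(
    record_id = "r", segment_index = 0L, lead_name = leads,
    p_st = 10, p_pr = 10, label = NA_character_))
  out <- predict(model, ft)
  expect_identical(nrow(out), 1L)
  expect_identical(out$label, "ischemia")   # 4 ischemia vs 3 normal
  expect_identical(out$n_leads, 7L)

  ft_bad <- feature_table(data.frame(record_id = "r", segment_index = 0L,
                                     lead_name = "V6", p_st = 1, p_pr = 1))
  expect_error(predict(model, ft_bad), "V6")
})

test_that("metrics arithmetic matches the definitions", {
  truth <- c(rep("ischemia", 100), rep("normal", 100))
  pred <- c(rep("ischemia", 99), "normal",
            rep("normal", 98), "ischemia", "ischemia")
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev$sensitivity, 0.99)
  expect_equal(ev$specificity, 0.98)
  expect_equal(ev$accuracy, 0.985)
  expect_identical(sum(ev$confusion), 200L)

  all_right <- evaluate_predictions(truth, truth)
  expect_identical(all_right$accuracy, 1)
  expect_identical(all_right$sensitivity, 1)
  expect_identical(all_right$specificity, 1)
  expect_error(evaluate_predictions("a", c("a", "b")), "length")
})

test_that("permuted predictions on balanced 3-class data sit at chance", {
  set.seed(77)
  truth <- rep(c("normal", "ischemia", "infarction"), each = 400)
  pred <- sample(truth)
  acc <- evaluate_predictions(pred, truth)$accuracy
  ci <- 2.576 * sqrt((1 / 3) * (2 / 3) / length(truth))
  expect_lt(abs(acc - 1 / 3), ci)
})

test_that("k-fold CV partitions records, is deterministic, matches a split", {
  ft <- blob_features(n_per = 100, records_per_class = 50,
                      classes = c("normal", "ischemia"), sd = 8)
  cv1 <- kfold_cv(ft, k = 10, seed = 4)
  cv2 <- kfold_cv(ft, k = 10, seed = 4)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(length(cv1$fold_assignment), 100L)
  expect_true(all(table(cv1$fold_assignment) > 0))
  # every record is held out exactly once
  expect_identical(sort(unique(cv1$predictions$record_id)),
                   sort(unique(ft$record_id)))

  split_ids <- names(cv1$fold_assignment)[cv1$fold_assignment <= 2]
  tr <- feature_table(ft[!(ft$record_id %in% split_ids), ])
  te <- feature_table(ft[ft$record_id %in% split_ids, ])
  p <- predict(train_model(tr), te)
  acc_split <- evaluate_predictions(p$label, p$truth)$accuracy
  expect_lt(abs(cv1$metrics$accuracy - acc_split), 0.02)

  expect_error(kfold_cv(ft, k = 200), "fewer records")
  expect_error(kfold_cv(ft, k = 1), "k")
})

test_that("a model survives the JSON round-trip", {
  ft <- blob_features(classes = c("normal", "ischemia", "infarction"))
  m <- train_model(ft)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model(m, path)
  back <- read_model(path)
  grid <- feature_table(expand_probe_grid())
  expect_identical(predict(back, grid)$label, predict(m, grid)$label)
})
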