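# Splitting, classifiers, evaluation

test_that("stratified split gives 3:1 within every class", {
  y <- rep(mold_levels(), each = 60)
  sp <- stratified_split(y, seed = 3)
  expect_length(sp$calibration, 180)
  expect_length(sp$prediction, 60)
  expect_equal(sort(c(sp$calibration, sp$prediction)), 1:240)
  for (l in mold_levels()) {
    expect_equal(sum(y[sp$calibration] == l), 45)
    expect_equal(sum(y[sp$prediction] == l), 15)
  }
  # single class of 60 -> 45/15
  s1 <- stratified_split(rep("a", 60), seed = 1)
  expect_length(s1$calibration, 45)
  expect_length(s1$prediction, 15)
  # reproducibility
  expect_identical(stratified_split(y, seed = 3)$prediction, sp$prediction)
  expect_false(identical(stratified_split(y, seed = 4)$prediction,
                         sp$prediction))
  expect_error(stratified_split(c("a", "b")), "at least 2")
})

test_that("evaluation produces the fixed-order confusion accounting", {
  lv <- mold_levels()
  truth <- factor(rep(lv, each = 3), levels = lv)
  perfect <- evaluate_predictions(truth, truth, lv)
  expect_equal(unname(diag(perfect$confusion)), rep(3L, 4))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$moldy_as_healthy, 0)
  all_healthy <- evaluate_predictions(factor(rep("healthy", 12), levels = lv),
                                      truth, lv)
  expect_equal(sum(all_healthy$confusion[, 1]), 12)
  expect_equal(all_healthy$moldy_as_healthy, 9)  # column 1 minus row 1
  expect_equal(all_healthy$accuracy, 25)
  expect_error(evaluate_predictions(rep("rotten", 12), truth, lv), "outside")
})

toy_4class <- function(n_per = 20, sd = 0.05, seed = 1) {
  set.seed(seed)
  y <- factor(rep(mold_levels(), each = n_per), levels = mold_levels())
  mu <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  X <- mu[as.integer(y), ] + matrix(rnorm(4 * n_per * 2, 0, sd), ncol = 2)
  list(X = X, y = y)
}

test_that("SVM separates a wide-margin toy problem perfectly", {
  tc <- toy_4class()
  sp <- stratified_split(tc$y, seed = 2)
  rep <- train_svm(tc$X, tc$y, sp, cost_grid = 2^(0:4),
                   gamma_grid = 2^(-2:2), seed = 2)
  expect_equal(rep$calibration_accuracy, 100)
  expect_equal(rep$prediction_accuracy, 100)
  expect_equal(rep$overfitting_gap, 0)
})

test_that("SVM on shuffled labels predicts at chance for 4 classes", {
  tc <- toy_4class(n_per = 30)
  set.seed(44)
  ysh <- sample(tc$y)
  sp <- stratified_split(ysh, seed = 5)
  rep <- train_svm(tc$X, ysh, sp, cost_grid = 2^(0:3), gamma_grid = 2^(-1:1),
                   seed = 5)
  # binomial CI around 25% on 30 held-out samples
  expect_lt(rep$prediction_accuracy, 55)
})

test_that("random forest reports are reproducible under a fixed seed", {
  tc <- toy_4class(sd = 0.4)
  sp <- stratified_split(tc$y, seed = 7)
  r1 <- train_rf(tc$X, tc$y, sp, seed = 7)
  r2 <- train_rf(tc$X, tc$y, sp, seed = 7)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$hyperparameters$n_trees, 50)
  expect_equal(r1$calibration_accuracy, 100)  # trivially fit at n=60
})

test_that("KNN honors k = 1 memorization and the smaller-class tie rule", {
  tc <- toy_4class()
  sp <- stratified_split(tc$y, seed = 9)
  rep <- train_knn(tc$X, tc$y, sp, k_grid = 1, seed = 9)
  expect_equal(rep$calibration_accuracy, 100)
  # duplicated point with conflicting labels: tie goes to smaller class index
  Xtr <- matrix(c(0, 0, 0, 0), 2, 2)
  ytr <- factor(c("mild", "healthy"), levels = mold_levels())
  pred <- maizemold:::knn_predict(Xtr, ytr, matrix(c(0, 0), 1, 2),
                                  k = 2, metric = "euclidean")
  expect_equal(as.character(pred), "healthy")
  expect_error(train_knn(tc$X, tc$y, sp, k_grid = 1000, seed = 1), "larger")
})

test_that("cityblock and euclidean metrics rank neighbours differently", {
  A <- matrix(c(0, 0), 1, 2)
  B <- rbind(c(2.5, 2.5), c(0, 4))
  de <- maizemold:::pairwise_dist(A, B, "euclidean")
  dc <- maizemold:::pairwise_dist(A, B, "cityblock")
  expect_equal(order(de), c(1, 2))  # sqrt(12.5) = 3.54 < 4
  expect_equal(order(dc), c(2, 1))  # 5 > 4: cityblock flips the ranking
  expect_equal(unname(dc[1, ]), c(5, 4))
})
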