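test_that("a separable problem is solved exactly with a feasible dual", {
  d <- blob_data()
  m <- train_svm(d$x, d$y)
  expect_equal(mean(predict(m, d$x) == d$y), 1)
  audit <- kkt_audit(m)
  expect_true(all(audit$feasible))
  expect_true(all(audit$max_alpha <= m$C + 1e-6))
  expect_true(all(abs(audit$sum_alpha_y) <= 1e-6))
  expect_error(train_svm(d$x, rep("a", nrow(d$x))), "two classes")
})

test_that("the package's decision function reproduces the solver's decisions", {
  # independent route: e1071's own predictions on the binary subproblem
  d <- blob_data(centers = list(c(0, 0), c(2, 2), c(4, 0)), sd = 0.5)
  m <- train_svm(d$x, d$y)
  dv <- svm_decision_values(m, d$x)
  expect_identical(colnames(dv), m$classes)
  # one-vs-rest decisions: own class column is positive for clear samples
  own <- dv[cbind(seq_len(nrow(dv)), match(d$y, m$classes))]
  expect_gt(mean(own > 0), 0.9)
  expect_equal(as.character(predict(m, d$x)),
               m$classes[max.col(dv, ties.method = "first")])
})

test_that("degenerate one-point classes are fit and recalled", {
  X <- rbind(c(0, 0), c(5, 5))
  y <- c("lo", "hi")
  m <- train_svm(X, y, C = 10)
  expect_identical(as.character(predict(m, X)), y)
})

test_that("random forests memorize separable training data and vote deterministically", {
  d <- blob_data(n_per = 30)
  rf <- train_random_forest(d$x, d$y, n_trees = 100, seed = 5)
  expect_equal(mean(predict(rf, d$x) == d$y), 1)
  # vote of one: a single-tree forest is its own majority
  rf1 <- train_random_forest(d$x, d$y, n_trees = 1, seed = 5)
  expect_identical(predict(rf1, d$x), predict(rf1, d$x))
  # seed determinism
  rfa <- train_random_forest(d$x, d$y, n_trees = 25, seed = 9)
  rfb <- train_random_forest(d$x, d$y, n_trees = 25, seed = 9)
  expect_identical(predict(rfa, d$x), predict(rfb, d$x))
})

test_that("the BPNN learns XOR and its loss decreases", {
  set.seed(3)
  Xx <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), byrow = TRUE, ncol = 2)
  Xx <- Xx[rep(1:4, 25), ] + matrix(stats::rnorm(200, 0, 0.05), ncol = 2)
  yy <- rep(c("p", "q", "q", "p"), 25)
  bp <- train_bpnn(Xx, yy, hidden_sizes = 8, epochs = 3000,
                   learning_rate = 0.5, seed = 2)
  expect_gte(mean(predict(bp, Xx) == yy), 0.95)
  # descent: smoothed loss at the end is below the start
  expect_lt(stats::median(utils::tail(bp$loss_history, 10)),
            stats::median(utils::head(bp$loss_history, 10)))
  # zero epochs: predictions come from the random initialization
  bp0 <- train_bpnn(Xx, yy, epochs = 0, seed = 2)
  expect_length(bp0$loss_history, 0)
  expect_s3_class(predict(bp0, Xx), "factor")
  # seed determinism
  bpa <- train_bpnn(Xx, yy, epochs = 50, seed = 7)
  bpb <- train_bpnn(Xx, yy, epochs = 50, seed = 7)
  expect_identical(bpa$weights, bpb$weights)
})

test_that("splits are seeded, disjoint, exhaustive and stratified", {
  df <- tibble::tibble(v = seq_len(100))
  y <- rep(c("a", "b", "c", "d", "e"), each = 20)
  sp <- split_data(df, y, 0.8, seed = 1)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_length(intersect(sp$train$v, sp$test$v), 0)
  expect_setequal(c(sp$train$v, sp$test$v), df$v)
  # per-class proportions preserved to +/- 1 sample
  expect_true(all(abs(table(sp$train_labels) - 16) <= 1))
  sp2 <- split_data(df, y, 0.8, seed = 1)
  expect_identical(sp$train$v, sp2$train$v)
  expect_error(split_data(df[1:21, ], c(rep("a", 20), "b"), 0.8, seed = 1),
               "at least 2")
  expect_error(split_data(df, y, 1.2), "train_fraction")
})

test_that("evaluation metrics match hand computations", {
  d <- blob_data(n_per = 10, centers = list(c(0, 0), c(8, 8)))
  rf <- train_random_forest(d$x, d$y, n_trees = 50, seed = 2)
  rep <- evaluate(rf, d$x, d$y)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)
  expect_true(all(rep$confusion == diag(c(10, 10))))
  expect_identical(rep$averaging, "macro")
  # confusion marginals are conserved
  expect_equal(rowSums(rep$confusion), c(a = 10, b = 10))
  expect_equal(sum(rep$confusion), 20)
  expect_error(evaluate(rf, d$x, rep("zzz", 20)), "vocabulary")
})

test_that("an always-one-class predictor on a balanced 5-class set scores 0.2", {
  constant_model <- structure(list(classes = letters[1:5]), class = "constant5")
  assign("predict.constant5",
         function(object, newdata, ...) {
           factor(rep("a", nrow(newdata)), levels = object$classes)
         }, envir = globalenv())
  on.exit(rm("predict.constant5", envir = globalenv()))
  X <- matrix(stats::rnorm(100), 50, 2)
  y <- rep(letters[1:5], each = 10)
  rep <- evaluate(constant_model, X, y)
  expect_equal(rep$accuracy, 0.2)
  expect_equal(rep$recall, 0.2)
})

test_that("a hand-counted 10-sample confusion matrix is reproduced", {
  truth <- c("a", "a", "a", "b", "b", "b", "b", "c", "c", "c")
  pred  <- c("a", "b", "a", "b", "b", "c", "b", "c", "c", "a")
  stub <- structure(list(classes = c("a", "b", "c"), pred = pred),
                    class = "stub_clf")
  assign("predict.stub_clf",
         function(object, newdata, ...) {
           factor(object$pred, levels = object$classes)
         }, envir = globalenv())
  on.exit(rm("predict.stub_clf", envir = globalenv()))
  rep <- evaluate(stub, matrix(0, 10, 1), truth)
  manual <- matrix(c(2, 1, 0,
                     0, 3, 1,
                     1, 0, 2), byrow = TRUE, nrow = 3)
  expect_equal(unname(unclass(rep$confusion)), manual)
  expect_equal(rep$accuracy, 7 / 10)
  expect_equal(rep$recall, mean(c(2 / 3, 3 / 4, 2 / 3)))
})

test_that("standardization is learned on the training set only", {
  # a memorizing model evaluated on its own training data is perfect
  d <- blob_data(n_per = 25)
  rf <- train_random_forest(d$x, d$y, n_trees = 200, seed = 3)
  expect_equal(evaluate(rf, d$x, d$y)$accuracy, 1)
  # the SVM stores train-set standardization: shifting the test inputs must
  # change the decision values (they would be identical if standardization
  # were re-learned on the test set)
  m <- train_svm(d$x, d$y)
  expect_false(isTRUE(all.equal(svm_decision_values(m, d$x + 100),
                                svm_decision_values(m, d$x))))
})

test_that("benchmark filters tasks, names classes and reproduces under a seed", {
  set.seed(20)
  n_ep <- 80
  actions <- rep(facial_actions(), length.out = n_ep)
  intens <- rep(c("normal", "forceful"), each = n_ep / 2)
  # discriminative synthetic features keyed to the action index
  X <- matrix(stats::rnorm(n_ep * 16), n_ep, 16) +
    3 * match(actions, facial_actions())
  colnames(X) <- paste0("c", rep(1:2, each = 8), "_",
                        rep(c("iemg", "var", "mav", "ssi", "rms", "fc", "mf",
                              "frms"), 2))
  fm <- dplyr::bind_cols(tibble::tibble(action = actions, intensity = intens),
                         tibble::as_tibble(X))
  res <- run_benchmark(fm, "five_class", classifiers = "rf", seed = 2)
  expect_identical(res$task, "five_class")
  expect_setequal(res$report[[1]]$classes,
                  c("RE", "FR", "CE", "PL", "LCM"))
  res2 <- run_benchmark(fm, "five_class", classifiers = "rf", seed = 2)
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$report[[1]]$confusion, res2$report[[1]]$confusion)
  res10 <- run_benchmark(fm, "ten_class", classifiers = "rf", seed = 2)
  expect_length(res10$report[[1]]$classes, 10L)
  fm_forceful <- dplyr::filter(fm, intensity == "forceful")
  expect_error(run_benchmark(fm_forceful, "ten_class", classifiers = "rf"),
               "both intensities")
  fm_normal <- dplyr::filter(fm, intensity == "normal")
  expect_error(run_benchmark(fm_normal, "five_class", classifiers = "rf"),
               "forceful")
})

test_that("accuracy does not degrade as the noise floor drops (SNR monotonicity)", {
  # 3 interference levels x 10 seeds; median five-class accuracy per level
  # must be non-decreasing as white noise shrinks
  p <- protocol_spec(blocks = 1, reps_per_block = 3, cue_duration_s = 0.5,
                     rest_duration_s = 1, interblock_rest_s = 1)
  noise_levels <- c(150e-6, 40e-6, 5e-6)
  acc <- sapply(noise_levels, function(sd_noise) {
    vapply(1:10, function(s) {
      sess <- simulate_session(p, noise = noise_spec(white_noise_sd = sd_noise),
                               seed = 100 + s)
      chain <- preprocess_chain(sess$recording)
      fit <- suppressWarnings(fit_ica(chain, 8, seed = s, restarts = 1))
      fm <- extract_feature_matrix(fit$components, sess$epochs, 1000)
      res <- run_benchmark(fm, "five_class", classifiers = "rf", seed = s)
      res$accuracy
    }, numeric(1))
  })
  med <- apply(acc, 2, stats::median)
  expect_true(all(diff(med) >= 0))
})

test_that("the BPNN is consistent with an established feedforward network", {
  # independent route: nnet's single-hidden-layer network on the same data
  d <- blob_data(n_per = 30, centers = list(c(0, 0), c(3, 3), c(0, 3)),
                 sd = 0.4)
  bp <- train_bpnn(d$x, d$y, hidden_sizes = 8, epochs = 1500,
                   learning_rate = 0.3, seed = 1)
  set.seed(1)
  ref <- nnet::nnet(d$x, nnet::class.ind(factor(d$y)), size = 8,
                    softmax = TRUE, maxit = 300, trace = FALSE)
  ref_acc <- mean(max.col(stats::predict(ref, d$x)) ==
                    as.integer(factor(d$y)))
  bp_acc <- mean(predict(bp, d$x) == d$y)
  expect_gte(bp_acc, 0.95)
  expect_gte(bp_acc, ref_acc - 0.05)
})
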