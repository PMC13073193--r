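make_subjects <- function(n_case, n_ctrl) {
  subject_table(sprintf("s%04d", seq_len(n_case + n_ctrl)),
                rep(c("case", "control"), c(n_case, n_ctrl)))
}

test_that("undersampling keeps all cases and draws nested control sets", {
  subjects <- make_subjects(546, 11363)
  u3 <- undersample(subjects, "1:3", seed = 42)
  expect_equal(sum(u3$label == "case"), 546)
  expect_equal(sum(u3$label == "control"), 1638)  # 3 x 546

  u1 <- undersample(subjects, "1:1", seed = 42)
  u2 <- undersample(subjects, "1:2", seed = 42)
  c1 <- u1$subject_id[u1$label == "control"]
  c2 <- u2$subject_id[u2$label == "control"]
  c3 <- u3$subject_id[u3$label == "control"]
  expect_true(all(c1 %in% c2))
  expect_true(all(c2 %in% c3))
  expect_lt(length(c1), length(c2))

  expect_identical(undersample(subjects, "all", seed = 1)$subject_id,
                   subjects$subject_id)

  small <- make_subjects(10, 15)
  expect_error(undersample(small, "1:2", seed = 1), "1:1")
})

test_that("train/test split is disjoint with a 1:9 test ratio", {
  subjects <- make_subjects(546, 11363)
  sp <- split_train_test(subjects, seed = 5)
  expect_equal(nrow(sp$test), round(0.2 * 11909))
  tab <- table(sp$test$label)
  expect_equal(unname(tab["case"]), round(nrow(sp$test) / 10))
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), 11909)

  sp2 <- split_train_test(subjects, seed = 5)
  expect_identical(sp, sp2)

  expect_error(split_train_test(make_subjects(2, 5), seed = 1), "test set")
})

sep_data <- function(n, seed = 1) {
  # linearly separated toy classes
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  x[, 1] <- x[, 1] + y * 2
  list(x = x, y = y)
}

test_that("the network memorizes a small separable dataset", {
  set.seed(3)
  n <- 32
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + ifelse(y == 1, 3, -3)   # wide-margin separation
  net <- network_config(hidden_sizes = c(32L, 16L), dropout_rates = c(0, 0),
                        seed = 1)
  model <- fit_network(x, y,
                       net = net,
                       train = train_config(optimizer = "adam",
                                            learning_rate = 0.01,
                                            max_epochs = 300L,
                                            patience = 300L,
                                            validation_fraction = 0.1))
  p <- predict_proba(model, x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(mean((p > 0.5) == y), 1.0)
})

test_that("training is deterministic given seeds", {
  d <- sep_data(60, seed = 8)
  m1 <- fit_network(d$x, d$y, net = tiny_net(seed = 7), train = fast_train(seed = 9))
  m2 <- fit_network(d$x, d$y, net = tiny_net(seed = 7), train = fast_train(seed = 9))
  expect_identical(predict_proba(m1, d$x), predict_proba(m2, d$x))

  m3 <- fit_network(d$x, d$y, net = tiny_net(seed = 8), train = fast_train(seed = 9))
  expect_false(identical(predict_proba(m1, d$x), predict_proba(m3, d$x)))
})

test_that("predictions are order-equivariant, bounded, and width-checked", {
  d <- sep_data(50, seed = 2)
  model <- fit_network(d$x, d$y, net = tiny_net(), train = fast_train())
  p <- predict_proba(model, d$x)
  perm <- sample(nrow(d$x))
  expect_equal(predict_proba(model, d$x[perm, ]), p[perm])
  extreme <- matrix(2, 3, 4)
  expect_true(all(is.finite(predict_proba(model, extreme))))
  expect_error(predict_proba(model, d$x[, 1:3]), "width")
})

test_that("an untrained zero-weight model outputs one half", {
  net <- network_config(hidden_sizes = c(4L, 2L), dropout_rates = c(0, 0))
  model <- structure(list(
    params = list(list(W = matrix(0, 3, 4), b = rep(0, 4)),
                  list(W = matrix(0, 4, 2), b = rep(0, 2)),
                  list(W = matrix(0, 2, 1), b = 0)),
    net = net, train = train_config(), n_features = 3L,
    best_epoch = 0L, history = NULL), class = "risk_model")
  expect_equal(predict_proba(model, matrix(rnorm(9), 3, 3)), rep(0.5, 3))
})

test_that("models round-trip through JSON serialisation", {
  d <- sep_data(40, seed = 5)
  model <- fit_network(d$x, d$y, net = tiny_net(), train = fast_train())
  tmp <- tempfile(fileext = ".json")
  save_model(model, tmp)
  back <- load_model(tmp)
  expect_equal(predict_proba(back, d$x), predict_proba(model, d$x),
               tolerance = 1e-12)
})

test_that("AUC equals brute-force pair counting with ties at one half", {
  brute_auc <- function(s, y) {
    cs <- s[y == 1]; ct <- s[y == 0]
    cmp <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)  # coarse scores force ties
    expect_equal(auc_mw(s, y), brute_auc(s, y))
  }
  expect_equal(auc_mw(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_error(auc_mw(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("random scores give a null AUC near one half", {
  set.seed(21)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  s <- rnorm(n)
  a <- auc_mw(s, y)
  se <- sqrt((1 / sum(y == 1) + 1 / sum(y == 0)) / 12)
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("DeLong interval brackets the AUC and variance tracks bootstrap", {
  set.seed(31)
  n <- 200
  y <- rep(c(1, 0), c(60, 140))
  s <- rnorm(n, mean = y)
  est <- auc_with_delong_ci(s, y)
  expect_true(est$ci_low <= est$auc && est$auc <= est$ci_high)
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
  expect_equal(est$auc, auc_mw(s, y))

  boot <- replicate(2000, {
    idx <- sample(n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample(n, replace = TRUE)
    auc_mw(s[idx], y[idx])
  })
  expect_lt(abs(est$se^2 - var(boot)) / var(boot), 0.25)
})

test_that("grid search evaluates the full grid and tie-breaks predictably", {
  d <- sep_data(80, seed = 13)
  net <- network_config(hidden_sizes = c(8L, 4L), dropout_rates = c(0, 0),
                        seed = 1)
  cv <- grid_search_cv(d$x, d$y, optimizers = c("sgd", "adam"),
                       learning_rates = c(0.1, 0.01, 0.001),
                       net = net,
                       train = train_config(max_epochs = 3L, patience = 3L),
                       seed = 2)
  expect_equal(nrow(cv$table), 6L)           # 2 optimizers x 3 rates
  expect_length(cv$best$fold_aucs, 5L)
  expect_true(all(cv$table$mean_auc >= 0 & cv$table$mean_auc <= 1))

  # forced tie: every config identical AUCs -> lowest rate, sgd first
  tied <- cv
  tied$table$mean_auc <- 0.9
  ord <- order(-tied$table$mean_auc, tied$table$learning_rate,
               match(tied$table$optimizer, c("sgd", "adam")))
  expect_equal(tied$table$optimizer[ord[1]], "sgd")
  expect_equal(tied$table$learning_rate[ord[1]], 0.001)
})

test_that("grid search separates an easy problem at least as well as a GLM", {
  d <- sep_data(150, seed = 17)
  glm_fit <- suppressWarnings(glm(d$y ~ d$x, family = binomial))
  glm_auc <- auc_mw(fitted(glm_fit), d$y)
  net <- network_config(hidden_sizes = c(16L, 8L), dropout_rates = c(0, 0),
                        seed = 1)
  cv <- grid_search_cv(d$x, d$y, optimizers = "adam",
                       learning_rates = c(0.01, 0.001),
                       net = net,
                       train = train_config(optimizer = "adam",
                                            max_epochs = 40L,
                                            patience = 10L),
                       seed = 3)
  expect_gt(cv$best$mean_auc, 0.95)
  expect_gt(glm_auc, 0.95)  # oracle lower-bound sanity on the same data
})

test_that("non-finite activations stop training with a diagnostic error", {
  d <- sep_data(60, seed = 23)
  x_bad <- d$x
  x_bad[, 1] <- Inf
  expect_error(
    fit_network(x_bad, d$y, net = tiny_net(),
                train = train_config(optimizer = "sgd", learning_rate = 0.01,
                                     max_epochs = 5L)),
    "non-finite")
})
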