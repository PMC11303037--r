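test_that("two separated 1-D classes split at the midpoint of means", {
  X <- matrix(c(rnorm(20, -4, 0.5), rnorm(20, 4, 0.5)), ncol = 1,
              dimnames = list(NULL, "t1"))
  set.seed(1)
  X[] <- c(rnorm(20, -4, 0.5), rnorm(20, 4, 0.5))
  y <- rep(c("A", "B"), each = 20)
  m <- fit_lda(X, y)
  mid <- mean(c(mean(X[1:20, ]), mean(X[21:40, ])))
  lo <- predict_lda(m, matrix(mid - 0.2, dimnames = list(NULL, "t1")),
                    prior = "equal")
  hi <- predict_lda(m, matrix(mid + 0.2, dimnames = list(NULL, "t1")),
                    prior = "equal")
  expect_equal(as.character(lo$class), "A")
  expect_equal(as.character(hi$class), "B")
  at <- predict_lda(m, matrix(mid, dimnames = list(NULL, "t1")),
                    prior = "equal")
  expect_equal(unname(at$posterior[1, ]), c(0.5, 0.5), tolerance = 0.05)
})

test_that("the model is a function of sufficient statistics", {
  inst <- random_lda_instance(5)
  m1 <- fit_lda(inst$X, inst$y)
  m2 <- fit_lda(rbind(inst$X, inst$X), c(inst$y, inst$y))
  expect_equal(m1$means, m2$means, tolerance = 1e-12)
  expect_equal(m1$center, m2$center, tolerance = 1e-12)
  expect_equal(m1$scale, m2$scale, tolerance = 1e-12)
  expect_equal(m1$cov, m2$cov, tolerance = 1e-12)
  p1 <- predict_lda(m1, inst$X_new)
  p2 <- predict_lda(m2, inst$X_new)
  expect_equal(p1$posterior, p2$posterior, tolerance = 1e-12)
})

test_that("posteriors equal the brute-force Gaussian Bayes oracle", {
  for (seed in 1:50) {
    inst <- random_lda_instance(seed)
    m <- fit_lda(inst$X, inst$y)
    got <- predict_lda(m, inst$X_new, prior = "equal")$posterior
    want <- bayes_oracle(inst$X, inst$y, inst$X_new)
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
    # training prior route
    got_t <- predict_lda(m, inst$X_new, prior = "training")$posterior
    want_t <- bayes_oracle(inst$X, inst$y, inst$X_new,
                           prior = as.numeric(table(inst$y)) /
                             length(inst$y))
    expect_equal(unname(got_t), unname(want_t), tolerance = 1e-8)
  }
})

test_that("posteriors normalize and respond monotonically to priors", {
  inst <- random_lda_instance(9)
  m <- fit_lda(inst$X, inst$y)
  pr_eq <- rep(1 / inst$k, inst$k)
  post0 <- predict_lda(m, inst$X_new, prior = pr_eq)$posterior
  expect_equal(rowSums(post0), rep(1, nrow(post0)), tolerance = 1e-9)
  # raising class 1's prior never lowers its posterior
  pr_up <- pr_eq; pr_up[1] <- pr_up[1] * 3
  post1 <- predict_lda(m, inst$X_new, prior = pr_up)$posterior
  expect_true(all(post1[, 1] >= post0[, 1] - 1e-12))
})

test_that("prior choice can flip a borderline assignment", {
  set.seed(8)
  # class A much more frequent in training (priors 0.9 vs 0.1)
  X <- matrix(c(rnorm(90, -1), rnorm(10, 1)), ncol = 1,
              dimnames = list(NULL, "t1"))
  y <- rep(c("A", "B"), c(90, 10))
  m <- fit_lda(X, y)
  grid <- matrix(seq(-3, 3, length.out = 301),
                 dimnames = list(NULL, "t1"))
  cls_t <- as.character(predict_lda(m, grid, prior = "training")$class)
  cls_e <- as.character(predict_lda(m, grid, prior = "equal")$class)
  # between the two decision boundaries the equal prior says B while
  # the training prior still says A; never the reverse
  expect_true(any(cls_t == "A" & cls_e == "B"))
  expect_false(any(cls_t == "B" & cls_e == "A"))
})

test_that("fit validates its preconditions", {
  inst <- random_lda_instance(2)
  expect_error(fit_lda(inst$X[1:5, , drop = FALSE], inst$y[1:5]),
               "at least 8")
  yy <- inst$y
  yy[yy == yy[1]] <- yy[length(yy)]
  yy[1] <- "Z"
  expect_error(fit_lda(inst$X, yy), ">= 2")
  Xn <- inst$X; Xn[1, 1] <- NaN
  expect_error(fit_lda(Xn, inst$y), "NaN")
  expect_error(predict_lda(fit_lda(inst$X, inst$y),
                           matrix(Inf, 1, ncol(inst$X),
                                  dimnames = list(NULL,
                                                  colnames(inst$X)))),
               "NaN/Inf")
})

test_that("LOOCV is perfect on separated classes, chance on permuted labels", {
  set.seed(20)
  X <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             matrix(rnorm(40, 20, 0.2), ncol = 2),
             matrix(rnorm(40, -20, 0.2), ncol = 2))
  colnames(X) <- c("t1", "t2")
  y <- rep(c("A", "B", "C"), each = 20)
  cv <- loocv_lda(X, y)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(cv$n_unclassifiable, 0L)

  # permuted labels, 4 balanced classes of 50: accuracy within the
  # Monte-Carlo band around chance (0.25)
  set.seed(21)
  Xp <- matrix(rnorm(200 * 3), 200, 3,
               dimnames = list(NULL, paste0("t", 1:3)))
  yp <- sample(rep(lunar_quarters(), each = 50))
  cvp <- loocv_lda(Xp, yp)
  expect_gt(cvp$accuracy, 0.12)
  expect_lt(cvp$accuracy, 0.38)
})

test_that("LOOCV accuracy never beats resubstitution (simulation property)", {
  for (seed in 1:20) {
    inst <- random_lda_instance(seed + 100)
    if (any(table(inst$y) < 3)) next
    m <- fit_lda(inst$X, inst$y)
    resub <- mean(as.character(predict_lda(m, inst$X,
                                           prior = "training")$class) ==
                    inst$y)
    cv <- loocv_lda(inst$X, inst$y, prior = "training")
    expect_lte(cv$accuracy, resub + 1e-12)
  }
})

test_that("adjacency fraction counts cyclic neighbours among errors", {
  lv <- lunar_quarters()
  cm <- matrix(0, 4, 4, dimnames = list(lv, lv))
  diag(cm) <- 10
  cm["NEW", "WAXING"] <- 5
  expect_equal(adjacency_fraction(cm), 1.0)
  cm["NEW", "WAXING"] <- 0
  cm["NEW", "FULL"] <- 5
  expect_equal(adjacency_fraction(cm), 0.0)
  cm["NEW", "WAXING"] <- 3
  cm["NEW", "FULL"] <- 1
  expect_equal(adjacency_fraction(cm), 0.75)
  cm["NEW", "WAXING"] <- 0
  cm["NEW", "FULL"] <- 0
  expect_warning(out <- adjacency_fraction(cm), "undefined")
  expect_true(is.na(out))
})

test_that("assign_cohort summarizes predictions as a stage cohort", {
  set.seed(4)
  centers <- c(NEW = -9, WAXING = -3, FULL = 3, WANING = 9)
  X <- do.call(rbind, lapply(centers, function(mu) {
    matrix(rnorm(20, mu, 0.3), ncol = 2)
  }))
  colnames(X) <- c("t1", "t2")
  y <- rep(lunar_quarters(), each = 10)
  m <- fit_lda(X, y)
  clones <- X[rep(1, 7), ]
  sc <- assign_cohort(m, clones, stage = "female")
  expect_s3_class(sc, "stage_cohort")
  expect_equal(sum(sc$P), 1)
  expect_equal(unname(sc$P["NEW"]), 1)
  expect_error(assign_cohort(m, X[0, , drop = FALSE]), "no fish")
})

test_that("total variation distance matches hand sums", {
  expect_equal(total_variation(c(0.25, 0.25, 0.25, 0.25),
                               c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(total_variation(c(1, 0, 0, 0), c(0, 1, 0, 0)), 1)
  # 0.5 * (0.15 + 0.05 + 0.05 + 0.15)
  expect_equal(total_variation(c(0.4, 0.3, 0.2, 0.1), rep(0.25, 4)),
               0.2)
  expect_error(total_variation(c(0.5, 0.6), c(0.5, 0.5)), "summing to 1")
})
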