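# Site-specific classifiers, prediction contracts, cross-site alignment

make_site_fixture <- function(seed = 61, n = 40, p = 12, d = 3) {
  dat <- planted_class_data(n, p, shift_cols = 1:2, d = d, seed = seed)
  ranked <- msvm_rfe_rank(dat$X, dat$y, rfe_config(n_subsamples = 3, seed = 1))
  hp <- structure(list(C = 2, gamma = 0.1, cv_accuracy = NA), class = "svm_hyperparams")
  model <- train_site_model(dat$X, dat$y, ranked, 2, hp, site = "A",
                            modality = "demo")
  list(dat = dat, ranked = ranked, model = model)
}

test_that("site models fit separable data and respect their feature set", {
  fx <- make_site_fixture()
  pred <- predict(fx$model, fx$dat$X)
  expect_gte(mean(pred == fx$dat$y), 0.95)

  # perturbing unselected features leaves predictions unchanged
  X2 <- fx$dat$X
  unsel <- setdiff(colnames(X2), fx$model$features)
  X2[, unsel] <- X2[, unsel] + 1000
  expect_identical(predict(fx$model, X2), pred)

  # duplicated rows get identical labels; prediction is deterministic
  X3 <- fx$dat$X[c(1, 1, 2, 2), ]
  p3 <- predict(fx$model, X3)
  expect_identical(as.character(p3[1]), as.character(p3[2]))
  expect_identical(predict(fx$model, fx$dat$X), pred)
})

test_that("single-class training data are routed to the across-site path", {
  dat <- planted_class_data(10, 4, seed = 62)
  one <- dat$y == "TD"
  expect_error(train_site_model(dat$X[one, ], dat$y[one], colnames(dat$X), 2,
                                site = "Pitt"),
               "across-site")
})

test_that("missing features error by name or are median-imputed under the flag", {
  fx <- make_site_fixture()
  feat <- fx$model$features[1]
  Xdrop <- as.data.frame(fx$dat$X)[, setdiff(colnames(fx$dat$X), feat)]
  expect_error(predict(fx$model, Xdrop), feat)
  pred <- predict(fx$model, Xdrop, impute = TRUE)
  expect_length(pred, nrow(Xdrop))

  Xna <- fx$dat$X
  Xna[3, feat] <- NA
  expect_error(predict(fx$model, Xna), "NA")
  expect_length(predict(fx$model, Xna, impute = TRUE), nrow(Xna))
})

test_that("TD alignment matches per-site TD means exactly and keeps contrasts", {
  set.seed(63)
  p <- 6
  base <- matrix(rnorm(60 * p), 60, p, dimnames = list(NULL, paste0("f", 1:p)))
  yA <- rep(c(TRUE, FALSE), each = 15)   # TRUE = TD
  yB <- rep(c(TRUE, FALSE), times = c(20, 10))
  XA <- base[1:30, ] + 10      # site offsets
  XB <- base[31:60, ] - 10
  XB[!yB, ] <- XB[!yB, ] + 2   # class effect at site B
  al <- align_sites_by_td(list(A = XA, B = XB), list(A = yA, B = yB))
  pooled <- colMeans(rbind(al$A[yA, ], al$B[yB, ]))
  expect_equal(colMeans(al$A[yA, ]), pooled, tolerance = 1e-12)
  expect_equal(colMeans(al$B[yB, ]), pooled, tolerance = 1e-12)
  # within-site class contrast untouched (pure shift)
  expect_equal(colMeans(XB[!yB, ]) - colMeans(XB[yB, ]),
               colMeans(al$B[!yB, ]) - colMeans(al$B[yB, ]), tolerance = 1e-12)
  expect_equal(unname(al$A - XA)[1, ], unname(al$A - XA)[30, ], tolerance = 1e-12)
})

test_that("unlabeled alignment is a grand-mean shift with exact round trips", {
  set.seed(64)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  # single site: alignment is the identity
  expect_equal(align_sites_unlabeled(list(A = X))$A, X, tolerance = 1e-12)

  # equal class mix: TD alignment and unlabeled alignment agree up to the
  # common class-mix offset (identical across sites, feature-wise constant)
  yA <- yB <- rep(c(TRUE, FALSE), each = 5)
  XA <- X + 5; XB <- X - 5
  XB[!yB, ] <- XB[!yB, ] + 1
  XA[!yA, ] <- XA[!yA, ] + 1
  td <- align_sites_by_td(list(A = XA, B = XB), list(A = yA, B = yB))
  un <- align_sites_unlabeled(list(A = XA, B = XB))
  offset <- un$A - td$A
  expect_equal(un$B - td$B, offset, tolerance = 1e-12)
  expect_lt(max(abs(sweep(offset, 2, colMeans(offset), "-"))), 1e-12)
})

test_that("a TD-only site is classified above chance after TD alignment", {
  # two labeled sites with a planted effect train an across-site model that
  # transfers to a shifted TD-only site
  set.seed(65)
  p <- 8; n <- 30
  mk <- function(offset, n_td, n_adhd, d = 2.5, p = 8) {
    X <- matrix(rnorm((n_td + n_adhd) * p), n_td + n_adhd, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- rep(c(TRUE, FALSE), times = c(n_td, n_adhd))
    X[!y, 1] <- X[!y, 1] + d
    list(X = X + offset, td = y)
  }
  A <- mk(8, n, n); B <- mk(-6, n, n)
  P <- mk(15, n, 0)          # known TD training rows of the Pitt-like site
  P2 <- mk(15, 20, 20)       # its unlabeled test rows
  # one joint alignment: only the known-TD rows anchor the site means
  al <- align_sites_by_td(
    list(A = A$X, B = B$X, P = rbind(P$X, P2$X)),
    list(A = A$td, B = B$td, P = c(P$td, rep(FALSE, nrow(P2$X)))))
  Xtr <- rbind(al$A, al$B)
  ytr <- factor(ifelse(c(A$td, B$td), "TD", "ADHD"), levels = c("TD", "ADHD"))
  ranked <- msvm_rfe_rank(Xtr, ytr, rfe_config(n_subsamples = 3, seed = 2))
  model <- train_site_model(Xtr, ytr, ranked, 2,
                            structure(list(C = 2, gamma = 0.125), class = "svm_hyperparams"),
                            site = "across", modality = "demo")
  newX <- al$P[(nrow(P$X) + 1):(nrow(P$X) + nrow(P2$X)), ]
  truth <- factor(ifelse(P2$td, "TD", "ADHD"), levels = c("TD", "ADHD"))
  acc <- mean(predict(model, newX) == truth)
  expect_gt(acc, 0.7)   # well above the 0.5 majority rate
})

test_that("models are bit-independent of excluded sites' data", {
  dat <- planted_class_data(30, 10, shift_cols = 1, d = 2, seed = 66)
  fit_on <- function(X, y) {
    ranked <- msvm_rfe_rank(X, y, rfe_config(n_subsamples = 3, seed = 4))
    train_site_model(X, y, ranked, 3,
                     structure(list(C = 1, gamma = 0.1), class = "svm_hyperparams"),
                     site = "A", modality = "m")
  }
  m1 <- fit_on(dat$X, dat$y)
  # an unrelated (WashU-like) site's data changes entirely; site A's model
  # and predictions must not move
  m2 <- fit_on(dat$X, dat$y)
  expect_identical(m1$features, m2$features)
  expect_identical(predict(m1, dat$X), predict(m2, dat$X))
  expect_identical(unname(m1$fit$coefs), unname(m2$fit$coefs))
})
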