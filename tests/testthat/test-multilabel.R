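test_that("RReliefF-style weights match a naive accumulation and rank signal first", {
  # 6 instances: f_inf tracks the labels, f_dup duplicates it,
  # f_const is constant, f_noise varies independently of the labels
  X <- cbind(f_const = rep(2L, 6),
             f_dup = c(0L, 0L, 0L, 3L, 3L, 3L),
             f_inf = c(0L, 0L, 0L, 3L, 3L, 3L),
             f_noise = c(0L, 3L, 0L, 3L, 0L, 3L))
  Y <- cbind(`GO:0000001` = c(0L, 0L, 0L, 1L, 1L, 1L),
             `GO:0000002` = c(1L, 1L, 1L, 0L, 0L, 1L))
  ranked <- rfml_rank_features(X, Y, k_nn = 3)
  naive <- rfml_naive(X, Y, k_nn = 3)
  expect_equal(ranked$weight[match(colnames(X), ranked$feature)],
               unname(naive), tolerance = 1e-12)
  # informative features first, duplicate ties broken by feature id
  expect_equal(ranked$feature[1:2], c("f_dup", "f_inf"))
  expect_equal(ranked$weight[1], ranked$weight[2])
  # constant feature never gains weight
  expect_lte(ranked$weight[ranked$feature == "f_const"], 0)
  expect_gt(ranked$weight[1], ranked$weight[ranked$feature == "f_noise"])
  # identical label rows carry no signal
  Yflat <- cbind(`GO:0000001` = rep(1L, 6))
  expect_warning(r0 <- rfml_rank_features(X, Yflat, k_nn = 3), "identical")
  expect_equal(r0$weight, rep(0, 4))
})

test_that("binary relevance fits one member per label", {
  fx <- separable_fixture()
  m <- fit_br(fx$X, fx$Y, base_learner_spec(n_trees = 60, seed = 3))
  expect_length(m$members, ncol(fx$Y))
  sc <- predict(m, fx$X)
  expect_true(all(sc >= 0 & sc <= 1))
  # separable fixture: training-set F1max is perfect
  expect_equal(f1max(fx$Y, sc)$f1max, 1.0)
  # an all-positive label column becomes a constant scorer at 1
  Y1 <- fx$Y
  Y1[, 1] <- 1L
  expect_warning(m1 <- fit_br(fx$X, Y1, base_learner_spec(n_trees = 20)),
                 "single")
  expect_equal(unname(predict(m1, fx$X)[, 1]), rep(1, nrow(fx$X)))
})

test_that("label powerset marginalizes class probabilities per label", {
  # observed labelsets {A} and {A,B}: score(A) = p({A}) + p({A,B}) = 1
  X <- cbind(f1 = c(0L, 0L, 3L, 3L, 0L, 3L))
  Y <- cbind(A = rep(1L, 6), B = c(0L, 0L, 1L, 1L, 0L, 1L))
  m <- fit_lp(X, Y, base_learner_spec(n_trees = 40, seed = 2))
  sc <- predict(m, X)
  expect_equal(unname(sc[, "A"]), rep(1, 6))
  expect_true(all(sc[, "B"] >= 0 & sc[, "B"] <= 1))
  # single distinct labelset degenerates to a constant scorer
  Yc <- cbind(A = rep(1L, 6), B = rep(1L, 6))
  expect_warning(mc <- fit_lp(X, Yc, base_learner_spec(n_trees = 20)),
                 "single distinct labelset")
  expect_equal(unname(predict(mc, X)), matrix(1, 6, 2))
})

test_that("RAkEL reduces exactly to LP and BR at the boundary settings", {
  fx <- separable_fixture(n = 30, L = 4, seed = 11)
  spec <- base_learner_spec(n_trees = 50, seed = 17)
  # k = |L|, m = 1: the single member is the full label powerset
  r_lp <- fit_rakel(fx$X, fx$Y, spec, k = 4, m = 1)
  lp <- fit_lp(fx$X, fx$Y, spec)
  expect_equal(predict(r_lp, fx$X), predict(lp, fx$X), tolerance = 0)
  # k = 1 with all labels covered: member per label == binary relevance
  r_br <- fit_rakel(fx$X, fx$Y, spec, k = 1, m = 4)
  br <- fit_br(fx$X, fx$Y, spec)
  expect_equal(predict(r_br, fx$X), predict(br, fx$X), tolerance = 0)
  # infeasible member count rejected
  expect_error(fit_rakel(fx$X, fx$Y, spec, k = 4, m = 2), "exceeds")
})

test_that("RAkEL keeps pace with BR on a planted fixture", {
  sim <- tiny_sim()
  pipe <- run_pipeline(sim$collection, sim$hits, sim$annotations)
  spec <- base_learner_spec(n_trees = 60, seed = 7)
  f_rakel <- cv_f1max(pipe$features, pipe$labels, "rakel", spec,
                      folds = 3, seed = 7)$f1max$f1max
  f_br <- cv_f1max(pipe$features, pipe$labels, "br", spec,
                   folds = 3, seed = 7)$f1max$f1max
  expect_gte(f_rakel, f_br - 0.05)
})

test_that("prediction is deterministic, aligned and registry-checked", {
  fx <- separable_fixture()
  spec <- base_learner_spec(n_trees = 40, seed = 9)
  m <- fit_rakel(fx$X, fx$Y, spec, k = 2)
  s1 <- predict(m, fx$X)
  s2 <- predict(m, fx$X)
  expect_identical(s1, s2)
  expect_equal(nrow(predict(m, fx$X[0, , drop = FALSE])), 0L)
  bad <- fx$X[, c(2, 1, 3)]
  expect_error(predict(m, bad), "registry mismatch")
  # refitting with the same seed reproduces the scores
  m2 <- fit_rakel(fx$X, fx$Y, spec, k = 2)
  expect_equal(predict(m2, fx$X), s1, tolerance = 0)
})

test_that("binary screening mode flags at the 80% reporting threshold", {
  positive <- rep(c(1L, 0L), each = 15)
  X <- cbind(f1 = 3L * positive, f2 = rep(0:3, length.out = 30))
  bm <- binary_mode_fit(X, positive, base_learner_spec(n_trees = 80,
                                                       seed = 4))
  pred <- binary_mode_predict(bm, X)
  expect_true(all(pred$flagged == (pred$score >= 0.8)))
  expect_true(all(pred$score[positive == 1] > 0.8))
  # negatives fall below the default decision threshold, let alone 0.8
  expect_true(all(pred$score[positive == 0] < 0.5))
  expect_false(any(pred$flagged[positive == 0]))
  # one-class training degenerates with a warning
  expect_warning(bm1 <- binary_mode_fit(X, rep(1, 30),
                                        base_learner_spec(n_trees = 10)),
                 "single")
  expect_equal(binary_mode_predict(bm1, X)$score, rep(1, 30))
})
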