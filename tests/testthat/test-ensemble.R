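test_that("balanced subsampling equalizes class sizes deterministically", {
  labels <- c(rep("FarRed", 500), rep("NIR", 30))
  subs <- balanced_subsamples(labels, n = 10, seed = 4)
  expect_length(subs, 10L)
  for (s in subs) {
    expect_length(s, 60L)
    expect_equal(as.integer(table(labels[s])), c(30L, 30L))
    expect_true(all(which(labels == "NIR") %in% s))  # minority rows identical
  }
  expect_gt(length(unique(vapply(subs, paste, character(1),
                                 collapse = ","))), 1L)
  expect_identical(subs, balanced_subsamples(labels, n = 10, seed = 4))
  expect_error(balanced_subsamples(c("A", "A", "B"), seed = 1),
               "fewer than 2")
})

test_that("equal-sized classes yield identical full-row subsamples", {
  labels <- rep(c("Green", "Red"), each = 25)
  subs <- balanced_subsamples(labels, n = 10, seed = 1)
  expect_true(all(vapply(subs, identical, logical(1), y = 1:50)))
})

test_that("majority-row usage across many draws is consistent with uniform sampling", {
  labels <- c(rep("Dark", 120), rep("NIR", 30))
  subs <- balanced_subsamples(labels, n = 100, seed = 8)
  picks <- table(factor(unlist(lapply(subs, function(s)
    s[labels[s] == "Dark"])), levels = 1:120))
  expect_true(all(picks > 0))  # every majority row seen at least once
  chi <- sum((picks - mean(picks))^2 / mean(picks))
  # 119 df; far tail would indicate biased sampling
  expect_lt(chi, qchisq(0.999, df = 119))
})

test_that("the fitted ensemble has 10 pairs x 10 members and is sparse", {
  fit <- fx_model()
  expect_s3_class(fit, "agn_ensemble")
  expect_length(fit$pair_models, 10L)
  n_members <- sum(vapply(fit$pair_models, function(pm) length(pm$members),
                          integer(1)))
  expect_equal(n_members, 100L)
  cf <- coef(fit)
  zero_frac <- mean(vapply(cf, function(p) mean(p$weights == 0), numeric(1)))
  expect_gt(zero_frac, 0.5)  # L1 zeroes most of the 144 weights
})

test_that("a single planted feature yields separable members and extreme sparsity", {
  set.seed(21)
  x <- matrix(rpois(400 * 144, 1), nrow = 400,
              dimnames = list(NULL, feature_names(8)))
  y <- ifelse(x[, "G_0G"] >= 1, "NIR", "Dark")
  # re-plant to balance roughly and remove boundary ambiguity
  x[y == "NIR", "G_0G"] <- x[y == "NIR", "G_0G"] + 2
  fit <- agn_ensemble(x, y, seed = 21, classes = c("Dark", "NIR"))
  pm <- fit$pair_models[[1]]
  for (m in pm$members) {
    margins <- as.numeric(x %*% m$w) + m$b
    expect_equal(mean((margins > 0) == (y == "Dark")), 1)  # Dark is class 1
  }
  w <- vapply(pm$members, function(m) m$w, numeric(144))
  expect_gte(mean(w == 0), 0.9)
})

test_that("pair probabilities complement to one and calibrate the margin", {
  fit <- fx_model()
  set.seed(6)
  seqs <- random_seqs(50)
  for (pair in list(c("Dark", "NIR"), c("Green", "FarRed"))) {
    p <- pair_probability(fit, pair, seqs)
    q <- pair_probability(fit, rev(pair), seqs)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(p + q, rep(1, 50), tolerance = 1e-12)
  }
  expect_error(pair_probability(fit, c("Dark", "Blue"), seqs[1]), "unknown")
  # hand-built members with margins +1 and -1 average to exactly 0.5
  toy <- fit
  toy$pair_models <- list("Dark|NIR" = list(
    pair = c("Dark", "NIR"),
    members = list(list(w = rep(0, 144), b = 1, subsample = 1),
                   list(w = rep(0, 144), b = -1, subsample = 2))))
  p <- pair_probability(toy, c("Dark", "NIR"), seqs[1])
  expect_equal(p, (plogis(1) + plogis(-1)) / 2)
  expect_equal(p, 0.5)
})

test_that("consensus prediction uses the min-over-pairs rule with ordered tie-break", {
  fit <- fx_model()
  set.seed(9)
  seqs <- random_seqs(20)
  pred <- predict(fit, seqs)
  # consensus class attains the maximum of the per-class min scores
  score_cols <- paste0("score_", fit$classes)
  for (i in seq_len(nrow(pred))) {
    sc <- as.numeric(pred[i, score_cols])
    expect_equal(pred$class[i],
                 fit$classes[which.max(sc)])
  }
  # symmetric all-0.5 model: tie flagged, first class in canonical order wins
  toy <- fit
  toy$pair_models <- lapply(fit$pair_models, function(pm) {
    pm$members <- lapply(pm$members, function(m) {
      m$w <- rep(0, 144); m$b <- 0; m })
    pm
  })
  tp <- predict(toy, seqs[1])
  expect_true(tp$tie)
  expect_equal(tp$class, "Dark")
})

test_that("consensus accuracy on a noiseless planted-rule test split is high", {
  d <- fx_dataset()
  fit <- fx_model()
  holdout <- generate_dataset(rule_set(label_noise = 0), n = 600, seed = 4242)
  pred <- predict(fit, holdout$data$sequence)
  expect_gte(mean(pred$class == holdout$data$label), 0.9)
})

test_that("cross-validation learns the planted pair rule and reports all pairs", {
  d <- fx_dataset()
  sub <- d$data$label %in% c("Dark", "FarRed")
  cv <- agn_cv(d$data$sequence[sub], d$data$label[sub], n_repeats = 10,
               seed = 2, classes = c("Dark", "FarRed"))
  expect_equal(nrow(cv$report), 1L)
  expect_gte(cv$report$mean_accuracy, 0.95)
  # full 5-class report has C(5,2) = 10 rows
  cv5 <- agn_cv(d$data$sequence, d$data$label, n_repeats = 2, seed = 2)
  expect_equal(nrow(cv5$report), 10L)
  expect_true(all(cv5$report$mean_accuracy >= 0 &
                  cv5$report$mean_accuracy <= 1))
})

test_that("shuffled labels drive cross-validated accuracy to chance", {
  d <- fx_dataset()
  sub <- which(d$data$label %in% c("Dark", "FarRed"))
  lab <- d$data$label[sub]
  shuf <- with_seed_test(77, sample(lab))
  cv <- agn_cv(d$data$sequence[sub], shuf, n_repeats = 100, seed = 3,
               classes = c("Dark", "FarRed"))
  expect_lt(abs(cv$report$mean_accuracy - 0.5), 0.05)
})

test_that("balanced subsampling beats a raw imbalanced fit on minority recall", {
  rules <- rule_set(proportions = c(Dark = 10 / 11, Green = 0, Red = 0,
                                    FarRed = 0, NIR = 1 / 11))
  d <- generate_dataset(rules, n = 1100, seed = 55)
  test <- generate_dataset(rules, n = 550, seed = 56)
  lab <- d$data$label
  fit <- agn_ensemble(d$data$sequence, lab, seed = 55,
                      classes = c("Dark", "NIR"))
  p_bal <- pair_probability(fit, c("NIR", "Dark"), test$data$sequence)
  recall_bal <- mean(p_bal[test$data$label == "NIR"] > 0.5)
  # single classifier on the raw imbalanced table, same cost
  x <- staple_features(d$data$sequence)
  raw <- agndesign:::fit_member(x, as.integer(lab == "NIR"), cost = 0.1)
  m_raw <- agndesign:::member_margin(raw, staple_features(test$data$sequence))
  recall_raw <- mean(m_raw[test$data$label == "NIR"] > 0)
  expect_gte(recall_bal, recall_raw)
  expect_gte(recall_bal, 0.8)
})

test_that("serialize-load round trip reproduces pair probabilities bit for bit", {
  fit <- fx_model()
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  set.seed(12)
  seqs <- random_seqs(30)
  p1 <- predict(fit, seqs)
  p2 <- predict(back, seqs)
  expect_identical(p1, p2)
})
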