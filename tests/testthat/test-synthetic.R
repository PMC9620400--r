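test_that("noiseless planted rules are perfectly recoverable by the rule itself", {
  d <- generate_dataset(rule_set(label_noise = 0), n = 400, seed = 2)
  relabel <- rule_labels(d$data$sequence, d$rules)
  expect_equal(relabel, d$data$true_label)
  expect_equal(d$data$label, d$data$true_label)   # no noise applied
})

test_that("the same seed reproduces the dataset exactly", {
  a <- generate_dataset(n = 300, seed = 9)
  b <- generate_dataset(n = 300, seed = 9)
  expect_identical(a$data, b$data)
  c <- generate_dataset(n = 300, seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("label noise flips the stated fraction of records", {
  rules <- rule_set(label_noise = 0.2)
  d <- generate_dataset(rules, n = 10000, seed = 8)
  flipped <- mean(d$data$label != d$data$true_label)
  expect_lt(abs(flipped - 0.2), 0.01)
  # flips land uniformly on other classes
  expect_true(all(d$data$label[d$data$label != d$data$true_label] %in%
                  rules$classes))
})

test_that("achieved class proportions track the targets", {
  d <- generate_dataset(rule_set(label_noise = 0), n = 5000, seed = 12)
  prof <- imbalance_profile(d)
  want <- c(Dark = 0.40, Green = 0.12, Red = 0.15, FarRed = 0.30, NIR = 0.03)
  expect_equal(setNames(prof$fraction, prof$class), want, tolerance = 0.02)
  expect_equal(sum(prof$count), 5000L)
  # FarRed:NIR imbalance ~10:1 by construction
  ratio <- prof$count[prof$class == "FarRed"] / prof$count[prof$class == "NIR"]
  expect_lt(abs(ratio - 10) / 10, 0.15)
})

test_that("a zero-proportion class yields zero records", {
  rules <- rule_set(proportions = c(Dark = 0.5, Green = 0, Red = 0,
                                    FarRed = 0.5, NIR = 0))
  d <- generate_dataset(rules, n = 200, seed = 3)
  prof <- imbalance_profile(d)
  expect_equal(prof$count[prof$class %in% c("Green", "Red", "NIR")],
               rep(0L, 3))
})

test_that("rule sets round-trip through JSON with generator-identical output", {
  rules <- rule_set(label_noise = 0.1)
  path <- tempfile(fileext = ".json")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(back, rules)
  expect_identical(generate_dataset(back, n = 100, seed = 6)$data,
                   generate_dataset(rules, n = 100, seed = 6)$data)
})

test_that("rule-set validation rejects inconsistent inputs", {
  expect_error(rule_set(label_noise = 1), "label_noise")
  expect_error(rule_set(proportions = c(Dark = 0.9, Green = 0.2, Red = 0,
                                        FarRed = 0, NIR = 0)), "sum to 1")
  expect_error(rule_set(motifs = list(Dark = c(T_1T = 1),
                                      NIR = numeric(0)),
                        intercepts = c(Dark = 1, NIR = 0),
                        proportions = c(Dark = 0.5, NIR = 0.5)),
               "at least one motif")
})

test_that("synthetic spectra round-trip through the fitting and curation stages", {
  d <- generate_dataset(rule_set(label_noise = 0), n = 40, seed = 20)
  sim <- generate_spectra(d, noise_sd = 0.01, seed = 20)
  cfg <- curation_config(bright_threshold = 0.05)
  hits <- 0; total <- 0
  for (i in seq_len(nrow(sim$truth))) {
    sp <- sim$spectra[[sim$truth$well_id[i]]]
    ps <- fit_peaks(sp$wavelength_nm, sp$intensity)
    ps <- normalize_brightness(ps, sim$control_area)
    if (sim$truth$label[i] == "Dark") {
      expect_equal(attr(ps, "n_components"), 0L)
    } else {
      total <- total + 1
      expect_gte(nrow(ps), 1L)
      expect_lt(abs(ps$lambda_nm[1] - sim$truth$lambda_nm[i]), 2)
      if (classify_peak(ps$lambda_nm[1], cfg) == sim$truth$label[i])
        hits <- hits + 1
    }
  }
  expect_equal(hits, total)   # fitted peaks land in the generating class
})

test_that("XOR-combined motifs defeat the linear members (documented failure mode)", {
  # labels depending on an exclusive-or of two motif presences are outside
  # the linear model class; a planted linear rule is learnable, this is not
  set.seed(33)
  seqs <- random_seqs(1200)
  f <- staple_features(seqs)
  a <- f[, "G_0G"] > 0
  b <- f[, "C_0C"] > 0
  lab <- ifelse(xor(a, b), "NIR", "Dark")
  if (min(table(lab)) > 20) {
    fit <- agn_ensemble(f, lab, seed = 33, classes = c("Dark", "NIR"))
    p <- pair_probability(fit, c("NIR", "Dark"), f)
    acc <- mean((p > 0.5) == (lab == "NIR"))
    expect_lt(acc, 0.9)   # far from the ~1.0 reached on linear rules
  }
})

test_that("zero-noise spectra reproduce generator centers within 1 nm", {
  d <- generate_dataset(rule_set(label_noise = 0), n = 30, seed = 21)
  sim <- generate_spectra(d, noise_sd = 0, seed = 21)
  live <- which(sim$truth$label != "Dark")
  errs <- vapply(live, function(i) {
    sp <- sim$spectra[[sim$truth$well_id[i]]]
    ps <- fit_peaks(sp$wavelength_nm, sp$intensity)
    abs(ps$lambda_nm[1] - sim$truth$lambda_nm[i])
  }, numeric(1))
  expect_true(all(errs < 1))
})
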