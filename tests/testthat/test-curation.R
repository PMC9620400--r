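test_that("peak wavelengths map onto the color-class intervals", {
  expect_equal(classify_peak(c(550, 590, 630, 700, 1041)),
               c("Green", "gap", "Red", "FarRed", "NIR"))
  # boundary convention: gap closed, Red (600,660], FarRed (660,800]
  expect_equal(classify_peak(c(580, 600, 660, 800, 800.01)),
               c("gap", "gap", "Red", "FarRed", "NIR"))
  expect_error(classify_peak(-5), "positive")
})

test_that("training curation applies the label and exclusion rules", {
  cfg <- curation_config(bright_threshold = 0.5)
  rec <- data.frame(
    sequence = c("AAAAAAAAAA",                      # single bright Red
                 "CCCCCCCCCC", "CCCCCCCCCC",       # bright Red + bright NIR
                 "GGGGGGGGGG",                      # brightest in gap
                 "TTTTTTTTTT",                      # mediocre only
                 "ACACACACAC"),                     # dim only -> Dark
    lambda_nm = c(630, 630, 850, 590, 630, 630),
    brightness = c(2, 2, 1.5, 2, 0.4, 0.1))
  cur <- curate_training(rec, all_sequences = "GTGTGTGTGT", config = cfg)
  lab <- setNames(cur$labeled$label, cur$labeled$sequence)
  expect_equal(unname(lab["AAAAAAAAAA"]), "Red")
  expect_equal(unname(lab["ACACACACAC"]), "Dark")
  expect_equal(unname(lab["GTGTGTGTGT"]), "Dark")   # no peaks at all
  exc <- setNames(cur$excluded$reason, cur$excluded$sequence)
  expect_equal(unname(exc["CCCCCCCCCC"]), "multiclass")
  expect_equal(unname(exc["GGGGGGGGGG"]), "gap")
  expect_equal(unname(exc["TTTTTTTTTT"]), "mediocre")
})

test_that("curation partitions its input and is deterministic", {
  set.seed(3)
  n <- 120
  seqs <- random_seqs(n)
  rec <- data.frame(sequence = rep(seqs, each = 2),
                    lambda_nm = runif(2 * n, 450, 1050),
                    brightness = runif(2 * n, 0, 2))
  cur1 <- curate_training(rec)
  cur2 <- curate_training(rec)
  expect_identical(cur1$labeled, cur2$labeled)
  expect_equal(nrow(cur1$labeled) + nrow(cur1$excluded), n)
  expect_equal(anyDuplicated(c(cur1$labeled$sequence,
                               cur1$excluded$sequence)), 0L)
  # labels are consistent with re-applying the rules
  expect_true(all(cur1$labeled$label %in%
                  c("Dark", "Green", "Red", "FarRed", "NIR")))
})

test_that("NIR override labels NIR despite other bright peaks", {
  rec <- data.frame(sequence = rep("ACGTACGTAC", 2),
                    lambda_nm = c(630, 850), brightness = c(2, 1))
  strict <- curate_training(rec, config = curation_config())
  expect_equal(strict$excluded$reason, "multiclass")
  override <- curate_training(
    rec, config = curation_config(nir_overrides_training = TRUE))
  expect_equal(override$labeled$label, "NIR")
})

test_that("design outcomes follow the target-specific success rules", {
  cfg <- curation_config(bright_threshold = 0.5)
  pk <- function(lam, bri) data.frame(lambda_nm = lam, brightness = bri)
  # NIR target succeeds on any bright NIR peak; dual label kept
  out <- evaluate_design_outcome(pk(c(545, 900), c(1, 1)), "NIR", cfg)
  expect_true(out$success)
  expect_setequal(out$labels, c("NIR", "Green"))
  # visible target judged by the brightest visible peak
  out <- evaluate_design_outcome(pk(c(545, 640), c(1, 2)), "Green", cfg)
  expect_false(out$success)
  out <- evaluate_design_outcome(pk(c(545, 640), c(2, 1)), "Green", cfg)
  expect_true(out$success)
  # no peaks at all -> Dark, failure
  out <- evaluate_design_outcome(pk(numeric(0), numeric(0)), "FarRed", cfg)
  expect_false(out$success)
  expect_equal(out$labels, "Dark")
})

test_that("two point masses are clustered exactly", {
  km <- kmeans_cutoffs(c(rep(500, 7), rep(900, 3)), k = 2)
  expect_equal(km$centroids, c(500, 900))
  expect_equal(km$midpoints, 700)
  expect_equal(km$sizes, c(7, 3))
  expect_error(kmeans_cutoffs(1:10, k = 1), "k must be")
})

test_that("DP clustering matches the exhaustive-partition oracle", {
  set.seed(13)
  for (rep in 1:5) {
    x <- c(rnorm(6, 550, 20), rnorm(5, 650, 15), rnorm(5, 800, 25))
    km <- kmeans_cutoffs(x, k = 3)
    orc <- oracle_kmeans_1d(x, 3)
    expect_equal(km$centroids, orc$centroids, tolerance = 1e-9)
    expect_equal(sum(km$withinss), orc$sse, tolerance = 1e-9)
  }
})

test_that("DP clustering is at least as good as multi-start Lloyd", {
  set.seed(29)
  x <- c(rnorm(120, 547, 18), rnorm(150, 637, 12), rnorm(160, 687, 14),
         rnorm(40, 797, 30))
  km <- kmeans_cutoffs(x, k = 4)
  lloyd <- kmeans(x, centers = 4, nstart = 100)
  expect_lte(sum(km$withinss), lloyd$tot.withinss * (1 + 1e-9) + 1e-6)
  expect_equal(sort(km$centroids), km$centroids)      # ascending
  # midpoints strictly interleave centroids
  expect_true(all(km$midpoints > km$centroids[-4] &
                  km$midpoints < km$centroids[-1]))
})
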