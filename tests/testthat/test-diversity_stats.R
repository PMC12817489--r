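test_that("Shannon entropy closed forms and permutation invariance", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon_entropy(c(0.5, 0, 0.5)), 1)  # zeros contribute 0
  set.seed(2)
  f <- stats::runif(6)
  f <- f / sum(f)
  expect_equal(shannon_entropy(f), shannon_entropy(sample(f)))
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.3, 0.3)), "sum to 1")
})

test_that("evenness normalizes by log2(k) with the degenerate case defined", {
  expect_equal(evenness(2, 4), 1)
  expect_equal(evenness(1, 4), 0.5)
  expect_equal(evenness(0, 1), 1)
  expect_error(evenness(3, 4), "exceeds")
  # J = 1 iff uniform
  for (k in c(2, 5, 10))
    expect_equal(evenness(shannon_entropy(rep(1 / k, k)), k), 1)
  expect_lt(evenness(shannon_entropy(c(0.7, 0.1, 0.1, 0.1)), 4), 1)
})

test_that("tf-idf removes ubiquitous and rare-but-weak pair types", {
  # a type present in every structure has idf 0 and is removed
  counts <- rbind(s1 = c(everywhere = 3, rare = 10, weak = 1),
                  s2 = c(everywhere = 1, rare = 0, weak = 1),
                  s3 = c(everywhere = 2, rare = 0, weak = 0))
  out <- tfidf_filter(counts, threshold = 1)
  expect_false(out$retained[out$pair_type == "everywhere"])
  # tf = 10 in 1 of 3 structures: tfidf = 10 ln 3
  expect_equal(out$tfidf[out$pair_type == "rare"], 10 * log(3))
  expect_true(out$retained[out$pair_type == "rare"])
  # tf = 2 in 2 of 3 structures: 2 ln(1.5) < 1, removed
  expect_false(out$retained[out$pair_type == "weak"])
  expect_equal(out$tfidf[out$pair_type == "weak"], 2 * log(1.5))
  # threshold 0 keeps everything except idf-zero types
  out0 <- tfidf_filter(counts, threshold = 0)
  expect_true(all(out0$retained))
  expect_equal(nrow(tfidf_filter(matrix(nrow = 0, ncol = 0))), 0)
})

test_that("PMI is zero at independence for both branches and shifts by log2 c", {
  expect_equal(pmi(0.04, 0.2, 0.2, homogeneous = TRUE), 0)
  expect_equal(pmi(0.08, 0.2, 0.2, homogeneous = FALSE), 0)
  expect_equal(pmi(0.16, 0.2, 0.2, homogeneous = FALSE), 1.0)
  for (c_ in c(1.5, 2, 4)) {
    expect_equal(pmi(c_ * 0.04, 0.2, 0.2, TRUE), log2(c_))
    expect_equal(pmi(c_ * 2 * 0.06 * 0.1, 0.06, 0.1, FALSE), log2(c_))
  }
  expect_true(is.na(pmi(0, 0.2, 0.2, TRUE)))  # missing, not -Inf
  expect_error(pmi(1.2, 0.2, 0.2, TRUE), "frequencies")
})

test_that("coupled frequency fixture recovers its target PMI", {
  fx <- make_frequency_fixture(coupled_pair = c("negative", "positive"),
                               coupling = 2, n_draws = 5e4, seed = 9)
  fr <- pair_class_frequencies(fx$pairs)
  got <- pmi(fr$pair_freq[["negative-positive"]],
             fr$residue_freq[["negative"]], fr$residue_freq[["positive"]],
             homogeneous = FALSE)
  expect_equal(got, fx$expected_pmi, tolerance = 0.05)
  # c = 1: no coupling, PMI ~ 0 everywhere it is defined
  fx1 <- make_frequency_fixture(coupling = 1, n_draws = 5e4, seed = 9)
  fr1 <- pair_class_frequencies(fx1$pairs)
  got1 <- pmi(fr1$pair_freq[["negative-positive"]],
              fr1$residue_freq[["negative"]], fr1$residue_freq[["positive"]],
              homogeneous = FALSE)
  expect_equal(got1, 0, tolerance = 0.05)
  expect_error(make_frequency_fixture(coupling = 0), "positive")
})

test_that("region PMI analysis averages per-complex frequencies", {
  fx <- make_frequency_fixture(coupled_pair = c("negative", "positive"),
                               coupling = 2, n_draws = 2000, seed = 4)
  one <- list(c1 = fx$pairs)
  two <- list(c1 = fx$pairs, c2 = fx$pairs)
  g1 <- c(c1 = "stable")
  g2 <- c(c1 = "stable", c2 = "stable")
  t1 <- region_pmi_analysis(one, g1, region_set = "core",
                            tfidf_threshold = 0)
  t2 <- region_pmi_analysis(two, g2, region_set = "core",
                            tfidf_threshold = 0)
  # duplicating a complex does not change mean-of-frequencies PMI
  expect_equal(t1$pmi, t2$pmi)
  np <- t1[t1$pair_class == "negative-positive", ]
  expect_equal(np$pmi, 1, tolerance = 0.25)
  expect_error(region_pmi_analysis(one, c(c1 = NA)), "no complexes")
})

test_that("Wilson interval matches its closed form and boundary behavior", {
  expect_equal(unname(wilson_interval(0, 10, 0.95)[1]), 0)
  expect_equal(unname(wilson_interval(10, 10, 0.95)[2]), 1)
  # independent evaluation of the closed form at 5/10
  z <- stats::qnorm(0.975)
  center <- (0.5 + z^2 / 20) / (1 + z^2 / 10)
  half <- z / (1 + z^2 / 10) * sqrt(0.025 + z^2 / 400)
  expect_equal(unname(wilson_interval(5, 10, 0.95)),
               c(center - half, center + half), tolerance = 1e-12)
  expect_equal(round(unname(wilson_interval(5, 10, 0.95)), 4),
               c(0.2366, 0.7634))
  expect_error(wilson_interval(11, 10), "invalid")
})

test_that("probability of superiority equals brute force on small samples", {
  expect_equal(probability_of_superiority(c(1, 2, 3), 0), 1.0)
  expect_equal(probability_of_superiority(c(1, 2), c(1, 2)), 0.5)
  expect_equal(probability_of_superiority(c(1, 3), 2), 0.5)
  brute <- function(xs, ys) {
    tot <- 0
    for (x in xs) for (y in ys)
      tot <- tot + (x > y) + 0.5 * (x == y)
    tot / (length(xs) * length(ys))
  }
  set.seed(13)
  for (rep in 1:25) {
    xs <- sample(0:4, sample(1:6, 1), replace = TRUE)
    ys <- sample(0:4, sample(1:6, 1), replace = TRUE)
    expect_equal(probability_of_superiority(xs, ys), brute(xs, ys))
  }
  expect_error(probability_of_superiority(numeric(0), 1), "empty")
})

test_that("bootstrap intervals are deterministic, degenerate-aware and calibrated", {
  x <- c(1, 2, 3, 4, 5)
  b1 <- bootstrap_ci(mean, x, n_boot = 500, seed = 42)
  b2 <- bootstrap_ci(mean, x, n_boot = 500, seed = 42)
  expect_identical(b1, b2)
  const <- bootstrap_ci(function(d) 7, x, n_boot = 100, seed = 1)
  expect_equal(c(const$lo, const$hi), c(7, 7))
  expect_true(const$degenerate)
  # coverage of the mean of a standard normal sample
  set.seed(99)
  cover <- vapply(1:120, function(i) {
    d <- stats::rnorm(60)
    ci <- bootstrap_ci(mean, d, n_boot = 300, seed = i)
    ci$lo <= 0 && 0 <= ci$hi
  }, logical(1))
  expect_gt(mean(cover), 0.85)
  # intervals shrink with sample size, in expectation
  set.seed(7)
  big <- stats::rnorm(400)
  w_small <- bootstrap_ci(mean, big[1:50], n_boot = 300, seed = 3)
  w_big <- bootstrap_ci(mean, big, n_boot = 300, seed = 3)
  expect_lt(w_big$hi - w_big$lo, w_small$hi - w_small$lo)
})
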