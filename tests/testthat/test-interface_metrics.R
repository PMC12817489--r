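fake_regions <- function(resnames, regions, asa_mono = NULL,
                         asa_cplx = NULL) {
  n <- length(resnames)
  data.frame(
    key = paste0("A:", seq_len(n), ":"),
    chain = "A", resno = seq_len(n), insert = "",
    resname = resnames, region = regions,
    asa_monomer = if (is.null(asa_mono)) rep(100, n) else asa_mono,
    asa_complex = if (is.null(asa_cplx)) rep(50, n) else asa_cplx,
    stringsAsFactors = FALSE
  )
}

test_that("region composition percentages are correct and sum to 100", {
  rg <- fake_regions(c("ARG", "LYS", "ASP", "LEU"), rep("core", 4))
  comp <- region_composition(rg, "charge")
  expect_equal(comp$positive[comp$region == "core"], 50)
  expect_equal(comp$negative[comp$region == "core"], 25)
  expect_equal(comp$neutral[comp$region == "core"], 25)
  expect_equal(sum(comp[comp$region == "core", -1]), 100)
})

test_that("class partitioning across interface regions sums to one", {
  rg <- fake_regions(c("ARG", "LYS", "ARG", "HIS"),
                     c("core", "core", "support", "rim_interacting"))
  p <- partition_by_region(rg, "positive", "charge")
  expect_equal(unname(p), c(0.5, 0.25, 0.25, 0))
  expect_equal(sum(p), 1)
  rg2 <- fake_regions(c("ARG", "LYS"), c("support", "support"))
  expect_equal(unname(partition_by_region(rg2, "positive")), c(0, 1, 0, 0))
  # absent class is missing, not zero
  expect_true(all(is.na(partition_by_region(rg2, "negative"))))
  # randomized placement matches a brute-force tally
  set.seed(11)
  res <- sample(c("ARG", "LYS", "HIS"), 40, replace = TRUE)
  reg <- sample(c("core", "support", "rim_interacting", "rim_nis"),
                40, replace = TRUE)
  rg3 <- fake_regions(res, reg)
  p3 <- partition_by_region(rg3, "positive")
  tallied <- table(factor(reg, levels = c("core", "support",
                                          "rim_interacting", "rim_nis")))
  expect_equal(unname(p3), as.numeric(tallied) / sum(tallied))
})

test_that("stickiness is the log ratio of area fractions", {
  s <- stickiness(c(ALA = 10, LEU = 10), c(ALA = 10, LEU = 10))
  expect_equal(unname(s), c(0, 0), tolerance = 1e-4)
  s2 <- stickiness(c(ALA = 20, LEU = 10), c(ALA = 10, LEU = 20))
  expect_equal(unname(s2[["ALA"]]), log(2), tolerance = 1e-4)
  # random vectors against direct evaluation
  set.seed(3)
  ia <- stats::setNames(stats::runif(5, 1, 100),
                        c("ALA", "ARG", "TRP", "SER", "GLY"))
  sa <- stats::setNames(stats::runif(5, 1, 100), names(ia))
  got <- stickiness(ia, sa, eps = 0)
  expect_equal(unname(got), unname(log((ia / sum(ia)) / (sa / sum(sa)))))
  expect_error(stickiness(c(ALA = 0), c(ALA = 0)), "zero total")
  # type absent from both sides is missing, not zero
  s3 <- stickiness(c(ALA = 10, TRP = 0), c(ALA = 10, TRP = 0))
  expect_true(is.na(s3[["TRP"]]))
})

test_that("same-region and cross-region interaction counting are exact", {
  records <- data.frame(
    type = c("salt_bridge", "hbond"),
    key1 = c("A:1:", "A:2:"), key2 = c("B:1:", "B:2:"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    key1 = c("A:1:", "A:2:"), key2 = c("B:1:", "B:2:"),
    region1 = c("core", "core"), region2 = c("core", "rim_interacting"),
    stringsAsFactors = FALSE)
  same <- count_interactions_by_region(records, pairs, "same_region")
  expect_equal(nrow(same), 1)
  expect_equal(same$region, "core")
  expect_equal(same$type, "salt_bridge")
  cross <- count_interactions_by_region(records, pairs, "cross_region")
  expect_equal(cross$region, "corexrim_interacting")
  expect_equal(cross$count, 1)
})

test_that("mean count per capable pair uses capable pairs as denominator", {
  # 4 capable LYS-ASP pairs, one of which forms a salt bridge
  candidates <- data.frame(
    key1 = paste0("A:", 1:5, ":"), key2 = paste0("B:", 1:5, ":"),
    res1 = c("LYS", "LYS", "LYS", "LYS", "LYS"),
    res2 = c("ASP", "ASP", "ASP", "ASP", "LEU"),
    stringsAsFactors = FALSE)
  records <- data.frame(type = "salt_bridge", key1 = "A:1:", key2 = "B:1:",
                        stringsAsFactors = FALSE)
  r <- mean_count_per_pair(records, candidates, type = "salt_bridge")
  expect_equal(r$n_capable, 4)  # the LYS-LEU pair is incapable
  expect_equal(r$mean, 0.25)
  expect_true(r$binary)
  expect_equal(c(r$lo, r$hi), unname(wilson_interval(1, 4, 0.95)),
               tolerance = 1e-12)
  # count-valued type: mean over counts {2, 1, 0}
  cand3 <- candidates[1:3, ]
  recs3 <- data.frame(
    type = "hbond",
    key1 = c("A:1:", "A:1:", "A:2:"), key2 = c("B:1:", "B:1:", "B:2:"),
    stringsAsFactors = FALSE)
  r3 <- mean_count_per_pair(recs3, cand3, type = "hbond")
  expect_equal(r3$mean, 1.0)
  expect_false(r3$binary)
  # invariant to adding incapable pairs to the candidate set
  cand_extra <- rbind(candidates,
                      data.frame(key1 = "A:9:", key2 = "B:9:",
                                 res1 = "LEU", res2 = "LEU"))
  r_extra <- mean_count_per_pair(records, cand_extra, type = "salt_bridge")
  expect_equal(r_extra$mean, r$mean)
  # zero capable pairs: missing
  expect_null(mean_count_per_pair(records, candidates[5, ],
                                  type = "salt_bridge"))
})

test_that("pair-BSA scaling doubles same-region pairs and merges the rim", {
  mk_pairs <- function(regions1, regions2) {
    data.frame(key1 = paste0("A:", seq_along(regions1), ":"),
               key2 = paste0("B:", seq_along(regions1), ":"),
               region1 = regions1, region2 = regions2,
               stringsAsFactors = FALSE)
  }
  cd <- list(list(
    pairs = mk_pairs(c("core", "core", "core", "rim_nis"),
                     c("core", "core", "core", "rim_interacting")),
    bsa_by_region = c(core = 100, support = 20, rim_interacting = 30,
                      rim_nis = 10)))
  sc_core <- pair_bsa_scaling(cd, "core")
  expect_equal(sc_core$points$y, 6)  # 3 same-region core pairs, doubled
  expect_equal(sc_core$points$x, 100)
  # rim merges rim_interacting and rim_nis, for pairs and for BSA
  sc_rim <- pair_bsa_scaling(cd, "rim")
  expect_equal(sc_rim$points$y, 2)
  expect_equal(sc_rim$points$x, 40)
  expect_null(sc_core$fit)  # a single point cannot be fitted
})

test_that("pair-BSA scaling recovers a generating slope", {
  set.seed(5)
  cds <- lapply(1:60, function(i) {
    x <- stats::runif(1, 50, 400)
    y_target <- max(0, round((1.2 * x + stats::rnorm(1, 0, 12)) / 2))
    pairs <- if (y_target > 0)
      data.frame(key1 = paste0("A:", seq_len(y_target), ":"),
                 key2 = paste0("B:", seq_len(y_target), ":"),
                 region1 = "support", region2 = "support",
                 stringsAsFactors = FALSE)
    else data.frame(key1 = character(0), key2 = character(0),
                    region1 = character(0), region2 = character(0))
    list(pairs = pairs, bsa_by_region = c(core = 0, support = x,
                                          rim_interacting = 0, rim_nis = 0))
  })
  fit <- pair_bsa_scaling(cds, "support")$fit
  expect_equal(fit$slope, 1.2, tolerance = 0.05)
  expect_gt(fit$r_squared, 0.9)
})
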