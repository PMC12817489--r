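# a small manifest of synthetic dimers written as PDB files
build_test_manifest <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  models <- list(
    sb = make_interaction_geometry("salt_bridge", positive = TRUE)$model,
    hb = make_interaction_geometry("hbond", positive = TRUE)$model,
    bd = make_burial_dimer(labels = c("core", "rim_interacting", "surface"),
                           verify = FALSE)$model
  )
  paths <- vapply(names(models), function(id) {
    p <- file.path(dir, paste0(id, ".pdb"))
    write_pdb_file(models[[id]], p)
    p
  }, character(1))
  man <- data.frame(
    structure_id = names(models),
    path = unname(paths),
    group_a = "A", group_b = "B",
    affinity = c(1e-10, 5e-8, 100),
    affinity_kind = c("KD", "KD", "KD"),
    affinity_unit = c("M", "M", "uM"),
    stringsAsFactors = FALSE
  )
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  mf
}

test_that("stability classification follows the log10-affinity cutoffs", {
  expect_equal(classify_stability(-5), "transient")
  expect_equal(classify_stability(-9.5), "stable")
  expect_equal(classify_stability(-6), "intermediate")   # boundary
  expect_equal(classify_stability(-9), "intermediate")   # boundary
  expect_equal(classify_stability(-7), "intermediate")
  expect_equal(classify_stability(c(-5, -7, -10)),
               c("transient", "intermediate", "stable"))
  expect_error(classify_stability(NaN), "non-finite")
})

test_that("affinity unit conversion lands on the molar log scale", {
  expect_equal(log10_affinity(1, "uM"), -6)
  expect_equal(log10_affinity(1, "nM"), -9)
  expect_equal(log10_affinity(1e-7, "M"), -7)
  expect_error(log10_affinity(1, "furlongs"), "unknown affinity unit")
})

test_that("manifest reading annotates affinity and stability", {
  mf <- build_test_manifest()
  man <- read_manifest(mf)
  expect_equal(man$stability, c("stable", "intermediate", "transient"))
  expect_equal(man$log10_affinity, c(-10, log10(5e-8), -4))
})

test_that("run_complex composes the full per-complex pipeline", {
  fx <- make_interaction_geometry("salt_bridge", positive = TRUE)
  cfgr <- run_config(n_points = 240)
  s <- run_complex(fx$model, "A", "B", cfgr)
  expect_s3_class(s, "complex_summary")
  expect_true("salt_bridge" %in% s$records$type)
  expect_gte(nrow(s$pairs), 1)
  expect_equal(nrow(s$regions), 2)
  expect_gt(s$bsa$total, 0)
  # far-apart chains: no interface, no interactions
  far <- make_burial_dimer(labels = "surface", verify = FALSE)
  s2 <- run_complex(far$model, "A", "B", cfgr)
  expect_equal(s2$bsa$total, 0, tolerance = 1e-9)
  expect_equal(nrow(s2$records), 0)
})

test_that("the pipeline is deterministic and conserves its bookkeeping", {
  mf <- build_test_manifest()
  man <- read_manifest(mf)
  cfgr <- run_config(n_points = 240)
  run1 <- run_manifest(man, cfgr)
  run2 <- run_manifest(man, cfgr)
  expect_equal(length(run1$failures), 0)
  # byte-identical output tables on re-run with the same config
  t1 <- tempfile()
  t2 <- tempfile()
  utils::write.table(run1$summaries$sb$regions, t1, sep = "\t")
  utils::write.table(run2$summaries$sb$regions, t2, sep = "\t")
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  expect_identical(run1$summaries$sb$regions, run2$summaries$sb$regions)
  expect_identical(run1$summaries$bd$records, run2$summaries$bd$records)
  # BSA partition sums to the total for every complex
  for (s in run1$summaries)
    expect_equal(sum(s$bsa$by_region), s$bsa$total, tolerance = 1e-9)
  # stability groups partition the manifest
  agg <- aggregate_dataset(run1, cfgr)
  expect_equal(sum(agg$stability_counts), nrow(man))
})

test_that("aggregation is invariant to manifest order", {
  mf <- build_test_manifest()
  man <- read_manifest(mf)
  cfgr <- run_config(n_points = 240)
  a1 <- aggregate_dataset(run_manifest(man, cfgr), cfgr)
  a2 <- aggregate_dataset(run_manifest(man[c(3, 1, 2), ], cfgr), cfgr)
  expect_equal(a1$stability_counts, a2$stability_counts)
  expect_equal(a1$bsa_fractions, a2$bsa_fractions)
  for (r in names(a1$scaling))
    expect_setequal(
      paste(round(a1$scaling[[r]]$points$x, 6), a1$scaling[[r]]$points$y),
      paste(round(a2$scaling[[r]]$points$x, 6), a2$scaling[[r]]$points$y))
})

test_that("failures are quarantined without aborting the run", {
  mf <- build_test_manifest()
  man <- read_manifest(mf)
  man$path[2] <- "/nonexistent/file.pdb"
  run <- run_manifest(man, run_config(n_points = 240))
  expect_equal(names(run$failures), "hb")
  expect_setequal(names(run$summaries), c("sb", "bd"))
})
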