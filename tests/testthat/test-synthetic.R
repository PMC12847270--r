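test_that("default design yields 30 rows per table and unique design keys", {
  ds <- generate_dataset(default_calibration(seed = 2))
  for (tab in list(ds$sieve, ds$chem, ds$copies)) {
    expect_equal(nrow(tab), 30)
    expect_false(anyDuplicated(tab[c("treatment", "depth", "replicate")]) > 0)
  }
  expect_equal(dim(ds$counts), c(30L, 200L))
  expect_equal(unname(rowSums(ds$counts)), rep(20000L, 30))
})

test_that("a fixed seed reproduces the dataset byte-for-byte", {
  cfg <- default_calibration(seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in c("sieve.csv", "chem.csv", "copies.csv", "counts.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # and a different seed does not
  cfg2 <- default_calibration(seed = 100)
  expect_false(identical(generate_dataset(cfg2)$chem$SOM,
                         generate_dataset(cfg)$chem$SOM))
  # generating a subset of tables leaves the shared draws unchanged
  expect_identical(generate_dataset(cfg, tables = "copies")$copies,
                   generate_dataset(cfg)$copies)
})

test_that("zero noise collapses every replicate onto its expected mean", {
  cfg <- default_calibration(seed = 5, noise_cv = 0)
  ds <- generate_dataset(cfg)
  m <- cfg$effect_multipliers
  for (v in c("SOM", "pH")) {
    expect_equal(ds$chem[[v]],
                 cfg$baseline_means[v, ds$chem$depth] *
                   m[v, , ][cbind(ds$chem$treatment, ds$chem$depth)],
                 ignore_attr = TRUE)
  }
  expect_equal(ds$copies$bacterial_copies,
               cfg$baseline_means["bacterial_copies", ds$copies$depth] *
                 m["bacterial_copies", , ][cbind(ds$copies$treatment,
                                                 ds$copies$depth)],
               ignore_attr = TRUE)
  # replicates within a treatment x depth cell are identical
  expect_equal(ds$sieve$class_gt2[1], ds$sieve$class_gt2[2])
})

test_that("sieve fraction masses always sum to the configured total", {
  cfg <- default_calibration(seed = 6)
  ds <- generate_dataset(cfg, tables = "sieve")
  cols <- grep("^class_", names(ds$sieve))
  expect_equal(unname(rowSums(ds$sieve[cols])), rep(50, 30),
               tolerance = 1e-9)
  cfg2 <- synth_config(seed = 6, total_sieve_mass_g = 12.5)
  ds2 <- generate_dataset(cfg2, tables = "sieve")
  expect_equal(unname(rowSums(ds2$sieve[cols])), rep(12.5, 30),
               tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(noise_cv = -0.1), class = "psq_config_error")
  expect_error(synth_config(total_sieve_mass_g = 0), class = "psq_config_error")
  bm <- matrix(c(1, -1), 1, 2, dimnames = list("SOM", c("D0_20", "D20_40")))
  expect_error(synth_config(baseline_means = bm), class = "psq_config_error")
  cfg <- default_calibration()
  bad <- cfg$effect_multipliers
  bad["SOM", "IO", "D0_20"] <- 0
  expect_error(synth_config(baseline_means = cfg$baseline_means,
                            effect_multipliers = bad),
               class = "psq_config_error")
})

test_that("default calibration anchors on the published gene-copy means", {
  cfg <- default_calibration()
  expect_equal(cfg$baseline_means["bacterial_copies", "D0_20"], 1.654e7)
  expect_equal(cfg$baseline_means["fungal_copies", "D20_40"], 1.71e6)
  expect_equal(cfg$baseline_means["bacterial_copies", "D20_40"], 1.29e7)
  expect_equal(cfg$baseline_means["fungal_copies", "D0_20"], 2.60e6)
  # multipliers reproduce the published treatment means exactly
  tab <- gene_copy_table()
  for (v in c("bacterial_copies", "fungal_copies")) {
    for (d in c("D0_20", "D20_40")) {
      sub <- tab[tab$variable == v & tab$depth == d, ]
      means <- setNames(sub$mean, sub$treatment)
      expect_equal(cfg$baseline_means[v, d] *
                     cfg$effect_multipliers[v, names(means), d],
                   means, tolerance = 1e-12)
    }
  }
  # chemistry baselines are placeholder scale values, multipliers encode
  # the reported percent effects
  expect_equal(cfg$baseline_means["SOM", "D0_20"], 20)
  expect_equal(cfg$effect_multipliers["SOM", "IS", "D0_20"], 1.1698)
})
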