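test_that("one-way ANOVA matches the textbook closed form", {
  r <- anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(r$F, 1.5) # SSB = 1.5, SSW = 4, df = (1, 4)
  expect_equal(r$df_between, 1)
  expect_equal(r$df_within, 4)

  r0 <- anova_oneway(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(r0$F, 0)

  # invariance under relabeling and under adding a constant
  set.seed(61)
  x <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  r1 <- anova_oneway(x, g)
  r2 <- anova_oneway(x, chartr("abc", "zyx", g))
  r3 <- anova_oneway(x + 100, g)
  expect_equal(r1$F, r2$F)
  expect_equal(r1$F, r3$F)

  # independent route: stats::oneway.test with pooled variances
  ow <- stats::oneway.test(x ~ factor(g), var.equal = TRUE)
  expect_equal(r1$F, unname(ow$statistic), tolerance = 1e-12)
  expect_equal(r1$p_value, unname(ow$p.value), tolerance = 1e-12)

  expect_error(anova_oneway(1:3, c("a", "a", "b")), ">= 2 groups")
})

test_that("summary-statistic ANOVA agrees with the raw-data ANOVA", {
  set.seed(62)
  x <- c(rnorm(10, 1.6, 1.1), rnorm(9, 1.4, 0.7), rnorm(11, 1.3, 0.7))
  g <- rep(c("p1", "p2", "p3"), c(10, 9, 11))
  raw <- anova_oneway(x, g)
  n <- tapply(x, g, length)
  m <- tapply(x, g, mean)
  s <- tapply(x, g, sd)
  summ <- anova_from_summary(as.integer(n), as.numeric(m), as.numeric(s),
                             names(n))
  expect_equal(summ$F, raw$F, tolerance = 1e-12)
  expect_equal(summ$p_value, raw$p_value, tolerance = 1e-12)
  expect_equal(summ$df_within, raw$df_within)
})

test_that("the pipeline runs end to end on a planted library", {
  specs <- list(planted_family("A60", 60, 0.6, target_abundance = 0.01,
                               copy_divergence_mean = 2))
  lib <- build_library(specs, genome_size = 4e5, coverage = 8, seed = 42)
  cfg <- pipeline_config(seed = 1, discovery_pairs = 8000L,
                         quant_pairs = 10000L)
  d <- withr::local_tempdir()
  run <- run_pipeline(lib, "Tst", cfg, out_dir = d)
  expect_equal(nrow(run$catalog), 1)
  expect_match(run$catalog$name, "^TstSat01-")
  truth_fr <- manifest_fractions(lib)[["A60"]]
  expect_lt(abs(run$catalog$abundance - truth_fr) / truth_fr, 0.2)
  expect_gte(similarity(run$catalog$consensus, lib$truth$monomer[1]), 95)
  expect_true(file.exists(file.path(d, "Tst_catalog.fasta")))
  expect_true(file.exists(file.path(d, "Tst_rounds.tsv")))

  # determinism: identical config, identical catalog
  run2 <- run_pipeline(lib, "Tst", cfg)
  expect_identical(run2$catalog$consensus, run$catalog$consensus)
  expect_equal(run2$catalog$abundance, run$catalog$abundance)

  # unknown config entries and missing divergence times fail fast
  expect_error(pipeline_config(bogus = 1), "unknown config")
  other <- tibble::tibble(label = "x", consensus = lib$truth$monomer[1])
  expect_error(run_pipeline(lib, "Tst", cfg, compare_catalogs = list(Oth = other)),
               "configuration error")
})

test_that("pipeline comparison recovers shared families across species", {
  sp <- c("Aaa", "Bbb")
  times <- setNames(1e7, species_pair_key("Aaa", "Bbb"))
  sc <- make_species_scenario(sp, times, n_shared = 2, n_private = 0,
                              rate = 1e-9, shared_lengths = c(60, 90),
                              seed = 8)
  # build a read library for species Aaa from its true catalog
  cat_a <- sc$catalogs$Aaa
  specs <- lapply(seq_len(nrow(cat_a)), function(i)
    planted_family(cat_a$label[i], cat_a$monomer_length[i],
                   target_abundance = c(0.01, 0.006)[i],
                   copy_divergence_mean = 2, monomer = cat_a$consensus[i]))
  lib <- build_library(specs, genome_size = 3e5, coverage = 10, seed = 9)
  cfg <- pipeline_config(seed = 1, discovery_pairs = 8000L,
                         quant_pairs = 8000L, times_years = times)
  run <- run_pipeline(lib, "Aaa", cfg,
                      compare_catalogs = list(Bbb = sc$catalogs$Bbb))
  expect_equal(nrow(run$catalog), 2)
  expect_equal(nrow(run$comparison$pairs), 2)
  # at this shallow divergence the conserved pairs stay nearly identical
  expect_true(all(run$comparison$pairs$similarity > 80))
  expect_true(all(run$comparison$pairs$T_years == 1e7))
})
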