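test_that("make_monomer hits the requested composition deterministically", {
  m <- make_monomer(24, 0.666, seed = 1)
  expect_equal(nchar(m), 24)
  expect_equal(sum(strsplit(m, "")[[1]] %in% c("A", "T")), 16) # round(0.666*24)

  gc <- make_monomer(10, 0, seed = 1)
  expect_false(grepl("[AT]", gc))

  expect_identical(make_monomer(30, 0.533, seed = 7),
                   make_monomer(30, 0.533, seed = 7))
  expect_error(make_monomer(9, 0.5), ">= 10")
  expect_error(make_monomer(20, 1.5), "\\[0, 1\\]")
})

test_that("evolve_sequence follows the K2P substitution process", {
  set.seed(5)
  s <- random_seq(500)
  expect_identical(evolve_sequence(s, 0, 1e7), s)
  expect_error(evolve_sequence(s, -1, 10), ">= 0")

  # single lineage: mean K2P estimate ~ rate * time = 0.74
  anc <- random_seq(1000)
  ks <- vapply(1:40, function(i) {
    der <- evolve_sequence(anc, 1.85e-8, 40e6, ts_tv_ratio = 2, seed = 1000 + i)
    seq_distance(anc, der)$K
  }, 0)
  expect_equal(mean(ks, na.rm = TRUE), 0.74, tolerance = 0.08)

  # two independent lineages from one ancestor: K2P ~ 2 * rate * T
  k2 <- vapply(1:25, function(i) {
    a <- evolve_sequence(anc, 1e-8, 30e6, seed = 2000 + i)
    b <- evolve_sequence(anc, 1e-8, 30e6, seed = 3000 + i)
    seq_distance(a, b)$K
  }, 0)
  expect_equal(mean(k2, na.rm = TRUE), 2 * 1e-8 * 30e6, tolerance = 0.08)

  # K2P estimate grows on average with rate x time
  k_lo <- mean(vapply(1:15, function(i)
    seq_distance(anc, evolve_sequence(anc, 1e-9, 40e6, seed = 4000 + i))$K, 0))
  k_hi <- mean(vapply(1:15, function(i)
    seq_distance(anc, evolve_sequence(anc, 8e-9, 40e6, seed = 5000 + i))$K, 0))
  expect_gt(k_hi, k_lo)
})

test_that("build_library plants families at their target fractions", {
  specs <- list(planted_family("fam", 42, 0.6, target_abundance = 0.01,
                               copy_divergence_mean = 2))
  lib <- build_library(specs, genome_size = 1e6, coverage = 10, seed = 42)
  fr <- manifest_fractions(lib)
  expect_true(fr[["fam"]] > 0.009 && fr[["fam"]] < 0.011)
  expect_equal(nrow(lib$manifest), length(lib$fwd))
  expect_true(all(nchar(lib$fwd) == lib$read_length))
  expect_true(all(nchar(lib$rev) == lib$read_length))

  # zero specs: all background
  bg <- build_library(list(), genome_size = 2e5, coverage = 4, seed = 3)
  expect_true(all(bg$manifest$origin == "background"))

  # abundance accumulates toward the target as coverage grows
  lo <- build_library(specs, genome_size = 5e5, coverage = 2, seed = 9)
  hi <- build_library(specs, genome_size = 5e5, coverage = 30, seed = 9)
  expect_lt(abs(manifest_fractions(hi)[["fam"]] - 0.01),
            abs(manifest_fractions(lo)[["fam"]] - 0.01) + 0.002)

  too_much <- list(planted_family("a", 50, 0.5, target_abundance = 0.6),
                   planted_family("b", 50, 0.5, target_abundance = 0.5))
  expect_error(build_library(too_much, 1e5), "sum to < 1")
  expect_error(build_library(list(planted_family("x", 200, 0.5,
                                                 target_abundance = 1e-4)),
                             genome_size = 1e5), "< 2 monomer copies")
})

test_that("library generation and FASTQ export are seed-deterministic", {
  specs <- list(planted_family("fam", 60, 0.5, target_abundance = 0.02))
  l1 <- build_library(specs, genome_size = 1e5, coverage = 3, seed = 77)
  l2 <- build_library(specs, genome_size = 1e5, coverage = 3, seed = 77)
  expect_identical(l1$fwd, l2$fwd)
  expect_identical(l1$rev, l2$rev)

  d <- withr::local_tempdir()
  write_library_fastq(l1, file.path(d, "a"))
  write_library_fastq(l2, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a_1.fastq")),
                   readLines(file.path(d, "b_1.fastq")))
  expect_identical(readLines(file.path(d, "a_2.fastq")),
                   readLines(file.path(d, "b_2.fastq")))

  rt <- read_library_fastq(file.path(d, "a"))
  expect_identical(rt$fwd, l1$fwd)
  expect_identical(rt$rev, l1$rev)
  expect_identical(rt$manifest$origin, l1$manifest$origin)
})

test_that("species scenarios share ancestral monomers that drift apart", {
  sp <- c("Aaa", "Bbb")
  times <- setNames(4e7, species_pair_key("Aaa", "Bbb"))

  # zero rate: identical monomers across species
  sc0 <- make_species_scenario(sp, times, n_shared = 3, n_private = 1,
                               rate = 0, shared_lengths = 120, seed = 2)
  for (lab in sc0$truth$shared_labels) {
    a <- sc0$catalogs$Aaa$consensus[sc0$catalogs$Aaa$label == lab]
    b <- sc0$catalogs$Bbb$consensus[sc0$catalogs$Bbb$label == lab]
    expect_identical(a, b)
    expect_equal(similarity(a, b), 100)
  }

  # missing time entry is a configuration error
  expect_error(make_species_scenario(c("Aaa", "Bbb", "Ccc"), times,
                                     n_shared = 2),
               "missing divergence time")

  # three species: one row per shared family per species pair
  t3 <- setNames(c(4e7, 4e7, 3.49e7),
                 c(species_pair_key("Aaa", "Bbb"),
                   species_pair_key("Aaa", "Ccc"),
                   species_pair_key("Bbb", "Ccc")))
  sc3 <- make_species_scenario(c("Aaa", "Bbb", "Ccc"), t3, n_shared = 4,
                               n_private = 1, rate = 1e-9,
                               shared_lengths = 150, seed = 4)
  rec <- scenario_ctr_recovery(sc3, pairing = "truth")
  expect_equal(nrow(rec), 4 * 3)

  d <- withr::local_tempdir()
  fp <- write_scenario_config(sc3, file.path(d, "scen"))
  cfg <- readLines(file.path(d, "scen_config.txt"))
  expect_true(any(grepl("^substitution_rate = 1e-09", cfg)))
  anc <- Biostrings::readDNAStringSet(file.path(d, "scen_ancestral.fasta"))
  expect_equal(length(anc), 4)
  expect_equal(sort(unique(rec$species_pair)),
               sort(unname(c(species_pair_key("Aaa", "Bbb"),
                             species_pair_key("Aaa", "Ccc"),
                             species_pair_key("Bbb", "Ccc")))))
})
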