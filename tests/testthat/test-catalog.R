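# helper: mutate a fraction of positions, avoiding back-mutations
mutate_frac <- function(s, frac, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  pos <- sample(length(v), round(frac * length(v)))
  v[pos] <- flip[v[pos]]
  paste(v, collapse = "")
}

test_that("tiering collapses same-variant candidates and groups the rest", {
  set.seed(41)
  base <- random_seq(100)
  cand <- tibble::tibble(
    consensus = c(base,
                  base,                          # exact duplicate (SV)
                  mutate_frac(base, 0.15, 1),    # ~85 % similar (V)
                  mutate_frac(base, 0.40, 2),    # ~60 % similar (SF)
                  random_seq(100)),              # unrelated
    abundance = c(0.05, 0.04, 0.03, 0.02, 0.01))
  fam <- tier_and_dedupe(cand)
  expect_equal(nrow(fam), 4) # duplicate collapsed
  expect_equal(fam$abundance[1], 0.05) # higher-abundance consensus kept

  # no retained pair above the SV threshold
  for (i in seq_len(nrow(fam) - 1)) for (j in seq(i + 1, nrow(fam))) {
    expect_lte(similarity(fam$consensus[i], fam$consensus[j]), 95)
  }

  # the 85 % pair shares a variant group, the 60 % one only a superfamily
  expect_equal(fam$variant_group[1], fam$variant_group[2])
  expect_false(is.na(fam$variant_group[1]))
  expect_true(is.na(fam$variant_group[3]))
  expect_equal(fam$superfamily_id[1], fam$superfamily_id[3])
  expect_true(is.na(fam$superfamily_id[4]))
})

test_that("contaminant screening drops matching candidates", {
  set.seed(43)
  te <- random_seq(120)
  cand <- tibble::tibble(consensus = c(te, random_seq(120)),
                         abundance = c(0.02, 0.01))
  fam <- tier_and_dedupe(cand, contaminants = te)
  expect_equal(nrow(fam), 1)
  expect_equal(fam$consensus, cand$consensus[2])
})

test_that("catalog naming follows the abundance-sorted convention", {
  set.seed(45)
  fams <- tibble::tibble(
    consensus = c(random_seq(206), random_seq(650)),
    monomer_length = c(206L, 650L),
    abundance = c(0.0027586, 0.0041737))
  named <- name_catalog(fams, "Mti")
  expect_equal(named$name, c("MtiSat01-650", "MtiSat02-206"))

  single <- name_catalog(fams[1, ], "Xyz")
  expect_equal(single$name, "XyzSat01-206")

  # ties: the shorter monomer takes the lower index
  tied <- tibble::tibble(consensus = c(random_seq(60), random_seq(40)),
                         monomer_length = c(60L, 40L),
                         abundance = c(0.01, 0.01))
  named2 <- name_catalog(tied, "Abc")
  expect_equal(named2$name, c("AbcSat01-40", "AbcSat02-60"))

  # renaming is idempotent
  again <- name_catalog(named, "Mti")
  expect_equal(again$name, named$name)

  p <- parse_sat_name("MtiSat01-650")
  expect_equal(p$species_prefix, "Mti")
  expect_equal(p$catalog_index, 1L)
  expect_equal(p$monomer_length, 650L)
  expect_error(parse_sat_name("nonsense"), "malformed")
})

test_that("catalog summaries compute order statistics as documented", {
  s <- summarize_catalog(tibble::tibble(monomer_length = c(10, 20, 30, 40)))
  expect_equal(s$median_length, 25)
  expect_equal(s$short_fraction + s$long_fraction, 100)

  one <- summarize_catalog(tibble::tibble(monomer_length = 50))
  expect_equal(one$median_length, 50)

  expect_error(summarize_catalog(tibble::tibble(monomer_length = numeric(0))),
               "empty")
})

test_that("catalog files round-trip losslessly and reject malformed input", {
  set.seed(47)
  fams <- name_catalog(tibble::tibble(
    consensus = c(random_seq(60), random_seq(120)),
    monomer_length = c(60L, 120L),
    abundance = c(0.01, 0.002),
    mean_divergence = c(1.5, 7.2),
    variant_group = c(NA_integer_, NA_integer_),
    superfamily_id = c(1L, 1L)), "Tst")
  d <- withr::local_tempdir()
  write_catalog(fams, file.path(d, "cat"))
  back <- read_catalog(file.path(d, "cat"))
  expect_equal(back$name, fams$name)
  expect_equal(back$consensus, fams$consensus)
  expect_equal(back$abundance, fams$abundance)
  expect_equal(back$mean_divergence, fams$mean_divergence)
  expect_equal(back$superfamily_id, fams$superfamily_id)

  # duplicate FASTA headers are a parse error
  writeLines(c(">TstSat01-60", "ACGT", ">TstSat01-60", "ACGT"),
             file.path(d, "dup.fasta"))
  writeLines(c(paste(c("name", "RUL", "AT_percent", "abundance", "divergence",
                       "variant_group", "superfamily_id"), collapse = "\t"),
               paste(c("TstSat01-60", "4", "50", "0.1", "0", "NA", "NA"),
                     collapse = "\t")),
             file.path(d, "dup.tsv"))
  expect_error(read_catalog(file.path(d, "dup")), "duplicate")

  # names that do not parse are a parse error naming the line
  writeLines(c(">badname", "ACGT"), file.path(d, "bad.fasta"))
  writeLines(c(paste(c("name", "RUL", "AT_percent", "abundance", "divergence",
                       "variant_group", "superfamily_id"), collapse = "\t"),
               paste(c("badname", "4", "50", "0.1", "0", "NA", "NA"),
                     collapse = "\t")),
             file.path(d, "bad.tsv"))
  expect_error(read_catalog(file.path(d, "bad")), "line 2")
})

test_that("the bundled catalog table matches its published statistics", {
  cat32 <- mti_catalog()
  expect_equal(nrow(cat32), 32)
  # indices strictly follow non-increasing abundance
  expect_true(all(diff(cat32$abundance) < 0))
  # name-embedded lengths equal the RUL column
  expect_equal(parse_sat_name(cat32$name)$monomer_length,
               cat32$monomer_length)
  # A+T range as published
  expect_equal(min(cat32$at_percent), 40)
  expect_equal(max(cat32$at_percent), 66.6)
})
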