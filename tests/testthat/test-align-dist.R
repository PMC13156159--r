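test_that("circular alignment is rotation- and strand-invariant", {
  set.seed(1)
  s <- random_seq(40)
  a <- best_circular_alignment(s, rotate_seq(s, 3))
  expect_equal(a$identity, 100)
  expect_equal(a$rotation_offset, 3)
  expect_equal(a$strand, "forward")

  b <- best_circular_alignment(s, revcomp(s))
  expect_equal(b$identity, 100)
  expect_equal(b$strand, "reverse-complement")

  # invariance of similarity under rotation/revcomp of either argument
  t <- random_seq(37)
  base <- similarity(s, t)
  expect_equal(similarity(s, rotate_seq(t, 11)), base)
  expect_equal(similarity(s, revcomp(t)), base)
  expect_equal(similarity(rotate_seq(s, 5), t), base)
  expect_equal(similarity(t, s), base) # symmetry
})

test_that("identity counts mismatching positions as constructed", {
  set.seed(7)
  s <- random_seq(50)
  v <- strsplit(s, "")[[1]]
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  pos <- sample(50, 10)
  v[pos] <- flip[v[pos]]
  m <- paste(v, collapse = "")
  a <- best_circular_alignment(s, m)
  expect_equal(a$identity, 80)
  expect_equal(a$aligned_columns, 50)
  expect_equal(a$matches + a$P_count + a$Q_count + a$gap_columns,
               a$aligned_columns)
})

test_that("very different lengths align without error", {
  set.seed(3)
  short <- random_seq(60)
  long <- random_seq(2000)
  s <- similarity(short, long)
  expect_true(s >= 0 && s <= 100)
  expect_error(best_circular_alignment("", "ACGT"), "non-empty")
})

test_that("alignment equals the brute-force rotation x strand oracle", {
  set.seed(42)
  for (i in 1:60) {
    a <- random_seq(sample(4:12, 1))
    b <- random_seq(sample(4:12, 1))
    o <- oracle_circular(a, b)
    r <- best_circular_alignment(a, b)
    expect_equal(r$identity, o$identity, tolerance = 1e-12)
    expect_equal(r$strand, o$strand)
    expect_equal(r$rotation_offset, o$rotation_offset)
  }
})

test_that("doubled-sequence shortcut agrees with the exhaustive scan", {
  set.seed(8)
  anc <- random_seq(600)
  der <- evolve_sequence(anc, rate = 0.1, time = 1, seed = 9)
  der <- rotate_seq(der, 123)
  exact <- best_circular_alignment(anc, der, rotation_limit = 1000L)
  fast <- best_circular_alignment(anc, der, rotation_limit = 100L)
  expect_equal(fast$identity, exact$identity, tolerance = 1e-9)
  expect_equal(fast$rotation_offset, exact$rotation_offset)
})

test_that("K2P and JC estimators match their closed forms", {
  expect_equal(k2p(0, 0), 0)
  expect_equal(round(k2p(0.10, 0.05), 4), 0.1702)
  expect_true(is.na(k2p(0.5, 0.1)))  # 1 - 2P - Q <= 0
  expect_error(k2p(-0.1, 0.2), "P >= 0")
  expect_error(k2p(0.7, 0.5), "P \\+ Q")

  expect_equal(jc(0), 0)
  expect_equal(jc(0.30), 0.3831, tolerance = 1e-4)
  expect_true(is.na(jc(0.75)))
  expect_error(jc(1.2), "\\[0, 1\\]")

  # K2P dominates the p-distance on its domain, both strictly increasing
  for (p in seq(0.02, 0.4, by = 0.02)) {
    K <- k2p(2 * p / 3, p / 3)
    expect_gt(K, p - 1e-12)
    expect_gt(jc(p), jc(p - 0.01))
    expect_gt(K, k2p(2 * (p - 0.01) / 3, (p - 0.01) / 3))
  }
})

test_that("seq_distance computes P/Q from constructed pairs", {
  d0 <- seq_distance("ACGTACGTACGT", "ACGTACGTACGT")
  expect_equal(d0$p_distance, 0)
  expect_equal(d0$K, 0)
  expect_equal(d0$method_used, "K2P")

  # plant exactly 10 transitions and 5 transversions in 100 sites
  set.seed(11)
  s <- random_seq(100)
  v <- strsplit(s, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "C", C = "A", T = "A")
  pos <- sample(100, 15)
  v[pos[1:10]] <- ts_map[v[pos[1:10]]]
  v[pos[11:15]] <- tv_map[v[pos[11:15]]]
  d <- seq_distance(s, paste(v, collapse = ""))
  expect_equal(d$p_distance, 0.15)
  expect_equal(round(d$K, 4), 0.1702)
  expect_equal(d$method_used, "K2P")

  # saturated K2P falls back to the Jukes-Cantor correction
  set.seed(12)
  s2 <- random_seq(300)
  v2 <- strsplit(s2, "")[[1]]
  pos2 <- sample(300, 180)
  v2[pos2[1:150]] <- ts_map[v2[pos2[1:150]]]   # P = 0.5
  v2[pos2[151:180]] <- tv_map[v2[pos2[151:180]]] # Q = 0.1
  d2 <- seq_distance(s2, paste(v2, collapse = ""))
  expect_equal(d2$method_used, "JC")
  expect_equal(d2$p_distance, 0.6)
  expect_equal(d2$jc, jc(0.6), tolerance = 1e-12)
  expect_equal(d2$jc, 1.2071, tolerance = 1e-4)
})

test_that("distance estimators agree with ape's K80 and JC69 on aligned pairs", {
  skip_if_not_installed("ape")
  set.seed(71)
  anc <- random_seq(300)
  der <- evolve_sequence(anc, 0.08, 1, seed = 72)
  d <- seq_distance(anc, der)
  m <- rbind(strsplit(tolower(anc), "")[[1]], strsplit(tolower(der), "")[[1]])
  bin <- ape::as.DNAbin(m)
  expect_equal(d$K, as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-9)
  expect_equal(d$jc, as.numeric(ape::dist.dna(bin, model = "JC69")),
               tolerance = 1e-9)
})

test_that("distance is invariant under rotation and strand of either input", {
  set.seed(21)
  anc <- random_seq(200)
  der <- evolve_sequence(anc, 0.05, 1, seed = 22)
  d <- seq_distance(anc, der)
  expect_equal(seq_distance(anc, rotate_seq(der, 60))$K, d$K)
  expect_equal(seq_distance(anc, revcomp(der))$K, d$K)
  expect_equal(seq_distance(der, anc)$K, d$K)
})
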