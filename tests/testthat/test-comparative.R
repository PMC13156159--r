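test_that("CTR arithmetic matches the published closed-form examples", {
  expect_equal(round(ctr(2.53, 40e6) * 1e6, 4), 0.0316)
  expect_equal(ctr(0, 1e7), 0)
  expect_equal(round(ctr(1.40, 34.9e6) * 1e6, 4), 0.0201)
  expect_error(ctr(1, 0), "> 0")
  # symmetric in the species order by construction
  expect_equal(ctr(1.2, 4e7), ctr(1.2, 4e7))
})

make_catalog <- function(labels, seqs) {
  tibble::tibble(label = labels, consensus = seqs,
                 monomer_length = nchar(seqs))
}

test_that("conserved-family detection is one-to-one and thresholded", {
  set.seed(51)
  seqs <- vapply(1:4, function(i) random_seq(100), "")
  ca <- make_catalog(paste0("A", 1:4), seqs)

  # identical catalogs: everything matches at 100
  prs <- find_conserved(ca, ca)
  expect_equal(nrow(prs), 4)
  expect_true(all(prs$similarity == 100))
  expect_equal(prs$family_a, prs$family_b)

  # one shared (moderately drifted), one drifted beyond recognition,
  # plus private families on both sides
  drifted <- evolve_sequence(seqs[1], 0.10, 1, seed = 52)   # ~90 % left
  lost <- evolve_sequence(seqs[2], 2.2, 1, seed = 53)       # way past 50 %
  cb <- make_catalog(c("B1", "B2", "B3"),
                     c(drifted, lost, random_seq(100)))
  prs2 <- find_conserved(ca, cb, threshold = 50)
  expect_equal(nrow(prs2), 1)
  expect_equal(prs2$family_a, "A1")
  expect_equal(prs2$family_b, "B1")
  expect_true("A2" %in% attr(prs2, "private_a"))

  # one-to-one: no family appears twice
  expect_false(any(duplicated(prs2$family_a)))
  expect_false(any(duplicated(prs2$family_b)))

  expect_error(find_conserved(ca[0, ], cb), "non-empty")
})

test_that("distances and turnover rates propagate divergence times", {
  set.seed(55)
  seqs <- vapply(1:2, function(i) random_seq(200), "")
  ca <- make_catalog(c("A1", "A2"), seqs)
  cb <- make_catalog(c("B1", "B2"), seqs) # zero drift
  prs <- find_conserved(ca, cb)
  times <- setNames(4e7, species_pair_key("SpA", "SpB"))
  filled <- fill_distances(prs, ca, cb, "SpA", "SpB", times)
  expect_true(all(filled$K2P == 0))
  expect_true(all(filled$ctr_per_myr == 0))
  expect_true(all(filled$method == "K2P"))

  expect_error(fill_distances(prs, ca, cb, "SpA", "SpX", times),
               "no divergence time")
})

test_that("pair summaries aggregate exactly", {
  f <- tibble::tibble(
    family_a = paste0("F", 1:4), family_b = paste0("G", 1:4),
    species_pair = c("X|Y", "X|Y", "X|Z", "X|Z"),
    distance = c(1, 2, 3, NA), method = c("K2P", "K2P", "K2P", "undefined"),
    ctr_per_myr = c(0.01, 0.02, 0.03, NA))
  s <- summarize_pairs(f)
  xy <- s$per_pair[s$per_pair$species_pair == "X|Y", ]
  expect_equal(xy$k2p_mean, 1.5)
  expect_equal(xy$k2p_sd, sd(c(1, 2)))
  xz <- s$per_pair[s$per_pair$species_pair == "X|Z", ]
  expect_equal(xz$n_pairs, 1)
  expect_equal(xz$n_undefined, 1)
  expect_equal(xz$k2p_sd, 0)
  expect_equal(s$overall$k2p_mean, 2)
  expect_equal(s$overall$n_pairs, 3)

  expect_error(summarize_pairs(f[is.na(f$distance), ]), "undefined")
})

test_that("three-way tables mirror the published 9/2/1 sharing structure", {
  set.seed(57)
  # 12 focal families: 9 in all three catalogs, 2 shared with B only,
  # 1 shared with C only; moderate drift keeps similarity above 50
  mono <- vapply(1:12, function(i) random_seq(120), "")
  drift <- function(s, seed) evolve_sequence(s, 0.05, 1, seed = seed)
  focal <- make_catalog(sprintf("F%02d", 1:12), mono)
  b_idx <- c(1:9, 10, 11)
  c_idx <- c(1:9, 12)
  cb <- make_catalog(sprintf("B%02d", seq_along(b_idx)),
                     vapply(seq_along(b_idx), function(i)
                       drift(mono[b_idx[i]], 100 + i), ""))
  cc <- make_catalog(sprintf("C%02d", seq_along(c_idx)),
                     vapply(seq_along(c_idx), function(i)
                       drift(mono[c_idx[i]], 200 + i), ""))
  tw <- three_way_table(list(Foc = focal, Bsp = cb, Csp = cc))
  expect_equal(attr(tw, "shared_with_both"), 9)
  expect_equal(attr(tw, "shared_with_one"), 3)
  expect_equal(nrow(tw), 12)

  # disjoint catalogs: no rows survive
  other <- make_catalog("X1", random_seq(120))
  tw0 <- three_way_table(list(Foc = focal[1:2, ], B = other,
                              C = make_catalog("Y1", random_seq(120))))
  expect_equal(nrow(tw0), 0)
})

test_that("mean CTR over a drift scenario recovers the planted rate", {
  sp <- c("Mti", "Cma", "Pme")
  times <- setNames(c(40e6, 40e6, 34.9e6),
                    c(species_pair_key("Mti", "Cma"),
                      species_pair_key("Mti", "Pme"),
                      species_pair_key("Cma", "Pme")))
  sc <- make_species_scenario(sp, times, n_shared = 5, n_private = 2,
                              rate = 1.85e-8, seed = 2)
  rec <- scenario_ctr_recovery(sc, pairing = "truth")
  expect_equal(nrow(rec), 5 * 3)
  est <- mean(rec$ctr_per_year, na.rm = TRUE)
  expect_lt(abs(est - 1.85e-8) / 1.85e-8, 0.25)

  # zero drift: all distances and rates are exactly zero
  sc0 <- make_species_scenario(sp[1:2], times[species_pair_key("Mti", "Cma")],
                               n_shared = 3, n_private = 0, rate = 0,
                               shared_lengths = 100, seed = 3)
  rec0 <- scenario_ctr_recovery(sc0, pairing = "truth")
  expect_true(all(rec0$distance == 0))
  expect_true(all(rec0$ctr_per_year == 0))
})
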