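#' Consensus turnover rate
#'
#' `CTR = K / (2 T)`: the per-year rate at which two orthologous consensus
#' sequences accumulate substitutions, given their genetic distance `K`
#' (substitutions/site, typically K2P) and the divergence time `T` of the
#' two species in years. Multiply by `1e6` for the per-Myr value usually
#' reported.
#'
#' @param K genetic distance in substitutions/site (>= 0, or `NA`).
#' @param T_years divergence time in years (> 0).
#' @return CTR in substitutions/site/year.
#' @export
#' @examples
#' ctr(2.53, 40e6) * 1e6 # 0.0316 substitutions/site/Myr
ctr <- function(K, T_years) {
  if (any(T_years <= 0)) stop("T_years must be > 0", call. = FALSE)
  K / (2 * T_years)
}

# Significant local homology between two monomers (either strand, doubled
# subject so segments may cross the junction). The best circular global
# identity of two UNRELATED monomers sits near 50 % (the rotation-and-gap
# maximum over hundreds of candidate alignments), so a bare >50 % identity
# threshold cannot separate homology from chance. Detection pipelines gate
# conservation on a significant homology hit first (the RepeatMasker step)
# and assess similarity second; this reproduces that structure with a
# local-alignment score gate whose threshold grows with log(search space),
# capped at half the shorter monomer so short repeats remain detectable.
homology_score <- function(a, b) {
  dbl <- paste0(b, b)
  max(sw_align_cpp(a, dbl)$score,
      sw_align_cpp(a, paste0(revcomp(b), revcomp(b)))$score)
}

homology_min_score <- function(len_a, len_b) {
  max(8, min(0.5 * min(len_a, len_b), 4 + log2(len_a * len_b)))
}

#' Find conserved satDNA families between two catalogs
#'
#' All-vs-all circular similarity between the consensus sequences of two
#' species' catalogs; families with at least `threshold` percent similarity
#' to some partner, supported by a significant local homology segment
#' (see Details), are considered conserved. Matching is one-to-one and
#' greedy by descending similarity (a family already paired is skipped;
#' conflicts are recorded), unless `allow_many_to_one` is set.
#'
#' @details The homology gate exists because the best circular gapped
#' identity between two *unrelated* monomers already sits near 50 percent
#' (it is a maximum over every rotation, strand and gap placement), so the
#' 50 percent conservation threshold alone would admit chance matches.
#' A pair is only considered when its best local alignment score (match
#' +1, mismatch -1, gap -2, doubled subject, both strands) reaches
#' `max(8, min(len_min / 2, 4 + log2(len_a * len_b)))` — a
#' Karlin-Altschul-style log-scaled significance floor, capped so short
#' monomers remain detectable. Set `min_score = 0` to disable the gate.
#'
#' @param catalog_a,catalog_b data frames with `name` (or `label`) and
#'   `consensus` columns.
#' @param threshold minimum percent similarity; default 50.
#' @param min_score local homology score gate; `NULL` (default) uses the
#'   length-scaled floor above, `0` disables it.
#' @param allow_many_to_one allow one family to match several partners;
#'   default `FALSE`.
#' @return tibble of pairs (`family_a`, `family_b`, `similarity`), with
#'   attributes `private_a` / `private_b` (unmatched family names) and
#'   `conflicts` (matches discarded by the one-to-one rule).
#' @export
find_conserved <- function(catalog_a, catalog_b, threshold = 50,
                           min_score = NULL, allow_many_to_one = FALSE) {
  if (!nrow(catalog_a) || !nrow(catalog_b))
    stop("catalogs must be non-empty", call. = FALSE)
  name_a <- catalog_a[[if ("name" %in% names(catalog_a)) "name" else "label"]]
  name_b <- catalog_b[[if ("name" %in% names(catalog_b)) "name" else "label"]]
  sims <- expand.grid(ia = seq_len(nrow(catalog_a)),
                      ib = seq_len(nrow(catalog_b)))
  keep_h <- mapply(function(ia, ib) {
    a <- catalog_a$consensus[ia]
    b <- catalog_b$consensus[ib]
    gate <- if (is.null(min_score))
      homology_min_score(nchar(a), nchar(b)) else min_score
    gate <= 0 || homology_score(a, b) >= gate
  }, sims$ia, sims$ib)
  sims <- sims[keep_h, , drop = FALSE]
  sims$similarity <- if (nrow(sims)) mapply(function(ia, ib)
    similarity(catalog_a$consensus[ia], catalog_b$consensus[ib]),
    sims$ia, sims$ib) else numeric(0)
  sims <- sims[sims$similarity >= threshold, , drop = FALSE]
  sims <- sims[order(-sims$similarity, sims$ia, sims$ib), , drop = FALSE]
  used_a <- logical(nrow(catalog_a))
  used_b <- logical(nrow(catalog_b))
  keep <- logical(nrow(sims))
  conflict <- logical(nrow(sims))
  for (i in seq_len(nrow(sims))) {
    ia <- sims$ia[i]; ib <- sims$ib[i]
    if (allow_many_to_one || (!used_a[ia] && !used_b[ib])) {
      if (used_a[ia] || used_b[ib]) conflict[i] <- !allow_many_to_one
      keep[i] <- TRUE
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
    } else conflict[i] <- TRUE
  }
  pairs <- tibble::tibble(family_a = name_a[sims$ia[keep]],
                          family_b = name_b[sims$ib[keep]],
                          similarity = sims$similarity[keep])
  attr(pairs, "private_a") <- name_a[!used_a]
  attr(pairs, "private_b") <- name_b[!used_b]
  attr(pairs, "conflicts") <- tibble::tibble(
    family_a = name_a[sims$ia[conflict]],
    family_b = name_b[sims$ib[conflict]],
    similarity = sims$similarity[conflict])
  pairs
}

#' Compute distances and turnover rates for conserved pairs
#'
#' For every conserved pair, estimates the genetic distance between the two
#' consensus sequences ([seq_distance()]: K2P with Jukes-Cantor fallback on
#' saturation) and the consensus turnover rate `CTR = K/(2T)` using the
#' divergence time of the species pair.
#'
#' @param pairs tibble of pairs (as returned by [find_conserved()]) with
#'   `family_a`, `family_b`; consensus sequences are looked up in the two
#'   catalogs.
#' @param catalog_a,catalog_b the catalogs the pair names refer to.
#' @param species_a,species_b species prefixes of the two catalogs.
#' @param times_years named vector of divergence times in years, keyed by
#'   [species_pair_key()]. A missing key is a configuration error.
#' @return tibble with `family_a`, `family_b`, `species_pair`,
#'   `similarity`, `p_distance`, `K2P`, `JC`, `method`, `distance`,
#'   `T_years`, `ctr_per_year`, `ctr_per_myr`.
#' @export
fill_distances <- function(pairs, catalog_a, catalog_b, species_a, species_b,
                           times_years) {
  key <- species_pair_key(species_a, species_b)
  if (!key %in% names(times_years))
    stop("no divergence time configured for species pair ", key,
         call. = FALSE)
  T_years <- times_years[[key]]
  name_a <- catalog_a[[if ("name" %in% names(catalog_a)) "name" else "label"]]
  name_b <- catalog_b[[if ("name" %in% names(catalog_b)) "name" else "label"]]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ca <- catalog_a$consensus[match(pairs$family_a[i], name_a)]
    cb <- catalog_b$consensus[match(pairs$family_b[i], name_b)]
    d <- seq_distance(ca, cb)
    cv <- if (is.na(d$distance)) NA_real_ else ctr(d$distance, T_years)
    tibble::tibble(family_a = pairs$family_a[i],
                   family_b = pairs$family_b[i],
                   species_pair = key,
                   similarity = d$similarity,
                   p_distance = d$p_distance,
                   K2P = d$K, JC = d$jc, method = d$method_used,
                   distance = d$distance,
                   T_years = T_years,
                   ctr_per_year = cv, ctr_per_myr = cv * 1e6)
  })
  dplyr::bind_rows(rows)
}

#' Summarize conserved-pair distances per species pair
#'
#' Mean and standard deviation of the selected distance (K2P or its JC
#' fallback, whichever `method` produced) and of the CTR, per species pair
#' and overall. Pairs whose distance is undefined (both estimators
#' saturated) are excluded from the means and counted in `n_undefined`.
#'
#' @param filled tibble from [fill_distances()] (possibly several species
#'   pairs row-bound together).
#' @return a `sat_pair_summary` list with `per_pair` (tibble: species_pair,
#'   n_pairs, n_undefined, k2p_mean, k2p_sd, ctr_myr_mean, ctr_myr_sd) and
#'   `overall` (one-row tibble with the same statistics over all pairs).
#' @export
summarize_pairs <- function(filled) {
  ok <- !is.na(filled$distance)
  if (!any(ok)) stop("all pair distances are undefined", call. = FALSE)
  one <- function(df) {
    use <- df[!is.na(df$distance), , drop = FALSE]
    tibble::tibble(n_pairs = nrow(use),
                   n_undefined = sum(is.na(df$distance)),
                   k2p_mean = mean(use$distance),
                   k2p_sd = if (nrow(use) > 1) sd(use$distance) else 0,
                   ctr_myr_mean = mean(use$ctr_per_myr),
                   ctr_myr_sd = if (nrow(use) > 1) sd(use$ctr_per_myr) else 0)
  }
  per <- lapply(split(filled, filled$species_pair), one)
  per_pair <- dplyr::bind_rows(per, .id = "species_pair")
  structure(list(per_pair = tibble::as_tibble(per_pair),
                 overall = one(filled)),
            class = "sat_pair_summary")
}

#' @export
print.sat_pair_summary <- function(x, ...) {
  cat("Per species pair:\n"); print(x$per_pair)
  cat("Overall:\n"); print(x$overall)
  invisible(x)
}

#' Recover the substitution rate planted in a drift scenario
#'
#' Runs the comparative machinery over every species pair of a
#' [make_species_scenario()] object and reports the distance and CTR per
#' orthologous family pair. With `pairing = "truth"` the orthology recorded
#' in the scenario manifest is used directly, which isolates the distance
#' and CTR estimators from the conserved-family matching step; this is the
#' right choice at deep divergence times, where true consensus identity
#' drops near or below the 50 % operational conservation threshold. With
#' `pairing = "similarity"` pairs come from [find_conserved()] at
#' `threshold`.
#'
#' @param scenario a `sat_scenario`.
#' @param pairing `"truth"` or `"similarity"`.
#' @param threshold conservation threshold for `pairing = "similarity"`.
#' @return tibble in the format of [fill_distances()] (all species pairs
#'   row-bound); pass to [summarize_pairs()] for the mean CTR, whose
#'   per-year value estimates the planted rate.
#' @export
scenario_ctr_recovery <- function(scenario, pairing = c("truth", "similarity"),
                                  threshold = 50) {
  pairing <- match.arg(pairing)
  sp <- scenario$truth$species
  times <- scenario$truth$times_years
  out <- list()
  for (i in seq_len(length(sp) - 1)) for (j in seq(i + 1, length(sp))) {
    ca <- scenario$catalogs[[sp[i]]]
    cb <- scenario$catalogs[[sp[j]]]
    if (pairing == "truth") {
      shared <- scenario$truth$shared_labels
      prs <- tibble::tibble(family_a = shared, family_b = shared,
                            similarity = NA_real_)
    } else {
      prs <- find_conserved(ca, cb, threshold)
    }
    out[[length(out) + 1L]] <-
      fill_distances(prs, ca, cb, sp[i], sp[j], times)
  }
  dplyr::bind_rows(out)
}

#' Three-species conserved-family table
#'
#' One row per family of the focal (first) catalog, listing its conserved
#' match (or `"-"`) in each of the other two catalogs, in the style of
#' published cross-species satellitome tables. Also reports how many focal
#' families are shared with both other species and with exactly one.
#'
#' @param catalogs named list of three catalogs (focal species first).
#' @param threshold conservation threshold in percent; default 50.
#' @return tibble with one row per focal family plus attributes
#'   `shared_with_both` and `shared_with_one` (counts) and `pair_objects`
#'   (the underlying [find_conserved()] results).
#' @export
three_way_table <- function(catalogs, threshold = 50) {
  stopifnot(length(catalogs) == 3)
  sp <- names(catalogs)
  focal <- catalogs[[1]]
  fname <- focal[[if ("name" %in% names(focal)) "name" else "label"]]
  match_cols <- list()
  pair_objects <- list()
  for (oi in 2:3) {
    pr <- find_conserved(catalogs[[1]], catalogs[[oi]], threshold)
    pair_objects[[sp[oi]]] <- pr
    mm <- setNames(rep("-", length(fname)), fname)
    mm[pr$family_a] <- pr$family_b
    match_cols[[sp[oi]]] <- unname(mm)
  }
  out <- tibble::tibble(a = fname, b = match_cols[[sp[2]]],
                        c = match_cols[[sp[3]]])
  names(out) <- sp
  in2 <- match_cols[[sp[2]]] != "-"
  in3 <- match_cols[[sp[3]]] != "-"
  out <- out[in2 | in3, , drop = FALSE]
  attr(out, "shared_with_both") <- sum(in2 & in3)
  attr(out, "shared_with_one") <- sum(xor(in2, in3))
  attr(out, "pair_objects") <- pair_objects
  out
}
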