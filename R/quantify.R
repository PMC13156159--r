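#' Align one read against a family consensus
#'
#' Local alignment of the read (both strands) against the tiled
#' consensus, so hits crossing the monomer junction are found. A hit is
#' reported when the identity is at least `min_identity` percent over an
#' alignment spanning at least `min_hit_length` read bases; it carries the
#' matched nucleotide count (read bases inside the alignment) and the K2P
#' divergence (percent) of the matched segment, with the Jukes-Cantor
#' correction as fallback on saturation.
#'
#' @param read a DNA string of at least 30 bases.
#' @param family a list or one-row data frame with a `consensus` entry, or
#'   a bare consensus string.
#' @param min_identity minimum percent identity; default 70.
#' @param min_hit_length minimum read bases spanned; default 50: a 30 nt
#'   floor at 70 percent identity admits chance hits (score ~12, the
#'   noise level once a shared prefilter k-mer seeds the alignment),
#'   measurably inflating rare families.
#' @return a list (`identity`, `matched_nt`, `divergence`, `strand`) or
#'   `NULL` when there is no qualifying hit.
#' @export
align_read_to_family <- function(read, family, min_identity = 70,
                                 min_hit_length = 50L) {
  read <- check_dna(read, "read")
  if (nchar(read) < 30) stop("read must be >= 30 bases", call. = FALSE)
  cons <- if (is.character(family)) family else family$consensus
  h <- read_family_hit(read, cons)
  if (is.null(h)) return(NULL)
  if (h$identity < min_identity || h$read_span < min_hit_length) return(NULL)
  h
}

#' Estimate family abundances, divergences and repeat landscapes
#'
#' Aligns a read sample against every catalog consensus and accumulates,
#' per family: abundance (matched read nucleotides over total nucleotides
#' analyzed), the abundance-weighted mean divergence, and a repeat
#' landscape of abundance mass per 1 % divergence bin (0-50 %, divergences
#' beyond 50 % fall in the last bin so the landscape mass always equals the
#' abundance exactly). Every read nucleotide is assigned to at most one
#' family: the hit with the highest identity wins, ties going to the lower
#' catalog index.
#'
#' @param lib a `read_library`.
#' @param catalog data frame with at least `label` and `consensus` columns
#'   (order defines the tie-break index).
#' @param n_pairs_sample read pairs to analyze; clamped (with a warning) to
#'   the library size. Default 100000; full-scale protocols use 5e6.
#' @param seed integer RNG seed for the read sample.
#' @param min_identity,min_hit_length hit thresholds, see
#'   [align_read_to_family()].
#' @param prefilter_k exact k-mer prefilter size; default 10. Smaller than
#'   the subtraction prefilter because quantification must keep reads from
#'   copies diverged by 10-15 percent, whose substitutions can interrupt
#'   every clean 12-mer window.
#' @return a `quant_result` list: `families` (tibble: `family_label`,
#'   `abundance`, `mean_divergence`, `n_hits`, `matched_nt`), `landscape`
#'   (tibble: `family_label`, `bin_low`, `bin_high`, `mass`) and
#'   `nucleotides_analyzed`.
#' @export
estimate_abundance <- function(lib, catalog, n_pairs_sample = 100000L,
                               seed = 1L, min_identity = 70,
                               min_hit_length = 50L, prefilter_k = 10L) {
  if (is.null(catalog) || !nrow(catalog))
    stop("catalog must be non-empty", call. = FALSE)
  avail <- length(lib$fwd)
  if (n_pairs_sample > avail) {
    warning("n_pairs_sample exceeds library size; clamping to ", avail)
    n_pairs_sample <- avail
  }
  sub <- subsample_reads(lib, n_pairs_sample, seed = seed)
  reads <- c(sub$fwd, sub$rev)
  total_nt <- sum(nchar(reads))
  n_fam <- nrow(catalog)

  # best hit per read across families
  hit_fam <- integer(0); hit_nt <- numeric(0); hit_div <- numeric(0)
  hit_id <- numeric(0); hit_read <- integer(0)
  best_by_read <- vector("list", length(reads))
  for (fi in seq_len(n_fam)) {
    cons <- catalog$consensus[fi]
    cand <- which(prefilter_hits(reads, cons, prefilter_k))
    for (ri in cand) {
      h <- read_family_hit(reads[ri], cons)
      if (is.null(h)) next
      if (h$identity < min_identity || h$read_span < min_hit_length) next
      prev <- best_by_read[[ri]]
      if (is.null(prev) || h$identity > prev$identity)
        best_by_read[[ri]] <- list(family = fi, identity = h$identity,
                                   matched_nt = h$matched_nt,
                                   divergence = h$divergence)
    }
  }

  bin_edges <- 0:50
  fam_rows <- vector("list", n_fam)
  land_rows <- vector("list", n_fam)
  for (fi in seq_len(n_fam)) {
    hits <- Filter(function(h) !is.null(h) && h$family == fi, best_by_read)
    nt <- vapply(hits, function(h) h$matched_nt, 0)
    dv <- vapply(hits, function(h) h$divergence, 0)
    abundance <- sum(nt) / total_nt
    mean_div <- if (sum(nt) > 0) sum(nt * dv) / sum(nt) else NA_real_
    bin <- pmin(floor(pmax(dv, 0)), 50 - 1)
    mass <- vapply(0:49, function(b) sum(nt[bin == b]) / total_nt, 0)
    fam_rows[[fi]] <- tibble::tibble(
      family_label = catalog$label[fi], abundance = abundance,
      mean_divergence = mean_div, n_hits = length(hits),
      matched_nt = sum(nt))
    land_rows[[fi]] <- tibble::tibble(
      family_label = catalog$label[fi], bin_low = 0:49, bin_high = 1:50,
      mass = mass)
  }
  structure(list(families = dplyr::bind_rows(fam_rows),
                 landscape = dplyr::bind_rows(land_rows),
                 nucleotides_analyzed = total_nt),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Quantification over %d nucleotides:\n", x$nucleotides_analyzed))
  print(x$families)
  invisible(x)
}

#' Write quantification tables as TSV
#'
#' Writes a per-family table (label, RUL, A+T %, abundance, divergence, in
#' the column order of standard satellitome catalog tables) and a repeat
#' landscape table (family, bin_low, bin_high, mass).
#'
#' @param quant a `quant_result`.
#' @param catalog the catalog used (for RUL and A+T columns; optional).
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_quant_tables <- function(quant, catalog = NULL, prefix) {
  fam <- quant$families
  tab <- data.frame(SatDNA = fam$family_label,
                    RUL = NA_integer_, AT_percent = NA_real_,
                    Abundance = fam$abundance,
                    Divergence = fam$mean_divergence)
  if (!is.null(catalog)) {
    key <- if ("label" %in% names(catalog)) catalog$label else catalog$name
    m <- match(fam$family_label, key)
    tab$RUL <- catalog$monomer_length[m]
    if ("at_percent" %in% names(catalog)) tab$AT_percent <- catalog$at_percent[m]
  }
  f1 <- paste0(prefix, "_families.tsv")
  f2 <- paste0(prefix, "_landscape.tsv")
  write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(quant$landscape, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
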