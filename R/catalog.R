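#' Group candidate families into similarity tiers and remove redundancy
#'
#' Implements the standard satellitome curation tiers based on pairwise
#' consensus similarity: candidates more than 95 % similar are the same
#' variant (SV) and are collapsed, keeping the highest-abundance consensus;
#' retained families more than 80 % similar are variants (V) of one satDNA
#' and share a `variant_group`; families more than 50 % similar belong to
#' one superfamily (SF) and share a `superfamily_id`. All three tiers use
#' single-linkage transitive closure, and all thresholds are strict
#' inequalities. Optionally screens candidates against a contaminant set
#' (e.g. multigene families or transposable elements) first, dropping any
#' candidate more than 80 % similar to a contaminant sequence.
#'
#' @param candidates data frame with `consensus` and an abundance column
#'   (`abundance` or `kmer_abundance`).
#' @param sv_threshold,v_threshold,sf_threshold tier thresholds in percent;
#'   defaults 95, 80, 50.
#' @param contaminants optional character vector (or DNAStringSet) of
#'   contaminant sequences.
#' @param contaminant_threshold similarity above which a candidate is
#'   dropped as a contaminant; default 80.
#' @return tibble of retained families with `consensus`,
#'   `monomer_length`, `abundance`, `variant_group`, `superfamily_id`
#'   (group ids are `NA` for families with no partner in that tier).
#' @export
tier_and_dedupe <- function(candidates, sv_threshold = 95, v_threshold = 80,
                            sf_threshold = 50, contaminants = NULL,
                            contaminant_threshold = 80) {
  stopifnot(nrow(candidates) >= 0)
  cand <- tibble::as_tibble(candidates)
  if (!"abundance" %in% names(cand)) {
    if ("kmer_abundance" %in% names(cand)) cand$abundance <- cand$kmer_abundance
    else stop("candidates need an abundance column", call. = FALSE)
  }
  if (!is.null(contaminants) && nrow(cand)) {
    contaminants <- as.character(contaminants)
    is_cont <- vapply(cand$consensus, function(x)
      any(vapply(contaminants, function(ct)
        similarity(x, ct) > contaminant_threshold, TRUE)), TRUE)
    cand <- cand[!is_cont, , drop = FALSE]
  }
  n <- nrow(cand)
  if (n == 0)
    return(tibble::tibble(consensus = character(0),
                          monomer_length = integer(0),
                          abundance = numeric(0),
                          variant_group = integer(0),
                          superfamily_id = integer(0)))
  sim <- matrix(100, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      sim[i, j] <- sim[j, i] <- similarity(cand$consensus[i], cand$consensus[j])
    }
  }
  # SV collapse: single-linkage components at > sv_threshold
  sv_comp <- link_components(sim > sv_threshold)
  keep <- vapply(split(seq_len(n), sv_comp), function(ix)
    ix[which.max(cand$abundance[ix])], 0L)
  keep <- sort(unname(keep))
  cand <- cand[keep, , drop = FALSE]
  sim <- sim[keep, keep, drop = FALSE]
  m <- nrow(cand)
  v_comp <- link_components(sim > v_threshold)
  # the superfamily threshold sits near the chance-identity level of the
  # circular gapped aligner, so SF edges additionally require a significant
  # local homology segment (same gate as cross-species conservation)
  sf_adj <- sim > sf_threshold
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      if (sf_adj[i, j] && sim[i, j] <= v_threshold) {
        gate <- homology_min_score(nchar(cand$consensus[i]),
                                   nchar(cand$consensus[j]))
        ok <- homology_score(cand$consensus[i], cand$consensus[j]) >= gate
        sf_adj[i, j] <- sf_adj[j, i] <- ok
      }
    }
  }
  sf_comp <- link_components(sf_adj)
  # only report group ids for tiers that actually group more than one family
  v_id <- group_ids(v_comp)
  sf_id <- group_ids(sf_comp)
  tibble::tibble(consensus = cand$consensus,
                 monomer_length = nchar(cand$consensus),
                 abundance = cand$abundance,
                 variant_group = v_id,
                 superfamily_id = sf_id)
}

# connected components of a logical adjacency matrix (single linkage)
link_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        old <- max(comp[i], comp[j])
        comp[comp == old] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# NA for singleton components, consecutive ids for real groups
group_ids <- function(comp) {
  sizes <- table(comp)
  grouped <- as.integer(names(sizes)[sizes > 1])
  out <- rep(NA_integer_, length(comp))
  for (gi in seq_along(grouped)) out[comp == grouped[gi]] <- gi
  out
}

#' Assign catalog names in decreasing order of abundance
#'
#' Names follow the standard satDNA convention
#' `<Prefix>Sat<NN>-<monomer length>` (e.g. `MtiSat01-650`): families are
#' sorted by decreasing abundance (ties: shorter monomer first, then
#' lexicographic consensus) and numbered consecutively with zero-padded
#' two-digit indices.
#'
#' @param families data frame with `consensus`, `monomer_length` and
#'   `abundance` columns.
#' @param prefix species prefix, conventionally three letters (e.g. `"Mti"`).
#' @return the input tibble with `name`, `species_prefix` and
#'   `catalog_index` columns, sorted by catalog index.
#' @export
name_catalog <- function(families, prefix) {
  stopifnot(nrow(families) >= 1)
  fam <- tibble::as_tibble(families)
  ord <- order(-fam$abundance, fam$monomer_length, fam$consensus)
  fam <- fam[ord, , drop = FALSE]
  fam$catalog_index <- seq_len(nrow(fam))
  fam$species_prefix <- prefix
  fam$name <- sprintf("%sSat%02d-%d", prefix, fam$catalog_index,
                      fam$monomer_length)
  fam
}

#' Parse a satDNA family name
#'
#' @param name character vector of names like `"MtiSat01-650"`.
#' @return tibble with `species_prefix`, `catalog_index`, `monomer_length`.
#' @export
parse_sat_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+)Sat([0-9]+)-([0-9]+)$", name))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("malformed satDNA name(s): ", paste(name[bad], collapse = ", "),
         call. = FALSE)
  tibble::tibble(
    species_prefix = vapply(m, `[`, "", 2L),
    catalog_index = as.integer(vapply(m, `[`, "", 3L)),
    monomer_length = as.integer(vapply(m, `[`, "", 4L)))
}

#' Summary statistics of a satDNA catalog
#'
#' Reports the family count, the minimum / maximum / median repeat unit
#' length, the percent of short (< 100 bp) and long families, and the
#' A+T range and mean. The median is the midpoint of the two central order
#' statistics for even counts.
#'
#' @param families data frame with a `monomer_length` column and optionally
#'   `at_percent` (computed from `consensus` when absent).
#' @return a one-row tibble (`n_families`, `min_length`, `max_length`,
#'   `median_length`, `short_fraction`, `long_fraction`, `at_min`,
#'   `at_max`, `at_mean`).
#' @export
summarize_catalog <- function(families) {
  if (is.null(families) || nrow(families) == 0)
    stop("catalog is empty", call. = FALSE)
  len <- families$monomer_length
  at <- if ("at_percent" %in% names(families)) families$at_percent
        else if ("consensus" %in% names(families))
          vapply(families$consensus, at_percent_of, 0)
        else rep(NA_real_, nrow(families))
  tibble::tibble(
    n_families = nrow(families),
    min_length = min(len), max_length = max(len),
    median_length = stats::median(len),
    short_fraction = 100 * mean(len < 100),
    long_fraction = 100 * mean(len >= 100),
    at_min = min(at), at_max = max(at), at_mean = mean(at))
}

#' A+T content of a sequence, in percent
#' @param x a DNA string.
#' @return percent of A or T bases.
#' @export
at_percent_of <- function(x) {
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  100 * mean(b %in% c("A", "T"))
}

#' Write a satDNA catalog as FASTA plus a TSV side table
#'
#' The FASTA holds consensus sequences with family names as headers; the
#' TSV holds all per-family fields with columns `name`, `RUL`,
#' `AT_percent`, `abundance`, `divergence`, `variant_group`,
#' `superfamily_id`. The round trip through [read_catalog()] is lossless.
#'
#' @param families named catalog tibble (output of [name_catalog()],
#'   optionally with `mean_divergence`).
#' @param prefix output path prefix (writes `<prefix>.fasta` and
#'   `<prefix>.tsv`).
#' @return invisibly, the two file paths.
#' @export
write_catalog <- function(families, prefix) {
  stopifnot(all(c("name", "consensus") %in% names(families)))
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  x <- Biostrings::DNAStringSet(families$consensus)
  names(x) <- families$name
  Biostrings::writeXStringSet(x, fa)
  tab <- data.frame(
    name = families$name,
    RUL = families$monomer_length,
    AT_percent = vapply(families$consensus, at_percent_of, 0),
    abundance = families$abundance,
    divergence = if ("mean_divergence" %in% names(families))
      families$mean_divergence else NA_real_,
    variant_group = if ("variant_group" %in% names(families))
      families$variant_group else NA_integer_,
    superfamily_id = if ("superfamily_id" %in% names(families))
      families$superfamily_id else NA_integer_)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}

#' Read a satDNA catalog written by [write_catalog()]
#'
#' Validates that FASTA headers are unique, parse as satDNA names and
#' agree with the TSV side table.
#'
#' @param prefix path prefix used when writing.
#' @return catalog tibble with the same fields written out.
#' @export
read_catalog <- function(prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  x <- Biostrings::readDNAStringSet(fa)
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA header in ", fa, ": ",
         names(x)[duplicated(names(x))][1], call. = FALSE)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("name", "RUL", "AT_percent", "abundance", "divergence",
            "variant_group", "superfamily_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("catalog TSV ", tsv, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({parse_sat_name(tab$name[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok)
      stop("catalog TSV ", tsv, " line ", i + 1L,
           ": name does not parse as <Prefix>Sat<NN>-<len>: ",
           tab$name[i], call. = FALSE)
  }
  if (!setequal(names(x), tab$name))
    stop("FASTA headers and TSV names disagree for catalog ", prefix,
         call. = FALSE)
  parsed <- parse_sat_name(tab$name)
  ord <- match(tab$name, names(x))
  tibble::tibble(
    name = tab$name,
    species_prefix = parsed$species_prefix,
    catalog_index = parsed$catalog_index,
    consensus = unname(as.character(x)[ord]),
    monomer_length = tab$RUL,
    at_percent = tab$AT_percent,
    abundance = tab$abundance,
    mean_divergence = tab$divergence,
    variant_group = tab$variant_group,
    superfamily_id = tab$superfamily_id)
}
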