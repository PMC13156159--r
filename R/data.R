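#' Published satellitome catalog of Myloplus tiete
#'
#' The 32 satDNA families characterized for the Serrasalmid fish
#' *Myloplus tiete*: family name (`<Prefix>Sat<NN>-<monomer length>`),
#' repeat unit length (RUL, bp), A+T content (%), genomic abundance
#' (fraction of analyzed nucleotides) and mean Kimura divergence of
#' genomic copies from the consensus (%). Families are numbered in
#' decreasing order of abundance. Consensus sequences themselves are not
#' bundled; this table carries the catalog statistics.
#'
#' @return tibble with columns `name`, `monomer_length`, `at_percent`,
#'   `abundance`, `divergence`.
#' @export
mti_catalog <- function() {
  p <- system.file("extdata", "mtiete_satellitome.tsv",
                   package = "satellitome", mustWork = TRUE)
  tab <- read.delim(p, stringsAsFactors = FALSE)
  tibble::tibble(name = tab$name, monomer_length = as.integer(tab$RUL),
                 at_percent = tab$AT_percent, abundance = tab$abundance,
                 divergence = tab$divergence)
}

#' Conserved satDNA families across three Serrasalmidae satellitomes
#'
#' The published cross-species table of conserved families between
#' *M. tiete* (Mti), *C. macropomum* (Cma) and *P. mesopotamicus* (Pme):
#' one row per conserved *M. tiete* family with its match (or `"-"`) in
#' each Colossomatinae catalog.
#'
#' @return tibble with columns `Mti`, `Cma`, `Pme`.
#' @export
serrasalmidae_conserved <- function() {
  p <- system.file("extdata", "serrasalmidae_conserved_families.tsv",
                   package = "satellitome", mustWork = TRUE)
  tibble::as_tibble(read.delim(p, stringsAsFactors = FALSE))
}

#' Published K2P / CTR summaries per Serrasalmidae species pair
#'
#' Mean and standard deviation of the Kimura 2-parameter distances between
#' conserved consensus sequences, per species pair, together with the
#' divergence time used (Myr) and the resulting consensus turnover rates
#' (substitutions/site/Myr). Group sizes follow from the conserved-family
#' table: 9 families are shared by all three species, two Mti families are
#' shared with Pme only and one with Cma only (10 + 11 + 9 = 30 pairwise
#' comparisons).
#'
#' @return tibble with columns `species_pair`, `n`, `k2p_mean`, `k2p_sd`,
#'   `t_myr`, `ctr_myr_mean`, `ctr_myr_sd`.
#' @export
serrasalmidae_k2p_summary <- function() {
  p <- system.file("extdata", "serrasalmidae_k2p_summary.tsv",
                   package = "satellitome", mustWork = TRUE)
  tibble::as_tibble(read.delim(p, stringsAsFactors = FALSE))
}

#' Published per-family K2P extremes of the Serrasalmidae comparison
#'
#' The highest and lowest conserved-family K2P distances reported for the
#' three-species comparison, with the divergence time applicable to the
#' pairwise (highest) value.
#'
#' @return tibble with columns `family_pair`, `k2p`, `t_myr`, `note`.
#' @export
serrasalmidae_family_k2p <- function() {
  p <- system.file("extdata", "serrasalmidae_family_k2p.tsv",
                   package = "satellitome", mustWork = TRUE)
  tibble::as_tibble(read.delim(p, stringsAsFactors = FALSE))
}
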