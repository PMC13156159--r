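#' Classic one-way fixed-effects ANOVA
#'
#' `F = (SSB / df_between) / (SSW / df_within)` with
#' `df_between = groups - 1` and `df_within = n - groups`; the p-value
#' comes from the F distribution. Used to test whether K2P distances differ
#' among species-pair comparisons. Welch's unequal-variance variant is
#' available behind a flag.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (same length as `values`); at least two
#'   groups with at least two values each.
#' @param welch use Welch's ANOVA instead of the classic pooled form.
#' @return an `anova_result` list: `F`, `p_value`, `df_between`,
#'   `df_within`, `group_means`.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
anova_oneway <- function(values, groups, welch = FALSE) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  if (welch) {
    ow <- stats::oneway.test(values ~ factor(groups), var.equal = FALSE)
    return(structure(list(F = unname(ow$statistic),
                          p_value = unname(ow$p.value),
                          df_between = unname(ow$parameter[1]),
                          df_within = unname(ow$parameter[2]),
                          group_means = tapply(values, groups, mean)),
                     class = "anova_result"))
  }
  k <- length(tab)
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ni <- as.numeric(tab[names(means)])
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- k - 1
  dfw <- n - k
  # SSB = 0 means no between-group signal regardless of SSW (avoids 0/0)
  Fv <- if (ssb == 0) 0 else (ssb / dfb) / (ssw / dfw)
  structure(list(F = Fv, p_value = pf(Fv, dfb, dfw, lower.tail = FALSE),
                 df_between = dfb, df_within = dfw,
                 group_means = means),
            class = "anova_result")
}

#' One-way ANOVA reconstructed from per-group summary statistics
#'
#' Computes the classic one-way F statistic from group sizes, means and
#' standard deviations alone: `SSB = sum n_i (m_i - m)^2`,
#' `SSW = sum (n_i - 1) s_i^2`. Useful when only published group summaries
#' are available rather than the raw values.
#'
#' @param n integer vector of group sizes.
#' @param means numeric vector of group means.
#' @param sds numeric vector of group standard deviations.
#' @param labels optional group labels.
#' @return an `anova_result` (see [anova_oneway()]).
#' @export
anova_from_summary <- function(n, means, sds, labels = NULL) {
  stopifnot(length(n) == length(means), length(n) == length(sds))
  if (length(n) < 2 || any(n < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  if (is.null(labels)) labels <- paste0("group", seq_along(n))
  N <- sum(n)
  gm <- sum(n * means) / N
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((n - 1) * sds^2)
  dfb <- length(n) - 1
  dfw <- N - length(n)
  Fv <- (ssb / dfb) / (ssw / dfw)
  structure(list(F = Fv, p_value = pf(Fv, dfb, dfw, lower.tail = FALSE),
                 df_between = dfb, df_within = dfw,
                 group_means = setNames(means, labels)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f on (%g, %g) df, p = %.3g\n",
              x$F, x$df_between, x$df_within, x$p_value))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults for [run_pipeline()]. The `scale` profile switches
#' the subsample sizes between desk-scale values that run in minutes on a
#' laptop and the full-scale values of the published protocol (2 x 500000
#' discovery pairs, 2 x 5000000 quantification pairs).
#'
#' @param scale `"desk"` or `"paper"` subsample profile.
#' @param ... named overrides of any configuration entry.
#' @return a `RunConfig`-style list.
#' @export
pipeline_config <- function(scale = c("desk", "paper"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = 1L,
    scale = scale,
    discovery_pairs = if (scale == "desk") 50000L else 500000L,
    quant_pairs = if (scale == "desk") 100000L else 5000000L,
    k = 21L,
    min_abundance = 5e-4,
    min_support = 50L,
    subtract_identity = 80,
    subtract_coverage = 0.5,
    sv_threshold = 95, v_threshold = 80, sf_threshold = 50,
    conserved_threshold = 50,
    min_identity = 70, min_hit_length = 50L,
    max_rounds = 8L,
    times_years = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Run the full satellitome pipeline on a read library
#'
#' Discover -> quantify -> curate -> name, optionally followed by a
#' cross-species comparison against previously built catalogs. Stage
#' errors abort with a stage-named message; a run manifest records the
#' package version, seed and all parameters, so identical configurations
#' give identical outputs.
#'
#' @param lib a `read_library`.
#' @param prefix species prefix for catalog names (e.g. `"Mti"`).
#' @param config list from [pipeline_config()].
#' @param compare_catalogs optional named list of other species' catalogs
#'   (names are their species prefixes); requires `config$times_years`
#'   entries for every species pair involved (checked before any
#'   computation).
#' @param out_dir optional directory; when given, catalog FASTA/TSV,
#'   quantification tables, the per-round discovery log, conserved-pair
#'   tables and the manifest are written there.
#' @return a `sat_run` list: `catalog`, `quant`, `summary`, `discovery`
#'   (with the per-round log attribute), `comparison` (or `NULL`) and
#'   `manifest`.
#' @export
run_pipeline <- function(lib, prefix, config = pipeline_config(),
                         compare_catalogs = NULL, out_dir = NULL) {
  # fail fast on comparison configuration
  if (!is.null(compare_catalogs)) {
    if (is.null(names(compare_catalogs)) || any(!nzchar(names(compare_catalogs))))
      stop("configuration error: compare_catalogs must be a named list",
           call. = FALSE)
    for (other in names(compare_catalogs)) {
      key <- species_pair_key(prefix, other)
      if (!key %in% names(config$times_years))
        stop("configuration error: no divergence time for species pair ",
             key, call. = FALSE)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  discovery <- stage("discover", iterate_discovery(
    lib, subsample_pairs = config$discovery_pairs, k = config$k,
    min_abundance = config$min_abundance, min_support = config$min_support,
    identity_threshold = config$subtract_identity,
    coverage_threshold = config$subtract_coverage,
    max_rounds = config$max_rounds, seed = config$seed))
  if (!nrow(discovery)) {
    catalog <- NULL; quant <- NULL; summary <- NULL
  } else {
    tiered <- stage("catalog", tier_and_dedupe(
      discovery, sv_threshold = config$sv_threshold,
      v_threshold = config$v_threshold, sf_threshold = config$sf_threshold))
    quant0 <- stage("quantify", estimate_abundance(
      lib, tibble::tibble(label = paste0("cand", seq_len(nrow(tiered))),
                          consensus = tiered$consensus),
      n_pairs_sample = min(config$quant_pairs, length(lib$fwd)),
      seed = config$seed,
      min_identity = config$min_identity,
      min_hit_length = config$min_hit_length))
    tiered$abundance <- quant0$families$abundance
    tiered$mean_divergence <- quant0$families$mean_divergence
    catalog <- stage("catalog", name_catalog(tiered, prefix))
    quant <- quant0
    # quant rows follow the tiered candidate order; rename to catalog names
    new_names <- catalog$name[match(tiered$consensus, catalog$consensus)]
    relabel <- setNames(new_names, paste0("cand", seq_len(nrow(tiered))))
    quant$families$family_label <- unname(relabel[quant$families$family_label])
    quant$landscape$family_label <- unname(relabel[quant$landscape$family_label])
    summary <- stage("catalog", summarize_catalog(catalog))
  }
  comparison <- NULL
  if (!is.null(compare_catalogs) && !is.null(catalog)) {
    comparison <- stage("compare", {
      filled <- list()
      for (other in names(compare_catalogs)) {
        prs <- find_conserved(catalog, compare_catalogs[[other]],
                              config$conserved_threshold)
        filled[[other]] <- fill_distances(prs, catalog,
                                          compare_catalogs[[other]],
                                          prefix, other, config$times_years)
      }
      filled <- dplyr::bind_rows(filled)
      list(pairs = filled,
           summary = if (nrow(filled) && any(!is.na(filled$distance)))
             summarize_pairs(filled) else NULL)
    })
  }
  manifest <- list(package = "satellitome",
                   version = as.character(utils::packageVersion("satellitome")),
                   prefix = prefix, config = config,
                   n_pairs_input = length(lib$fwd),
                   n_families = if (is.null(catalog)) 0L else nrow(catalog))
  res <- list(catalog = catalog, quant = quant, summary = summary,
              discovery = discovery, comparison = comparison,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(catalog))
      write_catalog(catalog, file.path(out_dir, paste0(prefix, "_catalog")))
    if (!is.null(quant))
      write_quant_tables(quant, catalog, file.path(out_dir, paste0(prefix, "_quant")))
    rounds <- attr(discovery, "rounds")
    if (!is.null(rounds))
      write.table(rounds, file.path(out_dir, paste0(prefix, "_rounds.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(comparison))
      write.table(comparison$pairs,
                  file.path(out_dir, paste0(prefix, "_conserved_pairs.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    dput(manifest, file.path(out_dir, paste0(prefix, "_manifest.R")))
  }
  structure(res, class = "sat_run")
}

#' @export
print.sat_run <- function(x, ...) {
  cat(sprintf("satellitome run: %d families\n",
              if (is.null(x$catalog)) 0L else nrow(x$catalog)))
  if (!is.null(x$catalog)) print(x$catalog[, c("name", "monomer_length",
                                               "abundance")])
  invisible(x)
}
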