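#' Specification of one planted satDNA family
#'
#' Describes a tandem-repeat family to be planted in a synthetic genome:
#' its monomer length and base composition, the fraction of library
#' nucleotides the array should occupy, and how far individual copies drift
#' from the consensus. Mirrors the columns of a satellitome catalog table
#' (repeat unit length, A+T %, abundance, divergence).
#'
#' @param label family label used in the truth manifest.
#' @param monomer_length monomer length in bp (>= 10).
#' @param at_fraction target A+T fraction of the monomer, in `[0, 1]`.
#' @param target_abundance fraction of total library nucleotides occupied
#'   by the family's array, in `[0, 1)`.
#' @param copy_divergence_mean expected percent substitutions per copy
#'   relative to the consensus (Poisson per-site process); default 2,
#'   matching the recent-amplification regime typical of abundant
#'   satellites.
#' @param indel_rate per-site indel probability per copy; default 0 (the
#'   distance estimators assume a substitution-only process).
#' @param monomer optional explicit monomer sequence; when `NULL` a random
#'   monomer with the requested composition is generated at build time.
#' @return a `planted_family` list.
#' @export
planted_family <- function(label, monomer_length, at_fraction = 0.56,
                           target_abundance = 0.01,
                           copy_divergence_mean = 2, indel_rate = 0,
                           monomer = NULL) {
  if (monomer_length < 10)
    stop("monomer_length must be >= 10", call. = FALSE)
  if (at_fraction < 0 || at_fraction > 1)
    stop("at_fraction must lie in [0, 1]", call. = FALSE)
  if (target_abundance < 0 || target_abundance >= 1)
    stop("target_abundance must lie in [0, 1)", call. = FALSE)
  if (copy_divergence_mean < 0)
    stop("copy_divergence_mean must be >= 0", call. = FALSE)
  if (!is.null(monomer)) {
    monomer <- check_dna(monomer, "monomer")
    if (nchar(monomer) != monomer_length)
      stop("monomer length does not match monomer_length", call. = FALSE)
  }
  structure(list(label = label, monomer_length = as.integer(monomer_length),
                 at_fraction = at_fraction,
                 target_abundance = target_abundance,
                 copy_divergence_mean = copy_divergence_mean,
                 indel_rate = indel_rate, monomer = monomer),
            class = "planted_family")
}

#' Generate a random monomer with a fixed A+T content
#'
#' The number of A/T bases is the nearest integer (round half to even) to
#' `at_fraction * length`; their positions and the A-vs-T / G-vs-C choices
#' are uniform. Deterministic for a fixed seed.
#'
#' @param length monomer length in bp (>= 10).
#' @param at_fraction target A+T fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a DNA string of exactly `length` bases.
#' @export
make_monomer <- function(length, at_fraction, seed = 1L) {
  if (length < 10) stop("length must be >= 10", call. = FALSE)
  if (at_fraction < 0 || at_fraction > 1)
    stop("at_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  n_at <- round(at_fraction * length)
  bases <- character(length)
  at_pos <- sample.int(length, n_at)
  bases[at_pos] <- sample(c("A", "T"), n_at, replace = TRUE)
  bases[-at_pos] <- sample(c("G", "C"), length - n_at, replace = TRUE)
  if (n_at == 0) bases <- sample(c("G", "C"), length, replace = TRUE)
  paste(bases, collapse = "")
}

#' Evolve a sequence under a Kimura 2-parameter substitution process
#'
#' Each site receives a Poisson(`rate * time`) number of substitution
#' events; each event is a transition with probability
#' `ts_tv_ratio / (ts_tv_ratio + 1)` and otherwise one of the two possible
#' transversions, uniformly. Multiple hits at a site are applied
#' sequentially, so the expected number of substitution events per site is
#' exactly `rate * time` while the observed p-distance saturates, as in the
#' model the K2P estimator inverts. Optionally applies per-site indels
#' (insertion or deletion with equal probability).
#'
#' @param seq DNA string.
#' @param rate substitutions per site per year (>= 0).
#' @param time elapsed time in years (>= 0).
#' @param ts_tv_ratio expected transitions per transversion (> 0);
#'   default 2, the standard vertebrate value.
#' @param indel_rate per-site indel probability; default 0.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return the evolved DNA string.
#' @export
evolve_sequence <- function(seq, rate, time, ts_tv_ratio = 2,
                            indel_rate = 0, seed = NULL) {
  seq <- check_dna(seq)
  if (rate < 0 || time < 0)
    stop("rate and time must be >= 0", call. = FALSE)
  if (ts_tv_ratio <= 0) stop("ts_tv_ratio must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_events <- rpois(n, rate * time)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  for (i in which(n_events > 0L)) {
    b <- bases[i]
    if (b == "N") next
    for (e in seq_len(n_events[i])) {
      if (runif(1) < p_ts) b <- ts_map[[b]] else b <- sample(tv_map[[b]], 1L)
    }
    bases[i] <- b
  }
  if (indel_rate > 0) {
    keep <- runif(length(bases)) >= indel_rate / 2
    ins <- runif(length(bases)) < indel_rate / 2
    out <- character(0)
    for (i in seq_along(bases)) {
      if (keep[i]) out <- c(out, bases[i])
      if (ins[i]) out <- c(out, sample(DNA_BASES, 1L))
    }
    bases <- out
  }
  paste(bases, collapse = "")
}

#' Build a synthetic paired-end read library with planted tandem arrays
#'
#' Constructs a genome of `genome_size` bp: one contiguous head-to-tail
#' tandem array per planted family (each copy independently mutated away
#' from the consensus by its family's `copy_divergence_mean`), embedded at
#' random non-overlapping positions in random background of composition
#' `background_at`. Paired-end reads are then sampled uniformly: each
#' fragment of `2 * read_length` contiguous bases yields a forward read and
#' a reverse-complemented mate, with uniform per-base sequencing errors.
#' The truth manifest tags every pair with the region containing the
#' fragment midpoint, so the manifest-true planted fraction is an unbiased
#' estimate of each family's genomic fraction.
#'
#' @param specs list of [planted_family()] specifications (possibly empty).
#' @param genome_size genome length in bp; must leave room for at least two
#'   full monomer copies per family.
#' @param read_length read length in bp; default 150 (2 x 150 bp paired-end).
#' @param coverage mean sequencing depth; default 2.
#' @param error_rate per-base substitution error probability; default 0.001.
#' @param background_at A+T fraction of the background; default 0.56,
#'   mirroring the mean composition of published fish satellitome catalogs.
#' @param seed integer RNG seed.
#' @return a `read_library` list with `fwd`, `rev` (character vectors of
#'   reads), `read_length`, `manifest` (tibble: `read_id`, `origin`), and
#'   `truth` (tibble of per-family planted monomers, copies and realized
#'   genomic fractions).
#' @export
build_library <- function(specs, genome_size, read_length = 150L,
                          coverage = 2, error_rate = 0.001,
                          background_at = 0.56, seed = 1L) {
  stopifnot(is.list(specs))
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "planted_family")) stop("specs must be planted_family objects")
    s
  })
  ab <- vapply(specs, function(s) s$target_abundance, 0)
  if (sum(ab) >= 1) stop("family abundances must sum to < 1", call. = FALSE)
  set.seed(seed)

  # per-family arrays
  arrays <- list()
  truth_rows <- list()
  for (s in specs) {
    array_nt <- round(s$target_abundance * genome_size)
    n_copies <- round(array_nt / s$monomer_length)
    if (n_copies < 2)
      stop("genome too small: family '", s$label,
           "' array would hold < 2 monomer copies", call. = FALSE)
    monomer <- s$monomer
    if (is.null(monomer))
      monomer <- make_monomer(s$monomer_length, s$at_fraction,
                              seed = sample.int(.Machine$integer.max, 1L))
    copies <- vapply(seq_len(n_copies), function(i)
      evolve_sequence(monomer, rate = s$copy_divergence_mean / 100, time = 1,
                      indel_rate = s$indel_rate), "")
    arr <- paste(copies, collapse = "")
    arrays[[s$label]] <- arr
    truth_rows[[s$label]] <- tibble::tibble(
      label = s$label, monomer = monomer,
      monomer_length = s$monomer_length, n_copies = n_copies,
      target_abundance = s$target_abundance,
      copy_divergence_mean = s$copy_divergence_mean)
  }

  arr_len <- vapply(arrays, nchar, 0L)
  bg_len <- genome_size - sum(arr_len)
  if (bg_len < 0) stop("arrays exceed genome size", call. = FALSE)
  background <- random_dna(bg_len, background_at)

  # place arrays at random cut points of the background
  n_fam <- length(arrays)
  if (n_fam > 0) {
    cuts <- sort(sample.int(bg_len + 1L, n_fam, replace = FALSE)) - 1L
    order_fam <- sample.int(n_fam)
    pieces <- character(0)
    origins <- integer(0) # region table built below
    prev <- 0L
    region_label <- character(0)
    region_len <- integer(0)
    for (i in seq_len(n_fam)) {
      seg <- substr(background, prev + 1L, cuts[i])
      if (nchar(seg) > 0) {
        pieces <- c(pieces, seg)
        region_label <- c(region_label, "background")
        region_len <- c(region_len, nchar(seg))
      }
      lab <- names(arrays)[order_fam[i]]
      pieces <- c(pieces, arrays[[lab]])
      region_label <- c(region_label, lab)
      region_len <- c(region_len, nchar(arrays[[lab]]))
      prev <- cuts[i]
    }
    seg <- substr(background, prev + 1L, bg_len)
    if (nchar(seg) > 0) {
      pieces <- c(pieces, seg)
      region_label <- c(region_label, "background")
      region_len <- c(region_len, nchar(seg))
    }
    genome <- paste(pieces, collapse = "")
  } else {
    genome <- background
    region_label <- "background"
    region_len <- bg_len
  }
  g_len <- nchar(genome)
  region_end <- cumsum(as.numeric(region_len))

  # realized genomic fractions
  if (n_fam > 0) {
    for (lab in names(arrays))
      truth_rows[[lab]]$genome_fraction <- nchar(arrays[[lab]]) / g_len
  }

  # sample read pairs
  frag_len <- 2L * as.integer(read_length)
  n_pairs <- max(1L, round(g_len * coverage / frag_len))
  starts <- sample.int(g_len - frag_len + 1L, n_pairs, replace = TRUE)
  frag <- substring(genome, starts, starts + frag_len - 1L)
  fwd <- substr(frag, 1L, read_length)
  rev <- revcomp(substr(frag, read_length + 1L, frag_len))
  fwd <- add_seq_errors(fwd, error_rate)
  rev <- add_seq_errors(rev, error_rate)
  mid <- starts + frag_len %/% 2L
  origin <- region_label[findInterval(mid - 1L, c(0, region_end),
                                      rightmost.closed = TRUE)]
  manifest <- tibble::tibble(
    read_id = sprintf("read%06d", seq_len(n_pairs)), origin = origin)
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
    tibble::tibble(label = character(0), monomer = character(0),
                   monomer_length = integer(0), n_copies = integer(0),
                   target_abundance = numeric(0),
                   copy_divergence_mean = numeric(0),
                   genome_fraction = numeric(0))
  structure(list(fwd = fwd, rev = rev, read_length = as.integer(read_length),
                 manifest = manifest, truth = truth),
            class = "read_library")
}

# uniform substitution errors over a character vector of reads
add_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < error_rate)
    if (!length(hit)) return(r)
    b <- strsplit(r, "", fixed = TRUE)[[1]]
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(DNA_BASES, x), 1L), "")
    paste(b, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' @export
print.read_library <- function(x, ...) {
  tab <- table(x$manifest$origin)
  cat(sprintf("Paired-end read library: %d pairs of 2 x %d bp\n",
              length(x$fwd), x$read_length))
  cat("  origin:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of read pairs in a library
#' @param lib a `read_library`.
#' @return integer pair count.
#' @export
n_pairs <- function(lib) length(lib$fwd)

#' Manifest-true nucleotide fraction per origin
#'
#' Fraction of library nucleotides whose read pair is tagged with each
#' origin label in the truth manifest. This is the ground truth against
#' which abundance estimates are checked.
#'
#' @param lib a `read_library`.
#' @return named numeric vector of fractions summing to 1.
#' @export
manifest_fractions <- function(lib) {
  tab <- table(lib$manifest$origin)
  as.numeric(tab) / sum(tab) -> fr
  setNames(fr, names(tab))
}

#' Write a read library as paired FASTQ plus a truth manifest
#'
#' Writes `<prefix>_1.fastq`, `<prefix>_2.fastq` (Sanger Phred+33, constant
#' quality `I`) and `<prefix>_manifest.tsv` with columns `read_id`,
#' `origin`. Byte-identical for identical libraries.
#'
#' @param lib a `read_library`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_library_fastq <- function(lib, prefix) {
  ids <- lib$manifest$read_id
  write_one <- function(reads, mate, path) {
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- paste0(ids, "/", mate)
    q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  fm <- paste0(prefix, "_manifest.tsv")
  write_one(lib$fwd, 1L, f1)
  write_one(lib$rev, 2L, f2)
  write.table(lib$manifest, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, fm))
}

#' Read a paired FASTQ library (as written by [write_library_fastq()])
#'
#' @param prefix path prefix used when writing.
#' @return a `read_library` (manifest loaded if present, otherwise all
#'   origins are `NA`).
#' @export
read_library_fastq <- function(prefix) {
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  fwd <- as.character(Biostrings::readDNAStringSet(f1, format = "fastq"))
  rev <- as.character(Biostrings::readDNAStringSet(f2, format = "fastq"))
  fm <- paste0(prefix, "_manifest.tsv")
  manifest <- if (file.exists(fm)) {
    tibble::as_tibble(read.delim(fm, stringsAsFactors = FALSE))
  } else {
    tibble::tibble(read_id = sub("/1$", "", names(fwd)), origin = NA_character_)
  }
  structure(list(fwd = unname(fwd), rev = unname(rev),
                 read_length = nchar(fwd[1]), manifest = manifest,
                 truth = NULL),
            class = "read_library")
}

#' Multi-species drift scenario with shared and private satDNA families
#'
#' Emulates the library hypothesis: related species inherit a common
#' ancestral collection of satDNA monomers which then drift independently
#' in each lineage. Shared families descend from ancestral monomers evolved
#' along an ultrametric species tree reconstructed from the pairwise
#' divergence times (UPGMA on times); private families are drawn fresh per
#' species. True orthology, ancestral monomers and times are recorded so
#' downstream comparative estimates can be checked against the planted
#' substitution rate.
#'
#' @param species character vector of species prefixes (e.g. `c("Mti",
#'   "Cma", "Pme")`).
#' @param times_years named numeric vector of pairwise divergence times in
#'   years, names `"A|B"` with the two species prefixes sorted
#'   alphabetically (see [species_pair_key()]).
#' @param n_shared number of shared (ancestral) families.
#' @param n_private integer vector (recycled) of private families per
#'   species.
#' @param rate substitution rate per site per year.
#' @param ts_tv_ratio transition:transversion ratio of the drift process.
#' @param shared_lengths monomer lengths of the shared families; defaults
#'   to a log-spaced range 1000-2000 bp. Deep (tens of Myr) divergences
#'   leave ~ 30-40 % consensus identity, which is only estimable from
#'   monomers long enough that the true rotation outscores chance
#'   alignments.
#' @param private_lengths monomer lengths of private families (recycled).
#' @param at_fraction A+T fraction of generated monomers.
#' @param library_params optional list of [build_library()] arguments
#'   (`genome_size`, `coverage`, `read_length`, `error_rate`,
#'   `abundance_range`); when supplied, a read library is generated per
#'   species.
#' @param seed integer RNG seed.
#' @return a `sat_scenario` list: `catalogs` (per species, tibble with
#'   `label`, `consensus`, `monomer_length`, `abundance`), `truth` (list
#'   with `ancestral_monomers`, `ortholog_map`, `times_years`, `rate`,
#'   `shared_labels`, `private_labels`), and `libraries` (per species or
#'   `NULL`).
#' @export
make_species_scenario <- function(species, times_years, n_shared = 5L,
                                  n_private = 2L, rate = 1.85e-8,
                                  ts_tv_ratio = 2,
                                  shared_lengths = NULL,
                                  private_lengths = 60L,
                                  at_fraction = 0.56,
                                  library_params = NULL, seed = 1L) {
  n_sp <- length(species)
  stopifnot(n_sp >= 2)
  if (any(times_years <= 0)) stop("divergence times must be > 0", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  for (i in seq_len(n_sp - 1)) for (j in seq(i + 1, n_sp)) {
    key <- species_pair_key(species[i], species[j])
    if (!key %in% names(times_years))
      stop("missing divergence time for pair ", key, call. = FALSE)
  }
  set.seed(seed)
  if (is.null(shared_lengths))
    shared_lengths <- round(exp(seq(log(1000), log(2000),
                                    length.out = max(2, n_shared))))
  shared_lengths <- rep_len(as.integer(shared_lengths), n_shared)
  private_lengths <- rep_len(as.integer(private_lengths), n_sp * 1L)
  n_private <- rep_len(as.integer(n_private), n_sp)

  # ultrametric species tree from pairwise times (UPGMA merge order)
  tmat <- matrix(0, n_sp, n_sp, dimnames = list(species, species))
  for (i in seq_len(n_sp - 1)) for (j in seq(i + 1, n_sp)) {
    key <- species_pair_key(species[i], species[j])
    tmat[i, j] <- tmat[j, i] <- times_years[[key]]
  }
  hc <- if (n_sp > 2) stats::hclust(stats::as.dist(tmat), method = "average")
        else NULL

  shared_labels <- sprintf("shared%02d", seq_len(n_shared))
  anc <- setNames(vapply(seq_len(n_shared), function(i)
    make_monomer(shared_lengths[i], at_fraction,
                 seed = sample.int(.Machine$integer.max, 1L)), ""),
    shared_labels)

  # evolve each ancestral monomer down the clock tree; each leaf sits at
  # height 0, the root at the deepest divergence time
  evolve_tree <- function(monomer) {
    if (n_sp == 2) {
      t2 <- times_years[[species_pair_key(species[1], species[2])]]
      return(setNames(
        lapply(species, function(s)
          evolve_sequence(monomer, rate, t2, ts_tv_ratio)), species))
    }
    heights <- hc$height
    seqs_at <- list() # sequences entering each hclust node
    n_leaf <- n_sp
    node_seq <- vector("list", nrow(hc$merge))
    root <- nrow(hc$merge)
    # walk from root down: assign to each node the sequence evolved from its
    # parent over (parent_height - node_height)
    desc <- function(node, seq_in, h_parent) {
      res <- list()
      if (node < 0) { # leaf; evolve over the remaining height
        leaf <- hc$labels[-node]
        res[[leaf]] <- evolve_sequence(seq_in, rate, h_parent, ts_tv_ratio)
        return(res)
      }
      h <- heights[node]
      s <- evolve_sequence(seq_in, rate, h_parent - h, ts_tv_ratio)
      c(desc(hc$merge[node, 1], s, h), desc(hc$merge[node, 2], s, h))
    }
    desc(root, monomer, heights[root])
  }

  catalogs <- setNames(vector("list", n_sp), species)
  derived <- lapply(anc, evolve_tree)
  priv_labels <- setNames(vector("list", n_sp), species)
  for (si in seq_len(n_sp)) {
    sp <- species[si]
    labs <- shared_labels
    seqs <- vapply(derived, function(d) d[[sp]], "")
    npv <- n_private[si]
    if (npv > 0) {
      pl <- sprintf("%s_private%02d", sp, seq_len(npv))
      ps <- vapply(seq_len(npv), function(i)
        make_monomer(rep_len(private_lengths, npv)[i], at_fraction,
                     seed = sample.int(.Machine$integer.max, 1L)), "")
      labs <- c(labs, pl)
      seqs <- c(seqs, ps)
      priv_labels[[sp]] <- pl
    } else priv_labels[[sp]] <- character(0)
    ab <- 0.01 * 0.7^(seq_along(labs) - 1)
    catalogs[[sp]] <- tibble::tibble(
      label = labs, consensus = unname(seqs),
      monomer_length = nchar(unname(seqs)), abundance = ab,
      species = sp)
  }

  libraries <- NULL
  if (!is.null(library_params)) {
    lp <- library_params
    libraries <- setNames(lapply(seq_len(n_sp), function(si) {
      cat_i <- catalogs[[species[si]]]
      specs <- lapply(seq_len(nrow(cat_i)), function(r)
        planted_family(cat_i$label[r], cat_i$monomer_length[r],
                       target_abundance = cat_i$abundance[r],
                       copy_divergence_mean = lp$copy_divergence_mean %||% 2,
                       monomer = cat_i$consensus[r]))
      build_library(specs, genome_size = lp$genome_size %||% 5e5,
                    read_length = lp$read_length %||% 150L,
                    coverage = lp$coverage %||% 2,
                    error_rate = lp$error_rate %||% 0.001,
                    seed = sample.int(.Machine$integer.max, 1L))
    }), species)
  }

  structure(list(
    catalogs = catalogs,
    truth = list(ancestral_monomers = anc, times_years = times_years,
                 rate = rate, shared_labels = shared_labels,
                 private_labels = priv_labels, species = species),
    libraries = libraries
  ), class = "sat_scenario")
}

#' Write a drift scenario's configuration as a plain-text key-value file
#'
#' Records species, substitution rate, pairwise divergence times and the
#' shared/private family labels of a [make_species_scenario()] object, one
#' `key = value` pair per line; ancestral monomers are written alongside
#' as FASTA.
#'
#' @param scenario a `sat_scenario`.
#' @param prefix output path prefix (writes `<prefix>_config.txt` and
#'   `<prefix>_ancestral.fasta`).
#' @return invisibly, the two file paths.
#' @export
write_scenario_config <- function(scenario, prefix) {
  tr <- scenario$truth
  lines <- c(
    paste0("species = ", paste(tr$species, collapse = ",")),
    paste0("substitution_rate = ", format(tr$rate, digits = 15)),
    vapply(names(tr$times_years), function(k)
      paste0("divergence_time_years.", k, " = ",
             format(tr$times_years[[k]], digits = 15)), ""),
    paste0("shared_families = ", paste(tr$shared_labels, collapse = ",")),
    vapply(tr$species, function(sp)
      paste0("private_families.", sp, " = ",
             paste(tr$private_labels[[sp]], collapse = ",")), ""))
  cfg <- paste0(prefix, "_config.txt")
  fa <- paste0(prefix, "_ancestral.fasta")
  writeLines(lines, cfg)
  x <- Biostrings::DNAStringSet(tr$ancestral_monomers)
  Biostrings::writeXStringSet(x, fa)
  invisible(c(cfg, fa))
}

#' Canonical key for a species pair
#'
#' @param a,b species prefixes.
#' @return `"A|B"` with the prefixes sorted alphabetically, so the key does
#'   not depend on argument order.
#' @export
species_pair_key <- function(a, b) {
  s <- sort(c(a, b))
  paste(s, collapse = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
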