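#' Subsample read pairs from a library
#'
#' Uniform sampling without replacement, preserving the original pair
#' order; deterministic for a fixed seed.
#'
#' @param lib a `read_library`.
#' @param n_pairs number of pairs to keep (`<=` available pairs).
#' @param seed integer RNG seed.
#' @return a `read_library` with `n_pairs` pairs.
#' @export
subsample_reads <- function(lib, n_pairs, seed = 1L) {
  n <- length(lib$fwd)
  if (n_pairs > n) stop("n_pairs exceeds available pairs", call. = FALSE)
  set.seed(seed)
  keep <- sort(sample.int(n, n_pairs))
  out <- lib
  out$fwd <- lib$fwd[keep]
  out$rev <- lib$rev[keep]
  out$manifest <- lib$manifest[keep, , drop = FALSE]
  out
}

# k-mer count table over both mates of a library; data.table with columns
# km (character) and N (count)
count_kmers <- function(reads, k) {
  reads <- reads[nchar(reads) >= k]
  if (!length(reads)) return(data.table::data.table(km = character(0), N = integer(0)))
  by_len <- split(reads, nchar(reads))
  km <- unlist(lapply(by_len, function(rr) {
    L <- nchar(rr[1])
    unlist(lapply(seq_len(L - k + 1L), function(s) substr(rr, s, s + k - 1L)),
           use.names = FALSE)
  }), use.names = FALSE)
  dt <- data.table::data.table(km = km)
  dt <- dt[!grepl("N", km, fixed = TRUE)]
  dt[, list(N = .N), by = "km"]
}

#' Detect tandem-repeat consensus candidates from reads
#'
#' Reimplements the core of graph-based tandem-repeat detection: count
#' k-mers over both mates, keep those above an abundance floor, and walk
#' the k-mer adjacency greedily (always extending to the heaviest unvisited
#' successor). A walk that returns to a k-mer already on its path closes a
#' cycle, which is spelled into a circular consensus; each consensus is
#' refined by one round of read realignment and per-column majority vote,
#' then normalized to its canonical rotation/strand. Candidates whose
#' k-mer-mass abundance estimate falls below `min_abundance`, or with fewer
#' supporting reads than `min_support`, are discarded.
#'
#' The floors are expressed relative to the effective coverage of the
#' sample, estimated as the mass-weighted median k-mer count (robust to the
#' singleton error k-mers that dominate the plain median): background
#' k-mers occur about `coverage` times while tandem-repeat k-mers occur
#' `copies x coverage` times, so walk seeds must exceed
#' `floor_mult x coverage`. Cycle extension uses a laxer floor (`ext_mult`)
#' so a single under-sampled k-mer does not break an otherwise
#' well-supported cycle.
#'
#' @param reads a `read_library`.
#' @param k k-mer size (11 <= k < read length); default 21.
#' @param min_abundance minimum k-mer-mass abundance estimate for a
#'   reported candidate; default 2e-4. The estimate (cycle k-mer mass over
#'   total mass, doubled because a cycle covers one strand) underestimates
#'   the true genomic fraction when copies are diverged, so this floor is
#'   intentionally below the abundance floor of interest; final abundances
#'   come from [estimate_abundance()].
#' @param min_support minimum number of supporting read pairs; default 50.
#' @param floor_mult seed floor as a multiple of the effective coverage;
#'   default 3.
#' @param ext_mult extension floor multiplier; default 1.5.
#' @param min_monomer minimum monomer (cycle) length; default 10.
#' @param max_candidates safety cap on reported candidates per call.
#' @return tibble of candidates: `consensus`, `monomer_length`,
#'   `supporting_read_count`, `kmer_abundance` (mass-fraction estimate).
#' @export
detect_tandem_families <- function(reads, k = 21L, min_abundance = 2e-4,
                                   min_support = 50L, floor_mult = 3,
                                   ext_mult = 1.5, min_monomer = 10L,
                                   max_candidates = 50L) {
  if (!length(reads$fwd)) stop("read library is empty", call. = FALSE)
  if (k < 11L || k >= reads$read_length)
    stop("require 11 <= k < read_length", call. = FALSE)
  allreads <- c(reads$fwd, reads$rev)
  cnt <- count_kmers(allreads, k)
  empty <- tibble::tibble(consensus = character(0),
                          monomer_length = integer(0),
                          supporting_read_count = integer(0),
                          kmer_abundance = numeric(0))
  if (!nrow(cnt)) return(empty)
  total_mass <- sum(cnt$N)
  # effective coverage: the k-mer count below which half the k-mer MASS
  # lies. The plain median is dragged to 1-2 by singleton error k-mers.
  ord <- order(cnt$N)
  cum <- cumsum(as.numeric(cnt$N[ord]))
  cov_eff <- cnt$N[ord][which(cum >= total_mass / 2)[1]]
  seed_floor <- max(6, floor_mult * cov_eff)
  ext_floor <- max(4, ext_mult * cov_eff)

  # only k-mers at or above the extension floor can ever contribute to a
  # walk, so the lookup table is restricted to them (missing => 0)
  live <- cnt[cnt$N >= ext_floor, ]
  counts <- list2env(setNames(as.list(live$N), live$km),
                     envir = new.env(parent = emptyenv(),
                                     size = max(16L, nrow(live))))
  getc <- function(km) {
    v <- counts[[km]]
    if (is.null(v)) 0L else v
  }
  visited <- new.env(parent = emptyenv())

  heavy <- cnt[cnt$N >= seed_floor, ]
  heavy <- heavy[order(-heavy$N), ]
  out <- list()
  for (si in seq_len(nrow(heavy))) {
    if (length(out) >= max_candidates) break
    seedkm <- heavy$km[si]
    if (!is.null(visited[[seedkm]])) next
    # greedy walk
    path <- character(0)
    pos <- new.env(parent = emptyenv())
    cur <- seedkm
    cycle <- NULL
    repeat {
      if (!is.null(pos[[cur]])) { # cycle closed
        start <- pos[[cur]]
        cycle <- path[start:length(path)]
        break
      }
      pos[[cur]] <- length(path) + 1L
      path <- c(path, cur)
      suf <- substr(cur, 2L, k)
      succ <- paste0(suf, DNA_BASES)
      w <- vapply(succ, getc, 0L)
      w[w < ext_floor] <- 0L
      if (all(w == 0L)) break # dead end
      cur <- succ[which.max(w)]
      if (length(path) > 5000L) break # runaway guard
    }
    for (km in path) visited[[km]] <- TRUE
    for (km in path) visited[[revcomp(km)]] <- TRUE
    if (is.null(cycle) || length(cycle) < min_monomer) next
    consensus <- paste(substr(cycle, 1L, 1L), collapse = "")
    mass <- sum(vapply(cycle, getc, 0L))
    kmer_abundance <- 2 * mass / total_mass # cycle covers one strand
    if (kmer_abundance < min_abundance) next
    out[[length(out) + 1L]] <- list(consensus = consensus,
                                    kmer_abundance = kmer_abundance,
                                    cycle = cycle)
  }
  if (!length(out)) return(empty)

  # drop duplicate cycles (phase/strand variants of one repeat) before the
  # expensive support/refinement step; keep the heaviest representative
  out <- out[order(-vapply(out, function(x) x$kmer_abundance, 0))]
  uniq <- list()
  for (cand in out) {
    dup <- any(vapply(uniq, function(u)
      similarity(cand$consensus, u$consensus) > 95, TRUE))
    if (!dup) uniq[[length(uniq) + 1L]] <- cand
  }
  out <- uniq

  # support counting + one refinement round per candidate
  res <- lapply(out, function(cand) {
    sup <- reads_with_kmers(reads, cand$cycle, k)
    if (length(sup) < min_support) return(NULL)
    refined <- refine_consensus(cand$consensus,
                                c(reads$fwd[sup], reads$rev[sup]))
    tibble::tibble(consensus = canonical_rotation(refined),
                   monomer_length = nchar(refined),
                   supporting_read_count = length(sup),
                   kmer_abundance = cand$kmer_abundance)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(empty)
  dplyr::bind_rows(res)
}

# indices of read pairs with at least one exact k-mer from `kms` (either
# strand, either mate)
reads_with_kmers <- function(lib, kms, k) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unique(c(kms, revcomp(kms)))))
  hit_one <- function(reads) {
    m <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(reads),
                                 collapse = 2)
    m > 0
  }
  which(hit_one(lib$fwd) | hit_one(lib$rev))
}

# one round of realignment + per-column majority vote. Reads are locally
# aligned to the tiled consensus; each ungapped column votes for its
# consensus position (positions taken modulo the monomer length).
refine_consensus <- function(consensus, reads, min_identity = 70,
                             max_reads = 200L) {
  L <- nchar(consensus)
  dbl <- tile_consensus(consensus, max(nchar(reads)))
  if (length(reads) > max_reads) reads <- reads[seq_len(max_reads)]
  votes <- matrix(0L, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  for (r in reads) {
    best <- NULL
    for (q in c(r, revcomp(r))) {
      h <- sw_align_cpp(q, dbl)
      if (is.null(best) || h$score > best$score) best <- h
    }
    if (best$columns < 20) next
    if (100 * best$matches / best$columns < min_identity) next
    a <- strsplit(best$a_aln, "", fixed = TRUE)[[1]]
    b <- strsplit(best$b_aln, "", fixed = TRUE)[[1]]
    bpos <- best$b_start - 1L
    for (ci in seq_along(a)) {
      if (b[ci] != "-") bpos <- bpos + 1L
      if (a[ci] %in% DNA_BASES && b[ci] != "-") {
        cpos <- ((bpos - 1L) %% L) + 1L
        votes[a[ci], cpos] <- votes[a[ci], cpos] + 1L
      }
    }
  }
  base_of <- apply(votes, 2, function(v)
    if (sum(v) == 0) NA_character_ else DNA_BASES[which.max(v)])
  orig <- strsplit(consensus, "", fixed = TRUE)[[1]]
  base_of[is.na(base_of)] <- orig[is.na(base_of)]
  paste(base_of, collapse = "")
}

#' Remove read pairs matching known satDNA families
#'
#' A pair is removed when either mate aligns locally (either strand) to any
#' family's tiled consensus at `>= identity_threshold` percent identity
#' over at least `coverage_threshold` of the read length. Exact-k-mer
#' prefiltering keeps the scan fast; both mates of a matching pair are
#' always removed together.
#'
#' @param lib a `read_library`.
#' @param families tibble with a `consensus` column (e.g. output of
#'   [detect_tandem_families()]), or an empty/`NULL` value to leave the
#'   library unchanged.
#' @param identity_threshold percent identity, in (0, 100]; default 80.
#' @param coverage_threshold fraction of the read that must be covered by
#'   the alignment, in (0, 1]; default 0.5.
#' @param prefilter_k k-mer size of the exact prefilter; default 12.
#' @return the filtered `read_library`.
#' @export
subtract_matching_reads <- function(lib, families, identity_threshold = 80,
                                    coverage_threshold = 0.5,
                                    prefilter_k = 12L) {
  if (is.null(families) || !nrow(families)) return(lib)
  if (identity_threshold <= 0 || identity_threshold > 100)
    stop("identity_threshold must lie in (0, 100]", call. = FALSE)
  if (coverage_threshold <= 0 || coverage_threshold > 1)
    stop("coverage_threshold must lie in (0, 1]", call. = FALSE)
  drop <- rep(FALSE, length(lib$fwd))
  for (cons in families$consensus) {
    for (mate in c("fwd", "rev")) {
      idx <- which(!drop)
      if (!length(idx)) break
      cand <- idx[prefilter_hits(lib[[mate]][idx], cons, prefilter_k)]
      for (i in cand) {
        h <- read_family_hit(lib[[mate]][i], cons)
        if (is.null(h)) next
        span <- h$read_span
        if (h$identity >= identity_threshold &&
            span >= coverage_threshold * nchar(lib[[mate]][i]))
          drop[i] <- TRUE
      }
    }
  }
  out <- lib
  out$fwd <- lib$fwd[!drop]
  out$rev <- lib$rev[!drop]
  out$manifest <- lib$manifest[!drop, , drop = FALSE]
  out
}

# logical vector: which reads share an exact prefilter k-mer with the
# tiled consensus (either strand)
prefilter_hits <- function(reads, consensus, k = 12L) {
  dbl <- tile_consensus(consensus, k)
  n <- nchar(dbl)
  kms <- unique(substring(dbl, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  kms <- unique(c(kms, revcomp(kms)))
  kms <- kms[!grepl("N", kms, fixed = TRUE)]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kms))
  Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(reads), collapse = 2) > 0
}

# tile a circular consensus so that a linear window of `span` bases can
# align at any phase: total length >= span + monomer length
tile_consensus <- function(consensus, span) {
  L <- nchar(consensus)
  strrep(consensus, max(2L, ceiling(span / L) + 1L))
}

# best local hit of one read against the tiled consensus (both strands);
# returns NULL when nothing aligns. identity is percent over aligned
# columns; read_span the number of read bases inside the alignment;
# divergence the K2P (fallback JC, fallback p) percent over ungapped
# columns.
read_family_hit <- function(read, consensus) {
  dbl <- tile_consensus(consensus, nchar(read))
  best <- NULL
  best_strand <- "forward"
  for (strand in c("forward", "reverse-complement")) {
    q <- if (strand == "forward") read else revcomp(read)
    h <- sw_align_cpp(q, dbl)
    if (is.null(best) || h$score > best$score) {
      best <- h
      best_strand <- strand
    }
  }
  if (best$columns == 0) return(NULL)
  cls <- classify_columns(best$a_aln, best$b_aln)
  ungapped <- cls$columns - cls$gap_columns - cls$ambiguous
  p <- if (ungapped > 0) (cls$transitions + cls$transversions) / ungapped else NA_real_
  K <- if (ungapped > 0) k2p(cls$transitions / ungapped,
                             cls$transversions / ungapped) else NA_real_
  div <- if (!is.na(K)) 100 * K
         else if (!is.na(p) && !is.na(jc(min(p, 0.749)))) 100 * jc(min(p, 0.749))
         else 100 * p
  read_span <- best$a_end - best$a_start + 1L
  list(identity = 100 * cls$matches / cls$columns,
       matched_nt = read_span, read_span = read_span,
       divergence = div, strand = best_strand, score = best$score)
}

#' Iterative satDNA discovery by detect-and-subtract rounds
#'
#' Repeats subsample -> detect -> subtract until a round yields no new
#' candidate families (a candidate is new when its similarity to every
#' previously retained family is `<= new_family_threshold`) or `max_rounds`
#' is reached. Each retained family is annotated with its discovery round.
#'
#' @param lib a `read_library`.
#' @param subsample_pairs pairs per round; default 50000 (use smaller
#'   values for desk-scale runs; the full-scale protocol uses 500000).
#' @param k k-mer size passed to [detect_tandem_families()].
#' @param min_abundance,min_support candidate filters, see
#'   [detect_tandem_families()].
#' @param identity_threshold,coverage_threshold subtraction thresholds, see
#'   [subtract_matching_reads()].
#' @param new_family_threshold percent similarity above which a candidate
#'   duplicates a known family; default 95.
#' @param max_rounds round cap; default 8.
#' @param seed integer RNG seed (per-round subsample seeds derive from it).
#' @param verbose print a per-round log line.
#' @return tibble of candidate families with `consensus`,
#'   `monomer_length`, `supporting_read_count`, `kmer_abundance`,
#'   `discovery_round`; the per-round log is attached as attribute
#'   `"rounds"` (tibble: round, candidates_found, new_families,
#'   reads_remaining).
#' @export
iterate_discovery <- function(lib, subsample_pairs = 50000L, k = 21L,
                              min_abundance = 5e-4, min_support = 50L,
                              identity_threshold = 80,
                              coverage_threshold = 0.5,
                              new_family_threshold = 95,
                              max_rounds = 8L, seed = 1L, verbose = FALSE) {
  families <- NULL
  log_rows <- list()
  cur <- lib
  for (round in seq_len(max_rounds)) {
    ns <- min(subsample_pairs, length(cur$fwd))
    if (ns == 0L) break
    sub <- subsample_reads(cur, ns, seed = seed + round)
    cand <- detect_tandem_families(sub, k = k, min_abundance = min_abundance,
                                   min_support = min_support)
    is_new <- rep(TRUE, nrow(cand))
    if (!is.null(families) && nrow(cand)) {
      for (i in seq_len(nrow(cand))) {
        sims <- vapply(families$consensus, function(f)
          similarity(cand$consensus[i], f), 0)
        if (any(sims > new_family_threshold)) is_new[i] <- FALSE
      }
    }
    new_fams <- cand[is_new, , drop = FALSE]
    # also dedupe within the round
    if (nrow(new_fams) > 1) {
      keep <- rep(TRUE, nrow(new_fams))
      for (i in seq(2, nrow(new_fams))) for (j in seq_len(i - 1)) {
        if (keep[j] && keep[i] &&
            similarity(new_fams$consensus[i], new_fams$consensus[j]) >
              new_family_threshold) keep[i] <- FALSE
      }
      new_fams <- new_fams[keep, , drop = FALSE]
    }
    if (nrow(new_fams)) {
      new_fams$discovery_round <- round
      families <- if (is.null(families)) new_fams else
        dplyr::bind_rows(families, new_fams)
    }
    if (nrow(cand)) cur <- subtract_matching_reads(
      cur, cand, identity_threshold, coverage_threshold)
    log_rows[[round]] <- tibble::tibble(
      round = round, candidates_found = nrow(cand),
      new_families = nrow(new_fams), reads_remaining = length(cur$fwd))
    if (verbose)
      message(sprintf("round %d: %d candidates, %d new, %d pairs left",
                      round, nrow(cand), nrow(new_fams), length(cur$fwd)))
    if (nrow(new_fams) == 0L) break
  }
  if (is.null(families))
    families <- tibble::tibble(consensus = character(0),
                               monomer_length = integer(0),
                               supporting_read_count = integer(0),
                               kmer_abundance = numeric(0),
                               discovery_round = integer(0))
  attr(families, "rounds") <- dplyr::bind_rows(log_rows)
  families
}
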