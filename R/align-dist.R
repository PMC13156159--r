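#' Best circular, strand-aware global alignment of two monomers
#'
#' Tandem-repeat monomers are circular and strand-less: two consensus
#' sequences describe the same repeat if one is a rotation and/or reverse
#' complement of the other. This function globally aligns `a` against every
#' rotation of `b` and of `revcomp(b)` (Needleman-Wunsch, match = +1,
#' mismatch = -1, gap column = -2) and returns the alignment with the
#' highest identity, defined as `100 * matches / aligned columns` with gap
#' columns included in the denominator. Ties are broken in favour of the
#' forward strand, then the smallest rotation offset. Substituted columns
#' are classified into transitions (A<->G, C<->T) and transversions; columns
#' involving N count as mismatches but are excluded from both substitution
#' counts.
#'
#' For rotations longer than `rotation_limit` the exhaustive rotation scan
#' is replaced by a doubled-sequence local-alignment shortcut that locates
#' the best rotation first and then runs the single global alignment there;
#' the two strategies agree on the brute-force oracle set.
#'
#' @param a,b single DNA strings (non-empty).
#' @param rotation_limit monomer length above which the doubled-sequence
#'   shortcut replaces the exhaustive rotation scan.
#' @return an object of class `sat_alignment`: a list with
#'   `rotation_offset` (left-rotation applied to `a`'s frame to reach `b`'s
#'   start), `strand` (`"forward"` or `"reverse-complement"`),
#'   `aligned_columns`, `matches`, `P_count` (transitions), `Q_count`
#'   (transversions), `ambiguous`, `gap_columns`, `identity` (percent), and
#'   the two gapped alignment strings `a_aln`, `b_aln`.
#' @export
#' @examples
#' s <- "ACGTACGTTAGC"
#' best_circular_alignment(s, rotate_seq(s, 3))$identity
best_circular_alignment <- function(a, b, rotation_limit = 500L) {
  a <- check_dna(a, "a")
  b <- check_dna(b, "b")
  cand <- list(
    forward = .circular_one_strand(a, b, rotation_limit),
    `reverse-complement` = .circular_one_strand(a, revcomp(b), rotation_limit)
  )
  pick <- if (cand[[2]]$identity > cand[[1]]$identity + 1e-12) 2L else 1L
  res <- cand[[pick]]
  res$strand <- names(cand)[pick]
  cls <- classify_columns(res$a_aln, res$b_aln)
  out <- list(
    rotation_offset = res$rotation_offset,
    strand = res$strand,
    aligned_columns = cls$columns,
    matches = cls$matches,
    P_count = cls$transitions,
    Q_count = cls$transversions,
    ambiguous = cls$ambiguous,
    gap_columns = cls$gap_columns,
    identity = 100 * cls$matches / cls$columns,
    a_aln = res$a_aln,
    b_aln = res$b_aln
  )
  structure(out, class = "sat_alignment")
}

.circular_one_strand <- function(a, b, rotation_limit) {
  m <- nchar(b)
  if (m <= rotation_limit && nchar(a) <= rotation_limit) {
    r <- circular_nw_cpp(a, b)
    return(list(rotation_offset = r$rotation_offset, matches = r$matches,
                columns = r$columns,
                identity = 100 * r$matches / max(1L, r$columns),
                a_aln = r$a_aln, b_aln = r$b_aln))
  }
  # doubled-sequence shortcut: locate the best rotation by one local
  # alignment against b+b, then align globally at that rotation (and its
  # neighbours, to absorb local-alignment end effects)
  loc <- sw_align_cpp(a, paste0(b, b))
  k0 <- (loc$b_start - 1L) %% m
  best <- NULL
  for (k in unique(((k0 + c(-1L, 0L, 1L)) %% m + m) %% m)) {
    nw <- nw_align_cpp(a, rotate_seq(b, k))
    ident <- 100 * nw$matches / max(1L, nw$columns)
    r <- (m - k) %% m
    if (is.null(best) || ident > best$identity + 1e-12 ||
        (abs(ident - best$identity) <= 1e-12 && r < best$rotation_offset)) {
      best <- list(rotation_offset = r, matches = nw$matches,
                   columns = nw$columns, identity = ident,
                   a_aln = nw$a_aln, b_aln = nw$b_aln)
    }
  }
  best
}

#' @export
print.sat_alignment <- function(x, ...) {
  cat(sprintf(
    "Circular alignment: identity %.2f%% (%d/%d columns), strand %s, offset %d\n",
    x$identity, x$matches, x$aligned_columns, x$strand, x$rotation_offset))
  cat(sprintf("  transitions %d, transversions %d, gap columns %d\n",
              x$P_count, x$Q_count, x$gap_columns))
  invisible(x)
}

#' Percent similarity between two monomers
#'
#' Identity of the best circular, strand-aware global alignment (see
#' [best_circular_alignment()]), in percent over all aligned columns
#' including gaps. Because [best_circular_alignment()] rotates only its
#' second argument, the raw identity can differ slightly between the two
#' argument orders when the monomers have different lengths; `similarity`
#' therefore evaluates both orientations and returns the larger identity,
#' which makes it exactly symmetric. This is the quantity thresholded when
#' grouping consensus sequences into same-variant (> 95), variant (> 80)
#' and superfamily (> 50) tiers, and when calling families conserved
#' across species (>= 50).
#'
#' @inheritParams best_circular_alignment
#' @return similarity in percent.
#' @export
similarity <- function(a, b, rotation_limit = 500L) {
  max(best_circular_alignment(a, b, rotation_limit)$identity,
      best_circular_alignment(b, a, rotation_limit)$identity)
}

#' Kimura 2-parameter distance from transition/transversion fractions
#'
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, with `P` the fraction of
#' sites showing a transition and `Q` the fraction showing a transversion.
#' When the argument of either logarithm is non-positive the estimator is
#' saturated and `NA_real_` is returned (a typed signal, not an error).
#'
#' @param P,Q transition and transversion fractions, `P, Q >= 0`,
#'   `P + Q <= 1`.
#' @return the K2P distance in substitutions/site, or `NA_real_` on
#'   saturation.
#' @export
#' @examples
#' k2p(0.10, 0.05) # 0.1702
k2p <- function(P, Q) {
  if (!is.numeric(P) || !is.numeric(Q) || any(is.na(c(P, Q))))
    stop("P and Q must be numeric", call. = FALSE)
  if (P < 0 || Q < 0 || P + Q > 1 + 1e-12)
    stop("require P >= 0, Q >= 0 and P + Q <= 1", call. = FALSE)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Jukes-Cantor distance from a p-distance
#'
#' `d = -3/4 * ln(1 - 4p/3)`. Used as the fallback when the K2P estimator
#' saturates on highly diverged pairs. Saturates itself at `p >= 0.75`
#' (returns `NA_real_`).
#'
#' @param p observed proportion of differing sites, in `[0, 1]`.
#' @return the Jukes-Cantor distance in substitutions/site, or `NA_real_`
#'   on saturation.
#' @export
#' @examples
#' jc(0.30) # 0.3831
jc <- function(p) {
  if (!is.numeric(p) || any(is.na(p)))
    stop("p must be numeric", call. = FALSE)
  if (p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise evolutionary distance between two monomer consensus sequences
#'
#' Aligns `a` and `b` with [best_circular_alignment()], computes the
#' substitution fractions over ungapped, unambiguous columns, and estimates
#' the distance with the Kimura 2-parameter model, falling back to the
#' Jukes-Cantor correction when K2P saturates (as is common for deeply
#' diverged satellite families). When both estimators saturate the method is
#' `"undefined"` and such pairs should be excluded from means.
#'
#' The substitution models are gap-free, so when the two monomers have the
#' same length (length-conserved families, or any substitution-only
#' process) the substitution fractions are counted over the best *gapless*
#' circular rotation: at deep divergence a gapped aligner shifts segments
#' to manufacture chance matches, which inflates identity and collapses the
#' distance estimate, whereas the gapless rotation is the alignment the
#' model actually assumes. For monomers of unequal length the gapped
#' circular alignment is used and gap columns are excluded from the
#' substitution fractions.
#'
#' @inheritParams best_circular_alignment
#' @param alignment `"auto"` (gapless when lengths are equal, gapped
#'   otherwise), `"gapless"` (requires equal lengths) or `"gapped"`.
#' @return a `sat_distance` list with `p_distance`, `K` (K2P), `jc`,
#'   `method_used` (`"K2P"`, `"JC"` or `"undefined"`), `distance` (the value
#'   selected by `method_used`, `NA` if undefined), `similarity` (percent)
#'   and the underlying `alignment`.
#' @export
seq_distance <- function(a, b, rotation_limit = 500L,
                         alignment = c("auto", "gapless", "gapped")) {
  alignment <- match.arg(alignment)
  a <- check_dna(a, "a")
  b <- check_dna(b, "b")
  if (alignment == "auto")
    alignment <- if (nchar(a) == nchar(b)) "gapless" else "gapped"
  if (alignment == "gapless") {
    if (nchar(a) != nchar(b))
      stop("gapless distance requires equal-length sequences", call. = FALSE)
    cand <- list(forward = circular_gapless_cpp(a, b),
                 `reverse-complement` = circular_gapless_cpp(a, revcomp(b)))
    pick <- if (cand[[2]]$matches > cand[[1]]$matches) 2L else 1L
    g <- cand[[pick]]
    cls <- classify_columns(a, g$b_rot)
    aln <- structure(list(
      rotation_offset = g$rotation_offset, strand = names(cand)[pick],
      aligned_columns = cls$columns, matches = cls$matches,
      P_count = cls$transitions, Q_count = cls$transversions,
      ambiguous = cls$ambiguous, gap_columns = 0L,
      identity = 100 * cls$matches / cls$columns,
      a_aln = a, b_aln = g$b_rot), class = "sat_alignment")
  } else {
    # symmetrize over the two argument orders (see similarity())
    a1 <- best_circular_alignment(a, b, rotation_limit)
    a2 <- best_circular_alignment(b, a, rotation_limit)
    aln <- if (a2$identity > a1$identity + 1e-12) a2 else a1
  }
  n_sub_cols <- aln$aligned_columns - aln$gap_columns - aln$ambiguous
  if (n_sub_cols <= 0) {
    P <- Q <- p <- NA_real_
  } else {
    P <- aln$P_count / n_sub_cols
    Q <- aln$Q_count / n_sub_cols
    p <- (aln$P_count + aln$Q_count) / n_sub_cols
  }
  K <- if (is.na(P)) NA_real_ else k2p(P, Q)
  d_jc <- if (is.na(p)) NA_real_ else jc(p)
  method <- if (!is.na(K)) "K2P" else if (!is.na(d_jc)) "JC" else "undefined"
  structure(list(
    p_distance = p, K = K, jc = d_jc, method_used = method,
    distance = switch(method, K2P = K, JC = d_jc, NA_real_),
    similarity = aln$identity, alignment = aln
  ), class = "sat_distance")
}

#' @export
print.sat_distance <- function(x, ...) {
  cat(sprintf("p = %.4f, K2P = %s, JC = %s, method = %s\n",
              x$p_distance,
              ifelse(is.na(x$K), "saturated", sprintf("%.4f", x$K)),
              ifelse(is.na(x$jc), "saturated", sprintf("%.4f", x$jc)),
              x$method_used))
  invisible(x)
}
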