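# Independent brute-force oracle for circular alignment, written as a
# plain-R dynamic program. Objective identical to the documented contract:
# maximize score (match +1, mismatch -1, gap -2), then matches, then
# minimize gap columns; identity = matches / columns with gap columns in
# the denominator; best rotation by identity, ties to the forward strand
# and then the smallest rotation offset.

oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  # cell = c(score, matches, gaps); lexicographic better()
  better <- function(x, y) {
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] < y[3]
  }
  prev <- lapply(0:m, function(j) c(gap * j, 0, j))
  for (i in seq_len(n)) {
    cur <- vector("list", m + 1)
    cur[[1]] <- c(gap * i, 0, i)
    for (j in seq_len(m)) {
      eq <- av[i] == bv[j] && av[i] %in% c("A", "C", "G", "T")
      d <- prev[[j]] + c(if (eq) match else mismatch, if (eq) 1 else 0, 0)
      u <- prev[[j + 1]] + c(gap, 0, 1)
      l <- cur[[j]] + c(gap, 0, 1)
      best <- d
      if (better(u, best)) best <- u
      if (better(l, best)) best <- l
      cur[[j + 1]] <- best
    }
    prev <- cur
  }
  res <- prev[[m + 1]]
  cols <- res[3] + (n + m - res[3]) / 2
  list(score = res[1], matches = res[2], gaps = res[3], columns = cols,
       identity = 100 * res[2] / max(1, cols))
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_rotate <- function(x, k) {
  n <- nchar(x)
  k <- k %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1, n), substr(x, 1, k))
}

# exhaustive rotation x strand enumeration
oracle_circular <- function(a, b) {
  m <- nchar(b)
  best <- NULL
  for (strand in c("forward", "reverse-complement")) {
    bb <- if (strand == "forward") b else oracle_revcomp(b)
    for (k in 0:(m - 1)) {
      r <- (m - k) %% m
      nw <- oracle_nw(a, oracle_rotate(bb, k))
      cand <- list(identity = nw$identity, strand = strand,
                   rotation_offset = r, matches = nw$matches,
                   columns = nw$columns)
      if (is.null(best) || cand$identity > best$identity + 1e-12) best <- cand
      else if (abs(cand$identity - best$identity) <= 1e-12) {
        if (strand == best$strand && r < best$rotation_offset) best <- cand
      }
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
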