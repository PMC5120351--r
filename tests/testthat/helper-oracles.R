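# Independent brute-force oracles. These re-derive expected results by
# exhaustive enumeration / direct formulas and stay independent of the
# package's own algorithms.

# Enumerate every (start, end, register) window whose first triplet
# positions are glycine at all but <= max_interruptions triplets, with
# G-anchored first and last triplets; keep windows not strictly contained
# in another valid window of the same register; drop windows shorter than
# min_triplets; then resolve overlaps longest-first (ties: smaller start,
# smaller register).
oracle_gxy <- function(seq, min_triplets, max_interruptions) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  valid <- list()
  for (r in 0:2) {
    if (L - 3 < r) next
    for (s in seq(r, L - 3, 3)) {
      for (t in seq_len(floor((L - s) / 3))) {
        e <- s + 3 * t
        anchors <- seq(s, e - 3, 3)
        gl <- chars[anchors + 1] == "G"
        if (!gl[1] || !gl[t]) next
        if (sum(!gl) > max_interruptions) next
        valid[[length(valid) + 1]] <-
          list(start = s, end = e, register = r, tc = t, intr = sum(!gl))
      }
    }
  }
  if (!length(valid)) return(list())
  contained <- vapply(seq_along(valid), function(i) {
    a <- valid[[i]]
    any(vapply(seq_along(valid), function(j) {
      if (i == j) return(FALSE)
      b <- valid[[j]]
      b$register == a$register && b$start <= a$start && b$end >= a$end &&
        (b$start < a$start || b$end > a$end)
    }, logical(1)))
  }, logical(1))
  valid <- valid[!contained]
  valid <- Filter(function(v) v$tc >= min_triplets, valid)
  if (!length(valid)) return(list())
  len <- vapply(valid, function(v) v$end - v$start, 0)
  ord <- order(-len, vapply(valid, `[[`, 0, "start"),
               vapply(valid, `[[`, 0, "register"))
  kept <- list()
  for (k in ord) {
    v <- valid[[k]]
    clash <- any(vapply(kept, function(x)
      max(x$start, v$start) < min(x$end, v$end), logical(1)))
    if (!clash) kept[[length(kept) + 1]] <- v
  }
  kept[order(vapply(kept, `[[`, 0, "start"))]
}

# direct entropy computation on a 20-residue count vector
oracle_info <- function(counts, pseudocount = 0) {
  tot <- sum(counts)
  if (tot == 0 && pseudocount == 0) return(0)
  p <- (counts + pseudocount) / (tot + 20 * pseudocount)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  log2(20) - h
}

# random sequences enriched for G so collagenous runs actually occur
random_gly_seq <- function(n) {
  paste(sample(c("G", "P", "A", "K", "R", "E", "S"), n, replace = TRUE,
               prob = c(0.35, 0.25, 0.1, 0.1, 0.05, 0.1, 0.05)),
        collapse = "")
}

as_region_df <- function(regions) {
  do.call(rbind, lapply(regions, function(x)
    data.frame(start = x$start, end = x$end, register = x$register,
               tc = x$triplet_count %||% x$tc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
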