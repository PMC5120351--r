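# Collagenous Gly-X-X' region detection.
#
# A collagenous region is a run of consecutive triplets, in one of three
# reading registers, whose first position is glycine at all but at most
# `max_interruptions` triplets. Regions are trimmed to G-anchored first and
# last triplets, so interruptions are always interior. All coordinates
# 0-based half-open.

helix_region <- function(start, end, register, triplet_count, interruptions,
                         label = "gxy") {
  structure(list(start = as.integer(start), end = as.integer(end),
                 label = label, register = as.integer(register),
                 triplet_count = as.integer(triplet_count),
                 interruptions = as.integer(interruptions)),
            class = c("helix_region", "region"))
}

#' @export
print.helix_region <- function(x, ...) {
  cat(sprintf("<helix_region %s> [%d, %d) register %d, %d triplets, %d interruption(s)\n",
              x$label, x$start, x$end, x$register, x$triplet_count,
              x$interruptions))
  invisible(x)
}

#' Detect collagenous Gly-X-X' regions
#'
#' Finds, in each of the three triplet registers, the maximal runs of
#' consecutive triplets with glycine at the first position, tolerating up to
#' `max_interruptions` interior non-G first positions per run. Runs shorter
#' than `min_triplets` are discarded; overlapping runs (within or across
#' registers) are resolved in favour of the longer one, ties broken by
#' smaller start, then smaller register.
#'
#' @param chain A `collagen_chain` or plain sequence string.
#' @param min_triplets Minimum triplets per reported region (>= 2).
#' @param max_interruptions Tolerated interior non-G first positions per run.
#' @return List of `helix_region`, sorted by start; empty list if none.
#' @export
#' @examples
#' detect_gxy_regions("AAGPPGPPGPPGPPAA", min_triplets = 2,
#'                    max_interruptions = 0)
detect_gxy_regions <- function(chain, min_triplets = 5L,
                               max_interruptions = 1L) {
  if (min_triplets < 2L)
    stop_colx("param_error", "min_triplets must be >= 2")
  if (max_interruptions < 0L)
    stop_colx("param_error", "max_interruptions must be >= 0")
  seqc <- chain_chars(chain)
  L <- length(seqc)
  found <- list()
  for (r in 0:2) {
    if (L - 3L < r) next
    anchors <- seq.int(r, L - 3L, by = 3L)        # 0-based triplet starts
    g <- seqc[anchors + 1L] == "G"
    n <- length(g)
    mis <- c(0L, cumsum(!g))                      # mis[i+1] = mismatches in 1..i
    # furthest G index reachable from each start within the budget
    lastG <- cummax(ifelse(g, seq_len(n), 0L))
    j <- 0L
    prev_end <- 0L
    for (i in seq_len(n)) {
      if (j < i) j <- i - 1L
      while (j + 1L <= n && mis[j + 2L] - mis[i] <= max_interruptions)
        j <- j + 1L
      if (!g[i]) next
      e <- lastG[j]                               # trim to G-anchored last triplet
      if (e < i || e <= prev_end) next            # not maximal
      prev_end <- e
      tc <- e - i + 1L
      if (tc < min_triplets) next
      found[[length(found) + 1L]] <-
        helix_region(anchors[i], anchors[e] + 3L, r, tc, mis[e + 1L] - mis[i])
    }
  }
  if (!length(found)) return(list())
  # overlap resolution: longer wins; tie smaller start; then smaller register
  len <- vapply(found, function(x) x$end - x$start, 0L)
  st  <- vapply(found, `[[`, 0L, "start")
  reg <- vapply(found, `[[`, 0L, "register")
  ord <- order(-len, st, reg)
  kept <- list()
  for (k in ord) {
    cand <- found[[k]]
    clash <- any(vapply(kept, function(x)
      max(x$start, cand$start) < min(x$end, cand$end), logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  kept[order(vapply(kept, `[[`, 0L, "start"))]
}

#' Classify detected regions into minor and main helix
#'
#' The main helix is the region with the greatest triplet count (ties go to
#' the more C-terminal). The minor (short N-terminal) helix is the longest
#' region lying strictly N-terminal to the main helix whose triplet count is
#' at most `minor_max_fraction` of the main's; absent if none qualifies.
#' Equal-length minor candidates resolve to the more C-terminal one, whose
#' end anchors the N-telopeptide window.
#'
#' @param regions List of `helix_region` from [detect_gxy_regions()].
#' @param minor_max_fraction Maximum minor/main triplet-count ratio.
#' @return `list(minor = , main = )`; `minor` is `NULL` when absent.
#' @export
classify_helices <- function(regions, minor_max_fraction = 0.25) {
  if (!length(regions))
    stop_colx("no_helix_error", "no collagenous domain")
  tc <- vapply(regions, `[[`, 0L, "triplet_count")
  st <- vapply(regions, `[[`, 0L, "start")
  main_i <- order(tc, st, decreasing = TRUE)[1L]   # greatest tc, then most C-terminal
  main <- regions[[main_i]]
  main$label <- "main_helix"
  cand <- which(vapply(regions, `[[`, 0L, "end") <= main$start &
                  tc <= minor_max_fraction * main$triplet_count)
  minor <- NULL
  if (length(cand)) {
    best <- cand[order(tc[cand], st[cand], decreasing = TRUE)[1L]]
    minor <- regions[[best]]
    minor$label <- "minor_helix"
  }
  list(minor = minor, main = main)
}

#' Locate the (GPP)n motif marking the C-terminal end of the main helix
#'
#' Returns the most C-terminal run of at least `min_repeats` consecutive
#' exact `GPP` triplets within (and ending at or before the end of) the main
#' helix, in the helix register; `NULL` if there is none.
#'
#' @param chain A `collagen_chain` or sequence string.
#' @param main The main `helix_region`.
#' @param min_repeats Minimum consecutive GPP triplets to call the terminus.
#' @return A `region` labelled `gpp_terminus`, or `NULL`.
#' @export
find_gpp_terminus <- function(chain, main, min_repeats = 2L) {
  if (min_repeats < 1L)
    stop_colx("param_error", "min_repeats must be >= 1")
  seqstr <- if (inherits(chain, "collagen_chain")) chain$sequence else toupper(chain)
  anchors <- seq.int(main$start, main$end - 3L, by = 3L)
  trips <- substring(seqstr, anchors + 1L, anchors + 3L)
  runs <- rle(trips == "GPP")
  stops <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= min_repeats)
  if (!length(hit)) return(NULL)
  h <- hit[length(hit)]                           # rightmost qualifying run
  first <- stops[h] - runs$lengths[h] + 1L
  region(anchors[first], anchors[stops[h]] + 3L, "gpp_terminus")
}
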