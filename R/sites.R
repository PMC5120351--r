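# Candidate cross-linking site detection and scoring.
#
# Telopeptide (LOX substrate) sites follow the X-K-X'-X'' consensus: K the
# reactive lysine, X' mostly glycine or alanine, X'' mostly proline. Helical
# acceptor sites follow Y-K-G-Y''-Y''': K in the third position of a triplet
# immediately before an anchor glycine, with Y'' and Y''' typically
# histidine and arginine. The weight tables operationalising "mostly" are
# data (part of the run configuration), not code constants; the defaults
# below seed them from the residues reported at each consensus position.

#' Motif weight model
#'
#' A per-offset residue weight table relative to the anchor lysine (offset
#' 0, fixed and unweighted). Each offset maps residues to weights in
#' \[0, 1\]; unknown residues, `X`, and positions outside the chain fall back
#' to the table's `default` weight. A site's score is the mean weight over
#' the model's offsets.
#'
#' @param weights Named list: names are signed offsets (e.g. `"1"`, `"2"`),
#'   values are named numeric vectors that include a `default` entry.
#' @return A `motif_model`.
#' @export
motif_model <- function(weights) {
  offs <- suppressWarnings(as.integer(names(weights)))
  if (any(is.na(offs)) || any(offs == 0L))
    stop_colx("param_error", "weight offsets must be non-zero integers")
  for (w in weights) {
    if (!"default" %in% names(w))
      stop_colx("param_error", "each weight table needs a 'default' entry")
    if (any(w < 0) || any(w > 1))
      stop_colx("param_error", "weights must lie in [0, 1]")
  }
  structure(list(weights = weights, offsets = offs), class = "motif_model")
}

#' @rdname motif_model
#' @export
default_telo_model <- function() {
  motif_model(list(
    `1` = c(G = 1.0, A = 0.8, S = 0.5, default = 0.1),
    `2` = c(P = 1.0, H = 0.6, G = 0.6, default = 0.1)))
}

#' @rdname motif_model
#' @export
default_helix_model <- function() {
  motif_model(list(
    `2` = c(H = 1.0, default = 0.2),
    `3` = c(R = 1.0, default = 0.2)))
}

residue_weight <- function(tab, res) {
  if (res %in% c("X", "-")) return(unname(tab[["default"]]))
  if (res %in% names(tab)) unname(tab[[res]]) else unname(tab[["default"]])
}

score_at <- function(seqc, k, model) {
  w <- vapply(seq_along(model$offsets), function(i) {
    pos <- k + model$offsets[i]
    res <- if (pos >= 0L && pos < length(seqc)) seqc[pos + 1L] else "-"
    residue_weight(model$weights[[i]], res)
  }, numeric(1))
  mean(w)
}

# 7-residue context k-2 .. k+4, '-' padded at chain ends
site_window <- function(seqc, k) {
  paste(vapply(-2:4, function(o) {
    p <- k + o
    if (p >= 0L && p < length(seqc)) seqc[p + 1L] else "-"
  }, character(1)), collapse = "")
}

res_at <- function(seqc, p) {
  if (p >= 0L && p < length(seqc)) seqc[p + 1L] else "-"
}

site_row <- function(chain_id, site_class, seqc, k, score, flank_clear) {
  data.frame(chain_id = chain_id, site_class = site_class, k_pos = k,
             window = site_window(seqc, k),
             res_p1 = res_at(seqc, k + 1L), res_p2 = res_at(seqc, k + 2L),
             res_p3 = res_at(seqc, k + 3L),
             score = score, flank_clear = flank_clear, rank = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Scan a telopeptide for X-K-X'-X'' cross-linking candidates
#'
#' Every lysine in the window is a candidate; the score is the mean of the
#' model weights at offsets +1 (X') and +2 (X''). Candidates scoring below
#' `score_min` are dropped; the rest are ranked by score (ties: the K
#' closest to the main helix).
#'
#' @param telo A `telopeptide_region`.
#' @param chain The owning `collagen_chain`.
#' @param main The main `helix_region` (for tie-breaking distance).
#' @param model A `motif_model`; default [default_telo_model()].
#' @param score_min Minimum retained score.
#' @param flank Lysine-exclusion flank width (residues) for the
#'   `flank_clear` flag, checked within the telopeptide window.
#' @return Site table (0 rows if no candidate survives).
#' @export
scan_telopeptide <- function(telo, chain, main, model = default_telo_model(),
                             score_min = 0.3, flank = 5L) {
  if (is.null(telo) || telo$end <= telo$start) return(empty_sites())
  seqc <- chain_chars(chain)
  ks <- telo$start + which(seqc[(telo$start + 1L):telo$end] == "K") - 1L
  if (!length(ks)) return(empty_sites())
  rows <- lapply(ks, function(k) {
    site_row(chain$chain_id, paste0("telo_", telo$side), seqc, k,
             score_at(seqc, k, model),
             check_flank_exclusion(chain, k, flank, telo))
  })
  out <- do.call(rbind, rows)
  out <- out[out$score >= score_min, , drop = FALSE]
  if (!nrow(out)) return(empty_sites())
  dist <- if (telo$side == "N") main$start - out$k_pos else out$k_pos - main$end
  out <- out[order(-out$score, dist), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Scan the main-helix termini for Y-K-G-Y''-Y''' acceptor candidates
#'
#' Only the first and last `end_window` residues of the main helix are
#' scanned. Candidates are lysines immediately followed by glycine; with
#' `enforce_register` the K must occupy the third triplet position
#' (`(k - start) mod 3 == 2`), so that the following G is a triplet anchor.
#' The score is the mean model weight at offsets +2 (Y'') and +3 (Y''');
#' the best-scoring candidate per end is retained (ties: nearer the helix
#' end). No score floor is applied: the consensus third/fourth positions
#' vary, and a lone K-G at a helix end is still the best available acceptor.
#'
#' @param chain A `collagen_chain`.
#' @param main The main `helix_region`.
#' @param end_window Residues scanned at each helix end.
#' @param model A `motif_model`; default [default_helix_model()].
#' @param enforce_register Require K at the third triplet position.
#' @param flank Flank width for `flank_clear`, bounded by the main helix.
#' @return Site table with at most one `helix_N` and one `helix_C` row.
#' @export
scan_helical <- function(chain, main, end_window = 30L,
                         model = default_helix_model(),
                         enforce_register = TRUE, flank = 5L) {
  seqc <- chain_chars(chain)
  ks <- main$start + which(seqc[(main$start + 1L):main$end] == "K") - 1L
  ks <- ks[ks + 1L < main$end & seqc[ks + 2L] == "G"]
  if (enforce_register) ks <- ks[(ks - main$start) %% 3L == 2L]
  if (!length(ks)) return(empty_sites())
  out <- empty_sites()
  for (side in c("N", "C")) {
    if (side == "N") {
      w_lo <- main$start; w_hi <- min(main$start + end_window, main$end)
      cand <- ks[ks >= w_lo & ks < w_hi]
      d <- cand - main$start
    } else {
      w_lo <- max(main$start, main$end - end_window); w_hi <- main$end
      cand <- ks[ks >= w_lo & ks < w_hi]
      d <- main$end - 1L - cand
    }
    if (!length(cand)) next
    sc <- vapply(cand, function(k) score_at(seqc, k, model), numeric(1))
    best <- order(-sc, d)[1L]
    out <- rbind(out, site_row(chain$chain_id, paste0("helix_", side), seqc,
                               cand[best], sc[best],
                               check_flank_exclusion(chain, cand[best],
                                                     flank, main)))
  }
  if (nrow(out)) out$rank <- 1L
  rownames(out) <- NULL
  out
}

#' Check the lysine-exclusion flank rule
#'
#' `TRUE` iff no lysine other than the site's own occurs within `flank`
#' residues on either side of it, clipped to the containing analysis region
#' (the published five-residue rule corresponds to `flank = 5`).
#'
#' @param chain A `collagen_chain` or sequence string.
#' @param site A site (anything with `k_pos`) or a bare 0-based K index.
#' @param flank Flank width in residues.
#' @param bounds The containing region (anything with `start`/`end`).
#' @return Logical scalar.
#' @export
check_flank_exclusion <- function(chain, site, flank = 5L, bounds) {
  k <- if (is.numeric(site)) as.integer(site) else as.integer(site$k_pos)
  seqc <- chain_chars(chain)
  if (res_at(seqc, k) != "K")
    stop_colx("site_error", sprintf("no lysine at position %d", k))
  lo <- max(bounds$start, k - as.integer(flank))
  hi <- min(bounds$end - 1L, k + as.integer(flank))
  idx <- setdiff(seq.int(lo, hi), k)
  !any(seqc[idx + 1L] == "K")
}
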