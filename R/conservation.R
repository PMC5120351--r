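# K-anchored conservation profiles and the lysine-depletion statistic.
#
# Windows are aligned on the cross-linking lysine rather than by progressive
# multiple alignment: every window is extracted at a fixed offset range
# around its K, which is how the published site logos are centred.

#' Build a K-anchored site profile (PWM + information content)
#'
#' Windows span `[k_pos - flank_left, k_pos + flank_right]`, padded with `-`
#' at chain ends. Counts exclude `-` and `X`; column frequencies are
#' `(count + pseudocount) / (column_total + 20 * pseudocount)`; information
#' content per column is `log2(20)` minus the column's Shannon entropy in
#' bits. A column with no countable residues (and zero pseudocount) gets
#' zero information content.
#'
#' @param sites Site table; all rows must share one `site_class`.
#' @param chains Named list of `collagen_chain` the sites refer to.
#' @param flank_left,flank_right Window half-widths around the anchor K.
#' @param pseudocount Added to every residue count per column.
#' @return A `site_profile`: windows, per-column counts, frequencies,
#'   information content, and anchor-relative offsets.
#' @export
build_profile <- function(sites, chains, flank_left = 2L, flank_right = 4L,
                          pseudocount = 0) {
  if (is.null(sites) || nrow(sites) == 0L)
    stop_colx("empty_error", "no sites to profile")
  if (length(unique(sites$site_class)) != 1L)
    stop_colx("param_error", "all sites must share one site_class")
  if (pseudocount < 0)
    stop_colx("param_error", "pseudocount must be non-negative")
  width <- flank_left + flank_right + 1L
  offsets <- seq.int(-flank_left, flank_right)
  windows <- vapply(seq_len(nrow(sites)), function(i) {
    seqc <- chain_chars(chains[[sites$chain_id[i]]])
    k <- sites$k_pos[i]
    paste(vapply(offsets, function(o) res_at(seqc, k + o), character(1)),
          collapse = "")
  }, character(1))
  counts <- matrix(0L, nrow = 20L, ncol = width,
                   dimnames = list(AA_ALPHABET, offsets))
  for (w in windows) {
    ch <- strsplit(w, "")[[1]]
    for (j in seq_len(width))
      if (ch[j] %in% AA_ALPHABET)
        counts[ch[j], j] <- counts[ch[j], j] + 1L
  }
  tot <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2L, tot + 20 * pseudocount, `/`)
  dead <- tot == 0 & pseudocount == 0
  freq[, dead] <- 0
  info <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(0)
    log2(20) + sum(p * log2(p))
  })
  info[dead] <- 0
  anchor <- flank_left + 1L
  if (any(substr(windows, anchor, anchor) != "K"))
    stop_colx("site_error", "anchor column is not all lysine")
  structure(list(site_class = sites$site_class[1L], windows = windows,
                 offsets = offsets, counts = counts, frequencies = freq,
                 info_content = unname(info)),
            class = "site_profile")
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("<site_profile %s> %d windows, width %d, total info %.3f bits\n",
              x$site_class, length(x$windows), length(x$offsets),
              sum(x$info_content)))
  invisible(x)
}

#' Probability of a lysine-free stretch arising by chance
#'
#' For lysine-free stretches of the given lengths (one per chain) and a
#' background lysine frequency `f_k`, the probability that all
#' `N = sum(lengths)` independently drawn residues avoid lysine is
#' `(1 - f_k)^N`. Small values indicate selected lysine exclusion.
#'
#' @param region_lengths Non-negative integer lengths, one per chain.
#' @param f_k Background lysine frequency in (0, 1); 0.072 is the standard
#'   proteome-wide value.
#' @return A `depletion_result` with `region_lengths`, `n_total`, `f_k`,
#'   and `probability`.
#' @export
#' @examples
#' lysine_depletion_probability(c(275), 0.072)   # ~1.2e-9
lysine_depletion_probability <- function(region_lengths, f_k = 0.072) {
  if (length(region_lengths) && (any(!is.finite(region_lengths)) ||
                                 any(region_lengths < 0)))
    stop_colx("value_error", "region lengths must be finite and non-negative")
  if (!is.finite(f_k) || f_k <= 0 || f_k >= 1)
    stop_colx("value_error", "f_k must lie in (0, 1)")
  n_total <- sum(as.numeric(region_lengths))
  structure(list(region_lengths = as.integer(region_lengths),
                 n_total = n_total, f_k = f_k,
                 probability = (1 - f_k)^n_total),
            class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("<depletion_result> %d region(s), N = %d, f_K = %.3f, P = %.3g\n",
              length(x$region_lengths), as.integer(x$n_total), x$f_k,
              x$probability))
  invisible(x)
}

#' Measure lysine-depletion regions from annotated, scanned chains
#'
#' For each chain's rank-1 site: `telo_C` length is the open interval from
#' the main-helix end to the cross-linking K (`k_pos - main_helix.end`);
#' `telo_N` length runs from the minor-helix end (`k_pos - minor_helix.end`).
#' Chains lacking the site or the landmark are skipped with a message. Each
#' measured stretch is also checked for actually being lysine-free.
#'
#' @param results Per-chain analysis results, as produced by [run_scan()]
#'   (each element has `chain`, `minor`, `main`, `sites`).
#' @return `list(telo_C = , telo_N = )` of data frames with `chain_id`,
#'   `length`, `lysine_free`.
#' @export
measure_depletion_regions <- function(results) {
  out <- list()
  for (cls in c("telo_C", "telo_N")) {
    rows <- list()
    for (res in results) {
      if (is.null(res$main)) next
      s <- res$sites[res$sites$site_class == cls & res$sites$rank == 1L, ,
                     drop = FALSE]
      if (!nrow(s)) {
        message(sprintf("chain '%s': no rank-1 %s site; skipped",
                        res$chain$chain_id, cls))
        next
      }
      landmark <- if (cls == "telo_C") res$main$end else {
        if (is.null(res$minor)) {
          message(sprintf("chain '%s': no minor helix landmark for telo_N; skipped",
                          res$chain$chain_id))
          next
        }
        res$minor$end
      }
      k <- s$k_pos[1L]
      len <- k - landmark
      stretch <- substr(res$chain$sequence, landmark + 1L, k)  # excludes K at k
      rows[[length(rows) + 1L]] <-
        data.frame(chain_id = res$chain$chain_id, length = len,
                   lysine_free = !grepl("K", stretch, fixed = TRUE),
                   stringsAsFactors = FALSE)
    }
    out[[cls]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chain_id = character(0), length = integer(0),
                 lysine_free = logical(0), stringsAsFactors = FALSE)
  }
  out
}

#' Export a profile as a logo matrix TSV
#'
#' One row per window position: anchor-relative `offset`, the 20 residue
#' frequency columns, and `info_content` in bits — consumable by any logo
#' renderer.
#'
#' @param profile A `site_profile`.
#' @param path Output TSV path.
#' @export
export_logo_matrix <- function(profile, path) {
  df <- data.frame(offset = profile$offsets,
                   t(profile$frequencies),
                   info_content = profile$info_content,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
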