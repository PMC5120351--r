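# Telopeptide window delimitation.
#
# The N-telopeptide window runs from the end of the minor (short N-terminal)
# helix -- or the chain start if no minor helix was found -- to the start of
# the main helix. The C-telopeptide runs from the end of the main helix to
# the COLFI boundary when one is annotated, else for at most `c_max_len`
# residues. A side whose window has length zero (helix abuts the chain end,
# or the chain is N-terminally truncated so the main helix starts at 0 with
# no minor helix) is absent.

telopeptide_region <- function(start, end, side, sequence) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 label = if (side == "N") "n_telopeptide" else "c_telopeptide",
                 side = side, sequence = sequence),
            class = c("telopeptide_region", "region"))
}

#' @export
print.telopeptide_region <- function(x, ...) {
  cat(sprintf("<telopeptide_region %s> [%d, %d) %s\n", x$side, x$start,
              x$end, x$sequence))
  invisible(x)
}

#' Extract N- and C-telopeptide analysis windows
#'
#' @param chain A `collagen_chain`.
#' @param minor The minor `helix_region`, or `NULL` when absent.
#' @param main The main `helix_region`.
#' @param c_max_len C-telopeptide length cap (residues) used when no
#'   `colfi_stub` region is annotated on the chain; an annotated COLFI
#'   boundary always wins.
#' @return `list(n = , c = )` of `telopeptide_region` or `NULL` per side.
#' @export
extract_telopeptides <- function(chain, minor, main, c_max_len = 40L) {
  L <- chain_length(chain)
  n_start <- if (!is.null(minor)) minor$end else 0L
  n_telo <- NULL
  if (n_start < main$start)
    n_telo <- telopeptide_region(n_start, main$start, "N",
                                 substr(chain$sequence, n_start + 1L, main$start))
  c_end <- min(main$end + as.integer(c_max_len), L)
  colfi <- chain$annotations[chain$annotations$label == "colfi_stub", , drop = FALSE]
  if (nrow(colfi)) {
    b <- min(colfi$start)
    if (b >= main$end) c_end <- b
  }
  c_telo <- NULL
  if (main$end < c_end)
    c_telo <- telopeptide_region(main$end, c_end, "C",
                                 substr(chain$sequence, main$end + 1L, c_end))
  list(n = n_telo, c = c_telo)
}
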