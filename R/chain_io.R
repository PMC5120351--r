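# Chain records, FASTA/annotation input and report output.
#
# Coordinates are 0-based half-open everywhere: in memory, in every TSV and
# JSON this package reads or writes. Human-readable messages may add 1-based
# positions, labelled as such.

#' @importFrom utils read.delim write.table
NULL

# analysis alphabet: the 20 standard residues plus 'X' for unknown
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
CHAIN_ALPHABET <- c(AA_ALPHABET, "X")

REGION_LABELS <- c("minor_helix", "main_helix", "n_telopeptide",
                   "c_telopeptide", "gpp_terminus", "colfi_stub",
                   "n_propeptide")

stop_colx <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("colx_", class),
                                          "colx_error", "error", "condition")))
}

empty_regions <- function() {
  data.frame(label = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Construct a collagen chain record
#'
#' A chain is one protein sequence with identity metadata and an accumulating
#' table of labelled regions. The sequence must be upper-case one-letter code
#' over the 20 standard residues plus `X` (unknown); `X` never matches any
#' motif position and never counts as lysine downstream.
#'
#' @param chain_id Unique identifier (non-empty string).
#' @param sequence Amino-acid string; lower case is accepted and upper-cased.
#' @param species Free-text species / chain description.
#' @param annotations Optional region table (`label`, `start`, `end`;
#'   0-based half-open).
#' @return An object of class `collagen_chain`.
#' @export
#' @examples
#' ch <- collagen_chain("h1", "GPPGPPGPP", species = "demo")
#' ch
collagen_chain <- function(chain_id, sequence, species = "",
                           annotations = NULL) {
  if (!is.character(chain_id) || length(chain_id) != 1L || !nzchar(chain_id))
    stop_colx("id_error", "chain_id must be a non-empty string")
  sequence <- toupper(sequence)
  validate_sequence(sequence, chain_id)
  if (is.null(annotations)) annotations <- empty_regions()
  structure(list(chain_id = chain_id, species = species,
                 sequence = sequence, annotations = annotations),
            class = "collagen_chain")
}

#' @export
print.collagen_chain <- function(x, ...) {
  cat(sprintf("<collagen_chain> %s (%s): %d aa, %d annotation(s)\n",
              x$chain_id, x$species, nchar(x$sequence), nrow(x$annotations)))
  invisible(x)
}

validate_sequence <- function(sequence, chain_id = "?") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop_colx("sequence_error",
              sprintf("chain '%s': sequence must be a non-empty string", chain_id))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% CHAIN_ALPHABET)
  if (length(bad)) {
    stop_colx("alphabet_error",
              sprintf("chain '%s': invalid residue '%s' at position %d (0-based)",
                      chain_id, chars[bad[1L]], bad[1L] - 1L),
              residue = chars[bad[1L]], position = bad[1L] - 1L)
  }
  invisible(TRUE)
}

chain_chars <- function(chain) {
  if (inherits(chain, "collagen_chain")) strsplit(chain$sequence, "")[[1]]
  else strsplit(toupper(chain), "")[[1]]
}

chain_length <- function(chain) {
  if (inherits(chain, "collagen_chain")) nchar(chain$sequence)
  else nchar(chain)
}

# a labelled half-open interval; start/end 0-based
region <- function(start, end, label) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop_colx("bounds_error",
              sprintf("invalid region [%d, %d)", start, end))
  structure(list(start = start, end = end, label = label), class = "region")
}

region_seq <- function(chain, reg) {
  substr(if (inherits(chain, "collagen_chain")) chain$sequence else chain,
         reg$start + 1L, reg$end)
}

#' Read collagen chains from a FASTA file
#'
#' Each record becomes a [collagen_chain()]: the first whitespace-delimited
#' header token is the `chain_id`, the remainder the `species` text.
#' Sequences are upper-cased and trailing `*` stop characters stripped.
#' Records containing characters outside the 20 standard residues plus `X`
#' raise a `colx_alphabet_error` naming the offending character and its
#' 0-based position.
#'
#' @param path Path to a FASTA file.
#' @return Named list of `collagen_chain` objects (names are chain ids).
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) NULL)
  if (is.null(set) || length(set) == 0L) {
    warning(sprintf("no FASTA records read from '%s'", path))
    return(structure(list(), names = character(0)))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  species <- trimws(sub("^\\S+\\s*", "", headers))
  if (anyDuplicated(ids))
    stop_colx("id_error", sprintf("duplicate chain_id '%s' in '%s'",
                                  ids[anyDuplicated(ids)], path))
  chains <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    s <- sub("\\*+$", "", s)             # trailing terminators
    chains[[i]] <- collagen_chain(ids[i], s, species = species[i])
  }
  names(chains) <- ids
  chains
}

#' Write chains to a FASTA file
#'
#' Inverse of [read_fasta()] on (`chain_id`, `sequence`).
#'
#' @param chains Named list of `collagen_chain`.
#' @param path Output path.
#' @export
write_fasta <- function(chains, path) {
  seqs <- Biostrings::BStringSet(vapply(chains, `[[`, "", "sequence"))
  names(seqs) <- vapply(chains, function(ch)
    trimws(paste(ch$chain_id, ch$species)), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Attach region annotations from a TSV table
#'
#' The table has a header line `chain_id label start end`; coordinates are
#' 0-based half-open. Rows naming an unknown chain raise
#' `colx_unknown_chain_error`; out-of-bounds coordinates raise
#' `colx_bounds_error` with the offending row number; same-label regions on
#' one chain must not overlap.
#'
#' @param path Path to the TSV table.
#' @param chains Named list of `collagen_chain` to annotate.
#' @return The chain list with annotations attached.
#' @export
read_annotations <- function(path, chains) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chain_id", "label", "start", "end")
  if (!all(need %in% names(tab)))
    stop_colx("format_error",
              sprintf("annotation table must have columns %s",
                      paste(need, collapse = ", ")))
  for (i in seq_len(nrow(tab))) {
    id <- tab$chain_id[i]
    if (!id %in% names(chains))
      stop_colx("unknown_chain_error",
                sprintf("row %d: unknown chain_id '%s'", i, id))
    ch <- chains[[id]]
    lab <- tab$label[i]
    if (!lab %in% REGION_LABELS)
      stop_colx("label_error", sprintf("row %d: unknown label '%s'", i, lab))
    s <- as.integer(tab$start[i]); e <- as.integer(tab$end[i])
    L <- nchar(ch$sequence)
    if (is.na(s) || is.na(e) || s < 0L || s >= e || e > L)
      stop_colx("bounds_error",
                sprintf("row %d: region [%s, %s) out of bounds for chain '%s' (length %d)",
                        i, tab$start[i], tab$end[i], id, L))
    same <- ch$annotations[ch$annotations$label == lab, , drop = FALSE]
    if (nrow(same) && any(pmax(same$start, s) < pmin(same$end, e)))
      stop_colx("overlap_error",
                sprintf("row %d: '%s' regions overlap on chain '%s'", i, lab, id))
    ch$annotations <- rbind(ch$annotations,
                            data.frame(label = lab, start = s, end = e,
                                       stringsAsFactors = FALSE))
    chains[[id]] <- ch
  }
  chains
}

empty_sites <- function() {
  data.frame(chain_id = character(0), site_class = character(0),
             k_pos = integer(0), window = character(0),
             res_p1 = character(0), res_p2 = character(0),
             res_p3 = character(0), score = numeric(0),
             flank_clear = logical(0), rank = integer(0),
             stringsAsFactors = FALSE)
}

#' Write the site report (TSV + JSON)
#'
#' Emits `<prefix>.tsv` with one row per candidate cross-linking site
#' (`chain_id`, `site_class`, `k_pos` 0-based, `window`, `score`,
#' `flank_clear`, `rank`) and `<prefix>.json` mirroring the table plus each
#' chain's region annotations.
#'
#' @param chains Named list of annotated `collagen_chain`.
#' @param sites Site table as produced by the scan functions (possibly 0 rows).
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(chains, sites, prefix) {
  if (is.null(sites) || nrow(sites) == 0L) sites <- empty_sites()
  if (nrow(sites) && !all(sites$chain_id %in% names(chains)))
    stop_colx("unknown_chain_error", "sites reference chains not in the collection")
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  cols <- c("chain_id", "site_class", "k_pos", "window", "score",
            "flank_clear", "rank")
  write.table(sites[, cols, drop = FALSE], tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  doc <- list(
    sites = sites[, cols, drop = FALSE],
    chains = lapply(unname(chains), function(ch) list(
      chain_id = ch$chain_id, species = ch$species,
      length = nchar(ch$sequence), regions = ch$annotations))
  )
  jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}
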