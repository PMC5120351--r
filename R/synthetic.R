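# Synthetic fibrillar-collagen chain generator with planted ground truth.
#
# Architecture, N to C: propeptide filler, minor (short N-terminal) helix,
# N-telopeptide carrying one planted cross-link lysine, main Gly-X-X' helix
# with planted acceptor motifs near both ends and a terminal (GPP)n run,
# C-telopeptide with one planted cross-link lysine, COLFI stub filler.
#
# Background filler excludes glycine so no spurious Gly-X-X' register can
# arise by chance, and telopeptides are lysine-free apart from the planted
# (and optional decoy) lysines, so the depletion stretches are exact ground
# truth. Main-helix background lysines occur only at third-triplet positions
# strictly between the two planted acceptor motifs, keeping each planted
# site the end-proximal lysine of its helix terminus.

#' @importFrom stats runif
NULL

# background filler: lysine at k_freq, otherwise uniform over the remaining
# 18 residues (G excluded)
draw_background <- function(n, k_freq) {
  pool <- setdiff(AA_ALPHABET, c("G", "K"))
  res <- sample(pool, n, replace = TRUE)
  res[runif(n) < k_freq] <- "K"
  res
}

# lysine-free telopeptide background (no G, no K)
draw_telo_background <- function(n) {
  sample(setdiff(AA_ALPHABET, c("G", "K")), n, replace = TRUE)
}

# helix X / X' positions: P-enriched, G and K excluded (lysines are placed
# separately at controlled third-triplet positions)
draw_helix_xy <- function(n) {
  pool <- setdiff(AA_ALPHABET, c("G", "K", "P", "A"))
  probs <- c(0.30, 0.15, rep(0.55 / length(pool), length(pool)))
  sample(c("P", "A", pool), n, replace = TRUE, prob = probs)
}

derive_seed <- function(seed, index) {
  s <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + as.numeric(index) * 30269) %% 2147483647)
}

#' Specification for a synthetic collagen family
#'
#' Defaults emulate a compact clade A-like architecture: a 5-triplet minor
#' helix, 15-residue N-telopeptide, 100-triplet main helix ending in
#' (GPP)3, 20-residue C-telopeptide, with the cross-link lysines planted in
#' the standard contexts (`EKGP` in the telopeptides, `MKGHR` at the helix
#' termini) and background lysine frequency 0.072.
#'
#' @param seed Integer master seed; each chain draws from a substream
#'   derived from (seed, index), so families are reproducible chain by chain.
#' @param n_chains Number of chains in the family.
#' @param n_prop_len,colfi_len Filler lengths flanking the structured core.
#' @param minor_triplets,main_triplets Triplet counts of the two helices.
#' @param n_telo_len,c_telo_len Telopeptide lengths (residues).
#' @param gpp_repeats Terminal GPP triplets of the main helix.
#' @param telo_motif 4-mer planted around the telopeptide K (offsets -1..+2;
#'   position 2 must be `K`).
#' @param helix_motif 5-mer planted at the helix termini (Y-K-G-Y''-Y''';
#'   position 2 must be `K`, position 3 `G`).
#' @param helix_site_offset Triplets from each helix end to the planted
#'   acceptor K.
#' @param background_k_freq Background lysine frequency for filler and
#'   helix third-triplet positions.
#' @param substitution_rate Per-residue i.i.d. substitution probability
#'   applied after planting.
#' @param n_k_gap,c_k_gap Lysine-free gap (residues) from the minor-helix
#'   end / main-helix end to the planted telopeptide K; scalar, or one value
#'   per chain to set family-level depletion totals.
#' @param decoy_offset Optional extra lysine planted this many residues
#'   C-terminal of the C-telopeptide K (>= 3, to spare the motif), for
#'   exercising the flank-exclusion rule; `NULL` for none.
#' @param protect_anchors If `TRUE` (default) substitutions spare planted K
#'   anchors and triplet G positions, so recovery tests isolate scanner
#'   behaviour from helix-detection degradation.
#' @return A validated `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_chains = 19L, n_prop_len = 30L,
                           minor_triplets = 5L, n_telo_len = 15L,
                           main_triplets = 100L, c_telo_len = 20L,
                           colfi_len = 30L, gpp_repeats = 3L,
                           telo_motif = "EKGP", helix_motif = "MKGHR",
                           helix_site_offset = 3L,
                           background_k_freq = 0.072,
                           substitution_rate = 0,
                           n_k_gap = 5L, c_k_gap = 10L,
                           decoy_offset = NULL,
                           protect_anchors = TRUE) {
  spec <- list(seed = as.integer(seed), n_chains = as.integer(n_chains),
               n_prop_len = as.integer(n_prop_len),
               minor_triplets = as.integer(minor_triplets),
               n_telo_len = as.integer(n_telo_len),
               main_triplets = as.integer(main_triplets),
               c_telo_len = as.integer(c_telo_len),
               colfi_len = as.integer(colfi_len),
               gpp_repeats = as.integer(gpp_repeats),
               telo_motif = toupper(telo_motif),
               helix_motif = toupper(helix_motif),
               helix_site_offset = as.integer(helix_site_offset),
               background_k_freq = background_k_freq,
               substitution_rate = substitution_rate,
               n_k_gap = as.integer(n_k_gap), c_k_gap = as.integer(c_k_gap),
               decoy_offset = if (is.null(decoy_offset)) NULL else
                 as.integer(decoy_offset),
               protect_anchors = isTRUE(protect_anchors))
  validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_spec <- function(s) {
  pos <- c("n_chains", "n_prop_len", "minor_triplets", "n_telo_len",
           "main_triplets", "c_telo_len", "colfi_len", "gpp_repeats",
           "helix_site_offset")
  for (f in pos)
    if (any(s[[f]] < 1L))
      stop_colx("spec_error", sprintf("%s must be positive", f))
  if (s$background_k_freq < 0 || s$background_k_freq >= 1)
    stop_colx("spec_error", "background_k_freq must lie in [0, 1)")
  if (s$substitution_rate < 0 || s$substitution_rate >= 1)
    stop_colx("spec_error", "substitution_rate must lie in [0, 1)")
  if (nchar(s$telo_motif) != 4L || substr(s$telo_motif, 2L, 2L) != "K")
    stop_colx("spec_error", "telo_motif must be a 4-mer with K at position 2")
  if (nchar(s$helix_motif) != 5L || substr(s$helix_motif, 2L, 3L) != "KG")
    stop_colx("spec_error", "helix_motif must be a 5-mer with K-G at positions 2-3")
  if (s$helix_site_offset * 3L >= s$main_triplets * 3L / 2)
    stop_colx("spec_error", "helix_site_offset too large for main_triplets")
  i_c <- s$main_triplets - s$helix_site_offset - 2L
  if (i_c < s$helix_site_offset + 2L || i_c + 2L > s$main_triplets - s$gpp_repeats)
    stop_colx("spec_error",
              "planted helix motifs collide with each other or the GPP terminus")
  if (!length(s$n_k_gap) %in% c(1L, s$n_chains) ||
      !length(s$c_k_gap) %in% c(1L, s$n_chains))
    stop_colx("spec_error", "n_k_gap / c_k_gap must have length 1 or n_chains")
  if (any(s$n_k_gap < 1L) || any(s$n_k_gap > s$n_telo_len - 3L))
    stop_colx("spec_error", "n_k_gap must lie in [1, n_telo_len - 3]")
  if (any(s$c_k_gap < 1L) || any(s$c_k_gap > s$c_telo_len - 3L))
    stop_colx("spec_error", "c_k_gap must lie in [1, c_telo_len - 3]")
  if (!is.null(s$decoy_offset) &&
      (any(s$decoy_offset < 3L) ||
       any(s$c_k_gap + s$decoy_offset > s$c_telo_len - 1L)))
    stop_colx("spec_error", "decoy_offset must be >= 3 and fit in the C-telopeptide")
  invisible(TRUE)
}

#' Generate one synthetic chain with its ground truth
#'
#' Deterministic given `(spec$seed, index)`; the global RNG state is saved
#' and restored.
#'
#' @param spec A `synthetic_spec`.
#' @param index 0-based chain index within the family.
#' @return `list(chain = collagen_chain, truth = list(regions, sites,
#'   depletion))`; truth coordinates are 0-based half-open.
#' @export
generate_chain <- function(spec, index = 0L) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(derive_seed(spec$seed, index))

  n_gap <- rep_len(spec$n_k_gap, spec$n_chains)[index + 1L]
  c_gap <- rep_len(spec$c_k_gap, spec$n_chains)[index + 1L]
  tm <- strsplit(spec$telo_motif, "")[[1]]
  hm <- strsplit(spec$helix_motif, "")[[1]]

  prop <- draw_background(spec$n_prop_len, spec$background_k_freq)

  minor <- character(3L * spec$minor_triplets)
  minor[seq(1L, length(minor), 3L)] <- "G"
  minor[-seq(1L, length(minor), 3L)] <- draw_helix_xy(2L * spec$minor_triplets)

  n_telo <- draw_telo_background(spec$n_telo_len)
  n_telo[n_gap + 0:3] <- tm                     # K at telo offset n_gap (0-based)

  m <- spec$main_triplets
  i_n <- spec$helix_site_offset                 # motif occupies triplets i_n, i_n+1
  i_c <- m - spec$helix_site_offset - 2L
  main <- character(3L * m)
  main[seq(1L, length(main), 3L)] <- "G"
  xy <- draw_helix_xy(2L * m)
  main[-seq(1L, length(main), 3L)] <- xy
  k_zone <- seq.int(i_n + 2L, i_c - 1L)         # background lysines, X' only
  put_k <- k_zone[runif(length(k_zone)) < spec$background_k_freq]
  main[3L * put_k + 3L] <- "K"                  # X' of triplet j is index 3j+3 (1-based)
  for (i0 in c(i_n, i_c)) {                     # plant Y-K-G-Y''-Y'''
    main[3L * i0 + 2L] <- hm[1L]
    main[3L * i0 + 3L] <- hm[2L]
    main[3L * i0 + 5L] <- hm[4L]
    main[3L * i0 + 6L] <- hm[5L]
  }
  for (j in seq.int(m - spec$gpp_repeats, m - 1L))
    main[3L * j + 1:3] <- c("G", "P", "P")

  c_telo <- draw_telo_background(spec$c_telo_len)
  c_telo[c_gap + 0:3] <- tm
  if (!is.null(spec$decoy_offset))
    c_telo[c_gap + 1L + spec$decoy_offset] <- "K"

  colfi <- draw_background(spec$colfi_len, spec$background_k_freq)

  parts <- list(prop, minor, n_telo, main, c_telo, colfi)
  lens <- vapply(parts, length, 0L)
  starts <- cumsum(c(0L, lens[-length(lens)]))  # 0-based part starts
  seqc <- unlist(parts)

  minor_start <- starts[2L]; minor_end <- starts[3L]
  main_start <- starts[4L]; main_end <- starts[5L]
  k_telo_n <- minor_end + n_gap
  k_helix_n <- main_start + 3L * i_n + 2L
  k_helix_c <- main_start + 3L * i_c + 2L
  k_telo_c <- main_end + c_gap
  planted <- c(k_telo_n, k_helix_n, k_helix_c, k_telo_c)
  if (!is.null(spec$decoy_offset))
    planted <- c(planted, k_telo_c + spec$decoy_offset)

  if (spec$substitution_rate > 0) {
    protected <- planted + 1L                   # 1-based indices
    if (spec$protect_anchors)
      protected <- c(protected,
                     minor_start + seq(1L, 3L * spec$minor_triplets, 3L),
                     main_start + seq(1L, 3L * m, 3L))
    hit <- which(runif(length(seqc)) < spec$substitution_rate)
    hit <- setdiff(hit, protected)
    for (i in hit) seqc[i] <- sample(setdiff(AA_ALPHABET, seqc[i]), 1L)
  }

  regions <- data.frame(
    label = c("n_propeptide", "minor_helix", "n_telopeptide", "main_helix",
              "gpp_terminus", "c_telopeptide", "colfi_stub"),
    start = c(starts[1L], minor_start, minor_end, main_start,
              main_end - 3L * spec$gpp_repeats, main_end, starts[6L]),
    end = c(minor_start, minor_end, main_start, main_end, main_end,
            starts[6L], starts[6L] + spec$colfi_len),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    site_class = c("telo_N", "helix_N", "helix_C", "telo_C"),
    k_pos = c(k_telo_n, k_helix_n, k_helix_c, k_telo_c),
    stringsAsFactors = FALSE)

  chain <- collagen_chain(sprintf("syn_%03d", index + 1L),
                          paste(seqc, collapse = ""),
                          species = "synthetic clade A-like chain")
  list(chain = chain,
       truth = list(regions = regions, sites = sites,
                    depletion = c(telo_N = n_gap, telo_C = c_gap)))
}

#' Generate a synthetic family and write it to disk
#'
#' Writes `family.fasta`, a ground-truth region table `regions.tsv` (in the
#' annotation dialect of [read_annotations()]) and a planted-site table
#' `sites.tsv` into `dir`.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed); `NULL` to skip writing.
#' @return Invisibly, `list(chains, truths, paths)`.
#' @export
generate_family <- function(spec, dir = NULL) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  gen <- lapply(seq_len(spec$n_chains) - 1L, function(i)
    generate_chain(spec, i))
  chains <- lapply(gen, `[[`, "chain")
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  truths <- lapply(gen, `[[`, "truth")
  names(truths) <- names(chains)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "family.fasta")
    write_fasta(chains, fasta)
    reg <- do.call(rbind, lapply(names(truths), function(id)
      cbind(chain_id = id, truths[[id]]$regions)))
    reg_path <- file.path(dir, "regions.tsv")
    write.table(reg, reg_path, sep = "\t", quote = FALSE, row.names = FALSE)
    st <- do.call(rbind, lapply(names(truths), function(id)
      cbind(chain_id = id, truths[[id]]$sites)))
    sites_path <- file.path(dir, "sites.tsv")
    write.table(st, sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(fasta = fasta, regions = reg_path, sites = sites_path)
  }
  invisible(list(chains = chains, truths = truths, paths = paths))
}
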