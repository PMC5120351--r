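# Run configuration and the assembled analysis pipeline.
#
# All machine outputs are deterministic functions of (inputs, config); logs
# go to stderr via message(), data only to files. The effective config is
# echoed into the output directory of every run.

#' Default run configuration
#'
#' A nested list of every tunable the pipeline exposes. Unknown keys in a
#' user config are rejected, not ignored.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    helix = list(min_triplets = 5L, max_interruptions = 1L,
                 minor_max_fraction = 0.25, gpp_min_repeats = 2L),
    telo = list(c_max_len = 40L),
    sites = list(score_min = 0.3, end_window = 30L, flank = 5L,
                 enforce_register = TRUE,
                 telo_weights = list(
                   `1` = list(G = 1.0, A = 0.8, S = 0.5, default = 0.1),
                   `2` = list(P = 1.0, H = 0.6, G = 0.6, default = 0.1)),
                 helix_weights = list(
                   `2` = list(H = 1.0, default = 0.2),
                   `3` = list(R = 1.0, default = 0.2))),
    conservation = list(pseudocount = 0, flank_left = 2L, flank_right = 4L,
                        f_k = 0.072)
  )
}

merge_config <- function(base, override, path = character(0)) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop_colx("config_error", sprintf("unknown config key '%s'", full))
    if (is.list(base[[key]]) && !key %in% c("telo_weights", "helix_weights")) {
      if (!is.list(override[[key]]))
        stop_colx("config_error", sprintf("config key '%s' must be a group", full))
      base[[key]] <- merge_config(base[[key]], override[[key]], c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Values are merged over [default_config()]; unknown keys raise
#' `colx_config_error`.
#'
#' @param path YAML file path.
#' @return Full configuration list.
#' @export
load_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

echo_config <- function(config, out_dir) {
  yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
}

weights_to_model <- function(weights) {
  motif_model(lapply(weights, function(w) unlist(w)))
}

resolve_chains <- function(fasta) {
  chains <- if (is.character(fasta)) read_fasta(fasta) else fasta
  if (length(chains))
    names(chains) <- vapply(chains, `[[`, "", "chain_id")
  chains
}

annotate_chain <- function(chain, config) {
  regs <- detect_gxy_regions(chain, config$helix$min_triplets,
                             config$helix$max_interruptions)
  if (!length(regs))
    return(list(chain = chain, status = "no_main_helix", minor = NULL,
                main = NULL, gpp = NULL, telo_n = NULL, telo_c = NULL))
  cls <- classify_helices(regs, config$helix$minor_max_fraction)
  gpp <- find_gpp_terminus(chain, cls$main, config$helix$gpp_min_repeats)
  tel <- extract_telopeptides(chain, cls$minor, cls$main,
                              config$telo$c_max_len)
  list(chain = chain, status = "ok", minor = cls$minor, main = cls$main,
       gpp = gpp, telo_n = tel$n, telo_c = tel$c)
}

result_regions <- function(res) {
  regs <- Filter(Negate(is.null),
                 list(res$minor, res$main, res$gpp, res$telo_n, res$telo_c))
  if (!length(regs)) return(NULL)
  data.frame(chain_id = res$chain$chain_id,
             label = vapply(regs, `[[`, "", "label"),
             start = vapply(regs, `[[`, 0L, "start"),
             end = vapply(regs, `[[`, 0L, "end"),
             stringsAsFactors = FALSE)
}

#' Annotate chains: helices, (GPP)n terminus, telopeptides
#'
#' Chains with no detectable main helix are reported with status
#' `no_main_helix`, never dropped silently. When `out_dir` is given, writes
#' `regions.tsv` (annotation dialect of [read_annotations()]), `status.tsv`
#' and the config echo.
#'
#' @param fasta FASTA path or a named list of `collagen_chain`.
#' @param out_dir Output directory, or `NULL` for no files.
#' @param config Configuration list from [default_config()]/[load_config()].
#' @return Invisibly, the per-chain annotation results.
#' @export
run_annotate <- function(fasta, out_dir = NULL, config = default_config()) {
  chains <- resolve_chains(fasta)
  results <- lapply(chains, annotate_chain, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    reg_rows <- Filter(Negate(is.null), lapply(results, result_regions))
    reg <- if (length(reg_rows)) do.call(rbind, reg_rows) else
      data.frame(chain_id = character(0), label = character(0),
                 start = integer(0), end = integer(0))
    write.table(reg, file.path(out_dir, "regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    status <- data.frame(
      chain_id = vapply(results, function(r) r$chain$chain_id, ""),
      status = vapply(results, `[[`, "", "status"),
      stringsAsFactors = FALSE)
    write.table(status, file.path(out_dir, "status.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    echo_config(config, out_dir)
    if (!length(results)) message("no chains to annotate")
  }
  invisible(results)
}

scan_chain <- function(res, config) {
  if (res$status != "ok") return(empty_sites())
  telo_model <- weights_to_model(config$sites$telo_weights)
  helix_model <- weights_to_model(config$sites$helix_weights)
  rbind(
    scan_telopeptide(res$telo_n, res$chain, res$main, telo_model,
                     config$sites$score_min, config$sites$flank),
    scan_telopeptide(res$telo_c, res$chain, res$main, telo_model,
                     config$sites$score_min, config$sites$flank),
    scan_helical(res$chain, res$main, config$sites$end_window, helix_model,
                 config$sites$enforce_register, config$sites$flank))
}

#' Run the full cross-linking site analysis
#'
#' Annotates every chain, scans telopeptides and helix termini, ranks the
#' candidates, checks the flank-exclusion rule, builds K-anchored profiles
#' per site class from the rank-1 sites, and computes the lysine-depletion
#' statistic for the N- and C-telopeptide stretches. Chains yielding no
#' sites are tolerated (absence is a result). When `out_dir` is given,
#' writes `regions.tsv`, `status.tsv`, the site report (`sites.tsv` +
#' `sites.json`), one `logo_<class>.tsv` per populated site class,
#' `depletion.json`, and the config echo.
#'
#' @param fasta FASTA path or named list of `collagen_chain`.
#' @param out_dir Output directory, or `NULL` for no files.
#' @param config Configuration list.
#' @param site_class Optional filter: restrict outputs to one site class.
#' @return `list(results, sites, profiles, depletion)`.
#' @export
run_scan <- function(fasta, out_dir = NULL, config = default_config(),
                     site_class = NULL) {
  chains <- resolve_chains(fasta)
  results <- lapply(chains, annotate_chain, config = config)
  for (i in seq_along(results)) results[[i]]$sites <- scan_chain(results[[i]], config)
  sites <- do.call(rbind, c(list(empty_sites()),
                            lapply(results, `[[`, "sites")))
  rownames(sites) <- NULL
  depletion_input <- results
  if (!is.null(site_class)) {
    sites <- sites[sites$site_class %in% site_class, , drop = FALSE]
    for (i in seq_along(depletion_input))
      depletion_input[[i]]$sites <-
        depletion_input[[i]]$sites[
          depletion_input[[i]]$sites$site_class %in% site_class, , drop = FALSE]
  }
  profiles <- list()
  for (cls in unique(sites$site_class)) {
    top <- sites[sites$site_class == cls & sites$rank == 1L, , drop = FALSE]
    if (nrow(top))
      profiles[[cls]] <- build_profile(top, chains,
                                       config$conservation$flank_left,
                                       config$conservation$flank_right,
                                       config$conservation$pseudocount)
  }
  lengths <- measure_depletion_regions(depletion_input)
  depletion <- lapply(lengths, function(tab) {
    res <- lysine_depletion_probability(tab$length, config$conservation$f_k)
    list(chains = tab, n_total = res$n_total, f_k = res$f_k,
         probability = res$probability)
  })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    reg_rows <- Filter(Negate(is.null), lapply(results, result_regions))
    reg <- if (length(reg_rows)) do.call(rbind, reg_rows) else
      data.frame(chain_id = character(0), label = character(0),
                 start = integer(0), end = integer(0))
    write.table(reg, file.path(out_dir, "regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    status <- data.frame(
      chain_id = vapply(results, function(r) r$chain$chain_id, ""),
      status = vapply(results, `[[`, "", "status"),
      stringsAsFactors = FALSE)
    write.table(status, file.path(out_dir, "status.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    # annotate chains with their regions before the JSON report
    annotated <- chains
    for (res in results) {
      rr <- result_regions(res)
      if (!is.null(rr))
        annotated[[res$chain$chain_id]]$annotations <-
          rr[, c("label", "start", "end")]
    }
    write_report(annotated, sites, file.path(out_dir, "sites"))
    for (cls in names(profiles))
      export_logo_matrix(profiles[[cls]],
                         file.path(out_dir, paste0("logo_", cls, ".tsv")))
    jsonlite::write_json(
      lapply(depletion, function(d) list(
        lengths = d$chains$length, chain_ids = d$chains$chain_id,
        lysine_free = d$chains$lysine_free, n_total = d$n_total,
        f_k = d$f_k, probability = d$probability)),
      file.path(out_dir, "depletion.json"), auto_unbox = TRUE, digits = NA)
    echo_config(config, out_dir)
  }
  list(results = results, sites = sites, profiles = profiles,
       depletion = depletion)
}

#' Generate a synthetic family on disk
#'
#' Delegates to [generate_family()] and echoes the generator spec.
#'
#' @param spec A `synthetic_spec` (or plain list of its fields).
#' @param out_dir Output directory.
#' @return Invisibly, the [generate_family()] result.
#' @export
run_simulate <- function(spec, out_dir) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  fam <- generate_family(spec, out_dir)
  yaml::write_yaml(unclass(spec), file.path(out_dir, "config_echo.yaml"))
  invisible(fam)
}
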