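mk_sites <- function(seqs, k_pos) {
  chains <- lapply(seq_along(seqs), function(i)
    collagen_chain(sprintf("c%d", i), seqs[i]))
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  sites <- data.frame(chain_id = names(chains), site_class = "telo_C",
                      k_pos = k_pos, stringsAsFactors = FALSE)
  list(chains = chains, sites = sites)
}

test_that("profile columns behave at the entropy extremes", {
  # two identical windows: point-mass columns carry log2(20) bits
  x <- mk_sites(c("AAEKGPAA", "AAEKGPAA"), c(3, 3))
  p <- build_profile(x$sites, x$chains, flank_left = 2, flank_right = 4,
                     pseudocount = 0)
  expect_equal(p$windows, c("AEKGPAA", "AEKGPAA"))
  expect_equal(p$info_content, rep(log2(20), 7), tolerance = 1e-12)
  expect_true(all(abs(colSums(p$frequencies) - 1) < 1e-9))
  # anchor column is all K
  expect_equal(unname(p$frequencies["K", 3]), 1)

  # a column uniform over the 20 residues carries 0 bits
  seqs <- paste0("AA", "EK", AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                     "")[[1]], "PAA")
  x <- mk_sites(seqs, rep(3, 20))
  p <- build_profile(x$sites, x$chains, 2, 4, 0)
  expect_equal(p$info_content[4], 0, tolerance = 1e-12)
})

test_that("a {G, G, A} column reproduces the hand-computed entropy", {
  x <- mk_sites(c("AAEKGPAA", "AAEKGPAA", "AAEKAPAA"), c(3, 3, 3))
  p <- build_profile(x$sites, x$chains, 2, 4, 0)
  expect_equal(unname(p$frequencies["G", 4]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(p$frequencies["A", 4]), 1 / 3, tolerance = 1e-12)
  h <- -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3)
  expect_equal(p$info_content[4], log2(20) - h, tolerance = 1e-12)
  expect_equal(p$info_content[4], 3.4036, tolerance = 1e-4)
})

test_that("information content matches the brute-force entropy oracle", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    pc <- sample(c(0, 0.5, 1), 1)
    flanks <- sample(1:4, 2, replace = TRUE)
    width <- sum(flanks) + 1
    wins <- vapply(seq_len(n), function(i)
      paste(sample(aas, width, TRUE), collapse = ""), character(1))
    substr(wins, flanks[1] + 1, flanks[1] + 1) <- "K"
    x <- mk_sites(wins, rep(flanks[1], n))
    p <- build_profile(x$sites, x$chains, flanks[1], flanks[2], pc)
    for (j in seq_len(width)) {
      counts <- vapply(aas, function(a)
        sum(substr(wins, j, j) == a), numeric(1))
      expect_equal(p$info_content[j], oracle_info(counts, pc),
                   tolerance = 1e-9)
    }
    expect_true(all(p$info_content >= -1e-12 &
                      p$info_content <= log2(20) + 1e-12))
  }
})

test_that("windows pad with '-' at chain ends and pads are not counted", {
  x <- mk_sites(c("KGPAA", "AAEKGPAA"), c(0, 3))
  p <- build_profile(x$sites, x$chains, 2, 4, 0)
  expect_equal(p$windows[1], "--KGPAA")
  # first two columns have one observation each (the longer chain's)
  expect_equal(sum(p$counts[, 1]), 1)
  expect_true(all(abs(colSums(p$frequencies) - 1) < 1e-9))
  expect_error(build_profile(x$sites[0, ], x$chains),
               class = "colx_empty_error")
})

test_that("depletion probability reproduces the published arithmetic", {
  # 19 C-telopeptide stretches totalling 275 lysine-free residues
  r <- lysine_depletion_probability(c(rep(14, 10), rep(15, 9)), 0.072)
  expect_equal(r$n_total, 275)
  expect_equal(signif(r$probability, 2), 1.2e-9)
  # 14 N-telopeptide stretches totalling 176
  r <- lysine_depletion_probability(c(rep(12, 6), rep(13, 8)), 0.072)
  expect_equal(r$n_total, 176)
  expect_equal(signif(r$probability, 2), 1.9e-6)
  # empty evidence: probability 1
  r <- lysine_depletion_probability(integer(0), 0.072)
  expect_equal(r$n_total, 0)
  expect_equal(r$probability, 1)
  expect_error(lysine_depletion_probability(c(5, -1), 0.072),
               class = "colx_value_error")
  expect_error(lysine_depletion_probability(10, 0), class = "colx_value_error")
})

test_that("depletion probability is strictly monotone in N and f_k", {
  for (f in c(0.01, 0.072, 0.2, 0.5)) {
    p <- vapply(c(0, 1, 5, 20, 100, 275),
                function(n) lysine_depletion_probability(n, f)$probability,
                numeric(1))
    expect_true(all(diff(p) < 0))
  }
  for (n in c(1, 10, 176, 275)) {
    p <- vapply(c(0.01, 0.05, 0.072, 0.1, 0.3),
                function(f) lysine_depletion_probability(n, f)$probability,
                numeric(1))
    expect_true(all(diff(p) < 0))
  }
})

test_that("measure_depletion_regions subtracts landmark ends from rank-1 sites", {
  fam <- generate_family(synthetic_spec(seed = 21, n_chains = 3,
                                        n_k_gap = c(4, 6, 8),
                                        c_k_gap = c(9, 11, 13)))
  out <- run_scan(fam$chains)
  dep <- measure_depletion_regions(out$results)
  expect_equal(dep$telo_N$length, c(4, 6, 8))
  expect_equal(dep$telo_C$length, c(9, 11, 13))
  expect_true(all(dep$telo_N$lysine_free))
  expect_true(all(dep$telo_C$lysine_free))
  # a chain with no telopeptide site is skipped with a message
  no_site <- out$results[1]
  no_site[[1]]$sites <- no_site[[1]]$sites[0, ]
  expect_message(dep2 <- measure_depletion_regions(no_site), "skipped")
  expect_equal(nrow(dep2$telo_C), 0)
})

test_that("export_logo_matrix writes one row per position, 21 numeric columns", {
  x <- mk_sites(c("AAEKGPAA", "AAEKAHAA"), c(3, 3))
  p <- build_profile(x$sites, x$chains, 2, 4, 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_logo_matrix(p, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(tab), 7)
  num <- setdiff(names(tab), "offset")
  expect_length(num, 21)
  expect_true(all(vapply(tab[num], is.numeric, logical(1))))
  freq <- as.matrix(tab[, setdiff(num, "info_content")])
  expect_true(all(abs(rowSums(freq) - 1) < 1e-9))
  # anchor row: K frequency 1 at pseudocount 0
  expect_equal(tab$K[tab$offset == 0], 1)
})
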