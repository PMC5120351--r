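# helper: wrap a telopeptide string into a chain with a fake main helix so
# the scanners can be exercised in isolation
telo_chain <- function(telo_seq, side = "C") {
  helix <- strrep("GPP", 40)
  if (side == "C") {
    seqs <- paste0(helix, telo_seq)
    main <- colxlink:::helix_region(0, 120, 0, 40, 0, "main_helix")
    telo <- colxlink:::telopeptide_region(120, 120 + nchar(telo_seq), "C",
                                          telo_seq)
  } else {
    seqs <- paste0(telo_seq, helix)
    main <- colxlink:::helix_region(nchar(telo_seq),
                                    nchar(telo_seq) + 120,
                                    nchar(telo_seq) %% 3, 40, 0, "main_helix")
    telo <- colxlink:::telopeptide_region(0, nchar(telo_seq), "N", telo_seq)
  }
  list(chain = collagen_chain("t", seqs), main = main, telo = telo)
}

test_that("scan_telopeptide scores the canonical human site contexts", {
  # REKGP: X' = G, X'' = P -> score 1.0
  x <- telo_chain("GDDANREKGPDPLNY")
  out <- scan_telopeptide(x$telo, x$chain, x$main)
  expect_equal(nrow(out), 1)
  expect_equal(out$res_p1, "G")
  expect_equal(out$res_p2, "P")
  expect_equal(out$score, 1.0)
  expect_equal(substr(x$chain$sequence, out$k_pos + 1, out$k_pos + 1), "K")

  # QEKAH: X' = A, X'' = H -> score (0.8 + 0.6) / 2
  x <- telo_chain("GDDANQEKAHDPLNY")
  out <- scan_telopeptide(x$telo, x$chain, x$main)
  expect_equal(out$score, 0.7)
  expect_equal(c(out$res_p1, out$res_p2), c("A", "H"))

  # lysine-free telopeptide: nothing to report
  x <- telo_chain("GDDANVVRDRDL")
  expect_equal(nrow(scan_telopeptide(x$telo, x$chain, x$main)), 0)
})

test_that("telopeptide candidates are ranked by score, ties toward the helix", {
  x <- telo_chain("AAREKGPAAQEKAHAA")
  out <- scan_telopeptide(x$telo, x$chain, x$main)
  expect_equal(out$rank, c(1L, 2L))
  expect_true(out$score[1] > out$score[2])
  expect_equal(out$res_p1, c("G", "A"))
  # equal scores: the K closer to the main helix (here: C side, smaller k)
  x <- telo_chain("AAREKGPAAREKGPAA")
  out <- scan_telopeptide(x$telo, x$chain, x$main)
  expect_equal(out$k_pos[1], min(out$k_pos))
  # low scorers fall below score_min
  x <- telo_chain("AAVEKVVAA")
  expect_equal(nrow(scan_telopeptide(x$telo, x$chain, x$main)), 0)
  expect_equal(nrow(scan_telopeptide(x$telo, x$chain, x$main,
                                     score_min = 0)), 1)
})

test_that("scan completeness: every K is a candidate before filtering", {
  set.seed(99)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "K", "G", "P", "E", "R"), 40, TRUE),
               collapse = "")
    x <- telo_chain(s)
    out <- scan_telopeptide(x$telo, x$chain, x$main, score_min = 0)
    want <- x$telo$start + which(strsplit(s, "")[[1]] == "K") - 1
    expect_setequal(out$k_pos, want)
  }
})

test_that("score is monotone in the X'/X'' weights", {
  model <- default_telo_model()
  base <- telo_chain("AAVEKVVAA")
  b <- scan_telopeptide(base$telo, base$chain, base$main, model, score_min = 0)
  for (s in c("AAVEKSVAA", "AAVEKAVAA", "AAVEKGVAA")) {
    x <- telo_chain(s)
    out <- scan_telopeptide(x$telo, x$chain, x$main, model, score_min = 0)
    expect_gte(out$score, b$score)
    b <- out
  }
  b <- scan_telopeptide(base$telo, base$chain, base$main, model, score_min = 0)
  for (s in c("AAVEKVGAA", "AAVEKVPAA")) {
    x <- telo_chain(s)
    out <- scan_telopeptide(x$telo, x$chain, x$main, model, score_min = 0)
    expect_gte(out$score, b$score)
    b <- out
  }
})

test_that("scan_helical finds Y-K-G-Y''-Y''' acceptors at helix termini", {
  # helix with planted MKGHR near the N end, in register (K at X')
  helix <- paste0("GPP", "GMKGHR", strrep("GPP", 30))
  ch <- collagen_chain("h", helix)
  main <- colxlink:::helix_region(0, nchar(helix), 0, nchar(helix) %/% 3, 0,
                                  "main_helix")
  out <- scan_helical(ch, main)
  n <- out[out$site_class == "helix_N", ]
  expect_equal(n$k_pos, 5)
  expect_equal(n$score, 1.0)
  expect_equal((n$k_pos - main$start) %% 3, 2)

  # K at a G-anchor position violates the register and is not a candidate
  helix2 <- paste0("GPPGPP", "KGG", strrep("GPP", 30))   # K replaces anchor G
  ch2 <- collagen_chain("h2", helix2)
  main2 <- colxlink:::helix_region(0, 6, 0, 2, 0, "main_helix")
  main2$end <- nchar(helix2); main2$triplet_count <- nchar(helix2) %/% 3
  main2$interruptions <- 1L
  out2 <- scan_helical(ch2, main2)
  expect_false(6 %in% out2$k_pos)
  # ... but is reported when the register constraint is disabled
  out2b <- scan_helical(ch2, main2, enforce_register = FALSE)
  expect_true(6 %in% out2b$k_pos)

  # KG with neither H nor R still reported, at the default weight
  helix3 <- paste0("GP", "KGPP", strrep("GPP", 30))
  ch3 <- collagen_chain("h3", helix3)
  main3 <- colxlink:::helix_region(0, nchar(helix3), 0, nchar(helix3) %/% 3,
                                   0, "main_helix")
  out3 <- scan_helical(ch3, main3)
  n3 <- out3[out3$site_class == "helix_N", ]
  expect_equal(n3$k_pos, 2)
  expect_equal(n3$score, 0.2)
})

test_that("scan_helical keeps the best candidate per end, ties nearer the end", {
  # two in-register KGHR sites in the N window: the more N-terminal wins
  helix <- paste0("GPP", "GMKGHR", "GMKGHR", strrep("GPP", 30))
  ch <- collagen_chain("h", helix)
  main <- colxlink:::helix_region(0, nchar(helix), 0, nchar(helix) %/% 3, 0,
                                  "main_helix")
  out <- scan_helical(ch, main)
  expect_equal(out[out$site_class == "helix_N", "k_pos"], 5)
  # scanning is restricted to the end windows
  mid_k <- paste0(strrep("GPP", 15), "GMKGHR", strrep("GPP", 15))
  chm <- collagen_chain("m", mid_k)
  mainm <- colxlink:::helix_region(0, nchar(mid_k), 0, nchar(mid_k) %/% 3, 0,
                                   "main_helix")
  expect_equal(nrow(scan_helical(chm, mainm, end_window = 30)), 0)
  expect_gt(nrow(scan_helical(chm, mainm, end_window = 60)), 0)
})

test_that("check_flank_exclusion applies the five-residue lysine rule", {
  b <- function(L) list(start = 0L, end = L)
  expect_true(check_flank_exclusion("AAAKAAA", 3, 3, b(7)))
  expect_false(check_flank_exclusion("AKAKAAA", 3, 3, b(7)))
  # a lysine exactly flank residues away violates the rule ...
  expect_false(check_flank_exclusion("KAAAAK", 0, 5, b(6)))
  # ... one residue further does not
  expect_true(check_flank_exclusion("KAAAAAK", 0, 5, b(7)))
  # clipping at the bounds hides an outside lysine
  expect_false(check_flank_exclusion("KAAAK", 4, 5, b(5)))
  expect_true(check_flank_exclusion("KAAAK", 4, 5, list(start = 1L, end = 5L)))
  expect_error(check_flank_exclusion("AAAAAAA", 3, 3, b(7)),
               class = "colx_site_error")
})
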