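test_that("the canonical substrate yields exactly one strict 12RSS hit", {
  akn1 <- fixture_oligo("AKN1")
  hits <- scan_rss(akn1, params = scan_params(0, 0), seq_id = "AKN1")
  top <- hits[hits$strand == "top", ]
  expect_equal(nrow(top), 1)
  expect_equal(top$hept_start0, 17)    # 17 nt 5' of the heptamer
  expect_equal(top$spacer_len, 12)     # a 12RSS
  expect_equal(top$nona_start0, 36)
  expect_equal(top$hept_mm, 0)
  expect_equal(top$nona_mm, 0)
  expect_equal(top$hept_seq, "CACAGTG")
  expect_equal(top$nona_seq, "ACAAAAACC")
  expect_equal(top$mismatch_score, 0)
})

test_that("RSS-free control substrates produce no hits at default bounds", {
  for (nm in c("DG13", "DG14", "DG27", "DG28", "MS20")) {
    expect_equal(nrow(scan_rss(fixture_oligo(nm))), 0, label = nm)
  }
})

test_that("cryptic substrate arrangements match brute-force findings", {
  # AMY1B substrate: one cryptic heptamer works with both a 12- and a
  # 23-type nonamer arrangement; both must be reported (no greedy masking)
  ap96 <- scan_rss(fixture_oligo("AP96"), params = scan_params(strands = "top"))
  expect_equal(sort(ap96$spacer_len), c(12, 23))
  expect_true(all(ap96$hept_start0 == 20))
  expect_true(all(ap96$hept_seq == "CACAGAA"))
  # RN7SKP123-MTF2 substrate: single cryptic 12RSS arrangement
  ap100 <- scan_rss(fixture_oligo("AP100"), params = scan_params(strands = "top"))
  expect_equal(ap100$hept_start0, 20)
  expect_equal(ap100$spacer_len, 12)
  # CAMK2D substrate: no hit at spacer exactly 12/23, but widening the
  # spacer tolerance recovers the cryptic arrangement at heptamer offset 20
  ap92 <- scan_rss(fixture_oligo("AP92"), params = scan_params(strands = "top"))
  expect_equal(nrow(ap92), 0)
  ap92w <- scan_rss(fixture_oligo("AP92"),
                    params = scan_params(spacer_tolerance = 2, strands = "top"))
  expect_true(20 %in% ap92w$hept_start0)
  expect_equal(ap92w$hept_seq[ap92w$hept_start0 == 20][1], "CACAGCA")
})

test_that("planted consensus sequences are recovered at the planted offset", {
  for (seed in 1:5) {
    k <- 10 + seed
    g <- gen_rss_sequence(80, k, 0, 12, 0, seed = seed)
    hits <- scan_rss(g$seq, params = scan_params(0, 0, strands = "top"))
    expect_true(k %in% hits$hept_start0)
    hit <- hits[hits$hept_start0 == k, ]
    expect_equal(hit$hept_mm, 0)
    expect_equal(hit$nona_mm, 0)
  }
  # planted mismatches above the scan bound make the plant invisible
  g <- gen_rss_sequence(80, 20, 3, 12, 2, seed = 99)
  strict <- scan_rss(g$seq, params = scan_params(2, 4, strands = "top"))
  expect_false(20 %in% strict$hept_start0)
  loose <- scan_rss(g$seq, params = scan_params(3, 4, strands = "top"))
  expect_true(20 %in% loose$hept_start0)
})

test_that("scan_rss equals the brute-force triple-loop oracle", {
  set.seed(2026)
  for (i in 1:30) {
    s <- random_dna(200)
    got <- scan_rss(s)
    want <- oracle_scan(s)
    expect_identical(hit_key(got), hit_key(want))
    # unanchored, looser spacer band
    got2 <- scan_rss(s, params = scan_params(2, 3, spacer_tolerance = 1,
                                             anchor_cac = FALSE))
    want2 <- oracle_scan(s, m_h = 2, m_n = 3, tol = 1, anchor = FALSE)
    expect_identical(hit_key(got2), hit_key(want2))
  }
})

test_that("scanning the reverse complement swaps strands consistently", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_dna(150)
    bottom <- scan_rss(s, params = scan_params(strands = "bottom"))
    flipped <- scan_rss(revcomp(s), params = scan_params(strands = "top"))
    expect_equal(nrow(bottom), nrow(flipped))
    if (nrow(bottom)) {
      expect_setequal(paste(bottom$hept_start0, bottom$spacer_len,
                            bottom$hept_mm, bottom$nona_mm),
                      paste(flipped$hept_start0, flipped$spacer_len,
                            flipped$hept_mm, flipped$nona_mm))
    }
  }
})

test_that("bottom-strand hits report a correct top-strand footprint", {
  # plant a consensus RSS, scan its reverse complement on the bottom strand
  g <- gen_rss_sequence(80, 25, 0, 12, 0, seed = 3)
  flipped <- revcomp(g$seq)
  hits <- scan_rss(flipped, params = scan_params(0, 0, strands = "bottom"))
  expect_gte(nrow(hits), 1)
  h <- hits[hits$hept_mm == 0 & hits$nona_mm == 0, ][1, ]
  # heptamer occupies [25, 32) of the original => same interval counted from
  # the right end of the flipped sequence
  expect_equal(h$hept_start0_top, nchar(flipped) - 25 - 7)
  expect_equal(h$hept_start0, 25)
  expect_equal(h$nona_start0, h$hept_start0 + 7 + h$spacer_len)
})

test_that("sequences shorter than the RSS footprint yield empty tables", {
  expect_equal(nrow(scan_rss("CACAGTGACG")), 0)
  expect_equal(nrow(scan_rss("ACGT")), 0)
})

test_that("mismatch score is the stated weighted sum and is monotone", {
  h <- data.frame(hept_mm = 0, nona_mm = 0, spacer_len = 12)
  expect_equal(mismatch_score(h, c(2, 1, 1)), 0)
  h2 <- data.frame(hept_mm = 2, nona_mm = 1, spacer_len = 12)
  expect_equal(mismatch_score(h2, c(2, 1, 1)), 5)
  h3 <- data.frame(hept_mm = 1, nona_mm = 2, spacer_len = 14)
  expect_equal(mismatch_score(h3, c(2, 1, 1)), 6)  # spacer deviation 2
  # non-decreasing in each mismatch count
  for (m in 0:6) {
    a <- mismatch_score(data.frame(hept_mm = m, nona_mm = 1, spacer_len = 12))
    b <- mismatch_score(data.frame(hept_mm = m + 1, nona_mm = 1, spacer_len = 12))
    expect_lt(a, b)
  }
  expect_error(mismatch_score(h, c(-1, 1, 1)), "non-negative")
})

test_that("nick site is the 5' edge of the heptamer", {
  akn1 <- fixture_oligo("AKN1")
  hit <- scan_rss(akn1, params = scan_params(0, 0, strands = "top"))
  expect_equal(hit$nick_site0, 17)
  expect_equal(nick_site(data.frame(hept_start0 = 0)), 0L)
  # best CAC-anchored heptamer on the CAMK2D substrate begins after 20 nt
  ap92 <- scan_rss(fixture_oligo("AP92"),
                   params = scan_params(spacer_tolerance = 2, strands = "top"))
  best <- ap92[1, ]
  expect_equal(nick_site(best), 20L)
})

test_that("a uniform model scores every window zero", {
  akn1 <- fixture_oligo("AKN1")
  hits <- scan_rss(akn1, params = scan_params(2, 4), model = uniform_rss_model())
  expect_true(all(abs(hits$model_score) < 1e-9))
})

test_that("the default model ranks the consensus above mutants and cryptic hits", {
  mdl <- rss_model()
  akn1 <- fixture_oligo("AKN1")
  canon <- scan_rss(akn1, params = scan_params(0, 0, strands = "top"),
                    model = mdl)
  # consensus beats the same arrangement with one CAC-position substitution
  mut <- akn1
  substr(mut, 18, 18) <- "T"   # C -> T at heptamer position 1
  mut_hits <- scan_rss(mut, params = scan_params(2, 2, anchor_cac = FALSE,
                                                 strands = "top"), model = mdl)
  mut_hit <- mut_hits[mut_hits$hept_start0 == 17, ]
  expect_lt(mut_hit$model_score, canon$model_score)
  # canonical substrate outranks the best cryptic RN7SKP123-MTF2 hit
  ap100 <- scan_rss(fixture_oligo("AP100"), params = scan_params(), model = mdl)
  expect_lt(max(ap100$model_score), canon$model_score)
  # exact consensus window attains the maximum over all 1-mutant windows
  base <- gen_rss_sequence(60, 17, 0, 12, 0, seed = 5)$seq
  base_score <- scan_rss(base, params = scan_params(0, 0, strands = "top"),
                         model = mdl)$model_score
  set.seed(41)
  for (i in 1:20) {
    pos <- sample(c(18:24, 37:45), 1)   # inside heptamer or nonamer, 1-based
    mutant <- base
    substr(mutant, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(base, pos, pos)), 1)
    mh <- scan_rss(mutant, params = scan_params(7, 9, anchor_cac = FALSE,
                                                strands = "top"), model = mdl)
    mh <- mh[mh$hept_start0 == 17 & mh$spacer_len == 12, ]
    expect_gte(base_score, mh$model_score)
  }
})

test_that("RSS models round-trip through JSON", {
  mdl <- rss_model(spacer_penalty = 2.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_rss_model(mdl, path)
  back <- read_rss_model(path)
  expect_equal(back$heptamer_freq, mdl$heptamer_freq, ignore_attr = TRUE)
  expect_equal(back$spacer_penalty, 2.5)
  expect_equal(back$pseudocount, mdl$pseudocount)
})

test_that("invalid scan and model parameters are rejected", {
  expect_error(scan_params(max_heptamer_mismatch = 8), "0..7")
  expect_error(scan_params(max_nonamer_mismatch = 10), "0..9")
  expect_error(scan_params(spacer_tolerance = -1), ">= 0")
  expect_error(rss_consensus(heptamer = "CACAGT"), "exactly 7")
  expect_error(rss_model(pseudocount = 0), "pseudocount")
  expect_error(rss_model(background = c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
})
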