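test_that("average masses reproduce printed theoretical masses", {
  expect_equal(average_mass("GVLDIFKDAAKQILAHAAEKI", amidated = TRUE),
               2250.67, tolerance = 0.05 / 2250)
  expect_equal(average_mass("GVVDILKDTGKKLLSHLMEKV", amidated = TRUE),
               2322.84, tolerance = 0.05 / 2322)
  expect_equal(average_mass("G"), 75.07, tolerance = 1e-4)
  expect_error(average_mass("GVB"), "B")
})

test_that("amidation shifts mass by -0.9847 Da and charge by +1", {
  fam <- cached_family()
  for (s in fam$sequence[c(1, 7, 13, 25)]) {
    expect_equal(average_mass(s, TRUE), average_mass(s, FALSE) - 0.9847)
    expect_equal(net_charge_formal(s, TRUE), net_charge_formal(s, FALSE) + 1L)
  }
})

test_that("formal pH-7 charges match the printed net charges", {
  cat <- cached_catalogue()
  seq_of <- function(n) cat$sequence[cat$name == n]
  expect_equal(net_charge_formal(seq_of("ocellatin-7"), TRUE), 2L)
  expect_equal(net_charge_formal(seq_of("ocellatin-2"), TRUE), 0L)
  expect_equal(net_charge_formal(seq_of("P3-Lla-2085"), TRUE), 2L)
  expect_equal(net_charge_formal("AAAA", amidated = TRUE), 1L)
  # the family stays weakly cationic: formal charges in {0..+3} for the
  # amidated members (the free-acid 32-mers drop below)
  fam <- cat[cat$group == "family_member" & cat$amidated, ]
  ch <- mapply(net_charge_formal, fam$sequence, fam$amidated)
  expect_true(all(ch %in% 0:3))
})

test_that("continuous charge is monotone in pH and zero at the pI", {
  fam <- cached_family()
  for (s in fam$sequence[c(2, 10, 28)]) {
    expect_gt(net_charge_continuous(s, TRUE, 0),
              net_charge_continuous(s, TRUE, 14))
    ph <- seq(0, 14, by = 0.5)
    q <- vapply(ph, function(p) net_charge_continuous(s, TRUE, p), numeric(1))
    expect_true(all(diff(q) < 0))
    pI <- compute_pI(s, TRUE)
    expect_lt(abs(net_charge_continuous(s, TRUE, pI)), 1e-4)
    # removing the acidic C-terminal group must raise the pI
    expect_gt(pI, compute_pI(s, FALSE))
  }
})

test_that("pI of ocellatin-11 brackets the expected basic range", {
  # independent oracle: coarse grid scan of the per-group charge sum
  seqc <- "GVLDIFKDAAKQILAHAAEKI"
  grid <- seq(0, 14, by = 0.01)
  q <- vapply(grid, function(p) net_charge_continuous(seqc, TRUE, p), numeric(1))
  oracle_pI <- grid[which.min(abs(q))]
  pI <- compute_pI(seqc, TRUE)
  expect_equal(pI, oracle_pI, tolerance = 0.01)
  expect_gt(pI, 9.0); expect_lt(pI, 11.5)
})

test_that("GRAVY matches the printed extremes and simple means", {
  fam <- cached_family()
  expect_equal(round(gravy(fam$sequence[fam$name == "ocellatin-PT6"]), 3),
               -0.103)
  expect_equal(round(gravy(fam$sequence[fam$name == "ocellatin-4"]), 2), 0.81)
  expect_equal(gravy("GG"), -0.4)
  # reversal invariance
  rev_seq <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (s in fam$sequence[c(3, 11, 20)]) expect_equal(gravy(s), gravy(rev_seq(s)))
})

test_that("hydrophobic fractions use the documented set with truncation", {
  expect_equal(hydrophobic_fraction("AVLDILKDVGKGLLSHFMEKV"), 52L)
  expect_equal(hydrophobic_fraction("GVVDILKDTGKKLLSHLMEKI"), 42L)
  expect_equal(hydrophobic_fraction("DDDD"), 0L)
  expect_equal(hydrophobic_fraction("LLLL"), 100L)
})

test_that("hydrophobic moment behaves like the brute-force vector sum", {
  # uniform hydropathy cancels over a full wheel period (18 residues at
  # 100 degrees = 5 turns hitting all multiples of 20 degrees once)
  expect_lt(hydrophobic_moment(strrep("L", 18)), 1e-9)
  # perfect alternation at delta = 180 equals the signed-sum oracle
  alt <- strrep("LK", 9)
  h <- KD_HYDROPATHY[strsplit(alt, "")[[1]]]
  oracle <- abs(sum(h * (-1)^(seq_along(h) - 1))) / nchar(alt)
  expect_equal(hydrophobic_moment(alt, delta = 180), oracle, tolerance = 1e-9)
  # direct vector-sum oracle at the helical 100-degree step
  seqc <- "GVLDIFKDAAKQILAHAAEKI"
  hh <- KD_HYDROPATHY[strsplit(seqc, "")[[1]]]
  ang <- (seq_along(hh) - 1) * 100 * pi / 180
  oracle2 <- sqrt(sum(hh * cos(ang))^2 + sum(hh * sin(ang))^2) / length(hh)
  expect_equal(hydrophobic_moment(seqc), oracle2)
  # reversal leaves the magnitude unchanged
  rev_seq <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (s in cached_family()$sequence[c(5, 14, 27)]) {
    expect_equal(hydrophobic_moment(s), hydrophobic_moment(rev_seq(s)),
                 tolerance = 1e-9)
  }
})

test_that("family hydrophobic moments bracket the printed range", {
  fam <- cached_family()
  mu <- vapply(fam$sequence, hydrophobic_moment, numeric(1))
  expect_true(all(mu >= 0.5 & mu <= 1.6))
})

test_that("helical wheel geometry places lysines on one cationic face", {
  w <- helical_wheel("GVLDIFKDAAKQILAHAAEKI")
  expect_equal(w$angle[1], 0)
  expect_equal(w$angle[2], 100)
  expect_equal(w$face[w$residue == "K"], rep("hydrophilic", 3))
  # 18 residues at 100 degrees cover every multiple of 20
  w18 <- helical_wheel(strrep("A", 18))
  expect_setequal(w18$angle, seq(0, 340, by = 20))
  # exhaustive half-plane search: some 180-degree arc holds all lysines
  k_ang <- w$angle[w$residue == "K"]
  in_halfplane <- vapply(0:359, function(center) {
    d <- (k_ang - center) %% 360
    all(d <= 90 | d >= 270)
  }, logical(1))
  expect_true(any(in_halfplane))
})

test_that("MIC conversion matches the printed unit pairs and round-trips", {
  expect_equal(round(mic_convert(32, 2273.77)), 14)
  expect_equal(round(mic_convert(64, 2311.82)), 28)
  expect_equal(round(mic_convert(31, 2085.52)), 15)
  x <- mic_convert(mic_convert(145, 2274.73), 2274.73, from = "um")
  expect_equal(x, 145, tolerance = 1e-9)
  expect_error(mic_convert(-1, 2000), "> 0")
})

test_that("physchem profile assembles the panel consistently", {
  p <- physchem_profile("GVLDIFKDAAKQILAHAAEKI", amidated = TRUE)
  expect_equal(p$mw, average_mass("GVLDIFKDAAKQILAHAAEKI", TRUE))
  expect_equal(p$net_charge_formal, 1L)
  expect_true(p$hydrophobic_pct >= 0 && p$hydrophobic_pct <= 100)
  expect_gte(p$mu_h, 0)
  expect_true(p$gravy >= -4.5 && p$gravy <= 4.5)
})
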