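# Fragment matching, the binary evidence matrix, NNLS apportionment and
# site localization over co-isolated isobaric candidates.

h4_setup <- function() {
  s <- ptm_schema("H4")
  e <- proteoform_masses(enumerate_proteoforms(s), s)
  cl <- isobaric_classes(e, ms_config())
  list(schema = s, classes = cl,
       bb = histone_backbone("H4"))
}

class_of <- function(cl, notation) {
  cid <- cl$members$class_id[cl$members$notation == notation]
  cl$members[cl$members$class_id == cid, , drop = FALSE]
}

test_that("a noise-free single-candidate spectrum matches fully with empty residual", {
  su <- h4_setup()
  cand <- class_of(su$classes, "H4<>")[1, ]
  sp <- mixture_ms2(list(character()), 1, su$schema,
                    neutral_to_mz(cand$mass, 13), 13)
  ev <- match_fragments(sp, cand, su$schema, ms_config())
  expect_equal(nrow(ev$residual), 0)
  expect_true(all(ev$observed$matched))
  ap <- apportion(ev)
  expect_equal(unname(ap$fractions), 1.0)
})

test_that("peaks outside the 10 ppm tolerance fall into the residual pool", {
  su <- h4_setup()
  cand <- class_of(su$classes, "H4<>")[1, ]
  fl <- etd_fragments(su$bb)
  good <- fl$c[10]
  off <- fl$c[20] * (1 + 15e-6)     # 15 ppm away from the nearest fragment
  sp <- spectrum_peaklist("MS2", sort(c(good, off)) + proton_mass(), c(5, 5),
                          precursor = list(mz = neutral_to_mz(cand$mass, 13),
                                           charge = 13),
                          scan_id = "t")
  ev <- match_fragments(sp, cand, su$schema, ms_config())
  expect_equal(nrow(ev$residual), 1)
  expect_equal(ev$residual$mass, off, tolerance = 1e-9)
})

test_that("positional isomers differing at K8 vs K16 have discriminating c-ion rows", {
  su <- h4_setup()
  f8 <- etd_fragments(su$bb, c(K8 = "ac", K20 = "me3"))
  f16 <- etd_fragments(su$bb, c(K16 = "ac", K20 = "me3"))
  d_ac <- ptm_deltas()$mono_da[ptm_deltas()$ptm == "ac"]
  expect_equal(f16$c[8:15] + d_ac, f8$c[8:15])   # c8..c15 differ by one acetyl
  expect_equal(f16$c[16:101], f8$c[16:101])      # beyond K16 they agree
  cand <- class_of(su$classes, "H4<K8acK20me3>")
  sp <- mixture_ms2(list(c(K8 = "ac", K20 = "me3")), 1, su$schema,
                    neutral_to_mz(mean(cand$mass), 13), 13)
  ev <- match_fragments(sp, cand, su$schema, ms_config())
  i8 <- match("H4<K8acK20me3>", colnames(ev$A))
  i16 <- match("H4<K16acK20me3>", colnames(ev$A))
  disc <- ev$A[, i8] != ev$A[, i16]
  expect_gt(sum(disc), 0)
})

test_that("empty candidate lists are rejected", {
  su <- h4_setup()
  sp <- spectrum_peaklist("MS2", 500, 1,
                          precursor = list(mz = 800, charge = 13),
                          scan_id = "t")
  expect_error(match_fragments(sp, su$classes$members[0, ], su$schema),
               "non-empty")
})

test_that("NNLS apportionment recovers a noise-free 70/30 mixture exactly", {
  su <- h4_setup()
  cand <- class_of(su$classes, "H4<K8acK20me3>")
  sp <- mixture_ms2(list(c(K8 = "ac", K20 = "me3"),
                         c(K16 = "ac", K20 = "me3")),
                    c(0.7, 0.3), su$schema,
                    neutral_to_mz(mean(cand$mass), 13), 13)
  ev <- match_fragments(sp, cand, su$schema, ms_config())
  ap <- apportion(ev)
  expect_equal(sum(ap$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(ap$fractions["H4<K8acK20me3>"]), 0.7, tolerance = 1e-6)
  expect_equal(unname(ap$fractions["H4<K16acK20me3>"]), 0.3, tolerance = 1e-6)
  expect_false(ap$ambiguous)
  expect_lt(ap$residual_norm, 1e-9)
})

test_that("apportionment is scale invariant and order equivariant", {
  su <- h4_setup()
  cand <- class_of(su$classes, "H4<K8acK20me3>")
  sp <- mixture_ms2(list(c(K8 = "ac", K20 = "me3"),
                         c(K5 = "ac", K20 = "me3")),
                    c(0.6, 0.4), su$schema,
                    neutral_to_mz(mean(cand$mass), 13), 13)
  ev1 <- match_fragments(sp, cand, su$schema, ms_config())
  ap1 <- apportion(ev1)
  ev_scaled <- ev1
  ev_scaled$b <- ev1$b * 1234.5
  ap2 <- apportion(ev_scaled)
  expect_equal(ap1$fractions, ap2$fractions, tolerance = 1e-9)
  # permuting candidate order permutes fractions identically
  perm <- withr::with_seed(2, sample(nrow(cand)))
  ev3 <- match_fragments(sp, cand[perm, ], su$schema, ms_config())
  ap3 <- apportion(ev3)
  expect_equal(ap3$fractions[names(ap1$fractions)], ap1$fractions,
               tolerance = 1e-9)
})

test_that("indistinguishable candidates split uniformly with the ambiguity flag", {
  su <- h4_setup()
  cand <- class_of(su$classes, "H4<K8acK20me3>")[1:2, ]
  # keep only fragments both candidates share: no discriminating rows
  st1 <- histoform:::.row_states(cand, su$schema, 1)
  st2 <- histoform:::.row_states(cand, su$schema, 2)
  fl1 <- etd_fragments(su$bb, st1)
  fl2 <- etd_fragments(su$bb, st2)
  shared <- intersect(round(c(fl1$c, fl1$z), 6), round(c(fl2$c, fl2$z), 6))
  sp <- spectrum_peaklist("MS2", sort(shared) + proton_mass(),
                          rep(10, length(shared)),
                          precursor = list(mz = neutral_to_mz(mean(cand$mass), 13),
                                           charge = 13),
                          scan_id = "shared")
  ev <- match_fragments(sp, cand, su$schema, ms_config())
  ap <- apportion(ev)
  expect_equal(unname(ap$fractions), c(0.5, 0.5), tolerance = 1e-9)
  expect_true(ap$ambiguous)
})

test_that("an all-zero intensity vector yields a flagged uniform split", {
  su <- h4_setup()
  cand <- class_of(su$classes, "H4<K8acK20me3>")[1:3, ]
  sp <- spectrum_peaklist("MS2", c(100.1, 200.2), c(0, 0),
                          precursor = list(mz = neutral_to_mz(mean(cand$mass), 13),
                                           charge = 13),
                          scan_id = "zero")
  ap <- apportion(match_fragments(sp, cand, su$schema, ms_config()))
  expect_equal(unname(ap$fractions), rep(1 / 3, 3))
  expect_true(ap$ambiguous)
})

test_that("NNLS agrees with an independent solver on random systems", {
  skip_if_not_installed("pracma")
  withr::with_seed(77, {
    for (i in 1:25) {
      A <- matrix(stats::runif(12 * 4), 12, 4)
      b <- stats::runif(12)
      x1 <- nnls_solve(A, b)
      x2 <- pracma::lsqnonneg(A, b)$x
      expect_equal(x1, x2, tolerance = 1e-6)
    }
  })
})

test_that("localization is unambiguous with a full ladder, ambiguous with c1..c4 only", {
  su <- h4_setup()
  # full noise-free ladder for the proteoform of the worked identification
  st <- c(K12 = "ac", K16 = "ac", K31 = "ac")
  cand <- class_of(su$classes, "H4<K12acK16acK31ac>")
  sp <- mixture_ms2(list(st), 1, su$schema,
                    neutral_to_mz(mean(cand$mass), 15), 15)
  ev <- match_fragments(sp, cand, su$schema, ms_config())
  loc <- localize(ev, "H4<K12acK16acK31ac>")
  expect_true(all(loc$status == "unambiguous"))
  expect_equal(loc$state[loc$site == "K12"], "ac")
  # only c1..c4: candidates differing at K12 vs K16 both explain the set
  fl <- etd_fragments(su$bb, st)
  sp2 <- spectrum_peaklist("MS2", fl$c[1:4] + proton_mass(), rep(5, 4),
                           precursor = list(mz = neutral_to_mz(mean(cand$mass), 15),
                                            charge = 15),
                           scan_id = "c14")
  ev2 <- match_fragments(sp2, cand, su$schema, ms_config())
  loc2 <- localize(ev2, "H4<K12acK16acK31ac>")
  expect_equal(loc2$status[loc2$site == "K12"], "ambiguous")
  expect_equal(loc2$status[loc2$site == "K16"], "ambiguous")
  # empty matched set: everything ambiguous
  sp3 <- spectrum_peaklist("MS2", 99.9, 5,
                           precursor = list(mz = neutral_to_mz(mean(cand$mass), 15),
                                            charge = 15),
                           scan_id = "none")
  ev3 <- match_fragments(sp3, cand, su$schema, ms_config())
  loc3 <- localize(ev3, "H4<K12acK16acK31ac>")
  expect_true(all(loc3$status == "ambiguous"))
})

test_that("noise-free mixtures over an isobaric class recover ground truth to 1e-6", {
  su <- h4_setup()
  cand <- class_of(su$classes, "H4<K8acK20me3>")
  # identifiable planting: members sharing K20me3 differ in one acetyl
  # position, so cumulative-mass ladders invert uniquely (mixtures of
  # 2-acetyl positional isomers can be chimera-degenerate)
  sub <- which(cand$K20 == "me3")
  withr::with_seed(101, {
    for (i in 1:5) {
      k <- sample(2:4, 1)
      pick <- sample(sub, k)
      w <- stats::rgamma(k, 2); w <- w / sum(w)
      states <- lapply(pick, function(j) histoform:::.row_states(cand, su$schema, j))
      sp <- mixture_ms2(states, w, su$schema,
                        neutral_to_mz(mean(cand$mass), 13), 13)
      ap <- apportion(match_fragments(sp, cand, su$schema, ms_config()))
      got <- unname(ap$fractions[cand$notation[pick]])
      expect_equal(got, w, tolerance = 1e-6)
    }
  })
})
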