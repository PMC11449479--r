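theo <- theoretical_masses()
quartet <- theoretical_table()[1, ]

test_that("peaks match to the nearest theoretical mass within tolerance", {
  peaks <- data.frame(mz = c(1154.56, 1000.58, 1500.00),
                      intensity = c(10, 5, 1))
  a <- match_peaks(peaks, theo, tol_ppm = 20)
  expect_equal(a$isotopologue[1], "nn")
  expect_equal(round_half_up(a$error_da[1]), -0.01)
  expect_equal(a$fragment[2], "MurNAc(r)-Ala-iGlu-DAP->Lys-Arg")
  expect_equal(a$isotopologue[2], "oo")
  expect_lt(abs(a$error_da[2]), 0.005)
  expect_true(is.na(a$isotopologue[3]))
  expect_error(match_peaks(peaks, theo[0, ]), "empty")
})

test_that("matching is order-invariant and flags coincident masses ambiguous", {
  peaks <- data.frame(mz = c(302.21, 674.37, 1212.68), intensity = 1:3)
  a1 <- match_peaks(peaks, theo)
  a2 <- match_peaks(peaks[3:1, ], theo)
  expect_equal(a1$theoretical_mass, rev(a2$theoretical_mass))
  # Lys-Arg light exists in both the nn and on columns: ambiguous, resolved
  # deterministically
  expect_true(a1$ambiguous[1])
  expect_equal(a1$fragment[1], "Lys-Arg")
  # re-matching the same peaks gives identical assignments
  expect_identical(a1, match_peaks(peaks, theo))
})

test_that("parental masses classify into their generating label state", {
  expect_equal(classify_isotopologue(1172.59, quartet)$isotopologue, "no")
  expect_equal(classify_isotopologue(1212.69, quartet)$isotopologue, "oo")
  expect_error(classify_isotopologue(1500, quartet), "no isotopologue")
  # exact midpoint between nn (1154.57) and no (1172.59): lower mass wins,
  # flagged ambiguous (needs a window wide enough to span both)
  mid <- unname((quartet["nn"] + quartet["no"]) / 2)
  got <- classify_isotopologue(mid, quartet, tol_da = 10)
  expect_equal(got$isotopologue, "nn")
  expect_true(got$ambiguous)
})

test_that("diagnostic fragments read the moiety labels and expose conflicts", {
  mk <- function(mzs) match_peaks(data.frame(mz = mzs, intensity = 1),
                                  theo, tol_da = 0.02, tol_ppm = NULL)
  # heavy Lys-Arg + heavy DAP->Lys-Arg: old->old
  d <- diagnostic_fragments(mk(c(320.23, 501.33)))
  expect_equal(d$isotopologue, "oo")
  expect_false(d$conflict)
  # all light: new->new
  d <- diagnostic_fragments(mk(c(302.21, 474.29)))
  expect_equal(d$isotopologue, "nn")
  # 492.31 implies heavy Lys-Arg but 302.21 implies light Lys-Arg
  d <- diagnostic_fragments(mk(c(302.21, 492.31)))
  expect_true(d$conflict)
  expect_true(is.na(d$isotopologue))
})

test_that("relative abundances are intensity shares in percent", {
  expect_equal(unname(relative_abundance(c(1, 1, 1, 1))), rep(25, 4))
  expect_equal(unname(relative_abundance(c(0, 5, 0, 0))), c(0, 100, 0, 0))
  expect_equal(unname(relative_abundance(c(nn = 2, oo = 3, on = 4, no = 1))),
               c(20, 30, 40, 10))
  expect_error(relative_abundance(c(0, 0, 0, 0)), "undefined")
  # sums to 100 for arbitrary positive intensities
  set.seed(3)
  for (i in 1:20)
    expect_equal(sum(relative_abundance(runif(4, 0, 1e6))), 100)
})

test_that("moiety aggregates pair old/new to 100", {
  q <- c(nn = 25, oo = 25, on = 25, no = 25)
  expect_equal(unname(aggregate_moieties(q)), rep(50, 4))
  expect_equal(aggregate_moieties(c(nn = 0, oo = 100, on = 0, no = 0))[["old_lpp"]], 100)
  agg <- aggregate_moieties(c(nn = 10, oo = 40, on = 30, no = 20))
  expect_equal(unname(agg), c(60, 40, 70, 30))
  set.seed(4)
  for (i in 1:20) {
    a <- aggregate_moieties(relative_abundance(runif(4)))
    expect_equal(a[["old_lpp"]] + a[["new_lpp"]], 100)
    expect_equal(a[["old_stem"]] + a[["new_stem"]], 100)
  }
})
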