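lib <- residue_library()

test_that("residue library holds the seven free-molecule formulas", {
  expect_setequal(names(lib),
                  c("GlcNAc", "MurNAc", "Ala", "iGlu", "DAP", "Lys", "Arg"))
  expect_equal(round_half_up(monoisotopic_mass(lib$Arg)), 174.11)
  # condensing Lys and Arg loses one water
  kr <- comp_subtract(comp_add(lib$Lys, lib$Arg), parse_formula("H2O"))
  expect_equal(round_half_up(monoisotopic_mass(kr)), 302.21)
  expect_error(assemble_composition(
    muropeptide("Xyz", "stem", n_bonds = 0)), "unknown residue")
})

test_that("assembly subtracts one water per condensation and adds H2 on reduction", {
  kr <- muropeptide(c("Lys", "Arg"), c("lpp", "lpp"))
  comp <- assemble_composition(kr, lib)
  expect_equal(comp[c("C", "H", "N", "O")], c(C = 12L, H = 26L, N = 6L, O = 3L),
               ignore_attr = TRUE)
  # a single residue with no bonds is unchanged
  single <- muropeptide("DAP", "stem", n_bonds = 0)
  expect_equal(monoisotopic_mass(assemble_composition(single, lib)),
               monoisotopic_mass(lib$DAP))
  # full reduced parental assembly
  expect_equal(round_half_up(monoisotopic_mass(assemble_composition(tri_kr(), lib))),
               1154.57)
  # reduction adds exactly 2 H and 2.0157 Da
  unred <- tri_kr(); unred$reduced <- FALSE
  d <- comp_subtract(assemble_composition(tri_kr(), lib),
                     assemble_composition(unred, lib))
  expect_equal(d[d > 0], c(H = 2L), ignore_attr = TRUE)
  expect_equal(monoisotopic_mass(assemble_composition(tri_kr(), lib)) -
                 monoisotopic_mass(assemble_composition(unred, lib)),
               2.0157, tolerance = 1e-4)
})

test_that("assembled mass equals brute-force residue sum minus condensation water", {
  # property: random sublists of the library treated as one fused chain
  set.seed(11)
  water <- monoisotopic_mass(parse_formula("H2O"))
  for (i in 1:25) {
    n <- sample(1:7, 1)
    picks <- sample(names(lib), n, replace = TRUE)
    red <- runif(1) < 0.3
    spec <- muropeptide(picks, rep("stem", n), reduced = red)
    got <- monoisotopic_mass(assemble_composition(spec, lib))
    want <- sum(vapply(picks, function(r) monoisotopic_mass(lib[[r]]),
                       numeric(1))) - (n - 1) * water + if (red) 2.0157 else 0
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("isotopologue masses add per-moiety heavy shifts", {
  expect_equal(round_half_up(isotopologue_mass(tri_kr(), label_state("light", "light"))),
               1154.57)
  expect_equal(round_half_up(isotopologue_mass(tri_kr(), label_state("heavy", "light"))),
               1194.66)
  expect_equal(round_half_up(isotopologue_mass(tri_kr(), label_state("heavy", "heavy"))),
               1212.69)
  expect_error(isotopologue_mass(tri_kr(), c(stem = "light")), "moieties")
})

test_that("fragment ladder matches the reference series", {
  frags <- fragment_series()
  expect_length(frags, 7)
  light <- vapply(frags, function(f)
    round_half_up(monoisotopic_mass(assemble_composition(f, lib))), numeric(1))
  expect_equal(unname(light),
               c(1154.57, 951.49, 674.37, 603.33, 474.29, 302.21, 174.11))
  expect_equal(unname(light[7]), round_half_up(monoisotopic_mass(lib$Arg)))
  # consecutive losses equal the lost residue's condensed mass
  water <- monoisotopic_mass(parse_formula("H2O"))
  lost <- c("GlcNAc", "MurNAc", "Ala", "iGlu", "DAP", "Lys")
  raw <- vapply(frags, function(f)
    monoisotopic_mass(assemble_composition(f, lib)), numeric(1))
  for (i in 1:6) {
    drop <- monoisotopic_mass(lib[[lost[i]]]) - water
    # the MurNAc loss also removes the 2H of the reduced muramitol
    if (lost[i] == "MurNAc") drop <- drop + 2 * 1.0078250319
    expect_equal(unname(raw[i] - raw[i + 1]), unname(drop), tolerance = 1e-6)
  }
  expect_error(fragment_series(muropeptide(c("Lys", "Arg"), c("lpp", "lpp"))),
               "parental")
})

test_that("theoretical 7x4 grid reproduces every reference mass within 0.01 Da", {
  tab <- theoretical_table(digits = 2)
  expect_equal(dim(tab), c(7, 4))
  expect_true(all(abs(tab - ref_calc) <= 0.01 + 1e-9))
  expect_equal(tab["Ala-iGlu-DAP->Lys-Arg", "oo"], 711.43)
  # fragments without a stem moiety repeat their light mass in heavy-stem columns
  expect_equal(tab["Arg", c("nn", "no", "on", "oo")],
               c(nn = 174.11, no = 184.12, on = 174.11, oo = 184.12))
})

test_that("moiety shifts are additive across the grid", {
  tab <- theoretical_table()
  # hybrid sum identity per row
  expect_true(all(abs(tab[, "no"] + tab[, "on"] - tab[, "nn"] - tab[, "oo"])
                  < 0.02))
  # full heavy shift equals the whole-fragment shift
  frags <- fragment_series()
  for (i in seq_along(frags)) {
    comp <- Reduce(comp_add, lapply(frags[[i]]$residues,
                                    function(r) lib[[r]]))
    expect_equal(tab[i, "oo"] - tab[i, "nn"], heavy_shift(comp),
                 tolerance = 1e-9)
  }
})
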