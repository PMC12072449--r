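test_that("formula parsing reproduces stoichiometry and rejects bad input", {
  dg <- parse_formula("C10H13N5O4")
  expect_equal(unclass(dg)[c("C", "H", "N", "O")],
               c(C = 10L, H = 13L, N = 5L, O = 4L), ignore_attr = TRUE)
  expect_equal(atom_count("C20H22O9"), 51L)  # 20 + 22 + 9
  expect_error(parse_formula("C10H13X5"), "X")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C0H4"), "zero")
  expect_error(parse_formula("c10h13"), "malformed")
})

test_that("parse and format round-trip on randomized compositions", {
  set.seed(11)
  for (i in 1:50) {
    x <- random_composition()
    expect_identical(parse_formula(format_formula(x)), x)
  }
})

test_that("combine_counts sums elementwise and preserves atom counts", {
  expect_identical(combine_counts(element_counts(c(C = 1)),
                                  element_counts(c(C = 1))),
                   element_counts(c(C = 2)))
  big <- combine_counts("C25H24O12", "C10H13N5O4", "H")
  expect_identical(format_formula(big), "C35H38N5O16")
  expect_equal(atom_count(big), 94L)
  x <- parse_formula("C5H8NO2")
  expect_identical(combine_counts(list(x)), x)
  set.seed(7)
  for (i in 1:30) {
    a <- random_composition(); b <- random_composition()
    expect_equal(atom_count(combine_counts(a, b)),
                 atom_count(a) + atom_count(b))
  }
})

test_that("monoisotopic masses match reference isotope sums and are additive", {
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 0.0005 / 18)
  expect_equal(monoisotopic_mass(element_counts(c(C = 1))), 12.0)
  expect_equal(monoisotopic_mass("C10H13N5O4"), 267.097, tolerance = 0.001 / 267)
  set.seed(23)
  for (i in 1:50) {
    a <- random_composition(); b <- random_composition()
    expect_equal(monoisotopic_mass(combine_counts(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9 / 100)
  }
})

test_that("nominal mass uses integer mass numbers, not rounding", {
  expect_identical(nominal_mass("C20H22O9"), 406L)   # 240 + 22 + 144
  expect_identical(nominal_mass("C7H12O6"), 192L)    # quinic acid
  expect_identical(nominal_mass(element_counts(c(H = 1))), 1L)
  set.seed(31)
  for (i in 1:30) {
    a <- random_composition(); b <- random_composition()
    expect_identical(nominal_mass(combine_counts(a, b)),
                     nominal_mass(a) + nominal_mass(b))
  }
})

test_that("vibrational DOF is 3N - 6, defined only for N >= 3", {
  expect_identical(vibrational_dof("H2O"), 3L)
  expect_identical(vibrational_dof("C10H13N5O4"), 90L)
  expect_identical(vibrational_dof("C35H38N5O16"), 276L)
  expect_error(vibrational_dof("H2"), "N < 3")
  # strictly increasing in atom count
  set.seed(41)
  xs <- replicate(20, random_composition(), simplify = FALSE)
  ns <- vapply(xs, atom_count, integer(1))
  ds <- vapply(xs, vibrational_dof, integer(1))
  ord <- order(ns)
  expect_true(all(diff(ds[ord][!duplicated(ns[ord])]) > 0))
})

test_that("adduct construction follows each attachment species", {
  m <- parse_formula("C20H22O9")
  dep <- make_adduct(m, "proton_loss")
  expect_identical(dep$mz_nominal, 405L)
  expect_identical(dep$charge, -1L)
  expect_identical(make_adduct(m, "chloride_add")$mz_nominal, 441L)
  expect_identical(make_adduct(m, "formate_add")$mz_nominal, 451L)
  prot <- make_adduct(m, "proton_add")
  expect_identical(prot$charge, 1L)
  expect_identical(format_formula(prot$composition), "C20H23O9")

  cplx <- make_adduct("C25H24O12", "nucleoside_proton_add", "dG")
  expect_identical(format_formula(cplx$composition), "C35H38N5O16")
  expect_identical(cplx$charge, 1L)
  expect_identical(cplx$dof, 276L)

  expect_error(make_adduct(element_counts(c(C = 2, Cl = 4)), "proton_loss"),
               "hydrogen")
  expect_error(make_adduct(m, "nucleoside_proton_add"), "nucleoside")
  expect_error(make_adduct(m, "proton_add", nucleoside = "dG"), "only meaningful")
})

test_that("fixed nominal m/z offsets between adduct species hold generally", {
  set.seed(53)
  for (i in 1:30) {
    x <- random_composition()
    if (!("H" %in% names(x))) x <- combine_counts(x, "H2")
    mh_pos <- make_adduct(x, "proton_add")$mz_nominal
    mh_neg <- make_adduct(x, "proton_loss")$mz_nominal
    expect_identical(mh_pos - mh_neg, 2L)
    expect_identical(make_adduct(x, "chloride_add")$mz_nominal - mh_neg, 36L)
    expect_identical(make_adduct(x, "formate_add")$mz_nominal - mh_neg, 46L)
  }
})

test_that("built-in nucleosides are dG and G with one oxygen difference", {
  dg <- nucleoside_formula("dG"); g <- nucleoside_formula("G")
  expect_identical(format_formula(dg), "C10H13N5O4")
  expect_identical(format_formula(g), "C10H13N5O5")
  expect_identical(atom_count(g) - atom_count(dg), 1L)
})

test_that("panels read from CSV with validated formulas and RT windows", {
  p <- file.path(tempdir(), "panel.csv")
  writeLines(c("name,formula,rt_min,rt_max,class",
               "cmpd2,C20H22O9,5.3,5.8,kawain",
               "quinic,C7H12O6,1.0,1.5,acid"), p)
  panel <- read_panel(p)
  expect_equal(nrow(panel), 2L)
  expect_identical(panel$formula[1], "C20H22O9")

  writeLines(c("name,formula,rt_min,rt_max",
               "bad,C10X5,1,2"), p)
  expect_error(read_panel(p), "row 1")
  writeLines(c("name,rt_min,rt_max", "x,1,2"), p)
  expect_error(read_panel(p), "formula")
})
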