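test_that("noise-free apex ratios equal adduct_fraction times survival", {
  fx <- one_compound_sim(seed = 1, noise_cv = 0)
  cp <- fx$cmp[[1]]
  b <- cp$binding$dG
  cplx <- make_adduct(cp$formula, "nucleoside_proton_add", "dG")
  free <- make_adduct(cp$formula, "proton_add")
  for (v in c(10, 30)) {
    run <- fx$sim$runs[[as.character(v)]]
    # scan nearest the elution apex (the grid need not hit rt_center exactly)
    t_apex <- run$scan_time_min[which.min(abs(run$scan_time_min - cp$rt_center))]
    apex <- run[abs(run$scan_time_min - t_apex) < 1e-9, ]
    i_free <- apex$intensity[abs(apex$mz - free$mz_mono) < 1e-6]
    i_add <- apex$intensity[abs(apex$mz - cplx$mz_mono) < 1e-6]
    e <- ecom(v, cplx$mz_mono, 28, 1)
    expect_equal(i_add / i_free,
                 b$adduct_fraction / (1 + exp(b$slope_true * (e - b$e50_true))),
                 tolerance = 1e-12)
  }
})

test_that("the same seed reproduces a run set exactly", {
  cmp <- reference_panel()
  cfg <- sim_config(seed = 99)
  s1 <- simulate_run_set(cmp, cfg)
  s2 <- simulate_run_set(cmp, cfg)
  expect_identical(s1$runs, s2$runs)
  expect_identical(s1$truth$expected, s2$truth$expected)
  s3 <- simulate_run_set(cmp, sim_config(seed = 100))
  expect_false(identical(s1$runs, s3$runs))
})

test_that("adduct peaks exist only inside the infusion window", {
  fx <- one_compound_sim(seed = 2, noise_cv = 0)
  cplx <- make_adduct(fx$cmp[[1]]$formula, "nucleoside_proton_add", "dG")
  for (run in fx$sim$runs) {
    tt <- run$scan_time_min[abs(run$mz - cplx$mz_mono) < 1e-6]
    expect_true(all(tt >= 4.5 & tt <= 6.5))
  }
  # free ion covers the whole simulated RT range
  free <- make_adduct(fx$cmp[[1]]$formula, "proton_add")
  tt_free <- fx$sim$runs[["10"]]$scan_time_min[
    abs(fx$sim$runs[["10"]]$mz - free$mz_mono) < 1e-6]
  expect_true(min(tt_free) < 4.5 && max(tt_free) > 6.5)
})

test_that("simulator rejects ions outside the acquired m/z range", {
  cmp <- reference_panel()[5]  # rutin: dG adduct near m/z 879
  cfg <- sim_config(noise_cv = 0, mz_range = c(100, 700))
  expect_error(simulate_run_set(cmp, cfg), "outside simulated m/z range")
  expect_error(sim_config(noise_cv = 0.05), "seed")
  expect_error(sim_config(noise_cv = -1), "noise_cv")
})

test_that("multiplicative noise is calibrated to the requested CV", {
  cmp <- list(sim_compound("probe", "C20H22O9", rt_center = 5.5,
                           rt_sigma = 0.2, base_intensity = 1e5,
                           binding = list(dG = list(adduct_fraction = 0.5,
                                                    e50_true = 0.7,
                                                    slope_true = 6))))
  free_mz <- make_adduct("C20H22O9", "proton_add")$mz_mono
  vals <- vapply(1:200, function(s) {
    cfg <- sim_config(cone_voltages = 10, scan_interval = 0.5,
                      rt_range = c(5, 6), noise_cv = 0.05, seed = s)
    run <- simulate_run_set(cmp, cfg)$runs[["10"]]
    run$intensity[abs(run$mz - free_mz) < 1e-6 &
                    abs(run$scan_time_min - 5.5) < 1e-9]
  }, numeric(1))
  cv_emp <- stats::sd(vals) / mean(vals)
  expect_gt(cv_emp, 0.05 * 0.8)
  expect_lt(cv_emp, 0.05 * 1.2)
})

test_that("ground truth alone predicts every analyzed ratio", {
  cmp <- reference_panel()
  cfg <- sim_config(noise_cv = 0)
  sim <- simulate_run_set(cmp, cfg)
  pars <- sim$truth$params
  recomputed <- do.call(rbind, lapply(seq_len(nrow(pars)), function(i) {
    cplx <- make_adduct(parse_formula(pars$formula[i]),
                        "nucleoside_proton_add", pars$nucleoside[i])
    d <- delta_factor(cplx$dof, sim$truth$reference_dof)
    e <- ecom(cfg$cone_voltages, cplx$mz_mono, cfg$gas_mass, d)
    data.frame(compound = pars$compound[i], cone_voltage_V = cfg$cone_voltages,
               expected = pars$adduct_fraction[i] /
                 (1 + exp(pars$slope_true[i] * (e - pars$e50_true[i]))))
  }))
  merged <- merge(recomputed, sim$truth$expected,
                  by = c("compound", "cone_voltage_V"))
  expect_equal(merged$expected, merged$expected_ratio, tolerance = 1e-12)
})

test_that("the reference panel encodes the documented stability ordering", {
  cmp <- reference_panel()
  expect_length(cmp, 5L)
  nm <- vapply(cmp, `[[`, character(1), "name")
  e50 <- vapply(cmp, function(x) x$binding$dG$e50_true, numeric(1))
  af <- vapply(cmp, function(x) x$binding$dG$adduct_fraction, numeric(1))
  phen <- 1:3; iso <- which(nm == "isoquercitrin"); rut <- which(nm == "rutin")
  expect_true(all(e50[phen] > e50[rut]) && e50[rut] > e50[iso])
  expect_true(all(af[phen] > af[rut]) && af[rut] > af[iso])
  # all five elute inside the infusion window
  rtc <- vapply(cmp, `[[`, numeric(1), "rt_center")
  expect_true(all(rtc > 4.5 & rtc < 6.5))
})

test_that("run sets persist to CSV plus a ground-truth sidecar", {
  fx <- one_compound_sim(seed = 5)
  dir <- file.path(tempdir(), "simset")
  paths <- write_run_set(fx$sim, dir)
  csvs <- grep("run_.*V\\.csv$", paths, value = TRUE)
  expect_length(csvs, 5L)
  back <- read_run(csvs[1])
  v <- sub(".*run_([0-9.]+)V\\.csv$", "\\1", csvs[1])
  orig <- fx$sim$runs[[v]]
  expect_equal(as.data.frame(back), as.data.frame(orig), tolerance = 1e-9,
               ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed, 5)
  expect_equal(gt$reference_dof, fx$sim$truth$reference_dof)
  expect_equal(gt$params$e50_true, fx$sim$truth$params$e50_true)
})
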