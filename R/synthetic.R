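# Synthetic post-column-addition LC-MS runs with known ground truth.
#
# Emulates the experiment desk-scale: Gaussian elution of each compound's
# [M+H]+, nucleoside infusion over a fixed window during which the
# proton-bound adduct [M+Nuc+H]+ appears with intensity
#   I_adduct = I_free * adduct_fraction * S(E_com_delta),
#   S(E) = 1 / (1 + exp(slope_true * (E - e50_true))),
# and multiplicative lognormal intensity noise with a given CV. The logistic
# survival shape is the standard energy-resolved breakdown form and makes the
# e50 summary well-posed; it is the simulator's stand-in for in-source CID.

#' Define a simulated compound
#'
#' @param name Compound name.
#' @param formula Neutral molecular formula (string or [element_counts]).
#' @param rt_center,rt_sigma Gaussian elution profile, minutes (`rt_sigma > 0`).
#' @param base_intensity Apex intensity of \[M+H\]+ in counts (> 0).
#' @param binding Named list per nucleoside (`dG`, `G`), each a list with
#'   `adduct_fraction` (ratio at zero collision energy, in (0,1)), `e50_true`
#'   (eV) and `slope_true` (1/eV).
#' @return A `sim_compound` list.
#' @export
sim_compound <- function(name, formula, rt_center, rt_sigma,
                         base_intensity, binding) {
  formula <- as_element_counts(formula)
  if (rt_sigma <= 0) stop("rt_sigma must be > 0")
  if (base_intensity <= 0) stop("base_intensity must be > 0")
  for (nuc in names(binding)) {
    b <- binding[[nuc]]
    if (!all(c("adduct_fraction", "e50_true", "slope_true") %in% names(b))) {
      stop("binding[['", nuc, "']] needs adduct_fraction, e50_true, slope_true")
    }
    if (b$adduct_fraction <= 0 || b$adduct_fraction >= 1) {
      stop("adduct_fraction must lie in (0, 1)")
    }
    if (b$e50_true <= 0 || b$slope_true <= 0) {
      stop("e50_true and slope_true must be > 0")
    }
  }
  structure(list(name = name, formula = formula, rt_center = rt_center,
                 rt_sigma = rt_sigma, base_intensity = base_intensity,
                 binding = binding),
            class = "sim_compound")
}

#' Simulation configuration
#'
#' Defaults mirror the acquisition design of the screening experiment:
#' cone-voltage ramp 10-30 V, nucleoside infusion over 4.5-6.5 min, analytes
#' eluting at 5-6 min, m/z range 100-1000, and run-to-run multiplicative
#' intensity variation of at most 5% (CV 0.05).
#'
#' @param cone_voltages Cone voltages in V.
#' @param scan_interval Scan spacing in minutes (default 0.02, ~1.2 s).
#' @param rt_range Simulated retention-time range, minutes.
#' @param infusion_window Nucleoside infusion window, minutes.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise (default 0.05); 0 disables noise.
#' @param seed Integer RNG seed; mandatory when `noise_cv > 0`.
#' @param nucleoside `"dG"` or `"G"`: which nucleoside this run set infuses.
#' @param gas_mass Collision-gas mass in amu (N2 = 28).
#' @param mz_range Acquired m/z range; adduct ions outside it are an error.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cone_voltages = c(10, 15, 20, 25, 30),
                       scan_interval = 0.02,
                       rt_range = c(4, 7),
                       infusion_window = c(4.5, 6.5),
                       noise_cv = 0.05,
                       seed = NULL,
                       nucleoside = c("dG", "G"),
                       gas_mass = 28,
                       mz_range = c(100, 1000)) {
  nucleoside <- match.arg(nucleoside)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (noise_cv > 0 && is.null(seed)) {
    stop("a seed is mandatory when noise_cv > 0")
  }
  if (scan_interval <= 0) stop("scan_interval must be > 0")
  if (rt_range[1] >= rt_range[2]) stop("invalid rt_range")
  structure(list(cone_voltages = sort(cone_voltages),
                 scan_interval = scan_interval, rt_range = rt_range,
                 infusion_window = infusion_window, noise_cv = noise_cv,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 nucleoside = nucleoside, gas_mass = gas_mass,
                 mz_range = mz_range),
            class = "sim_config")
}

# Logistic survival of the adduct at center-of-mass energy e.
survival_fun <- function(e, e50, slope) 1 / (1 + exp(slope * (e - e50)))

#' Simulate a post-column-addition run set
#'
#' Generates one run per cone voltage plus a ground-truth record sufficient
#' to compute every expected ratio without rerunning the simulator. The
#' reference DOF is auto-selected as the minimum adduct DOF over the
#' compound set, matching the analysis convention. Deterministic for a fixed
#' seed.
#'
#' @param compounds List of [sim_compound] objects.
#' @param cfg A [sim_config].
#' @return List with `runs` (named list cone voltage -> `ms_run`), `truth`
#'   (list: `params` tibble, `expected` per-voltage ratio tibble,
#'   `reference_dof`, `nucleoside`, `seed`, `noise_cv`).
#' @export
simulate_run_set <- function(compounds, cfg) {
  stopifnot(inherits(cfg, "sim_config"), length(compounds) >= 1L)
  if (inherits(compounds, "sim_compound")) compounds <- list(compounds)
  rtc <- vapply(compounds, `[[`, numeric(1), "rt_center")
  if (any(rtc < cfg$rt_range[1] | rtc > cfg$rt_range[2])) {
    stop("compound rt_center outside rt_range")
  }
  nuc <- nucleoside_formula(cfg$nucleoside)
  ions <- lapply(compounds, function(cp) {
    free <- make_adduct(cp$formula, "proton_add")
    cplx <- make_adduct(cp$formula, "nucleoside_proton_add", nucleoside = nuc)
    for (ion in list(free, cplx)) {
      if (ion$mz_mono < cfg$mz_range[1] || ion$mz_mono > cfg$mz_range[2]) {
        stop("ion m/z ", round(ion$mz_mono, 2), " of ", cp$name,
             " outside simulated m/z range ",
             cfg$mz_range[1], "-", cfg$mz_range[2])
      }
      if (is.null(cp$binding[[cfg$nucleoside]])) {
        stop("compound ", cp$name, " has no binding parameters for ",
             cfg$nucleoside)
      }
    }
    list(free = free, cplx = cplx)
  })
  reference_dof <- min(vapply(ions, function(x) x$cplx$dof, integer(1)))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  noise <- function(n) {
    if (cfg$noise_cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    # meanlog = -sdlog^2/2 gives mean 1, CV = noise_cv
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  times <- seq(cfg$rt_range[1], cfg$rt_range[2], by = cfg$scan_interval)
  infused <- times >= cfg$infusion_window[1] & times <= cfg$infusion_window[2]

  expected <- list(); runs <- list()
  for (v in cfg$cone_voltages) {
    rows <- list()
    for (k in seq_along(compounds)) {
      cp <- compounds[[k]]
      b <- cp$binding[[cfg$nucleoside]]
      d <- delta_factor(ions[[k]]$cplx$dof, reference_dof)
      e <- ecom(v, ions[[k]]$cplx$mz_mono, cfg$gas_mass, d)
      s <- survival_fun(e, b$e50_true, b$slope_true)
      free_i <- cp$base_intensity *
        exp(-0.5 * ((times - cp$rt_center) / cp$rt_sigma)^2)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_time_min = times, cone_voltage_V = v, polarity = "+",
        mz = ions[[k]]$free$mz_mono,
        intensity = free_i * noise(length(times)))
      rows[[length(rows) + 1L]] <- data.frame(
        scan_time_min = times[infused], cone_voltage_V = v, polarity = "+",
        mz = ions[[k]]$cplx$mz_mono,
        intensity = free_i[infused] * b$adduct_fraction * s *
          noise(sum(infused)))
      expected[[length(expected) + 1L]] <- tibble::tibble(
        compound = cp$name, nucleoside = cfg$nucleoside, cone_voltage_V = v,
        delta = d, e_com_eV = e, expected_ratio = b$adduct_fraction * s)
    }
    runs[[as.character(v)]] <- ms_run(
      do.call(rbind, rows),
      metadata = list(cone_voltage_V = v, nucleoside = cfg$nucleoside,
                      simulated = TRUE))
  }
  params <- dplyr::bind_rows(lapply(compounds, function(cp) {
    b <- cp$binding[[cfg$nucleoside]]
    tibble::tibble(compound = cp$name, formula = format_formula(cp$formula),
                   nucleoside = cfg$nucleoside,
                   rt_center = cp$rt_center, rt_sigma = cp$rt_sigma,
                   base_intensity = cp$base_intensity,
                   adduct_fraction = b$adduct_fraction,
                   e50_true = b$e50_true, slope_true = b$slope_true)
  }))
  list(runs = runs,
       truth = list(params = params,
                    expected = dplyr::bind_rows(expected),
                    reference_dof = reference_dof,
                    nucleoside = cfg$nucleoside,
                    seed = cfg$seed, noise_cv = cfg$noise_cv))
}

#' Five-compound phenolic reference panel
#'
#' The built-in screening panel: three phenolics of *Achyrocline
#' satureioides* (a flavonol glycoside, a dehydrokawain glycoside, and a
#' dicaffeoylquinic acid) plus two flavonol glycoside standards, with
#' ground-truth binding strengths ordered so that the three plant phenolics
#' form more stable nucleoside adducts than either standard, and rutin more
#' stable than isoquercitrin. All compounds elute in the 5-6 min window.
#'
#' Ground-truth e50 values sit inside the center-of-mass energy range swept
#' by the 10-30 V cone-voltage ramp; survival slopes are steeper for the
#' strong binders, so their ratio curves both start higher and fall faster,
#' without ever crossing below the standards' curves.
#'
#' @return List of five [sim_compound] objects.
#' @export
reference_panel <- function() {
  bind <- function(af, e50, slope) {
    list(dG = list(adduct_fraction = af, e50_true = e50, slope_true = slope),
         G  = list(adduct_fraction = af, e50_true = e50, slope_true = slope))
  }
  list(
    sim_compound("3-O-methylquercetin-7-O-glucoside", "C22H22O12",
                 rt_center = 5.35, rt_sigma = 0.08, base_intensity = 4e5,
                 binding = bind(0.55, 0.80, 8)),
    sim_compound("4'-hydroxydehydrokawain-4'-O-glucoside", "C20H22O9",
                 rt_center = 5.55, rt_sigma = 0.08, base_intensity = 5e5,
                 binding = bind(0.50, 0.75, 8)),
    sim_compound("3,5-di-O-caffeoylquinic acid", "C25H24O12",
                 rt_center = 5.45, rt_sigma = 0.10, base_intensity = 6e5,
                 binding = bind(0.50, 0.85, 8)),
    sim_compound("isoquercitrin", "C21H20O12",
                 rt_center = 5.70, rt_sigma = 0.08, base_intensity = 5e5,
                 binding = bind(0.20, 0.45, 4)),
    sim_compound("rutin", "C27H30O16",
                 rt_center = 5.85, rt_sigma = 0.08, base_intensity = 4e5,
                 binding = bind(0.30, 0.55, 4))
  )
}

#' Panel tibble for a list of simulated compounds
#'
#' Derives the analysis panel (name, formula, RT window) from simulated
#' compounds; the window is rt_center +/- `k_sigma` rt_sigma clipped to the
#' infusion window so adduct and free ion are integrated over the same scans.
#'
#' @param compounds List of [sim_compound]s.
#' @param cfg A [sim_config] (for the infusion window).
#' @param k_sigma Half-width of the RT window in units of rt_sigma.
#' @return Panel tibble compatible with [build_curve()].
#' @export
sim_panel <- function(compounds, cfg, k_sigma = 3) {
  dplyr::bind_rows(lapply(compounds, function(cp) {
    tibble::tibble(name = cp$name, formula = format_formula(cp$formula),
                   rt_min = max(cp$rt_center - k_sigma * cp$rt_sigma,
                                cfg$infusion_window[1]),
                   rt_max = min(cp$rt_center + k_sigma * cp$rt_sigma,
                                cfg$infusion_window[2]),
                   class = NA_character_)
  }))
}

#' Write a simulated run set to disk
#'
#' One tabular CSV per cone voltage (`run_<V>V.csv`) plus a
#' `ground_truth.json` sidecar with the generator parameters, expected
#' ratios, reference DOF and seed.
#'
#' @param sim Result of [simulate_run_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_run_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in names(sim$runs)) {
    p <- file.path(dir, paste0("run_", v, "V.csv"))
    write_run(sim$runs[[v]], p)
    paths <- c(paths, p)
  }
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$truth, gt, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, gt))
}
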