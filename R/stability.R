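# Adduct survival curves and compound ranking.
#
# The screening statistic is the abundance ratio [M+dG/G+H]+ / [M+H]+ per
# cone voltage. Plotted against the DOF-corrected center-of-mass energy it
# traces the gas-phase survival of the non-covalent complex; compounds whose
# curves sit higher / decay later bind the nucleoside more strongly, a proxy
# for G-quadruplex affinity.

#' Adduct survival ratio
#'
#' @param i_adduct Abundance of the proton-bound nucleoside adduct
#'   (\[M+Nuc+H\]+), >= 0.
#' @param i_free Abundance of the free protonated molecule (\[M+H\]+), > 0.
#' @return `i_adduct / i_free`. A zero free-ion abundance is an explicit
#'   error (`undefined_ratio` condition), never a silent `Inf`.
#' @export
survival_ratio <- function(i_adduct, i_free) {
  if (any(i_adduct < 0)) stop("adduct abundance must be >= 0")
  if (any(i_free <= 0)) {
    stop(structure(class = c("undefined_ratio", "error", "condition"),
                   list(message = "survival ratio undefined: free-ion abundance is zero",
                        call = sys.call())))
  }
  i_adduct / i_free
}

#' Build a stability curve for one compound and nucleoside
#'
#' For each configured cone voltage, integrates the extracted-ion
#' chromatograms of \[M+H\]+ and \[M+Nuc+H\]+ over the compound's
#' retention-time window, forms the survival ratio, and pairs it with the
#' DOF-corrected center-of-mass energy of the adduct.
#'
#' @param run_set Named list mapping cone voltage (as character, e.g. `"10"`)
#'   to an `ms_run`.
#' @param compound Compound name, present in `panel`.
#' @param nucleoside `"dG"` or `"G"` (or a custom composition).
#' @param settings A [collision_settings]; if `reference_dof` is `NULL` it is
#'   auto-selected as the minimum adduct DOF over the panel (logged via
#'   message).
#' @param panel Panel tibble as from [read_panel()].
#' @param tol m/z tolerance in Da (default 0.5).
#' @param mode `"area"` (integrated XIC, default) or `"apex"` (peak height).
#' @return A `stability_curve`: list with `compound`, `nucleoside`, `points`
#'   (tibble `e_lab_V`, `delta`, `e_com_eV`, `ratio`), `dropped` (voltages
#'   with undefined ratio), `fit` (`NULL` until [fit_sigmoid()]).
#' @export
build_curve <- function(run_set, compound, nucleoside, settings, panel,
                        tol = 0.5, mode = c("area", "apex")) {
  mode <- match.arg(mode)
  stopifnot(inherits(settings, "collision_settings"))
  row <- panel[panel$name == compound, ]
  if (nrow(row) != 1L) stop("compound not found in panel: ", compound)
  nuc_name <- if (is.character(nucleoside) && length(nucleoside) == 1L &&
                  nucleoside %in% c("dG", "G")) nucleoside else "custom"
  ligand <- parse_formula(row$formula)
  free <- make_adduct(ligand, "proton_add")
  complexed <- make_adduct(ligand, "nucleoside_proton_add",
                           nucleoside = nucleoside)

  missing_v <- setdiff(as.character(settings$cone_voltages), names(run_set))
  if (length(missing_v) > 0L) {
    stop("run_set is missing cone voltage(s): ",
         paste(missing_v, collapse = ", "))
  }
  if (is.null(settings$reference_dof)) {
    adducts <- lapply(panel$formula, function(f)
      make_adduct(parse_formula(f), "nucleoside_proton_add",
                  nucleoside = nucleoside))
    settings$reference_dof <- select_reference_dof(adducts)
    message("reference DOF auto-selected: ", settings$reference_dof,
            " (minimum adduct DOF over panel)")
  }
  d <- delta_factor(complexed$dof, settings$reference_dof)
  measure <- function(run, mz) {
    ch <- xic(run, mz, tol)
    if (mode == "area") integrate_window(ch, row$rt_min, row$rt_max)
    else apex_intensity(ch, row$rt_min, row$rt_max)
  }
  pts <- lapply(settings$cone_voltages, function(v) {
    run <- run_set[[as.character(v)]]
    i_free <- measure(run, free$mz_mono)
    i_add <- measure(run, complexed$mz_mono)
    r <- if (i_free <= 0) NA_real_ else i_add / i_free
    tibble::tibble(e_lab_V = v, delta = d,
                   e_com_eV = ecom(v, complexed$mz_mono, settings$gas_mass, d),
                   ratio = r)
  })
  pts <- dplyr::bind_rows(pts)
  dropped <- pts$e_lab_V[is.na(pts$ratio)]
  if (length(dropped) > 0L) {
    warning("compound ", compound, ": undefined ratio at cone voltage(s) ",
            paste(dropped, collapse = ", "), "; point(s) dropped")
    pts <- pts[!is.na(pts$ratio), ]
  }
  if (nrow(pts) < 2L) {
    stop("fewer than 2 defined ratio points for compound ", compound)
  }
  structure(list(compound = compound, nucleoside = nuc_name,
                 adduct = complexed, points = pts,
                 dropped = dropped, fit = NULL),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> %s + %s: %d points, e_com %.3f-%.3f eV\n",
              x$compound, x$nucleoside, nrow(x$points),
              min(x$points$e_com_eV), max(x$points$e_com_eV)))
  if (!is.null(x$fit) && isTRUE(x$fit$converged)) {
    cat(sprintf("  sigmoid fit: r0 = %.3g, e50 = %.3g eV, slope = %.3g /eV\n",
                x$fit$r0, x$fit$e50, x$fit$slope))
  }
  invisible(x)
}

#' Fit a three-parameter logistic to a stability curve
#'
#' Model: `ratio(E) = r0 / (1 + exp(slope * (E - e50)))` with free low-energy
#' plateau `r0`, midpoint `e50` (eV) and steepness `slope` (1/eV). The e50
#' summarizes curve position on the energy axis and makes ranking
#' reproducible. The initializer is fixed (r0 = max ratio, e50 = median
#' e_com, slope = 4 / range(e_com)), so fits are deterministic.
#'
#' @param curve A `stability_curve` with >= 4 defined points.
#' @return A `sigmoid_fit` list: `r0`, `e50`, `slope`, `rss`, `converged`,
#'   `reason`. Non-convergence and degenerate (flat) curves are flagged, not
#'   thrown.
#' @export
fit_sigmoid <- function(curve) {
  stopifnot(inherits(curve, "stability_curve"))
  pts <- curve$points
  if (nrow(pts) < 4L) stop("sigmoid fit needs >= 4 points, got ", nrow(pts))
  flagged <- function(reason) {
    structure(list(r0 = NA_real_, e50 = NA_real_, slope = NA_real_,
                   rss = NA_real_, converged = FALSE, reason = reason),
              class = "sigmoid_fit")
  }
  if (stats::sd(pts$ratio) < 1e-12 * max(abs(pts$ratio), 1e-300)) {
    return(flagged("degenerate: flat curve"))
  }
  e_range <- diff(range(pts$e_com_eV))
  start <- list(r0 = max(pts$ratio), e50 = stats::median(pts$e_com_eV),
                slope = 4 / e_range)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ r0 / (1 + exp(slope * (e_com_eV - e50))),
      data = pts, start = start,
      lower = c(r0 = 1e-12, e50 = 1e-9, slope = 1e-9),
      upper = c(r0 = Inf, e50 = Inf, slope = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged("non-convergence"))
  co <- stats::coef(fit)
  structure(list(r0 = unname(co["r0"]), e50 = unname(co["e50"]),
                 slope = unname(co["slope"]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = TRUE, reason = NA_character_),
            class = "sigmoid_fit")
}

#' Rank compounds by adduct stability
#'
#' Curves must share one nucleoside: dG and G panels are never ranked against
#' each other (the two nucleoside experiments are run under different solvent
#' conditions and are not comparable).
#'
#' Modes: `pointwise` scores each compound by its mean survival ratio on a
#' common center-of-mass energy grid (linear interpolation over the shared
#' support, no extrapolation); `e50` scores by the fitted sigmoid midpoint.
#' Higher score = more stable adduct. Ties break lexicographically by
#' compound name.
#'
#' @param curves List of `stability_curve` objects.
#' @param mode `"pointwise"` (default) or `"e50"`.
#' @param grid_n Number of grid points for pointwise mode.
#' @return Tibble `compound`, `nucleoside`, `score`, `rank` (1 = most stable).
#' @export
rank_compounds <- function(curves, mode = c("pointwise", "e50"),
                           grid_n = 25L) {
  mode <- match.arg(mode)
  if (inherits(curves, "stability_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "stability_curve")))
  nucs <- unique(vapply(curves, `[[`, character(1), "nucleoside"))
  if (length(nucs) > 1L) {
    stop("curves mix nucleosides (", paste(nucs, collapse = ", "),
         "); dG and G panels are ranked separately")
  }
  names_ <- vapply(curves, `[[`, character(1), "compound")
  if (mode == "pointwise") {
    lo <- max(vapply(curves, function(cv) min(cv$points$e_com_eV), numeric(1)))
    hi <- min(vapply(curves, function(cv) max(cv$points$e_com_eV), numeric(1)))
    if (length(curves) > 1L && lo >= hi) {
      stop("no overlapping e_com support across curves; use mode = 'e50'")
    }
    grid <- if (length(curves) == 1L) curves[[1]]$points$e_com_eV
            else seq(lo, hi, length.out = grid_n)
    scores <- vapply(curves, function(cv) {
      mean(stats::approx(cv$points$e_com_eV, cv$points$ratio,
                         xout = grid, rule = 1)$y)
    }, numeric(1))
  } else {
    scores <- vapply(curves, function(cv) {
      f <- if (!is.null(cv$fit) && isTRUE(cv$fit$converged)) cv$fit
           else fit_sigmoid(cv)
      if (!isTRUE(f$converged)) {
        stop("sigmoid fit failed for ", cv$compound, " (", f$reason,
             "); cannot rank in e50 mode")
      }
      f$e50
    }, numeric(1))
  }
  ord <- order(-scores, names_)
  tibble::tibble(compound = names_[ord], nucleoside = nucs,
                 score = scores[ord], rank = seq_along(ord))
}

#' Curve points of one or more stability curves as a tidy table
#'
#' @param curves A `stability_curve` or list of them.
#' @return Tibble `compound`, `nucleoside`, `e_lab_V`, `delta`, `e_com_eV`,
#'   `ratio` (the CSV export layout).
#' @export
curve_table <- function(curves) {
  if (inherits(curves, "stability_curve")) curves <- list(curves)
  dplyr::bind_rows(lapply(curves, function(cv) {
    dplyr::bind_cols(tibble::tibble(compound = cv$compound,
                                    nucleoside = cv$nucleoside),
                     cv$points)
  }))
}

#' Plot stability curves
#'
#' Survival ratio vs center-of-mass energy, one series per compound, faceted
#' by nucleoside if mixed.
#'
#' @param curves A `stability_curve` or list of them.
#' @return A ggplot object.
#' @export
plot_curves <- function(curves) {
  df <- curve_table(curves)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$e_com_eV, y = .data$ratio,
                                        colour = .data$compound)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(E[com*delta] ~ "(eV)"),
                  y = "[M+Nuc+H]+ / [M+H]+",
                  colour = "compound") +
    ggplot2::theme_minimal()
  if (length(unique(df$nucleoside)) > 1L) {
    p <- p + ggplot2::facet_wrap(~nucleoside)
  }
  p
}
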