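# Molecular-formula algebra: element counts, monoisotopic and nominal masses,
# adduct ions. All downstream m/z bookkeeping rests on these primitives.

# Most-abundant-isotope exact masses (Da) and integer mass numbers.
# Electron mass is ignored throughout: at +/-0.00055 Da per charge it is far
# below the unit-resolution use case of a single-quadrupole instrument.
.isotopes <- data.frame(
  symbol = c("C", "H", "N", "O", "S", "P", "Cl", "Na", "K",
             "F", "Br", "I", "Si"),
  mass = c(12.0, 1.0078250319, 14.0030740052, 15.9949146221,
           31.97207069, 30.97376151, 34.96885271, 22.98976928,
           38.96370690, 18.99840322, 78.91833760, 126.90447300,
           27.97692653),
  mass_number = c(12L, 1L, 14L, 16L, 32L, 31L, 35L, 23L, 39L,
                  19L, 79L, 127L, 14L + 14L),
  stringsAsFactors = FALSE
)

.hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  c(intersect(c("C", "H"), symbols), rest)
}

#' Construct an element-count composition
#'
#' An `element_counts` object is a named integer vector mapping element
#' symbols to strictly positive atom counts. It is the algebra underlying all
#' mass and degrees-of-freedom computations in the package.
#'
#' @param counts Named numeric/integer vector of atom counts (all >= 1), or a
#'   named list. Zero counts are rejected; they should simply be absent.
#' @return An `element_counts` object (named integer vector, Hill order).
#' @examples
#' element_counts(c(C = 10, H = 13, N = 5, O = 4))
#' @export
element_counts <- function(counts) {
  nm <- names(counts)
  counts <- unlist(counts, use.names = FALSE)
  if (length(counts) == 0L || is.null(nm) || any(nm == "")) {
    stop("element_counts requires a non-empty named vector of counts")
  }
  bad <- setdiff(nm, .isotopes$symbol)
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (any(is.na(counts)) || any(counts %% 1 != 0)) {
    stop("counts must be integers, got: ", paste(counts, collapse = ", "))
  }
  counts <- as.integer(counts)
  if (anyDuplicated(nm)) {
    counts <- vapply(split(counts, nm), sum, integer(1))
    nm <- names(counts)
  } else {
    names(counts) <- nm
  }
  if (any(counts < 0L)) stop("negative element counts are not representable")
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) stop("composition must contain at least one atom")
  counts <- counts[.hill_order(names(counts))]
  structure(counts, class = "element_counts")
}

#' Parse a Hill-notation molecular formula
#'
#' Accepts plain element-symbol/count strings such as `"C10H13N5O4"`. No
#' parentheses, isotope labels or charge signs.
#'
#' @param text Formula string.
#' @return An [element_counts] object.
#' @examples
#' parse_formula("C20H22O9")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || nchar(trimws(text)) == 0L) {
    stop("formula must be a single non-empty string")
  }
  text <- trimws(text)
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    stop("malformed formula: ", text)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("zero or invalid count in formula: ", text)
  }
  bad <- setdiff(syms, .isotopes$symbol)
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), " in ", text)
  }
  names(counts) <- syms
  element_counts(counts)
}

#' Format a composition as a Hill-notation string
#'
#' @param counts An [element_counts] object.
#' @return Formula string; `parse_formula(format_formula(x))` is the identity.
#' @export
format_formula <- function(counts) {
  counts <- as_element_counts(counts)
  paste0(names(counts), ifelse(unclass(counts) == 1L, "", unclass(counts)),
         collapse = "")
}

as_element_counts <- function(x) {
  if (inherits(x, "element_counts")) return(x)
  if (is.character(x)) return(parse_formula(x))
  element_counts(x)
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<element_counts> ", format_formula(x), " (", atom_count(x), " atoms)\n",
      sep = "")
  invisible(x)
}

#' Total atom count of a composition
#' @param counts An [element_counts] object or formula string.
#' @return Integer N, the total number of atoms.
#' @export
atom_count <- function(counts) {
  sum(unclass(as_element_counts(counts)))
}

#' Combine compositions elementwise
#'
#' Elementwise sum of any number of compositions, e.g. ligand + nucleoside +
#' proton when assembling a proton-bound adduct.
#'
#' @param ... [element_counts] objects, formula strings, or a single list of
#'   them.
#' @return The combined [element_counts].
#' @examples
#' combine_counts("C25H24O12", "C10H13N5O4", "H")
#' @export
combine_counts <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "element_counts")) {
    parts <- parts[[1]]
  }
  if (length(parts) == 0L) stop("combine_counts needs at least one composition")
  parts <- lapply(parts, as_element_counts)
  all_syms <- unique(unlist(lapply(parts, names)))
  total <- setNames(integer(length(all_syms)), all_syms)
  for (p in parts) total[names(p)] <- total[names(p)] + unclass(p)
  element_counts(total)
}

# Elementwise subtraction; errors if any count would go negative.
subtract_counts <- function(a, b) {
  a <- as_element_counts(a)
  b <- as_element_counts(b)
  all_syms <- union(names(a), names(b))
  av <- setNames(integer(length(all_syms)), all_syms)
  bv <- av
  av[names(a)] <- unclass(a)
  bv[names(b)] <- unclass(b)
  if (any(av - bv < 0L)) {
    stop("cannot remove ", format_formula(b), " from ", format_formula(a))
  }
  element_counts(av - bv)
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the exact mass of the most abundant
#' isotope. Additive under [combine_counts()].
#'
#' @param counts An [element_counts] object or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C10H13N5O4")  # 2'-deoxyguanosine, ~267.097 Da
#' @export
monoisotopic_mass <- function(counts) {
  counts <- as_element_counts(counts)
  masses <- .isotopes$mass[match(names(counts), .isotopes$symbol)]
  sum(unclass(counts) * masses)
}

#' Nominal (integer) mass of a composition
#'
#' Sum of count times the integer mass number of the most abundant isotope
#' (C = 12, H = 1, N = 14, O = 16, Cl = 35, ...). Computed from integer mass
#' numbers, never by rounding the monoisotopic float, so it cannot drift for
#' large compositions. This is the convention behind printed unit-resolution
#' m/z values.
#'
#' @param counts An [element_counts] object or formula string.
#' @return Integer mass in Da.
#' @examples
#' nominal_mass("C20H22O9")  # 406
#' @export
nominal_mass <- function(counts) {
  counts <- as_element_counts(counts)
  numbers <- .isotopes$mass_number[match(names(counts), .isotopes$symbol)]
  as.integer(sum(unclass(counts) * numbers))
}

#' Vibrational degrees of freedom, 3N - 6
#'
#' N is the total atom count of the composition; the nonlinear-species
#' convention 3N - 6 is applied to every ion, including the added proton of a
#' protonated adduct.
#'
#' @param counts An [element_counts] object or formula string.
#' @return Integer DOF.
#' @examples
#' vibrational_dof("C10H13N5O4")  # 90
#' @export
vibrational_dof <- function(counts) {
  n <- atom_count(counts)
  if (n < 3L) {
    stop("3N - 6 degrees of freedom undefined for N < 3 (got N = ", n, ")")
  }
  3L * n - 6L
}

# Built-in nucleoside compositions (overridable wherever a nucleoside formula
# is accepted).
.nucleosides <- list(
  dG = "C10H13N5O4",  # 2'-deoxyguanosine
  G  = "C10H13N5O5"   # guanosine
)

#' Built-in nucleoside composition
#' @param name `"dG"` (2'-deoxyguanosine) or `"G"` (guanosine).
#' @return [element_counts] of the neutral nucleoside.
#' @export
nucleoside_formula <- function(name = c("dG", "G")) {
  name <- match.arg(name)
  parse_formula(.nucleosides[[name]])
}

.attachments <- c("proton_add", "proton_loss", "formate_add",
                  "chloride_add", "nucleoside_proton_add")

#' Build an adduct ion from a ligand composition
#'
#' Supported species: `proton_add` (\[M+H\]+), `proton_loss` (\[M-H\]-),
#' `formate_add` (\[M+HCOO\]-), `chloride_add` (\[M+Cl\]-, using 35Cl) and
#' `nucleoside_proton_add` (\[M+dG+H\]+ / \[M+G+H\]+, the proton-bound
#' nucleoside complexes at the heart of the screen). Only singly charged ions
#' are in scope.
#'
#' @param ligand Ligand composition ([element_counts] or formula string).
#' @param species Attachment kind, one of
#'   `r paste0('"', c("proton_add","proton_loss","formate_add","chloride_add","nucleoside_proton_add"), '"', collapse = ", ")`.
#' @param nucleoside Nucleoside composition (or `"dG"`/`"G"`); required iff
#'   `species = "nucleoside_proton_add"`.
#' @return An `adduct_ion` list: `ligand`, `attachment`, `nucleoside`,
#'   `charge`, `composition`, `mz_mono`, `mz_nominal`, `dof`.
#' @examples
#' make_adduct("C20H22O9", "chloride_add")$mz_nominal   # 441
#' make_adduct("C25H24O12", "nucleoside_proton_add", "dG")
#' @export
make_adduct <- function(ligand, species, nucleoside = NULL) {
  ligand <- as_element_counts(ligand)
  species <- match.arg(species, .attachments)
  if (species == "nucleoside_proton_add") {
    if (is.null(nucleoside)) {
      stop("nucleoside_proton_add requires a nucleoside composition")
    }
    if (is.character(nucleoside) && nucleoside %in% names(.nucleosides)) {
      nucleoside <- parse_formula(.nucleosides[[nucleoside]])
    } else {
      nucleoside <- as_element_counts(nucleoside)
    }
  } else if (!is.null(nucleoside)) {
    stop("nucleoside is only meaningful for species = 'nucleoside_proton_add'")
  }
  comp_charge <- switch(species,
    proton_add = list(combine_counts(ligand, "H"), +1L),
    proton_loss = {
      if (!("H" %in% names(ligand))) {
        stop("proton_loss requires at least one hydrogen in ",
             format_formula(ligand))
      }
      list(subtract_counts(ligand, "H"), -1L)
    },
    formate_add = list(combine_counts(ligand, "CHO2"), -1L),
    chloride_add = list(combine_counts(ligand, "Cl"), -1L),
    nucleoside_proton_add = list(combine_counts(ligand, nucleoside, "H"), +1L)
  )
  composition <- comp_charge[[1]]
  structure(list(
    ligand = ligand,
    attachment = species,
    nucleoside = if (species == "nucleoside_proton_add") nucleoside else NULL,
    charge = comp_charge[[2]],
    composition = composition,
    mz_mono = monoisotopic_mass(composition),
    mz_nominal = nominal_mass(composition),
    dof = vibrational_dof(composition)
  ), class = "adduct_ion")
}

#' @export
print.adduct_ion <- function(x, ...) {
  lab <- switch(x$attachment,
    proton_add = "[M+H]+", proton_loss = "[M-H]-",
    formate_add = "[M+HCOO]-", chloride_add = "[M+Cl]-",
    nucleoside_proton_add = "[M+Nuc+H]+")
  cat(sprintf("<adduct_ion> %s of %s: %s, m/z %.4f (nominal %d), DOF %d\n",
              lab, format_formula(x$ligand), format_formula(x$composition),
              x$mz_mono, x$mz_nominal, x$dof))
  invisible(x)
}

#' Read a compound panel from CSV/TSV
#'
#' Expected columns: `name`, `formula`, `rt_min`, `rt_max` and optionally
#' `class`. The retention-time window (minutes) is where each compound's ion
#' chromatograms are integrated.
#'
#' @param path Path to a comma- or tab-separated panel file.
#' @return A tibble with parsed, validated columns.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("name", "formula", "rt_min", "rt_max")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_formula(df$formula[i]), error = function(e) {
      stop("panel row ", i, " (", df$name[i], "): ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (any(df$rt_min >= df$rt_max)) stop("panel has rt_min >= rt_max")
  tibble::as_tibble(df)
}
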