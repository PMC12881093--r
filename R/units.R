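#' NGSP/IFCC master-equation and glucose-unit constants
#'
#' The two standardized HbA1c reporting systems are related by an affine
#' "master equation", `NGSP(%) = slope * IFCC(mmol/mol) + intercept`.  The
#' rounded pair 0.0915 / 2.15 is used by default: it is the rounding that is
#' algebraically coherent with the IFCC-form uGMI constants (see
#' [formula_coherence()]).  Glucose conversion is fixed at 18.0 mg/dl per
#' mmol/l, again the value coherent with the uGMI parameterizations.
#'
#' @param ngsp_slope Percent NGSP per mmol/mol IFCC.
#' @param ngsp_intercept Percent NGSP at 0 mmol/mol.
#' @param glucose_factor mg/dl per mmol/l.
#' @return An object of class `conversion_constants`.
#' @export
#' @examples
#' cc <- conversion_constants()
#' ifcc_to_ngsp(53, cc = cc)
conversion_constants <- function(ngsp_slope = 0.0915, ngsp_intercept = 2.15,
                                 glucose_factor = 18.0) {
  for (v in c(ngsp_slope, ngsp_intercept, glucose_factor)) {
    if (!is.finite(v) || v <= 0) {
      stop("conversion constants must be finite and strictly positive", call. = FALSE)
    }
  }
  structure(list(ngsp_slope = ngsp_slope, ngsp_intercept = ngsp_intercept,
                 glucose_factor = glucose_factor),
            class = "conversion_constants")
}

#' uGMI formula constants (both printed parameterizations)
#'
#' The updated glucose management indicator is a reciprocal-form estimate of
#' steady-state HbA1c from mean sensor glucose (AG):
#' \deqn{uGMI(mmol/mol) = \frac{1}{a_{ifcc}/AG_{mmol/l} + b_{ifcc}} - c_{ifcc}}
#' \deqn{uGMI(\%) = \frac{1}{a_{ngsp}/AG_{mg/dl} + b_{ngsp}}}
#' The IFCC triple and the NGSP pair describe the same curve: converting the
#' NGSP form through the master equation reproduces the IFCC constants to
#' their printed precision ([ugmi_constants_from_ngsp()]).
#'
#' @param a_ifcc Glucose coefficient, mmol/l.
#' @param b_ifcc Dimensionless additive constant inside the reciprocal.
#' @param c_ifcc Offset subtracted outside the reciprocal, mmol/mol.
#' @param a_ngsp Glucose coefficient of the NGSP form, mg/dl.
#' @param b_ngsp Dimensionless additive constant of the NGSP form.
#' @return An object of class `ugmi_formula`.
#' @export
ugmi_formula <- function(a_ifcc = 0.07808, b_ifcc = 0.003889, c_ifcc = 23.497,
                         a_ngsp = 15.36, b_ngsp = 0.0425) {
  if (any(!is.finite(c(a_ifcc, b_ifcc, c_ifcc, a_ngsp, b_ngsp))) ||
      a_ifcc <= 0 || b_ifcc <= 0 || a_ngsp <= 0 || b_ngsp <= 0) {
    stop("uGMI formula constants must be finite; coefficients strictly positive",
         call. = FALSE)
  }
  structure(list(a_ifcc = a_ifcc, b_ifcc = b_ifcc, c_ifcc = c_ifcc,
                 a_ngsp = a_ngsp, b_ngsp = b_ngsp),
            class = "ugmi_formula")
}

#' Reference glycation kinetic constants
#'
#' The steady-state glycation model behind the uGMI uses a glycation rate
#' constant, a red-cell removal rate, and a Michaelis constant.  They are
#' carried as documented metadata: the closed-form [ugmi_formula()] is
#' authoritative and no computation in this package consumes them.
#'
#' @return A named list with `k_gly` (l mmol^-1 day^-1), `k_age` (day^-1)
#'   and `K_M` (mmol/l).
#' @export
kinetic_constants <- function() {
  list(k_gly = 3.4e-7, k_age = 0.0095, K_M = 8514)
}

check_hba1c <- function(value, unit = c("ifcc", "ngsp"), check = TRUE) {
  unit <- match.arg(unit)
  if (any(!is.finite(value))) {
    stop("HbA1c value must be finite, got ", paste(value[!is.finite(value)],
         collapse = ", "), call. = FALSE)
  }
  if (check) {
    lim <- if (unit == "ifcc") c(0, 250) else c(0, 25)
    bad <- value <= lim[1] | value >= lim[2]
    if (any(bad)) {
      stop("HbA1c (", unit, ") out of range (", lim[1], ", ", lim[2], "): ",
           paste(value[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(value)
}

#' Convert HbA1c between IFCC (mmol/mol) and NGSP (%) units
#'
#' @param x HbA1c values.
#' @param cc A [conversion_constants()] object.
#' @param check Validate the physiologic input range (IFCC in (0, 250),
#'   NGSP in (0, 25)).  Disable only for algebraic edge cases.
#' @return Converted HbA1c values.
#' @export
#' @examples
#' ifcc_to_ngsp(67)   # 8.3 % NGSP at 1 d.p.
#' ngsp_to_ifcc(7.0)  # 53 mmol/mol to the nearest integer
ifcc_to_ngsp <- function(x, cc = conversion_constants(), check = TRUE) {
  check_hba1c(x, "ifcc", check)
  cc$ngsp_slope * x + cc$ngsp_intercept
}

#' @rdname ifcc_to_ngsp
#' @export
ngsp_to_ifcc <- function(x, cc = conversion_constants(), check = TRUE) {
  check_hba1c(x, "ngsp", check)
  (x - cc$ngsp_intercept) / cc$ngsp_slope
}

#' Normalize glucose values to mmol/l
#'
#' @param value Glucose values, strictly positive.
#' @param unit `"mg/dl"` or `"mmol/l"` (case-insensitive; `"mgdl"`/`"mmol"`
#'   also accepted).
#' @param cc A [conversion_constants()] object.
#' @return Glucose in mmol/l.
#' @export
glucose_to_mmol <- function(value, unit, cc = conversion_constants()) {
  if (any(!is.finite(value) | value <= 0)) {
    stop("glucose values must be finite and > 0", call. = FALSE)
  }
  key <- gsub("[^a-z]", "", tolower(unit))
  if (length(key) == 1L) key <- rep(key, length(value))
  out <- ifelse(key == "mgdl", value / cc$glucose_factor,
         ifelse(key %in% c("mmoll", "mmol"), value, NA_real_))
  if (any(is.na(out))) {
    stop("unknown glucose unit: ", paste(unique(unit[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Updated glucose management indicator (uGMI)
#'
#' Estimates steady-state HbA1c from mean sensor glucose through the
#' reciprocal-form curve of [ugmi_formula()].  The IFCC form is primary;
#' the NGSP form is the independently printed parameterization of the same
#' curve (coherence is checked by [formula_coherence()]).  The function is
#' strictly increasing and concave in `ag`, with supremum
#' `1/b_ifcc - c_ifcc` mmol/mol.
#'
#' @param ag Mean sensor glucose in mmol/l, strictly positive.
#' @param unit_out `"ifcc"` (mmol/mol) or `"ngsp"` (%).
#' @param formula A [ugmi_formula()] object.
#' @param cc A [conversion_constants()] object (used by the NGSP form to
#'   express `ag` in mg/dl).
#' @return uGMI in the requested unit.
#' @export
#' @examples
#' ugmi(10.3)                    # 63.69 mmol/mol
#' ugmi(100 / 18, "ngsp")        # 5.10 % at AG = 100 mg/dl
ugmi <- function(ag, unit_out = c("ifcc", "ngsp"), formula = ugmi_formula(),
                 cc = conversion_constants()) {
  unit_out <- match.arg(unit_out)
  if (any(!is.finite(ag) | ag <= 0)) {
    stop("mean glucose must be finite and > 0, got ",
         paste(ag[!is.finite(ag) | ag <= 0], collapse = ", "), call. = FALSE)
  }
  if (unit_out == "ifcc") {
    1 / (formula$a_ifcc / ag + formula$b_ifcc) - formula$c_ifcc
  } else {
    1 / (formula$a_ngsp / (cc$glucose_factor * ag) + formula$b_ngsp)
  }
}

#' Linear glucose management indicator (comparator)
#'
#' The conventional GMI estimates HbA1c by linear regression on mean
#' glucose.  Coefficients are configurable because published pairs differ
#' by data source; the default is the widely used regression
#' `GMI(%) = 3.31 + 0.02392 * AG(mg/dl)`.  The provenance of a
#' non-default pair should be recorded by the caller.
#'
#' @param ag Mean sensor glucose in mmol/l, strictly positive.
#' @param slope Percent NGSP per mg/dl.
#' @param intercept Percent NGSP.
#' @param cc A [conversion_constants()] object.
#' @return GMI in % NGSP.
#' @export
gmi_comparator <- function(ag, slope = 0.02392, intercept = 3.31,
                           cc = conversion_constants()) {
  if (any(!is.finite(ag) | ag <= 0)) {
    stop("mean glucose must be finite and > 0", call. = FALSE)
  }
  intercept + slope * cc$glucose_factor * ag
}

#' Recover the IFCC-form uGMI constants from the NGSP form
#'
#' Substituting the master equation and the mg/dl conversion into the NGSP
#' form
#' \deqn{uGMI(\%) = 1/(a_{ngsp}/AG_{mg/dl} + b_{ngsp})}
#' and rearranging onto the IFCC scale yields a reciprocal form whose
#' constants are `slope * a_ngsp / glucose_factor`, `slope * b_ngsp`, and
#' `intercept / slope`.  With the default constants these reproduce the
#' printed IFCC triple to its printed precision.
#'
#' @param formula A [ugmi_formula()] object (only the NGSP pair is used).
#' @param cc A [conversion_constants()] object.
#' @return Named numeric vector `c(a_ifcc, b_ifcc, c_ifcc)` at full
#'   precision (not rounded).
#' @export
ugmi_constants_from_ngsp <- function(formula = ugmi_formula(),
                                     cc = conversion_constants()) {
  c(a_ifcc = cc$ngsp_slope * formula$a_ngsp / cc$glucose_factor,
    b_ifcc = cc$ngsp_slope * formula$b_ngsp,
    c_ifcc = cc$ngsp_intercept / cc$ngsp_slope)
}

#' Maximum discrepancy between the two printed uGMI forms
#'
#' Evaluates the IFCC form directly and the NGSP form converted back to the
#' IFCC scale on a grid of mean glucose values, and returns the maximum
#' absolute difference in mmol/mol.  With the default constants the two
#' printed parameterizations agree to well under 0.01 mmol/mol across the
#' physiologic range.
#'
#' @param ag_grid Mean glucose grid in mmol/l, all strictly positive.
#' @param formula A [ugmi_formula()] object.
#' @param cc A [conversion_constants()] object.
#' @return Maximum absolute discrepancy (mmol/mol).
#' @export
#' @examples
#' formula_coherence(seq(3, 25, by = 0.1))
formula_coherence <- function(ag_grid, formula = ugmi_formula(),
                              cc = conversion_constants()) {
  if (length(ag_grid) == 0L) stop("ag_grid must be nonempty", call. = FALSE)
  ifcc_direct <- ugmi(ag_grid, "ifcc", formula, cc)
  ifcc_via_ngsp <- ngsp_to_ifcc(ugmi(ag_grid, "ngsp", formula, cc),
                                cc = cc, check = FALSE)
  max(abs(ifcc_direct - ifcc_via_ngsp))
}

#' Display rounding for HbA1c values
#'
#' Reporting convention: NGSP to one decimal place, IFCC to the nearest
#' integer.
#'
#' @param x HbA1c values.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @return Rounded values.
#' @export
round_hba1c <- function(x, unit = c("ifcc", "ngsp")) {
  unit <- match.arg(unit)
  if (unit == "ifcc") round(x) else round(x, 1)
}

#' Serializable block of all unit-system constants
#'
#' @param cc A [conversion_constants()] object.
#' @param formula A [ugmi_formula()] object.
#' @return A nested list suitable for `jsonlite::toJSON()`; includes the
#'   kinetic metadata of [kinetic_constants()].
#' @export
constants_block <- function(cc = conversion_constants(), formula = ugmi_formula()) {
  list(ngsp_slope = cc$ngsp_slope, ngsp_intercept = cc$ngsp_intercept,
       glucose_factor = cc$glucose_factor,
       ugmi = unclass(formula), kinetic = kinetic_constants())
}
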