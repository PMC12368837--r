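# Physical constants (CODATA 2018), SI units.
.kB <- 1.380649e-23          # Boltzmann constant, J/K
.R_gas <- 8.314462618        # molar gas constant, J/(mol K)
.N_A <- 6.02214076e23        # Avogadro constant, 1/mol
.e_charge <- 1.602176634e-19 # elementary charge, C
.amu <- 1.66053906660e-27    # unified atomic mass unit, kg

#' Convert a mass in daltons to kilograms
#'
#' @param da Mass in daltons (unified atomic mass units).
#' @return Mass in kg.
#' @export
da_to_kg <- function(da) da * .amu

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg)
  invisible(NULL)
}
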