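# Monoisotopic masses of the lightest stable isotope (CODATA/AME2020), Da.
.isotope_mass <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268, Na = 22.9897692809,
  K = 38.96370668, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Si = 27.9769265325, Ca = 39.96259098, Fe = 55.9349375, Mg = 23.9850417
)
.electron_mass <- 0.00054857990907
.proton_mass <- 1.00782503207 - 0.00054857990907

#' Parse an elemental formula
#'
#' @param formula A Hill-style formula string such as `"C43H78NO8P"`.
#' @return A named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  abort_if(!is.character(formula) || length(formula) != 1,
           "formula must be a single string")
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  abort_if(sum(nchar(tokens)) != nchar(formula),
           paste0("cannot parse formula: ", formula))
  el <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(el, names(.isotope_mass))
  abort_if(length(unknown) > 0,
           paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  counts <- tapply(cnt, el, sum)[unique(el)]
  structure(as.integer(counts), names = names(counts))
}

#' Theoretical m/z of an adduct ion
#'
#' Monoisotopic mass from standard isotope masses, with electron-mass
#' bookkeeping: deprotonation removes a proton (the electron stays),
#' chloride attachment adds Cl plus an electron, protonation adds a proton.
#' The result carries full floating-point precision; round only for
#' display.
#'
#' @param formula Elemental formula of the neutral molecule M.
#' @param adduct One of `"[M-H]-"`, `"[M+Cl]-"`, `"[M+H]+"`.
#' @return The theoretical m/z (single charge assumed).
#' @examples
#' compute_mz("C5H5N5O", "[M-H]-")    # deprotonated guanine
#' compute_mz("C43H78NO8P", "[M-H]-") # deprotonated PE(38:4)
#' @export
compute_mz <- function(formula, adduct = c("[M-H]-", "[M+Cl]-", "[M+H]+")) {
  adduct <- match.arg(adduct)
  counts <- parse_formula(formula)
  M <- sum(.isotope_mass[names(counts)] * counts)
  switch(adduct,
         "[M-H]-" = M - .proton_mass,
         "[M+Cl]-" = M + .isotope_mass[["Cl"]] + .electron_mass,
         "[M+H]+" = M + .proton_mass)
}

#' Reference annotation table of LA-REIMS marker species
#'
#' Nucleobases, amino acids and lipid species routinely observed in
#' negative-mode tissue spectra, with theoretical m/z recomputed from their
#' formulas via [compute_mz()]. Note that the table stores the computed
#' values; for two lipid species the literature-reported image m/z differ
#' from the isotope-mass sums by more than the display precision, and the
#' computed values are kept.
#'
#' @return A tibble with `name`, `formula`, `adduct`, `mz`.
#' @export
annotation_table <- function() {
  tbl <- tibble::tribble(
    ~name,                 ~formula,       ~adduct,
    "adenine",             "C5H5N5",       "[M-H]-",
    "guanine",             "C5H5N5O",      "[M-H]-",
    "glutamine",           "C5H10N2O3",    "[M-H]-",
    "glutamate",           "C5H9NO4",      "[M-H]-",
    "PE(36:1)",            "C41H80NO8P",   "[M-H]-",
    "PE(36:2)",            "C41H78NO8P",   "[M-H]-",
    "PE(38:4)",            "C43H78NO8P",   "[M-H]-",
    "TG(52:2)",            "C55H102O6",    "[M+Cl]-",
    "leucine enkephalin",  "C28H37N5O7",   "[M-H]-"
  )
  tbl$mz <- purrr::map2_dbl(tbl$formula, tbl$adduct, compute_mz)
  tbl
}

#' Annotate peaks by accurate mass
#'
#' Each observed peak is matched to the annotation-table entry with the
#' smallest absolute ppm error within the tolerance; peaks with no match are
#' labelled `"unknown"`.
#'
#' @param peaks Numeric vector of observed m/z values.
#' @param table Annotation tibble with `name` and `mz` columns, see
#'   [annotation_table()].
#' @param tol_ppm Matching tolerance, parts per million.
#' @return A tibble: `mz`, `name`, `theoretical_mz`, `ppm_error`.
#' @export
annotate_peaks <- function(peaks, table = annotation_table(), tol_ppm = 10) {
  purrr::map_dfr(peaks, function(p) {
    ppm <- (p - table$mz) / table$mz * 1e6
    i <- which.min(abs(ppm))
    if (length(i) && abs(ppm[i]) <= tol_ppm) {
      tibble::tibble(mz = p, name = table$name[i],
                     theoretical_mz = table$mz[i], ppm_error = ppm[i])
    } else {
      tibble::tibble(mz = p, name = "unknown",
                     theoretical_mz = NA_real_, ppm_error = NA_real_)
    }
  })
}
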