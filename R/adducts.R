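# monoisotopic masses of the elements appearing in common lipid formulae
.monoisotopic <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069,
                   Na = 22.9897692809, K = 38.9637064864, Cl = 34.96885268)

# mass shifts of the searched ionisation adducts (Da)
.adduct_shifts <- c("M+H" = 1.007276, "M+Na" = 22.989218, "M-H" = -1.007276)

#' Monoisotopic mass from a molecular formula
#'
#' Parses a plain Hill-style formula (e.g. "C26H54NO7P") and sums standard
#' monoisotopic atomic masses.
#'
#' @param formula character vector of formulae.
#' @return monoisotopic masses in Da.
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(f)) stop("cannot parse formula: ", f)
    total <- 0
    for (tk in toks) {
      el <- sub("[0-9]*$", "", tk)
      ct <- sub("^[A-Za-z]+", "", tk)
      ct <- if (nchar(ct) == 0) 1L else as.integer(ct)
      if (!el %in% names(.monoisotopic)) stop("unknown element: ", el)
      total <- total + .monoisotopic[[el]] * ct
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Built-in reference list of candidate lipids
#'
#' The lysophosphatidylcholine and phosphatidylcholine species relevant to
#' burn-injury skin lipidomics, with formulae and monoisotopic masses
#' computed from standard atomic masses.
#'
#' @return data.frame `name`, `formula`, `monoisotopic_mass`.
#' @export
lipid_reference <- function() {
  ref <- data.frame(
    name = c("14:0 LPC", "16:0 LPC", "18:0 LPC", "18:1 LPC",
             "18:0/18:2 PC"),
    formula = c("C22H46NO7P", "C24H50NO7P", "C26H54NO7P", "C26H52NO7P",
                "C44H84NO8P"),
    stringsAsFactors = FALSE
  )
  ref$monoisotopic_mass <- monoisotopic_mass(ref$formula)
  ref
}

#' Match an observed m/z against candidate lipid adducts
#'
#' Searches mode-appropriate adducts (positive mode: M+H and M+Na; negative
#' mode: M-H only) within an absolute tolerance, and flags matches whose
#' relative error is below the ppm threshold as promising.
#'
#' @param observed_mz observed m/z values (Da).
#' @param mode "ESI+" or "ESI-".
#' @param reference data.frame with `name` and `monoisotopic_mass` (and
#'   optionally `formula`); default [lipid_reference()].
#' @param tol_da absolute match tolerance in Da (default 0.05).
#' @param flag_ppm matches with |delta| below this many ppm are flagged
#'   promising (default 35).
#' @return data.frame `observed_mz`, `name`, `formula`,
#'   `monoisotopic_mass`, `adduct`, `expected_mz`, `delta_da`, `delta_ppm`,
#'   `promising`; zero rows when nothing matches.
#' @export
match_adducts <- function(observed_mz, mode = c("ESI+", "ESI-"),
                          reference = lipid_reference(), tol_da = 0.05,
                          flag_ppm = 35) {
  mode <- match.arg(mode)
  adducts <- if (mode == "ESI+") c("M+H", "M+Na") else "M-H"
  if (!"formula" %in% names(reference)) reference$formula <- NA_character_
  cand <- expand.grid(ref = seq_len(nrow(reference)), adduct = adducts,
                      stringsAsFactors = FALSE)
  expected <- reference$monoisotopic_mass[cand$ref] +
    .adduct_shifts[cand$adduct]
  out <- do.call(rbind, lapply(observed_mz, function(mz) {
    delta <- mz - expected
    hit <- abs(delta) <= tol_da
    if (!any(hit)) return(NULL)
    data.frame(observed_mz = mz,
               name = reference$name[cand$ref[hit]],
               formula = reference$formula[cand$ref[hit]],
               monoisotopic_mass = reference$monoisotopic_mass[cand$ref[hit]],
               adduct = cand$adduct[hit],
               expected_mz = expected[hit],
               delta_da = delta[hit],
               delta_ppm = 1e6 * delta[hit] / expected[hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(observed_mz = numeric(0), name = character(0),
                      formula = character(0),
                      monoisotopic_mass = numeric(0), adduct = character(0),
                      expected_mz = numeric(0), delta_da = numeric(0),
                      delta_ppm = numeric(0), stringsAsFactors = FALSE)
  out$promising <- abs(out$delta_ppm) < flag_ppm
  rownames(out) <- NULL
  out
}
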