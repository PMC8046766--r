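#' Standard atomic masses (g/mol) for otolith panels
#'
#' IUPAC standard atomic weights for the elements measured in whole-otolith
#' solution chemistry, used by [ppm_to_element_ca_ratio()].
#' @export
atomic_masses <- c(
  Ca = 40.078, Na = 22.98976928, Mg = 24.305, Sr = 87.62, Ba = 137.327,
  Mn = 54.938043, Fe = 55.845, Pb = 207.2, Ni = 58.6934, Zn = 65.38,
  Cd = 112.414, Cr = 51.9961, K = 39.0983)

#' Instrument detection limits (ppm) for the measured elements
#'
#' Default minimum detection levels of the ICP-AES panel; concentrations
#' below these cannot be quantified and are treated as exact zeros by
#' [censor_below_lod()].
#' @export
detection_limits <- c(
  Ca = 0.005, Na = 0.05, Mg = 0.0005, Sr = 0.0005, Ba = 0.0005,
  Mn = 0.001, Fe = 0.005, Pb = 0.05, Ni = 0.005, Zn = 0.005,
  Cd = 0.005, Cr = 0.005, K = 0.1)

.element_cols <- function(panel, limits) {
  intersect(names(limits), colnames(panel))
}

#' Censor concentrations below the detection limit
#'
#' Sets every element concentration strictly below its detection limit to
#' an exact zero (values exactly at the limit are retained). The resulting
#' zeros are the "null observations" a Tweedie error structure models with
#' its point mass — no limit/2 substitution is performed.
#'
#' @param panel data frame with one row per fish; element concentrations in
#'   ppm in columns named by element symbol; any other columns (site,
#'   lengths, ids) pass through untouched.
#' @param limits named vector of detection limits (ppm); defaults to
#'   [detection_limits]. Every element column present must have a limit.
#' @return list with `panel` (censored), `flags` (logical matrix of
#'   censored cells) and `counts` (data frame of censored counts per
#'   element, and per element x site when a `site` column exists).
#' @export
censor_below_lod <- function(panel, limits = detection_limits) {
  el <- intersect(colnames(panel),
                  names(which(vapply(panel, is.numeric, TRUE))))
  el <- setdiff(el, c("total_length_mm", "otolith_weight_mg"))
  missing_lim <- setdiff(el, names(limits))
  if (length(missing_lim))
    stop("no detection limit configured for element(s): ",
         paste(missing_lim, collapse = ", "), call. = FALSE)
  if (any(limits <= 0)) stop("detection limits must be positive",
                             call. = FALSE)
  flags <- matrix(FALSE, nrow(panel), length(el),
                  dimnames = list(NULL, el))
  for (e in el) {
    below <- panel[[e]] < limits[[e]]
    flags[, e] <- below
    panel[[e]][below] <- 0
  }
  counts <- data.frame(element = el, n_censored = colSums(flags))
  if (!is.null(panel$site)) {
    by_site <- as.data.frame.table(
      rowsum(flags + 0, panel$site), responseName = "n_censored")
    names(by_site)[1:2] <- c("site", "element")
    counts <- list(total = counts, by_site = by_site)
  }
  list(panel = panel, flags = flags, counts = counts)
}

#' Convert ppm concentrations to element:Ca molar ratios
#'
#' `ratio = (element_ppm / M_element) / (Ca_ppm / M_Ca) * 1000`, in
#' mmol element per mol Ca, using the packaged standard atomic masses.
#' The molar normalisation to calcium controls for otolith size.
#'
#' @param panel data frame with a positive `Ca` ppm column and one ppm
#'   column per element to convert.
#' @param masses named atomic-mass vector; defaults to [atomic_masses].
#' @return numeric matrix of element:Ca ratios (mmol:mol), one column per
#'   non-Ca element present, zeros preserved exactly.
#' @examples
#' p <- data.frame(Ca = 380000, Sr = 1000)
#' ppm_to_element_ca_ratio(p)  # about 1.2037 mmol:mol
#' @export
ppm_to_element_ca_ratio <- function(panel, masses = atomic_masses) {
  if (is.null(panel$Ca)) stop("panel must contain a Ca column",
                              call. = FALSE)
  bad <- which(panel$Ca <= 0 | !is.finite(panel$Ca))
  if (length(bad))
    stop("non-positive Ca concentration for fish row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  el <- setdiff(intersect(colnames(panel), names(masses)), "Ca")
  if (!length(el)) stop("no element columns found", call. = FALSE)
  ca_mol <- panel$Ca / masses[["Ca"]]
  out <- vapply(el, function(e) (panel[[e]] / masses[[e]]) / ca_mol * 1000,
                numeric(nrow(panel)))
  out <- matrix(out, nrow = nrow(panel), dimnames = list(NULL, el))
  out
}
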