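# Conceptual-DFT global reactivity indices from frontier-orbital energies.
# The orbital energies themselves (and the Hirshfeld carbonyl-carbon charge
# qC) come from external quantum-chemistry output and are ingested as data.

#' Conceptual-DFT descriptors from frontier orbital energies
#'
#' Applies the Koopmans-type finite-difference convention: ionization
#' potential I = -E_HOMO, electron affinity A = -E_LUMO, chemical potential
#' mu = -(I+A)/2, hardness eta = (I-A)/2, electrophilicity
#' omega = mu^2 / (2 eta) and gap = E_LUMO - E_HOMO (all eV).  The
#' alternative hardness convention eta = I - A (twice the default) is
#' available via `hardness_factor = "full"`; omega scales accordingly.
#' When the gap is non-positive, eta <= 0 and omega is undefined (`NA` with
#' a warning).
#'
#' @param e_homo,e_lumo orbital energies in eV (vectorized).
#' @param hardness_factor `"half"` (eta = (I-A)/2, default) or `"full"`
#'   (eta = I-A).
#' @return data frame with columns `e_homo`, `e_lumo`, `I`, `A`, `mu`,
#'   `eta`, `omega`, `gap`.
#' @examples
#' conceptual_dft(-6.2, -1.1)
#' @export
conceptual_dft <- function(e_homo, e_lumo, hardness_factor = c("half", "full")) {
  hardness_factor <- match.arg(hardness_factor)
  stopifnot(length(e_homo) == length(e_lumo))
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo)))
    stop("orbital energies must be finite")
  I <- -e_homo
  A <- -e_lumo
  mu <- -(I + A) / 2
  eta <- (I - A) / 2
  if (hardness_factor == "full") eta <- I - A
  gap <- e_lumo - e_homo
  omega <- ifelse(eta > 0, mu^2 / (2 * eta), NA_real_)
  if (any(eta <= 0))
    warning(sprintf("%d record(s) with non-positive hardness; omega undefined",
                    sum(eta <= 0)))
  data.frame(e_homo = e_homo, e_lumo = e_lumo, I = I, A = A, mu = mu,
             eta = eta, omega = omega, gap = gap)
}

#' Load per-compound electronic data from CSV
#'
#' Accepts either orbital energies (`e_homo_eV`, `e_lumo_eV`), from which
#' EA and the conceptual-DFT indices are derived, or a direct `EA_eV`
#' column taken verbatim; `qC_e` (Hirshfeld charge of the carbamate
#' carbonyl carbon, elementary charges) is required alongside `id`.
#'
#' @param path CSV file.
#' @param hardness_factor passed to [conceptual_dft()].
#' @return data frame with columns `id`, `EA`, `qC` and, when orbital
#'   energies were supplied, `e_homo`, `e_lumo`, `I`, `mu`, `eta`, `omega`,
#'   `gap`.
#' @export
load_electronic_csv <- function(path, hardness_factor = "half") {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(d)) stop("missing required column: id")
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id))
    stop("duplicate ids: ", paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  has_orb <- all(c("e_homo_eV", "e_lumo_eV") %in% names(d))
  has_ea <- "EA_eV" %in% names(d)
  if (!has_orb && !has_ea)
    stop("missing required columns: either (e_homo_eV, e_lumo_eV) or EA_eV")
  if (!"qC_e" %in% names(d)) stop("missing required column: qC_e")
  if (has_orb) {
    cd <- conceptual_dft(d$e_homo_eV, d$e_lumo_eV, hardness_factor = hardness_factor)
    out <- cbind(data.frame(id = d$id, stringsAsFactors = FALSE), cd)
    out$EA <- if (has_ea) d$EA_eV else cd$A
    out$qC <- d$qC_e
  } else {
    out <- data.frame(id = d$id, EA = d$EA_eV, qC = d$qC_e,
                      stringsAsFactors = FALSE)
  }
  out
}
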