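# Standard amino-acid proton nomenclature (PDB v3 / IUPAC names), used to
# expand wildcard and pseudoatom selectors in distance-restraint files.

.PROTON_NAMES <- list(
  ALA = c("H", "HA", "HB1", "HB2", "HB3"),
  ARG = c("H", "HA", "HB2", "HB3", "HG2", "HG3", "HD2", "HD3", "HE",
          "HH11", "HH12", "HH21", "HH22"),
  ASN = c("H", "HA", "HB2", "HB3", "HD21", "HD22"),
  ASP = c("H", "HA", "HB2", "HB3"),
  CYS = c("H", "HA", "HB2", "HB3", "HG"),
  GLN = c("H", "HA", "HB2", "HB3", "HG2", "HG3", "HE21", "HE22"),
  GLU = c("H", "HA", "HB2", "HB3", "HG2", "HG3"),
  GLY = c("H", "HA2", "HA3"),
  HIS = c("H", "HA", "HB2", "HB3", "HD1", "HD2", "HE1", "HE2"),
  ILE = c("H", "HA", "HB", "HG12", "HG13", "HG21", "HG22", "HG23",
          "HD11", "HD12", "HD13"),
  LEU = c("H", "HA", "HB2", "HB3", "HG", "HD11", "HD12", "HD13",
          "HD21", "HD22", "HD23"),
  LYS = c("H", "HA", "HB2", "HB3", "HG2", "HG3", "HD2", "HD3",
          "HE2", "HE3", "HZ1", "HZ2", "HZ3"),
  MET = c("H", "HA", "HB2", "HB3", "HG2", "HG3", "HE1", "HE2", "HE3"),
  PHE = c("H", "HA", "HB2", "HB3", "HD1", "HD2", "HE1", "HE2", "HZ"),
  PRO = c("HA", "HB2", "HB3", "HG2", "HG3", "HD2", "HD3"),
  SER = c("H", "HA", "HB2", "HB3", "HG"),
  THR = c("H", "HA", "HB", "HG1", "HG21", "HG22", "HG23"),
  TRP = c("H", "HA", "HB2", "HB3", "HD1", "HE1", "HE3", "HZ2", "HZ3", "HH2"),
  TYR = c("H", "HA", "HB2", "HB3", "HD1", "HD2", "HE1", "HE2", "HH"),
  VAL = c("H", "HA", "HB", "HG11", "HG12", "HG13", "HG21", "HG22", "HG23")
)

# pseudoatom -> proton-name prefix (CYANA Q convention); QR is the aromatic
# ring set, handled specially.
.PSEUDO_PREFIX <- c(QA = "HA", QB = "HB", QG = "HG", QG1 = "HG1",
                    QG2 = "HG2", QD = "HD", QD1 = "HD1", QD2 = "HD2",
                    QE = "HE", QE2 = "HE2", QZ = "HZ", QH1 = "HH1",
                    QH2 = "HH2", QQG = "HG", QQD = "HD")

#' Expand a restraint atom selector to concrete proton names
#'
#' Handles plain names (\code{HA}), the HN alias (\code{HN} -> \code{H}),
#' trailing-wildcard selectors (\code{HB*}, \code{HB#}) and CYANA-style
#' pseudoatoms (\code{QB}, \code{QQD}, \code{QR}, ...), expanded against the
#' standard proton nomenclature of the residue type.
#'
#' @param resid three-letter residue name (e.g. \code{"LEU"}).
#' @param selector atom selector string.
#' @return character vector of proton names (length >= 1), or
#'   \code{character(0)} when the selector matches no proton of that residue.
#' @export
expand_proton_selector <- function(resid, selector) {
  resid <- toupper(resid); selector <- toupper(selector)
  protons <- .PROTON_NAMES[[resid]]
  if (is.null(protons)) return(NULL)  # unknown residue; caller reports
  if (selector == "HN") selector <- "H"
  if (selector == "QR")
    return(intersect(c("HD1", "HD2", "HE1", "HE2", "HZ"), protons))
  if (selector %in% names(.PSEUDO_PREFIX)) {
    pre <- .PSEUDO_PREFIX[[selector]]
    return(protons[startsWith(protons, pre)])
  }
  if (grepl("[*#]$", selector)) {
    pre <- sub("[*#]$", "", selector)
    return(protons[startsWith(protons, pre)])
  }
  intersect(selector, protons)
}
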