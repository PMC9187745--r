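#' Build a rigid rhombus molecule template
#'
#' Constructs the four-site rhombus geometry: two atoms on the long
#' diagonal at `(+-dLong/2, 0, 0)`, two on the short diagonal at
#' `(0, +-dShort/2, 0)`, all four bonds equal to `bond`.  The right-triangle
#' relation `(dLong/2)^2 + (dShort/2)^2 = bond^2` fixes both diagonals from
#' the bond length and their ratio.  Charges are initialized to zero; use
#' [assignCharges()] to create the permanent dipole.
#'
#' @param bond bond length b, nm (default 0.14982 nm, close to the
#'   carbon-carbon bond of a benzene ring).
#' @param diagonalRatio `dLong/dShort >= 1` (default 2: one diagonal twice
#'   the other).
#' @param mass atom mass recorded as metadata (amu, carbon by default);
#'   never used by any analysis here.
#' @return a [MoleculeTemplate-class].
#' @examples
#' tpl <- buildRhombus()
#' diagonals(tpl)              # 0.26801 / 0.13400 nm
#' @export
buildRhombus <- function(bond = 0.14982, diagonalRatio = 2, mass = 12.011) {
  if (!is.finite(bond) || bond <= 0) stop("bond length must be positive")
  if (!is.finite(diagonalRatio) || diagonalRatio < 1)
    stop("diagonalRatio must be >= 1")
  dShort <- 2 * bond / sqrt(1 + diagonalRatio^2)
  dLong <- diagonalRatio * dShort
  pos <- rbind(c(dLong / 2, 0, 0), c(-dLong / 2, 0, 0),
               c(0, dShort / 2, 0), c(0, -dShort / 2, 0))
  new("MoleculeTemplate", positions = pos, charges = numeric(4),
      bondLength = bond, dLong = dLong, dShort = dShort,
      metadata = list(mass = mass))
}

#' Assign the dipole-creating partial charges
#'
#' The long-diagonal atoms carry zero charge; the short-diagonal atoms
#' carry `+magnitude` and `-magnitude` (elementary-charge units), so the
#' net charge is always zero and the dipole points along the short
#' diagonal.  The sign assignment is positional, not an input.
#'
#' @param template a [MoleculeTemplate-class].
#' @param magnitude non-negative charge magnitude, e (0.5 for system I,
#'   0.75 for system II).
#' @return the template with charges `(0, 0, +magnitude, -magnitude)`.
#' @examples
#' sysI <- assignCharges(buildRhombus(), 0.5)
#' charges(sysI)
#' @export
assignCharges <- function(template, magnitude) {
  stopifnot(is(template, "MoleculeTemplate"))
  if (!is.finite(magnitude) || magnitude < 0)
    stop("charge magnitude must be non-negative")
  template@charges <- c(0, 0, magnitude, -magnitude)
  validObject(template)
  template
}

#' Dipole moment of a molecule template
#'
#' `|sum_i q_i r_i|` in e*nm; origin-independent because the net charge is
#' zero (a nonzero net charge is rejected).  Scaling all charges by `s`
#' scales the dipole by exactly `s`.
#'
#' @param template a [MoleculeTemplate-class] with charges assigned.
#' @return dipole magnitude, e*nm.
#' @examples
#' dipoleMoment(assignCharges(buildRhombus(), 0.5))   # 0.067 e nm
#' @export
dipoleMoment <- function(template) {
  stopifnot(is(template, "MoleculeTemplate"))
  if (abs(sum(charges(template))) > 1e-12)
    stop("dipole of a net-charged template is origin-dependent; refusing")
  mu <- colSums(charges(template) * atomPositions(template))
  sqrt(sum(mu^2))
}

#' Dipole direction of a molecule template
#'
#' Unit vector of the dipole; along the short diagonal for any positive
#' charge magnitude.  Zero vector for an apolar template.
#'
#' @param template a [MoleculeTemplate-class].
#' @return length-3 unit vector (or zeros).
#' @export
dipoleDirection <- function(template) {
  mu <- colSums(charges(template) * atomPositions(template))
  n <- sqrt(sum(mu^2))
  if (n == 0) c(0, 0, 0) else mu / n
}

#' Geometric center of a molecule template
#'
#' The unweighted mean of the four atom positions (the rhombus center);
#' this is the per-molecule point at which all order-parameter and
#' interface analyses are evaluated.
#'
#' @param template a [MoleculeTemplate-class].
#' @return length-3 position, nm.
#' @export
geometricCenter <- function(template) {
  colMeans(atomPositions(template))
}

#' Export a molecule template
#'
#' Writes the four-atom template either as a small GRO file or as JSON
#' (positions, charges, diagonals, bond length).
#'
#' @param template a [MoleculeTemplate-class].
#' @param path output path.
#' @param format `"GRO"` or `"JSON"`.
#' @param box box edges for the GRO export, nm.
#' @return `path`, invisibly.
#' @export
exportTemplate <- function(template, path, format = c("GRO", "JSON"),
                           box = c(2, 2, 2)) {
  stopifnot(is(template, "MoleculeTemplate"))
  format <- match.arg(format)
  if (format == "GRO") {
    fr <- makeFrame(atomPositions(template) + box / 2, box = box)
    writeStructure(fr, path, format = "GRO", title = "rhombus template")
  } else {
    jsonlite::write_json(
      list(positions_nm = atomPositions(template),
           charges_e = charges(template),
           bond_nm = bondLength(template),
           diagonals_nm = as.list(diagonals(template)),
           dipole_e_nm = dipoleMoment(template)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
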