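#' Cellular Potts model parameters
#'
#' Bundles every constant of the binary-population CPM: the area and
#' perimeter constraint strengths, the target geometry of normal and
#' senescent cells, the interfacial (adhesion) energy matrix, the
#' persistence strengths and polarity memory time, the fluctuation
#' amplitude, and the lattice-to-physical unit calibration.
#'
#' The two control parameters of the study are `E_sn`, the interfacial
#' energy of a normal-senescent contact edge (more negative = stickier),
#' and `V_target_sen_um2`, the target area of the senescent cell in
#' square microns.  All remaining values default to the fixed set used
#' throughout: \eqn{\lambda_{area} = \lambda_{perimeter} = 1},
#' \eqn{A_{target} = 100} sites, shape factor 0.9, \eqn{E_{nn} = -65},
#' cell-medium and medium-medium energies 0, \eqn{S = 2.8} for normal
#' cells and 0 for senescent cells, \eqn{\tau = 4} MCS, \eqn{T = 10}.
#'
#' Unit calibration: a normal cell of 100 lattice sites corresponds to a
#' target area of 3600 um^2, i.e. 36 um^2 per site and a 6 um lattice
#' constant; one Monte Carlo step (MCS) corresponds to 2 minutes.
#' Perimeter targets are expressed as a shape factor: the target edge
#' count is `perimeter_shape_factor` times the von Neumann boundary edge
#' count of the lattice disk of the cell's target area, which makes the
#' senescent perimeter target proportional to the square root of its
#' target area.
#'
#' @param E_sn interfacial energy of a normal-senescent edge
#'   (dimensionless, typically in `[-65, 0]`).
#' @param V_target_sen_um2 senescent-cell target area in um^2.
#' @param lambda_area,lambda_perimeter constraint strengths (>= 0).
#' @param area_target_normal normal-cell target area in lattice sites.
#' @param perimeter_shape_factor dimensionless factor applied to the
#'   lattice-disk perimeter of the target area to obtain the perimeter
#'   target (reported shape parameter 0.9 for both phenotypes).
#' @param E_nn normal-normal interfacial energy.
#' @param E_ss senescent-senescent interfacial energy; defaults to
#'   `E_nn` (senescent-senescent contacts are rare in all scenarios).
#' @param E_nm,E_sm,E_mm cell-medium and medium-medium energies.
#' @param S_normal,S_sen persistence (self-propulsion) strengths.
#' @param tau_memory polarity memory time in MCS (>= 1).
#' @param temperature membrane-fluctuation amplitude `T` (> 0).
#' @param mcs_to_min minutes per MCS.
#' @param site_to_um microns per lattice-site edge.
#'
#' @return An object of class `cpm_params` (a named list) with derived
#'   fields `area_target_sen` (sites), `perimeter_target_normal` and
#'   `perimeter_target_sen` (edge counts), and `um2_per_site`.
#' @examples
#' p <- cpm_params(E_sn = -20, V_target_sen_um2 = 3.4e4)
#' p$area_target_sen   # 34000 / 36, rounded
#' @export
cpm_params <- function(E_sn = -20,
                       V_target_sen_um2 = 3.4e4,
                       lambda_area = 1,
                       lambda_perimeter = 1,
                       area_target_normal = 100,
                       perimeter_shape_factor = 0.9,
                       E_nn = -65,
                       E_ss = E_nn,
                       E_nm = 0,
                       E_sm = 0,
                       E_mm = 0,
                       S_normal = 2.8,
                       S_sen = 0,
                       tau_memory = 4,
                       temperature = 10,
                       mcs_to_min = 2,
                       site_to_um = 6) {
  stopifnot(lambda_area >= 0, lambda_perimeter >= 0,
            temperature > 0, tau_memory >= 1,
            area_target_normal > 0, V_target_sen_um2 > 0,
            perimeter_shape_factor > 0, site_to_um > 0, mcs_to_min > 0)
  if (S_sen != 0)
    stop("S_sen must be 0: senescent cells have no self-propulsion")
  um2_per_site <- site_to_um^2
  area_target_sen <- max(1L, as.integer(round(V_target_sen_um2 / um2_per_site)))
  p <- structure(list(
    E_sn = E_sn, V_target_sen_um2 = V_target_sen_um2,
    lambda_area = lambda_area, lambda_perimeter = lambda_perimeter,
    area_target_normal = as.integer(area_target_normal),
    perimeter_shape_factor = perimeter_shape_factor,
    E_nn = E_nn, E_ss = E_ss, E_nm = E_nm, E_sm = E_sm, E_mm = E_mm,
    S_normal = S_normal, S_sen = S_sen,
    tau_memory = tau_memory, temperature = temperature,
    mcs_to_min = mcs_to_min, site_to_um = site_to_um,
    um2_per_site = um2_per_site,
    area_target_sen = area_target_sen,
    perimeter_target_normal =
      perimeter_shape_factor * disk_perimeter_edges(area_target_normal),
    perimeter_target_sen =
      perimeter_shape_factor * disk_perimeter_edges(area_target_sen)
  ), class = "cpm_params")
  p
}

#' @export
print.cpm_params <- function(x, ...) {
  cat("CPM parameters\n")
  cat(sprintf("  E_sn = %g, E_nn = %g, T = %g, tau = %g MCS\n",
              x$E_sn, x$E_nn, x$temperature, x$tau_memory))
  cat(sprintf("  targets: normal A = %d sites (P* = %.1f), senescent A = %d sites (P* = %.1f)\n",
              x$area_target_normal, x$perimeter_target_normal,
              x$area_target_sen, x$perimeter_target_sen))
  cat(sprintf("  S_normal = %g; calibration: %g min/MCS, %g um/site\n",
              x$S_normal, x$mcs_to_min, x$site_to_um))
  invisible(x)
}

#' Adhesion-energy lookup matrix by phenotype
#'
#' Returns the symmetric 3x3 matrix of interfacial energies indexed by
#' phenotype code (1 medium, 2 normal, 3 senescent in R indexing).
#'
#' @param params a [cpm_params()] object.
#' @return numeric 3x3 matrix.
#' @export
adhesion_matrix <- function(params) {
  E <- matrix(0, 3, 3)
  E[1, 1] <- params$E_mm
  E[1, 2] <- E[2, 1] <- params$E_nm
  E[1, 3] <- E[3, 1] <- params$E_sm
  E[2, 2] <- params$E_nn
  E[2, 3] <- E[3, 2] <- params$E_sn
  E[3, 3] <- params$E_ss
  E
}

# phenotype string <-> integer code (0 medium, 1 normal, 2 senescent)
phenotype_code <- function(phenotype) {
  code <- c(medium = 0L, normal = 1L, senescent = 2L)[phenotype]
  if (anyNA(code)) stop("unknown phenotype: ",
                        paste(unique(phenotype[is.na(code)]), collapse = ", "))
  unname(code)
}

phenotype_label <- function(code) {
  c("medium", "normal", "senescent")[code + 1L]
}
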