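# Plain-TSV particle metadata tables: the defocus/orientation parameters an
# upstream CTF-fitting program provides, one header row naming columns.

.pt_required <- c("stack_index", "defocus_A", "diameter_A", "pixel_size_A",
                  "euler_phi_rad", "euler_theta_rad", "euler_psi_rad")
.pt_optional <- c("voltage_kev", "cs_A", "amp_contrast", "wavelength_A")

#' Read a particle table
#'
#' Tab-separated with a header row. Required columns: `stack_index`,
#' `defocus_A` (or `defocus_um`, converted to Angstrom), `diameter_A`,
#' `pixel_size_A`, and the ZYZ Euler angles `euler_phi_rad`,
#' `euler_theta_rad`, `euler_psi_rad` in radians. Optional: `voltage_kev`,
#' `cs_A`, `amp_contrast`, `wavelength_A`. Physical quantities must be
#' positive and stack indices unique.
#'
#' @param path TSV file path.
#' @return data.frame with defocus stored in Angstrom.
#' @export
read_particle_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  if ("defocus_um" %in% names(tab) && !"defocus_A" %in% names(tab)) {
    tab$defocus_A <- tab$defocus_um * 1e4
    tab$defocus_um <- NULL
  }
  missing_cols <- setdiff(.pt_required, names(tab))
  if (length(missing_cols))
    stop("particle table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_particle_table(tab)
  tab
}

#' Write a particle table
#'
#' @param table data.frame as returned by [read_particle_table()] or built
#'   by [simulate_dataset()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(table, path) {
  validate_particle_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_particle_table <- function(tab) {
  for (col in c("defocus_A", "diameter_A", "pixel_size_A")) {
    if (!col %in% names(tab)) next
    if (any(!is.finite(tab[[col]])) || any(tab[[col]] <= 0))
      stop("column ", col, " must be positive and finite")
  }
  if (anyDuplicated(tab$stack_index))
    stop("stack_index values must be unique")
  invisible(TRUE)
}

#' Optical models from a particle table
#'
#' Builds one [optical_model] per table row.
#'
#' @param tab particle table data.frame (see [read_particle_table()]).
#' @return list of [optical_model] objects.
#' @export
particle_models <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    optical_model(
      voltage_kev = if ("voltage_kev" %in% names(tab) &&
                        is.finite(tab$voltage_kev[i])) tab$voltage_kev[i],
      defocus = tab$defocus_A[i],
      cs = if ("cs_A" %in% names(tab)) tab$cs_A[i] else 0,
      amp_contrast = if ("amp_contrast" %in% names(tab))
        tab$amp_contrast[i] else NULL,
      wavelength = if ("wavelength_A" %in% names(tab) &&
                       is.finite(tab$wavelength_A[i])) tab$wavelength_A[i])
  })
}

#' Rotation matrices from a particle table
#'
#' @param tab particle table data.frame (see [read_particle_table()]).
#' @return list of 3x3 rotation matrices.
#' @export
particle_rotations <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i)
    euler_to_matrix(tab$euler_phi_rad[i], tab$euler_theta_rad[i],
                    tab$euler_psi_rad[i]))
}
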