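#' Built-in table of linear attenuation coefficients
#'
#' Nominal linear attenuation coefficients (1/mm) for the six materials used
#' in the breast phantoms, tabulated on a coarse diagnostic-energy grid.
#' Values are rounded composites from standard tissue attenuation
#' compilations (NIST-style mass attenuation times nominal densities); they
#' are deliberately documented as nominal and can be replaced wholesale via
#' [read_material_table()]. The ordering adipose < fibroglandular <= lesion
#' holds at every tabulated energy, which is what the downstream contrast
#' behaviour relies on; ligament and skin track fibroglandular tissue.
#'
#' @return A `material_table`: data frame with columns `material`,
#'   `energy_keV`, `mu_per_mm`.
#' @export
default_material_table <- function() {
  energies <- c(15, 20, 25, 30, 40)
  tab <- rbind(
    data.frame(material = "air", energy_keV = energies,
               mu_per_mm = c(1.9e-6, 9.4e-7, 6.1e-7, 4.4e-7, 3.0e-7)),
    data.frame(material = "adipose", energy_keV = energies,
               mu_per_mm = c(0.1010, 0.0546, 0.0379, 0.0305, 0.0245)),
    data.frame(material = "fibroglandular", energy_keV = energies,
               mu_per_mm = c(0.1650, 0.0802, 0.0500, 0.0377, 0.0278)),
    data.frame(material = "ligament", energy_keV = energies,
               mu_per_mm = c(0.1650, 0.0802, 0.0500, 0.0377, 0.0278)),
    data.frame(material = "skin", energy_keV = energies,
               mu_per_mm = c(0.1710, 0.0830, 0.0519, 0.0390, 0.0287)),
    data.frame(material = "lesion", energy_keV = energies,
               mu_per_mm = c(0.1810, 0.0885, 0.0556, 0.0417, 0.0303))
  )
  as_material_table(tab)
}

#' Validate and class a material attenuation table
#'
#' @param x data frame with columns `material`, `energy_keV`, `mu_per_mm`.
#' @return The validated `material_table`.
#' @export
as_material_table <- function(x) {
  .assert(is.data.frame(x) &&
            all(c("material", "energy_keV", "mu_per_mm") %in% names(x)),
          "material table needs columns material, energy_keV, mu_per_mm")
  .assert(all(x$mu_per_mm >= 0), "attenuation coefficients must be >= 0")
  need <- names(.MATERIALS)
  .assert(all(need %in% x$material),
          paste("material table must cover:", paste(need, collapse = ", ")))
  air <- x$mu_per_mm[x$material == "air"]
  .assert(all(air < 1e-4), "mu(air) must be negligible")
  for (e in unique(x$energy_keV)) {
    sub <- x[x$energy_keV == e, ]
    mu_les <- sub$mu_per_mm[sub$material == "lesion"]
    mu_fib <- sub$mu_per_mm[sub$material == "fibroglandular"]
    .assert(length(mu_les) == 0 || length(mu_fib) == 0 || mu_les >= mu_fib,
            "lesion attenuation must be >= fibroglandular at all energies")
  }
  structure(x, class = c("material_table", "data.frame"))
}

#' Look up attenuation coefficients by material code at given energies
#'
#' Linear interpolation on the tabulated energy grid; energies outside the
#' grid are clamped to the nearest tabulated value.
#'
#' @param materials a `material_table`.
#' @param energies_keV numeric vector of energies.
#' @return Matrix `[n_materials x n_energies]` of mu (1/mm), rows ordered by
#'   the internal material codes (air, adipose, fibroglandular, ligament,
#'   skin, lesion).
#' @export
mu_matrix <- function(materials, energies_keV) {
  mats <- names(.MATERIALS)
  out <- matrix(0, nrow = length(mats), ncol = length(energies_keV),
                dimnames = list(mats, NULL))
  for (m in mats) {
    sub <- materials[materials$material == m, ]
    sub <- sub[order(sub$energy_keV), ]
    out[m, ] <- stats::approx(sub$energy_keV, sub$mu_per_mm,
                              xout = energies_keV, rule = 2)$y
  }
  out
}

#' Read / write a material table as CSV
#' @param path file path.
#' @return `read_material_table` returns a `material_table`;
#'   `write_material_table` returns `path` invisibly.
#' @export
read_material_table <- function(path) {
  as_material_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_material_table
#' @param materials a `material_table` to write.
#' @export
write_material_table <- function(materials, path) {
  utils::write.csv(as.data.frame(materials), path, row.names = FALSE)
  invisible(path)
}
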