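#' The default eight-ion nutrient panel
#'
#' The ions tracked by the sensing pipeline: six with a dedicated
#' ion-selective electrode (nitrate, ammonium, potassium, calcium, sodium,
#' chloride) and two inferred by sensor fusion (dihydrogen phosphate,
#' magnesium).
#'
#' @return a data.frame with columns `ion`, `charge` (signed integer valence),
#'   `molar_mass` (g/mol) and `has_electrode`.
#' @examples
#' ion_panel()
#' @export
ion_panel <- function() {
  data.frame(
    ion           = c("NO3", "NH4", "K", "Ca", "Na", "Cl", "H2PO4", "Mg"),
    charge        = c(-1L, 1L, 1L, 2L, 1L, -1L, -1L, 2L),
    molar_mass    = c(62.00, 18.04, 39.10, 40.08, 22.99, 35.45, 96.99, 24.31),
    has_electrode = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Names of the eight ions in panel order
#' @return character vector of length 8.
#' @export
ion_names <- function() ion_panel()$ion

#' Names of the six ions with a dedicated electrode
#' @return character vector of length 6.
#' @export
ise_ions <- function() {
  p <- ion_panel()
  p$ion[p$has_electrode]
}

#' Names of the eight measurement channels in record order
#'
#' Six ISE potentials, the pH transducer and the conductivity channel; this
#' ordering is fixed throughout the package (records, CSV schema, features).
#'
#' @return character vector of length 8.
#' @export
channel_names <- function() c(ise_ions(), "pH", "EC")

ion_charge <- function(ion) {
  p <- ion_panel()
  ch <- p$charge[match(ion, p$ion)]
  if (anyNA(ch)) stop_input("unknown ion: ", paste(ion[is.na(ch)], collapse = ", "))
  ch
}

ion_molar_mass <- function(ion) {
  p <- ion_panel()
  m <- p$molar_mass[match(ion, p$ion)]
  if (anyNA(m)) stop_input("unknown ion: ", paste(ion[is.na(m)], collapse = ", "))
  m
}
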