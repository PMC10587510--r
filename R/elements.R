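#' The 29-element ICP-MS panel
#'
#' Element symbols of the multi-element panel measured on every tobacco
#' compartment. Any other symbol in an input table is rejected by the
#' readers rather than silently carried along.
#'
#' @format Character vector of 29 element symbols.
#' @export
hookah_elements <- c(
  "Al", "As", "B", "Ba", "Ca", "Cd", "Ce", "Co", "Cr", "Cu",
  "Fe", "Hg", "K", "Mg", "Mn", "Mo", "Na", "Ni", "P", "Pb",
  "S", "Sb", "Se", "Si", "Sn", "Sr", "Ti", "V", "Zn"
)

#' The five main (bulk) elements
#'
#' Ca, K, Na, Mg and P dominate tobacco's mineral mass; composition shares
#' are reported as the percentage these five contribute to the panel total.
#'
#' @format Character vector of 5 element symbols.
#' @export
main_elements <- c("Ca", "K", "Na", "Mg", "P")

compartments <- c("raw", "ash", "water")

solid_compartments <- c("raw", "ash")
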