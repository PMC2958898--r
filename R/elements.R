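# Periodic-table lookups used by geometry perception.
# Only block membership and (for the p-block) the period are needed.

.SBLOCK <- c("H", "He", "Li", "Be", "Na", "Mg", "K", "Ca", "Rb", "Sr",
             "Cs", "Ba", "Fr", "Ra")

.PBLOCK <- list(
  `2` = c("B", "C", "N", "O", "F", "Ne"),
  `3` = c("Al", "Si", "P", "S", "Cl", "Ar"),
  `4` = c("Ga", "Ge", "As", "Se", "Br", "Kr"),
  `5` = c("In", "Sn", "Sb", "Te", "I", "Xe"),
  `6` = c("Tl", "Pb", "Bi", "Po", "At", "Rn")
)

.DBLOCK <- c("Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
             "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
             "La", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
             "Ac", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds", "Rg", "Cn")

.FBLOCK <- c("Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho",
             "Er", "Tm", "Yb", "Lu", "Th", "Pa", "U", "Np", "Pu", "Am",
             "Cm", "Bk", "Cf", "Es", "Fm", "Md", "No", "Lr")

#' Periodic block of an element symbol
#'
#' @param element Atomic symbol (case sensitive, e.g. `"Fe"`).
#' @return One of `"s"`, `"p"`, `"d"`, `"f"`, or `NA` for symbols that are not
#'   elements (abbreviations, Markush labels, `"*"` guide placeholders).
#' @keywords internal
element_block <- function(element) {
  if (element %in% .SBLOCK) return("s")
  if (element %in% unlist(.PBLOCK)) return("p")
  if (element %in% .DBLOCK) return("d")
  if (element %in% .FBLOCK) return("f")
  NA_character_
}

# Period of a p-block element (NA otherwise).
pblock_period <- function(element) {
  for (p in names(.PBLOCK)) if (element %in% .PBLOCK[[p]]) return(as.integer(p))
  NA_integer_
}

is_real_element <- function(element) !is.na(element_block(element))
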