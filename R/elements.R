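# Element bookkeeping: symbols, nuclear charges and covalent radii (Angstrom,
# used only by the auto-molecule fragment detection).

.elements <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  Z = 1:18,
  covalent_radius = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57,
                      0.58, 1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06),
  stringsAsFactors = FALSE
)

element_number <- function(symbol) {
  i <- match(symbol, .elements$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .elements$Z[i]
}

element_covalent_radius <- function(symbol) {
  .elements$covalent_radius[match(symbol, .elements$symbol)]
}
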