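# Built-in Gaussian basis sets (exponents and contraction coefficients for
# normalized primitives). Shells are (l, exponents, coefficients); sp shells
# of the Pople sets are stored as separate s and p entries sharing exponents.

.basis_library <- list(
  "sto-3g" = list(
    H = list(
      list(l = 0L,
           exps = c(3.42525091, 0.62391373, 0.16885540),
           coefs = c(0.15432897, 0.53532814, 0.44463454))
    ),
    O = list(
      list(l = 0L,
           exps = c(130.7093200, 23.8088610, 6.4436083),
           coefs = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0L,
           exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1L,
           exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    ),
    Ne = list(
      list(l = 0L,
           exps = c(207.0156100, 37.7081510, 10.2052970),
           coefs = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0L,
           exps = c(8.2463151, 1.9162662, 0.6232293),
           coefs = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1L,
           exps = c(8.2463151, 1.9162662, 0.6232293),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    )
  ),
  "6-31g" = list(
    H = list(
      list(l = 0L,
           exps = c(18.7311370, 2.8253937, 0.6401217),
           coefs = c(0.03349460, 0.23472695, 0.81375733)),
      list(l = 0L, exps = 0.1612778, coefs = 1.0)
    ),
    O = list(
      list(l = 0L,
           exps = c(5484.6717, 825.23495, 188.04696, 52.964500, 16.897570,
                    5.7996353),
           coefs = c(0.0018311, 0.0139501, 0.0684451, 0.2327143, 0.4701930,
                     0.3585209)),
      list(l = 0L,
           exps = c(15.539616, 3.5999336, 1.0137618),
           coefs = c(-0.1107775, -0.1480263, 1.1307670)),
      list(l = 1L,
           exps = c(15.539616, 3.5999336, 1.0137618),
           coefs = c(0.0708743, 0.3397528, 0.7271586)),
      list(l = 0L, exps = 0.2700058, coefs = 1.0),
      list(l = 1L, exps = 0.2700058, coefs = 1.0)
    ),
    Ne = list(
      list(l = 0L,
           exps = c(8425.8515, 1268.5194, 289.62141, 78.465471, 25.594300,
                    8.9014988),
           coefs = c(0.0018843, 0.0143368, 0.0701096, 0.2373732, 0.4730071,
                     0.3484012)),
      list(l = 0L,
           exps = c(23.812610, 5.3993060, 1.5995000),
           coefs = c(-0.1093467, -0.1407810, 1.1277735)),
      list(l = 1L,
           exps = c(23.812610, 5.3993060, 1.5995000),
           coefs = c(0.0836636, 0.3396908, 0.7405713)),
      list(l = 0L, exps = 0.3819260, coefs = 1.0),
      list(l = 1L, exps = 0.3819260, coefs = 1.0)
    )
  )
)

#' Available basis sets
#'
#' @return Character vector of basis-set names understood by [shell_basis()].
#' @export
available_bases <- function() names(.basis_library)

basis_shells_for_element <- function(basis_name, symbol) {
  bn <- tolower(basis_name)
  lib <- .basis_library[[bn]]
  if (is.null(lib)) {
    stop("unknown basis set '", basis_name, "'; available: ",
         paste(available_bases(), collapse = ", "))
  }
  sh <- lib[[symbol]]
  if (is.null(sh)) {
    stop("basis set '", basis_name, "' has no parameters for element ", symbol)
  }
  sh
}
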