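#' Physical constants and unit conversions (atomic units internally)
#'
#' The package works in Hartree atomic units: hbar = m_e = e = 1 and
#' epsilon_0 = 1/(4 pi).  These helpers convert between atomic units and the
#' I/O units used at the user surface (angstrom, cm^-1, fs/ps, amu, nm^3).
#'
#' @name units
#' @examples
#' cm_to_hartree(219474.6313632)  # 1 hartree
#' bohr_to_angstrom(1)
NULL

#' @rdname units
#' @export
HARTREE_PER_CM <- 1 / 219474.6313632

#' @rdname units
#' @export
BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' @rdname units
#' @export
AU_TIME_FS <- 0.02418884254

#' @rdname units
#' @export
ME_PER_AMU <- 1822.888486

#' Vacuum permittivity in Gaussian-flavoured atomic units
#' @rdname units
#' @export
EPSILON0_AU <- 1 / (4 * pi)

#' @param x numeric value(s) to convert
#' @rdname units
#' @export
cm_to_hartree <- function(x) x * HARTREE_PER_CM

#' @rdname units
#' @export
hartree_to_cm <- function(x) x / HARTREE_PER_CM

#' @rdname units
#' @export
angstrom_to_bohr <- function(x) x * BOHR_PER_ANGSTROM

#' @rdname units
#' @export
bohr_to_angstrom <- function(x) x / BOHR_PER_ANGSTROM

#' @rdname units
#' @export
fs_to_au <- function(x) x / AU_TIME_FS

#' @rdname units
#' @export
au_to_fs <- function(x) x * AU_TIME_FS

#' @rdname units
#' @export
ps_to_au <- function(x) x * 1000 / AU_TIME_FS

#' @rdname units
#' @export
au_to_ps <- function(x) x * AU_TIME_FS / 1000

#' @rdname units
#' @export
amu_to_me <- function(x) x * ME_PER_AMU

#' @rdname units
#' @export
bohr3_to_nm3 <- function(x) x * (0.0529177210903)^3

#' @rdname units
#' @export
nm3_to_bohr3 <- function(x) x / (0.0529177210903)^3

# standard atomic weights (amu) for the elements the package handles
.atomic_weights <- c(H = 1.008, D = 2.014, O = 15.999, C = 12.011,
                     N = 14.007)

atomic_mass_me <- function(symbols) {
  w <- .atomic_weights[symbols]
  if (anyNA(w))
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(w)]), collapse = ", "))
  unname(w) * ME_PER_AMU
}
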