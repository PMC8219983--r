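# Nearest-neighbor free-energy parameters at 37 C (kcal/mol), Turner 2004 set
# (Mathews et al. 2004, J Mol Biol; as distributed with ViennaRNA).
# Pair order throughout: CG, GC, GU, UG, AU, UA.

.pair_names <- c("CG", "GC", "GU", "UG", "AU", "UA")

.stack37 <- matrix(c(
  # CG     GC     GU     UG     AU     UA
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,  # CG
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,  # GC
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,  # GU
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,  # UG
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,  # AU
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30   # UA
), nrow = 6, byrow = TRUE, dimnames = list(.pair_names, .pair_names))

# loop initiation energies, sizes 1..30 (Inf = disallowed)
.hairpin37 <- c(Inf, Inf, 5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40, 6.50,
                6.60, 6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10, 7.20, 7.20,
                7.30, 7.30, 7.40, 7.40, 7.50, 7.50, 7.50, 7.60, 7.60, 7.70)

.bulge37 <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80, 4.90,
              5.00, 5.10, 5.20, 5.30, 5.40, 5.40, 5.50, 5.50, 5.60, 5.70,
              5.70, 5.80, 5.80, 5.80, 5.90, 5.90, 6.00, 6.00, 6.00, 6.10)

.interior37 <- c(Inf, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40, 2.50,
                 2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10, 3.20, 3.30,
                 3.30, 3.40, 3.40, 3.50, 3.50, 3.50, 3.60, 3.60, 3.70, 3.70)

# terminal mismatch of hairpin loops: [closing pair, first loop base (5'),
# last loop base (3')]; bases ordered A, C, G, U
.mismatch_hairpin37 <- local({
  b <- c("A", "C", "G", "U")
  arr <- array(0, dim = c(6, 4, 4), dimnames = list(.pair_names, b, b))
  arr["CG", , ] <- matrix(c(
    -1.50, -1.50, -1.40, -1.50,
    -1.00, -1.10, -1.00, -0.80,
    -2.30, -1.50, -2.40, -1.50,
    -1.00, -1.40, -1.00, -2.10), 4, 4, byrow = TRUE)
  arr["GC", , ] <- matrix(c(
    -1.10, -1.50, -1.30, -1.50,
    -1.10, -0.70, -1.10, -0.50,
    -2.50, -1.50, -2.20, -1.50,
    -1.10, -1.00, -1.10, -1.60), 4, 4, byrow = TRUE)
  arr["GU", , ] <- matrix(c(
     0.20, -0.50, -0.30, -0.50,
    -0.10, -0.20, -0.10, -0.20,
    -1.00, -0.50, -1.10, -0.50,
    -0.10, -0.30, -0.10, -1.00), 4, 4, byrow = TRUE)
  arr["UG", , ] <- matrix(c(
    -0.50, -0.30, -0.60, -0.30,
    -0.20, -0.10, -0.20,  0.00,
    -0.90, -0.30, -1.10, -0.30,
    -0.20, -0.10, -0.20, -0.90), 4, 4, byrow = TRUE)
  arr["AU", , ] <- matrix(c(
    -0.30, -0.50, -0.30, -0.50,
    -0.10, -0.20, -0.10, -0.20,
    -1.20, -0.50, -1.10, -0.50,
    -0.10, -0.30, -0.10, -1.20), 4, 4, byrow = TRUE)
  arr["UA", , ] <- matrix(c(
    -0.50, -0.30, -0.50, -0.30,
    -0.20, -0.10, -0.20,  0.00,
    -1.50, -0.30, -1.50, -0.30,
    -0.20, -0.10, -0.20, -0.90), 4, 4, byrow = TRUE)
  arr
})

#' Free-energy parameter set of the internal folding backend
#'
#' Returns the nearest-neighbor parameters (Turner 2004 set, 37 C, kcal/mol)
#' used by the internal single-hairpin folder: base-pair stacking, hairpin /
#' bulge / interior loop initiation, hairpin terminal mismatches, loop
#' asymmetry (NINIO) and the AU/GU helix-end penalty. Special tetraloop
#' bonuses and the tabulated small interior loops are not included; interior
#' and bulge loops use the generic initiation plus asymmetry terms.
#'
#' @param max_intloop maximum combined number of unpaired bases allowed in a
#'   single bulge or interior loop within a stem.
#' @return a named list of parameter tables, suitable for [fold_candidate()].
#' @export
slofe_energy_params <- function(max_intloop = 10L) {
  list(
    stack = .stack37,
    hp_init = .hairpin37,
    hp_mm = as.numeric(aperm(.mismatch_hairpin37, c(3, 2, 1))),
    bulge = .bulge37,
    interior = .interior37,
    ninio_m = 0.60,
    ninio_max = 3.00,
    term_au = 0.50,
    lxc = 1.07856,
    max_intloop = as.integer(max_intloop)
  )
}
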