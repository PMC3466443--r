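# Atomic property tables for the supported heavy elements. Implicit
# hydrogens are never graph atoms; their mass and electronegativity enter
# through the implicit-H count where needed.

.ELEMENTS <- data.frame(
  symbol  = c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  number  = c(5L, 6L, 7L, 8L, 9L, 14L, 15L, 16L, 17L, 35L, 53L),
  mass    = c(10.811, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974,
              32.06, 35.453, 79.904, 126.904),
  # Pauling electronegativity
  en      = c(2.04, 2.55, 3.04, 3.44, 3.98, 1.90, 2.19, 2.58, 3.16, 2.96, 2.66),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

.H_MASS <- 1.008
.H_EN <- 2.20

# standard valences; multi-valent elements list all allowed states
.VALENCES <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

# elements writable without brackets in SMILES
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMS <- c("B", "C", "N", "O", "P", "S")

.atomicNumber <- function(symbol) {
  n <- .ELEMENTS[symbol, "number"]
  if (anyNA(n)) {
    bad <- unique(symbol[is.na(n)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n
}
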