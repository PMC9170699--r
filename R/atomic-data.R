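# Elemental constants used throughout the package.
#
# Atomic weights: IUPAC 2021 conventional values (g/mol).
# K-shell binding energies in keV (X-ray absorption K edges).

.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, Si = 28.085,
  Ti = 47.867, W = 183.84, Hf = 178.486, Au = 196.967
)

.atomic_numbers <- c(
  H = 1, C = 6, N = 7, O = 8, Si = 14, Ti = 22, W = 74, Hf = 72, Au = 79
)

.k_edges_keV <- c(
  H = 0.0136, C = 0.284, N = 0.410, O = 0.543, Si = 1.839,
  Ti = 4.966, W = 69.525, Hf = 65.351, Au = 80.725
)

# L3 edges (keV); effectively zero for the light elements.
.l3_edges_keV <- c(
  H = 0, C = 0, N = 0, O = 0.041, Si = 0.099,
  Ti = 0.456, W = 10.207, Hf = 9.561, Au = 11.919
)

atomic_weight <- function(element) {
  w <- .atomic_weights[element]
  if (any(is.na(w)))
    stop_domain("unknown element symbol(s): ",
                paste(element[is.na(w)], collapse = ", "))
  unname(w)
}

atomic_number <- function(element) {
  z <- .atomic_numbers[element]
  if (any(is.na(z)))
    stop_domain("unknown element symbol(s): ",
                paste(element[is.na(z)], collapse = ", "))
  unname(z)
}

k_edge_keV <- function(element) {
  e <- .k_edges_keV[element]
  if (any(is.na(e)))
    stop_domain("unknown element symbol(s): ",
                paste(element[is.na(e)], collapse = ", "))
  unname(e)
}
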