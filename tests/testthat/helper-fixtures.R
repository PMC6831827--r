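# Shared fixtures, built in code. The assembled dimer and the packaged
# sequences are memoized because many tests reuse them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.cache[[key]])) .cache[[key]] <- fn()
  .cache[[key]]
}

fixture_seqs <- function() memo("seqs", fixture_sequences)

fixture_dimer <- function() memo("dimer", assemble_rh1_lzi_dimer)

# compact globular bead cloud: residue-density grid filling a sphere
make_globule <- function(radius = 20, spacing = 5.1) {
  g <- as.matrix(expand.grid(x = seq(-radius, radius, spacing),
                             y = seq(-radius, radius, spacing),
                             z = seq(-radius, radius, spacing)))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  new_protein_model(data.frame(chain = "A", resno = seq_len(nrow(g)),
                               res = "A", x = g[, 1], y = g[, 2], z = g[, 3]))
}

two_center_model <- function(d = 20, res = c("A", "A")) {
  new_protein_model(data.frame(chain = "A", resno = c(1L, 5L), res = res,
                               x = 0, y = 0, z = c(0, d)))
}

# analytic solid-sphere intensity on a grid
sphere_curve <- function(R, q) {
  x <- q * R
  saxs_curve(q, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}
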