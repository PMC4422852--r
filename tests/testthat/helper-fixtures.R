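# Shared fixture builders for the test suite.

# residue masses re-derived from atomic composition, independent of the
# package's internal table (atomic monoisotopic masses: H 1.0078250319,
# C 12, N 14.0030740052, O 15.9949146221, S 31.97207069, P 30.97376151)
atom_mass <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069, P = 30.97376151)

compose_mass <- function(counts) {
  sum(atom_mass[names(counts)] * unlist(counts))
}

# glycine residue C2H3NO; alanine residue C3H5NO; water H2O
oracle_gly_residue <- compose_mass(c(C = 2, H = 3, N = 1, O = 1))
oracle_ala_residue <- compose_mass(c(C = 3, H = 5, N = 1, O = 1))
oracle_water <- compose_mass(c(H = 2, O = 1))

# tiny two-atom dumbbell structure with named label
dumbbell <- function(sep = 4, element = "C") {
  structure_from_atoms(element = rep(element, 2),
                       xyz = rbind(c(0, 0, 0), c(sep, 0, 0)),
                       label = "dumbbell")
}

# exact orientation-averaged union area of two equal disks of radius r
# whose centers sit d apart in 3D (quadrature oracle, independent of the
# Monte-Carlo path)
dumbbell_area_oracle <- function(r, d) {
  union_area <- function(s) {
    s <- pmin(s, 2 * r)
    overlap <- 2 * r^2 * acos(s / (2 * r)) - (s / 2) * sqrt(4 * r^2 - s^2)
    2 * pi * r^2 - overlap
  }
  # uniform random axis: cos(theta) uniform on [0,1]
  stats::integrate(function(cth) union_area(d * sqrt(1 - cth^2)),
                   0, 1, rel.tol = 1e-10)$value
}

# coarse "blob" structures for clustering tests.  Because the pipeline
# superposes every structure before clustering, blobs must differ in
# SHAPE, not placement: each blob has its own random base conformation
# (inter-blob spread ~10x the within-blob scatter).
make_blobs <- function(sizes, centers_scale = 100, scatter = 1, seed = 42,
                       n_atoms = 6) {
  set.seed(seed)
  out <- list()
  for (b in seq_along(sizes)) {
    base <- matrix(rnorm(3 * n_atoms, sd = centers_scale / 10), ncol = 3)
    for (i in seq_len(sizes[b])) {
      xyz <- base + matrix(rnorm(3 * n_atoms, sd = scatter), ncol = 3)
      out[[length(out) + 1L]] <- structure_from_atoms(
        element = rep("C", n_atoms), xyz = xyz,
        elety = paste0("C", seq_len(n_atoms)),
        label = sprintf("blob%d_%03d", b, i))
    }
  }
  attr(out, "truth") <- rep(seq_along(sizes), sizes)
  out
}

# standard R6pS4 protonation hypotheses
pattern_salt_bridge <- function(phosphosite = 4L) {
  protonation_pattern(
    "R6+,K11+,K15+,POx-",
    data.frame(index = c(6L, 11L, 15L),
               kind = c("arg_guanidinium", "lys_ammonium", "lys_ammonium")),
    phosphate_state = -1L, phosphosite = phosphosite)
}

pattern_neutral_phosphate <- function(phosphosite = 4L) {
  protonation_pattern(
    "R6+,K15+,POx0",
    data.frame(index = c(6L, 15L),
               kind = c("arg_guanidinium", "lys_ammonium")),
    phosphate_state = 0L, phosphosite = phosphosite)
}
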