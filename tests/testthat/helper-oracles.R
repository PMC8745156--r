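# Independent oracles, deliberately built on different constructions than
# the package (latitude-longitude quadrature instead of the golden spiral,
# quadratic all-pairs blocking instead of neighbor lists).

# equal-area latitude-longitude quadrature on the unit sphere:
# z uniform in (-1, 1) on n_z bands, phi uniform on n_phi angles
latlong_points <- function(n_z, n_phi) {
  z <- (2 * (seq_len(n_z) - 0.5) / n_z) - 1
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  g <- expand.grid(z = z, phi = phi)
  rho <- sqrt(pmax(0, 1 - g$z^2))
  cbind(rho * cos(g$phi), rho * sin(g$phi), g$z)
}

# per-atom solvent-accessible area by brute force
oracle_sasa_atoms <- function(xyz, radii, probe = 1.4, n_z = 100,
                              n_phi = 100) {
  pts <- latlong_points(n_z, n_phi)
  rad <- radii + probe
  n <- nrow(xyz)
  vapply(seq_len(n), function(i) {
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in setdiff(seq_len(n), i)) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rad[j]^2
    }
    4 * pi * rad[i]^2 * mean(free)
  }, numeric(1))
}

# brute-force per-residue delta-ASA interface set on a two-chain complex
oracle_interface <- function(struct, chain_a, chain_b, delta = 1.0,
                             probe = 1.4, n_z = 60, n_phi = 60) {
  at <- struct$atoms
  rad <- unname(struct$radii[at$element])
  xyz <- as.matrix(at[c("x", "y", "z")])
  asa_for <- function(sel) {
    out <- rep(NA_real_, nrow(at))
    out[sel] <- oracle_sasa_atoms(xyz[sel, , drop = FALSE], rad[sel],
                                  probe, n_z, n_phi)
    out
  }
  asa_cplx <- asa_for(seq_len(nrow(at)))
  asa_iso <- ifelse(at$chain %in% chain_a,
                    asa_for(which(at$chain %in% chain_a)),
                    asa_for(which(at$chain %in% chain_b)))
  key <- paste(at$chain, at$resno)
  d <- tapply(asa_iso - asa_cplx, key, sum)
  names(d)[d >= delta]
}

# write a variant_table to a temp TSV and return the path
temp_table <- function(records) {
  path <- tempfile(fileext = ".tsv")
  write_variant_table(records, path)
  path
}
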