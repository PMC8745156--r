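# Deterministic synthetic fixtures: toy structures, toy dimers, simulated
# variant tables, a background type sampler and regulatory-like
# alignments. All generators are pure functions of their configuration
# (identical seeds give identical output); none attempts to model real
# protein energetics or evolution beyond what the pipeline needs.

# idealized alanine heavy-atom template (local frame, Angstrom):
# N-CA 1.46, CA-C 1.52, C-O 1.23, CA-CB 1.53; successive residues are
# translated along x so that C(i)-N(i+1) = 1.33
ala_template <- data.frame(
  atomname = c("N", "CA", "C", "O", "CB"),
  element  = c("N", "C", "C", "O", "C"),
  x = c(0.00, 1.46, 2.98, 3.60, 1.97),
  y = c(0.00, 0.00, 0.00, sqrt(1.23^2 - 0.62^2), -1.40),
  z = c(0.00, 0.00, 0.00, 0.00, 0.55))
residue_spacing <- 4.31  # C(i) at 2.98 + 1.33

#' Toy structures with known surface-area behaviour
#'
#' * `single_atom`: one carbon at the origin (analytic sphere ASA).
#' * `single_residue`: one idealized alanine, 5 heavy atoms.
#' * `tripeptide`: three alanines with the generator's idealized backbone
#'   geometry (N-CA 1.46, CA-C 1.52, C-O 1.23, CA-CB 1.53, peptide C-N
#'   1.33 Angstrom).
#' * `shell`: a central carbon enclosed by `shell_n` carbons on a sphere
#'   of radius `shell_distance`, burying the centre completely for any
#'   probe up to the configured geometry.
#'
#' @param kind One of `single_atom`, `single_residue`, `tripeptide`,
#'   `shell`.
#' @param chain Chain identifier.
#' @param shell_n,shell_distance Shell geometry (60 atoms at 3.5 A).
#' @param radii Radii table for the resulting structure.
#' @return A `protein_structure`.
#' @export
make_toy_structure <- function(kind = c("single_atom", "single_residue",
                                        "tripeptide", "shell"),
                               chain = "A", shell_n = 60,
                               shell_distance = 3.5,
                               radii = default_vdw_radii) {
  kind <- match.arg(kind)
  atoms <- switch(
    kind,
    single_atom = data.frame(
      chain = chain, resno = 1L, resname = "ALA", atomname = "CA",
      element = "C", x = 0, y = 0, z = 0, het = FALSE),
    single_residue = cbind(
      data.frame(chain = chain, resno = 1L, resname = "ALA"),
      ala_template, het = FALSE),
    tripeptide = do.call(rbind, lapply(1:3, function(i) {
      r <- ala_template
      r$x <- r$x + (i - 1) * residue_spacing
      cbind(data.frame(chain = chain, resno = i, resname = "ALA"),
            r, het = FALSE)
    })),
    shell = {
      dirs <- golden_spiral_points(shell_n) * shell_distance
      rbind(
        data.frame(chain = chain, resno = 1L, resname = "ALA",
                   atomname = "CA", element = "C", x = 0, y = 0, z = 0,
                   het = FALSE),
        data.frame(chain = chain, resno = seq_len(shell_n) + 1L,
                   resname = "ALA",
                   atomname = "CA", element = "C",
                   x = dirs[, 1], y = dirs[, 2], z = dirs[, 3],
                   het = FALSE))
    })
  atoms$atomname <- as.character(atoms$atomname)
  protein_structure(atoms, radii = radii)
}

#' Toy homodimer with a controlled contact
#'
#' Two copies of the idealized tripeptide (chains A and B) related by a
#' translation of `contact_offset` along y. At the documented contact
#' value (6 Angstrom) every residue pair is in contact and loses
#' at least 1 Angstrom^2 of ASA; at large offsets the interface is empty.
#'
#' @param contact_offset Translation between the chains (Angstrom), > 0.
#' @param radii Radii table.
#' @return A `protein_structure` with chains A and B.
#' @export
make_toy_dimer <- function(contact_offset = 6, radii = default_vdw_radii) {
  if (contact_offset <= 0) stop("contact_offset must be > 0")
  a <- make_toy_structure("tripeptide", chain = "A", radii = radii)$atoms
  b <- a
  b$chain <- "B"
  b$y <- b$y + contact_offset
  protein_structure(rbind(a, b), radii = radii)
}

#' Simulation configuration
#'
#' @param seed Integer seed; fixed seed means byte-identical output.
#' @param n_variants Number of simulated variants.
#' @param destabilizing_fraction Fraction with a destabilizing ground
#'   truth (0-1).
#' @param interface_fraction Fraction flagged as interaction sites (0-1).
#' @param domain_split Fraction of variants placed in the catalytic
#'   domain; default 41/72, the packaged table's split.
#' @param contact_offset Toy-dimer contact offset (Angstrom).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_variants = 100,
                              destabilizing_fraction = 0.5,
                              interface_fraction = 0.05,
                              domain_split = 41 / 72,
                              contact_offset = 6) {
  fr <- c(destabilizing_fraction, interface_fraction, domain_split)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (n_variants < 0) stop("n_variants must be >= 0")
  if (n_variants == 0 && destabilizing_fraction > 0)
    stop("impossible config: n_variants = 0 with positive fraction")
  structure(list(seed = as.integer(seed),
                 n_variants = as.integer(n_variants),
                 destabilizing_fraction = destabilizing_fraction,
                 interface_fraction = interface_fraction,
                 domain_split = domain_split,
                 contact_offset = contact_offset),
            class = "simulation_config")
}

#' Simulate a variant table with known ground truth
#'
#' Destabilizing variants draw ddG triplets from N(-2, 0.5), resampled
#' until at least two values are <= -1; neutral variants draw from
#' N(0, 0.5), resampled until at most one value is <= -1. The rejection
#' step guarantees exact label recovery by the consensus rule; the
#' distributions are a separability device, not a thermodynamic model.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (a `variant_table`) and `labels` (logical
#'   ground-truth destabilizing flags, same order).
#' @export
simulate_variant_table <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_variants
  if (n == 0)
    return(list(records = new_variant_table(empty_variant_df()),
                labels = logical(0)))
  with_seed(config$seed, {
    n_destab <- round(n * config$destabilizing_fraction)
    labels <- sample(rep(c(TRUE, FALSE), c(n_destab, n - n_destab)))
    n_cat <- round(n * config$domain_split)
    in_cat <- sample(rep(c(TRUE, FALSE), c(n_cat, n - n_cat)))
    pos <- ifelse(in_cat, sample(37:335, n, replace = TRUE),
                  sample(336:644, n, replace = TRUE))
    wt <- sample(aa_alphabet, n, replace = TRUE)
    mut <- vapply(wt, function(w) sample(setdiff(aa_alphabet, w), 1),
                  character(1), USE.NAMES = FALSE)
    draw_triplet <- function(destab) {
      repeat {
        v <- round(rnorm(3, mean = if (destab) -2 else 0, sd = 0.5), 2)
        hits <- sum(v <= -1)
        if ((destab && hits >= 2) || (!destab && hits <= 1)) return(v)
      }
    }
    ddg <- t(vapply(labels, draw_triplet, numeric(3)))
    df <- data.frame(
      wt = wt, pos = pos, mut = mut,
      domain = ifelse(in_cat, "catalytic", "regulatory"),
      effect = "",
      ddg_inps3d = ddg[, 1], ddg_foldx = ddg[, 2],
      ddg_popmusic2 = ddg[, 3],
      interaction = runif(n) < config$interface_fraction,
      rsa_percent = sample(0:100, n, replace = TRUE),
      stringsAsFactors = FALSE)
    list(records = new_variant_table(df), labels = labels)
  })
}

#' Simulate a regulatory-like multiple alignment
#'
#' An ungapped reference row spanning `ref_start .. ref_start + width - 1`
#' (default the regulatory model region 336-566) plus `n_seq - 1` mutated
#' copies: per-column substitution with probability `sub_rate` and
#' deletion (gap) with probability `del_rate`. Optionally a block of
#' insert-like columns (gapped in the reference and in most rows) is
#' spliced in so that match- and insert-column handling is exercised.
#'
#' @param n_seq Number of sequences (default 50).
#' @param ref_start First reference position (default 336).
#' @param width Reference length (default 231, i.e. up to position 566).
#' @param sub_rate,del_rate Per-column substitution / deletion rates.
#' @param insert_width Width of the spliced insert block (0 disables).
#' @param seed Integer seed.
#' @return An `msa` with reference row `"human"`.
#' @export
simulate_msa <- function(n_seq = 50, ref_start = 336, width = 231,
                         sub_rate = 0.1, del_rate = 0.05,
                         insert_width = 3, seed = 1) {
  if (n_seq < 2) stop("n_seq must be >= 2")
  with_seed(seed, {
    ref <- sample(aa_alphabet, width, replace = TRUE)
    rows <- list(human = ref)
    for (s in seq_len(n_seq - 1)) {
      row <- ref
      subst <- runif(width) < sub_rate
      row[subst] <- sample(aa_alphabet, sum(subst), replace = TRUE)
      row[runif(width) < del_rate] <- "-"
      rows[[paste0("seq", s)]] <- row
    }
    ali <- do.call(rbind, rows)
    if (insert_width > 0) {
      at <- floor(width / 2)
      ins <- matrix("-", n_seq, insert_width)
      # a minority of rows carry residues in the insert block, so the
      # block's gap fraction stays above any sensible match threshold
      carriers <- 1 + sample(seq_len(n_seq - 1), max(1, n_seq %/% 5))
      ins[carriers, ] <- sample(aa_alphabet,
                                length(carriers) * insert_width,
                                replace = TRUE)
      ali <- cbind(ali[, seq_len(at), drop = FALSE], ins,
                   ali[, (at + 1):width, drop = FALSE])
    }
    rownames(ali) <- names(rows)
    new_msa(ali, "human", ref_start)
  })
}
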