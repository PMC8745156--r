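# Shrake-Rupley solvent-accessible surface area and derived quantities.
#
# Per-atom ASA = 4*pi*(r + w)^2 * (accessible test points / n_points),
# where the test points are a deterministic golden-section spiral on the
# probe-expanded sphere and a point is accessible iff it lies outside every
# other atom's expanded sphere. Quadrature is evaluated in a canonical
# (centered, principal-axes) frame so the result is invariant under rigid
# motion of the whole structure.

#' Deterministic golden-section spiral points on the unit sphere
#'
#' @param n Number of points (>= 2).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  if (n < 2) stop("n_points must be >= 2")
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- 2 * pi * k * (1 + sqrt(5)) / 2
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Canonical frame: center, rotate onto principal axes with skewness-fixed
# signs, right-handedness enforced through the third axis. Structures that
# differ by a rigid motion map to the same coordinates (up to roundoff),
# making the fixed-orientation quadrature rotation invariant.
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  if (nrow(x) < 3) return(x)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  v2 <- ev$vectors[, 2]
  fix_sign <- function(v) {
    s <- sum((x %*% v)^3)
    if (abs(s) < 1e-9) {
      p <- x %*% v
      s <- p[which.max(abs(p))]
    }
    if (s < 0) -v else v
  }
  v1 <- fix_sign(v1)
  v2 <- fix_sign(v2)
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  x %*% cbind(v1, v2, v3)
}

# candidate neighbor pairs within `cutoff` via a uniform grid (cell list);
# method = "all" is the quadratic reference used in property tests
neighbor_candidates <- function(xyz, cutoff, method = c("cell", "all")) {
  method <- match.arg(method)
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (method == "all" || n <= 300) {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    d2 <- rowSums((xyz[idx[, 1], , drop = FALSE] -
                   xyz[idx[, 2], , drop = FALSE])^2)
    return(idx[d2 < cutoff^2, , drop = FALSE])
  }
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  coord <- do.call(rbind, strsplit(names(buckets), " "))
  storage.mode(coord) <- "integer"
  lut <- setNames(seq_along(buckets), names(buckets))
  out <- vector("list", length(buckets))
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in seq_along(buckets)) {
    nb_keys <- paste(coord[b, 1] + shifts[, 1],
                     coord[b, 2] + shifts[, 2],
                     coord[b, 3] + shifts[, 3])
    nb <- unlist(buckets[lut[nb_keys[nb_keys %in% names(lut)]]],
                 use.names = FALSE)
    i <- buckets[[b]]
    pairs <- expand.grid(i = i, j = nb)
    pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    out[[b]] <- as.matrix(pairs)
  }
  idx <- do.call(rbind, out)
  idx <- idx[!duplicated(paste(idx[, 1], idx[, 2])), , drop = FALSE]
  d2 <- rowSums((xyz[idx[, 1], , drop = FALSE] -
                 xyz[idx[, 2], , drop = FALSE])^2)
  idx[d2 < cutoff^2, , drop = FALSE]
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param struct A `protein_structure`.
#' @param probe_radius Probe (water) radius in Angstrom; default 1.4.
#' @param n_points Test points per atom sphere; default 960.
#' @param neighbor_method `"cell"` (grid neighbor list) or `"all"`
#'   (quadratic all-pairs); both give identical results.
#' @return A `sasa_result`: list with `atom` (data frame `chain`, `resno`,
#'   `resname`, `atomname`, `asa` in Angstrom^2) and `residue` (data frame
#'   `chain`, `resno`, `resname`, `asa`, plus `rsa` once
#'   [relative_accessibility()] has been applied), and the parameters used.
#' @examples
#' s <- make_toy_structure("single_atom")
#' shrake_rupley(s)$atom$asa  # 4*pi*(1.76 + 1.4)^2
#' @export
shrake_rupley <- function(struct, probe_radius = 1.4, n_points = 960,
                          neighbor_method = c("cell", "all")) {
  stopifnot(inherits(struct, "protein_structure"))
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_points < 2) stop("n_points must be >= 2")
  neighbor_method <- match.arg(neighbor_method)

  xyz <- canonical_frame(structure_xyz(struct))
  rad <- structure_radii(struct) + probe_radius
  n <- nrow(xyz)
  sphere <- golden_spiral_points(n_points)

  pairs <- neighbor_candidates(xyz, cutoff = 2 * max(rad),
                               method = neighbor_method)
  # keep only pairs whose expanded spheres actually intersect
  if (nrow(pairs) > 0) {
    d2 <- rowSums((xyz[pairs[, 1], , drop = FALSE] -
                   xyz[pairs[, 2], , drop = FALSE])^2)
    pairs <- pairs[d2 < (rad[pairs[, 1]] + rad[pairs[, 2]])^2, ,
                   drop = FALSE]
  }
  nb <- vector("list", n)
  if (nrow(pairs) > 0) {
    nb_i <- split(pairs[, 2], factor(pairs[, 1], levels = seq_len(n)))
    nb_j <- split(pairs[, 1], factor(pairs[, 2], levels = seq_len(n)))
    nb <- mapply(c, nb_i, nb_j, SIMPLIFY = FALSE)
  } else {
    nb <- rep(list(integer(0)), n)
  }

  asa <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (length(js) == 0) {
      asa[i] <- 4 * pi * rad[i]^2
      next
    }
    pts <- sphere * rad[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in js) {
      if (!any(free)) break
      d2 <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- d2 >= rad[j]^2
    }
    asa[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }

  a <- struct$atoms
  atom <- data.frame(chain = a$chain, resno = a$resno, resname = a$resname,
                     atomname = a$atomname, asa = asa,
                     stringsAsFactors = FALSE)
  key <- paste(a$chain, a$resno)
  first <- !duplicated(key)
  residue <- data.frame(chain = a$chain[first], resno = a$resno[first],
                        resname = a$resname[first],
                        asa = as.numeric(tapply(asa, factor(key, levels = key[first]), sum)),
                        stringsAsFactors = FALSE)
  structure(list(atom = atom, residue = residue,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "sasa_result: %d atoms, %d residues, total ASA %.1f A^2 (probe %.2f, %d points)\n",
    nrow(x$atom), nrow(x$residue), sum(x$atom$asa), x$probe_radius,
    x$n_points))
  invisible(x)
}

#' Relative solvent accessibility
#'
#' RSA = 100 * residue ASA / maximum ASA of that residue type, rounded to
#' the nearest integer and clamped to \[0, 100\].
#'
#' @param sasa A `sasa_result`.
#' @param max_table Named vector, three-letter residue name to maximal
#'   ASA (Angstrom^2); default [max_acc_tien2013].
#' @return The `sasa_result` with an integer `rsa` column added to
#'   `$residue`.
#' @export
relative_accessibility <- function(sasa, max_table = max_acc_tien2013) {
  stopifnot(inherits(sasa, "sasa_result"))
  res <- sasa$residue
  unknown <- setdiff(unique(res$resname), names(max_table))
  if (length(unknown))
    stop("no maximal accessibility for residue type(s): ",
         paste(unknown, collapse = ", "))
  rsa <- round(100 * res$asa / max_table[res$resname])
  sasa$residue$rsa <- as.integer(pmin(100, pmax(0, rsa)))
  sasa
}

#' Classify residues as buried or exposed
#'
#' A residue is exposed when its relative accessibility is at or above the
#' threshold (default 20 percent, inclusive).
#'
#' @param rsa_percent Numeric vector of RSA percentages in \[0, 100\].
#' @param threshold_percent Exposure threshold (default 20).
#' @return Character vector over `c("buried", "exposed")`.
#' @export
classify_exposure <- function(rsa_percent, threshold_percent = 20) {
  if (any(rsa_percent < 0 | rsa_percent > 100))
    stop("rsa_percent outside [0, 100]")
  ifelse(rsa_percent >= threshold_percent, "exposed", "buried")
}

#' Interface residues of a complex by buried surface area
#'
#' A residue belongs to the interface when its absolute ASA decreases by at
#' least `delta_threshold` (default 1 Angstrom^2) in the complex relative
#' to its isolated component; both are evaluated with identical quadrature
#' settings.
#'
#' @param complex A `protein_structure` holding all chains.
#' @param chains_a,chains_b Disjoint chain groups forming the two
#'   components.
#' @param delta_threshold Minimum ASA loss in Angstrom^2 (default 1.0).
#' @param probe_radius,n_points Passed to [shrake_rupley()].
#' @return Data frame `chain`, `resno`, `resname`, `delta_asa` for
#'   interface residues of both components, ordered by chain then residue.
#' @export
interface_residues <- function(complex, chains_a, chains_b,
                               delta_threshold = 1.0, probe_radius = 1.4,
                               n_points = 960) {
  if (length(chains_a) == 0 || length(chains_b) == 0)
    stop("both chain groups must be non-empty")
  if (length(intersect(chains_a, chains_b)))
    stop("chain groups overlap: ",
         paste(intersect(chains_a, chains_b), collapse = ","))
  both <- subset_chains(complex, c(chains_a, chains_b))
  res_cplx <- shrake_rupley(both, probe_radius, n_points)$residue
  iso <- rbind(
    shrake_rupley(subset_chains(complex, chains_a), probe_radius,
                  n_points)$residue,
    shrake_rupley(subset_chains(complex, chains_b), probe_radius,
                  n_points)$residue)
  key <- function(d) paste(d$chain, d$resno)
  m <- match(key(res_cplx), key(iso))
  delta <- iso$asa[m] - res_cplx$asa
  out <- data.frame(chain = res_cplx$chain, resno = res_cplx$resno,
                    resname = res_cplx$resname, delta_asa = delta,
                    stringsAsFactors = FALSE)
  out <- out[out$delta_asa >= delta_threshold, , drop = FALSE]
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-residue accessibility as TSV
#'
#' Columns `chain residue resname asa rsa` (`rsa` is `NA` when
#' [relative_accessibility()] has not been applied).
#'
#' @param sasa A `sasa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sasa_tsv <- function(sasa, path) {
  res <- sasa$residue
  out <- data.frame(chain = res$chain, residue = res$resno,
                    resname = res$resname, asa = sprintf("%.3f", res$asa),
                    rsa = if ("rsa" %in% names(res)) res$rsa else NA,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
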