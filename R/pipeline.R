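# Orchestration: full analysis of a variant table and, optionally, of a
# structure; deterministic machine-readable reports.

default_config <- function() {
  list(ddg_threshold = -1.0, min_votes = 2, exposure_threshold = 20,
       pseudocount = 0.5, delta_asa_threshold = 1.0,
       probe_radius = 1.4, n_points = 960)
}

#' Full analysis of a per-variant annotation table
#'
#' Parses the table, removes duplicated rows, applies the consensus
#' destabilization rule, tabulates exposure (RSA at or above the
#' threshold, default 20 percent) and interaction flags per domain,
#' builds the per-domain variation-type matrices and runs the
#' pseudocount chi-square homogeneity test.
#'
#' @param table_path TSV path (see [parse_variant_table()]); defaults to
#'   the packaged table.
#' @param config Named list overriding entries of the default
#'   configuration: `ddg_threshold` (-1 kcal/mol), `min_votes` (2),
#'   `exposure_threshold` (20 percent), `pseudocount` (0.5).
#' @return An `mthfr_report` list: `n_rows`, `n_unique`,
#'   `duplicates_removed`, `totals`, `destabilizing_counts`,
#'   `destabilizing_fraction`, `destabilizing_interaction` (variant
#'   labels), `exposure` (per domain: exposed, buried,
#'   exposed_not_interaction), `type_counts` (per domain 4x4),
#'   `chi_square` (statistic, df, p_value), `parameters`, `provenance`.
#' @examples
#' rep <- run_table_analysis(mthfr_table1_path())
#' rep$destabilizing_counts
#' @export
run_table_analysis <- function(table_path = mthfr_table1_path(),
                               config = list()) {
  cfg <- modifyList(default_config(), config)
  parsed <- parse_variant_table(table_path)
  dd <- deduplicate_variants(parsed)
  rec <- dd$records
  stab <- destabilizing_counts(rec, threshold = cfg$ddg_threshold,
                               min_votes = cfg$min_votes)

  doms <- c("catalytic", "regulatory")
  exposure <- lapply(setNames(doms, doms), function(d) {
    r <- rec[rec$domain == d, , drop = FALSE]
    ex <- if (nrow(r)) classify_exposure(r$rsa_percent,
                                         cfg$exposure_threshold)
          else character(0)
    list(exposed = sum(ex == "exposed"), buried = sum(ex == "buried"),
         exposed_not_interaction = sum(ex == "exposed" & !r$interaction))
  })

  tm <- lapply(setNames(doms, doms), function(d) type_matrix(rec, d))
  chi <- if (nrow(rec) > 0)
    chi_square_pseudocount(tm$catalytic, tm$regulatory,
                           pseudocount = cfg$pseudocount)
  else list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)

  report <- list(
    n_rows = nrow(parsed),
    n_rows_by_domain = list(
      catalytic = sum(parsed$domain == "catalytic"),
      regulatory = sum(parsed$domain == "regulatory")),
    n_unique = nrow(rec),
    duplicates_removed = dd$removed,
    totals = as.list(stab$totals),
    destabilizing_counts = as.list(stab$counts),
    destabilizing_fraction = if (nrow(rec)) sum(stab$counts) / nrow(rec)
                             else NA_real_,
    destabilizing_variants = variant_labels(stab$destabilizing),
    destabilizing_interaction =
      variant_labels(stab$destabilizing_interaction),
    exposure = exposure,
    type_counts = lapply(tm, function(m)
      apply(unclass(m), 1, as.list)),
    chi_square = chi,
    parameters = cfg[c("ddg_threshold", "min_votes", "exposure_threshold",
                       "pseudocount")],
    provenance = list(
      input = basename(table_path),
      input_md5 = unname(md5sum(table_path)),
      package_version = as.character(utils::packageVersion("mthfrvar"))))
  class(report) <- "mthfr_report"
  report
}

#' @export
print.mthfr_report <- function(x, ...) {
  cat("mthfr_report\n")
  cat(sprintf("  rows: %d (%d unique; removed: %s)\n", x$n_rows,
              x$n_unique,
              if (length(x$duplicates_removed))
                paste(x$duplicates_removed, collapse = ", ") else "none"))
  cat(sprintf("  destabilizing: catalytic %d/%d, regulatory %d/%d (%.1f%%)\n",
              x$destabilizing_counts$catalytic, x$totals$catalytic,
              x$destabilizing_counts$regulatory, x$totals$regulatory,
              100 * x$destabilizing_fraction))
  cat(sprintf("  destabilizing & interaction: %s\n",
              paste(x$destabilizing_interaction, collapse = ", ")))
  cat(sprintf("  chi-square (types, catalytic vs regulatory): X2 = %.2f, df = %d, p = %.4f\n",
              x$chi_square$statistic, x$chi_square$df,
              x$chi_square$p_value))
  invisible(x)
}

#' Structure-level analysis
#'
#' Computes per-residue absolute and relative accessibility for the
#' selected chains and, when two chain groups are given, the interface
#' residue set (ASA loss at or above the delta threshold). When a variant
#' table is supplied, computed RSA values are compared with the printed
#' ones per variant position.
#'
#' @param structure A `protein_structure` or a PDB/mmCIF path.
#' @param chains Chains to analyse (default: all).
#' @param interface Optional list of two chain-group vectors, e.g.
#'   `list("A", "B")`; requires at least two chains.
#' @param records Optional deduplicated `variant_table` for the RSA
#'   comparison (matched on position against the first selected chain).
#' @param config Overrides of `probe_radius`, `n_points`,
#'   `delta_asa_threshold`, `exposure_threshold`.
#' @return List with `residues` (chain, resno, resname, asa, rsa,
#'   exposure), `interface` (data frame or NULL) and `rsa_comparison`
#'   (data frame or NULL: variant, printed and computed RSA, absolute
#'   difference).
#' @export
run_structure_analysis <- function(structure, chains = NULL,
                                   interface = NULL, records = NULL,
                                   config = list()) {
  cfg <- modifyList(default_config(), config)
  if (is.character(structure))
    structure <- read_structure(structure, chains = chains)
  else if (!is.null(chains))
    structure <- subset_chains(structure, chains)
  have_chains <- unique(structure$atoms$chain)

  sasa <- shrake_rupley(structure, probe_radius = cfg$probe_radius,
                        n_points = cfg$n_points)
  sasa <- relative_accessibility(sasa)
  res <- sasa$residue
  res$exposure <- classify_exposure(res$rsa, cfg$exposure_threshold)

  iface <- NULL
  if (!is.null(interface)) {
    if (length(interface) != 2)
      stop("interface must list exactly two chain groups")
    missing_ch <- setdiff(unlist(interface), have_chains)
    if (length(missing_ch))
      stop("interface chain(s) not in structure: ",
           paste(missing_ch, collapse = ","))
    iface <- interface_residues(structure, interface[[1]], interface[[2]],
                                delta_threshold = cfg$delta_asa_threshold,
                                probe_radius = cfg$probe_radius,
                                n_points = cfg$n_points)
  }

  cmp <- NULL
  if (!is.null(records)) {
    first_chain <- sort(have_chains)[1]
    rc <- res[res$chain == first_chain, , drop = FALSE]
    m <- match(records$pos, rc$resno)
    cmp <- data.frame(variant = variant_labels(records),
                      position = records$pos,
                      rsa_printed = records$rsa_percent,
                      rsa_computed = rc$rsa[m],
                      stringsAsFactors = FALSE)
    cmp$abs_diff <- abs(cmp$rsa_printed - cmp$rsa_computed)
  }

  list(residues = res, interface = iface, rsa_comparison = cmp)
}

#' Write a report as deterministic JSON
#'
#' Fixed key order, no timestamps: identical inputs and configuration
#' produce byte-identical files.
#'
#' @param report An `mthfr_report` (or any list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
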