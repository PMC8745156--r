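# Consensus ddG destabilization classifier.
#
# Sign convention: ddG = dG_wt - dG_mut, so negative values mean the
# mutated protein is less stable. A variant is called destabilizing when
# at least `min_votes` of its per-method ddG predictions are at or below
# the threshold (default -1 kcal/mol, inclusive).

#' Consensus destabilization call from a ddG triplet
#'
#' @param ddg Numeric vector of per-method ddG predictions (kcal/mol);
#'   typically the (INPS3D, FoldX, PoPMuSiC2) triplet.
#' @param threshold Vote threshold in kcal/mol (inclusive); default -1.
#' @param min_votes Votes needed for a destabilizing call; default 2.
#' @return A `consensus_call`: list with `destabilizing` (logical),
#'   `votes`, `threshold` and `min_votes`.
#' @examples
#' consensus_call(c(-1.58, -3.74, -1.21))  # destabilizing, 3 votes
#' consensus_call(c(-0.13, -0.79, 0.2))    # not destabilizing
#' @export
consensus_call <- function(ddg, threshold = -1.0, min_votes = 2) {
  ddg <- as.numeric(ddg)
  if (any(!is.finite(ddg))) stop("non-finite ddG value")
  votes <- sum(ddg <= threshold)
  structure(list(destabilizing = votes >= min_votes, votes = votes,
                 threshold = threshold, min_votes = min_votes),
            class = "consensus_call")
}

#' @export
print.consensus_call <- function(x, ...) {
  cat(sprintf("consensus_call: %s (%d/%d votes at ddG <= %g kcal/mol)\n",
              if (x$destabilizing) "destabilizing" else "not destabilizing",
              x$votes, x$min_votes, x$threshold))
  invisible(x)
}

#' Antisymmetric ddG of the reverse variant
#'
#' When the crystal carries the mutant allele (6FCX has A at position 429),
#' the effect of the forward variant is obtained by computing the reverse
#' variant on the crystal and negating every value: ddG(A->B) =
#' -ddG(B->A). The operation is an involution.
#'
#' @param ddg_of_reverse Numeric ddG vector of the reverse variant.
#' @return The negated vector.
#' @export
reverse_variant <- function(ddg_of_reverse) {
  -as.numeric(ddg_of_reverse)
}

#' Per-domain destabilization counts
#'
#' Applies the consensus rule to every record and tabulates by domain.
#' Records must be deduplicated first (see [deduplicate_variants()]);
#' duplicated keys abort.
#'
#' @param records A deduplicated `variant_table`.
#' @inheritParams consensus_call
#' @return List with `counts` (named integer vector, destabilizing
#'   variants per domain), `totals` (variants per domain), `destabilizing`
#'   (the destabilizing subset as a `variant_table` with `votes` column)
#'   and `destabilizing_interaction` (the subset that is also
#'   interaction-flagged).
#' @export
destabilizing_counts <- function(records, threshold = -1.0, min_votes = 2) {
  if (anyDuplicated(paste(records$wt, records$pos, records$mut)))
    stop("records contain duplicates; run deduplicate_variants() first")
  doms <- c("catalytic", "regulatory")
  votes <- if (nrow(records) == 0) integer(0) else
    rowSums(cbind(records$ddg_inps3d, records$ddg_foldx,
                  records$ddg_popmusic2) <= threshold)
  hit <- votes >= min_votes
  sub <- new_variant_table(records[hit, , drop = FALSE])
  sub$votes <- votes[hit]
  list(
    counts = vapply(doms, function(d) sum(hit & records$domain == d),
                    integer(1)),
    totals = vapply(doms, function(d) sum(records$domain == d),
                    integer(1)),
    destabilizing = sub,
    destabilizing_interaction =
      new_variant_table(sub[sub$interaction, , drop = FALSE]))
}

#' Write consensus calls as TSV
#'
#' Columns `variant votes destabilizing`, one row per record.
#'
#' @param records A `variant_table`.
#' @param path Output path.
#' @inheritParams consensus_call
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(records, path, threshold = -1.0,
                                min_votes = 2) {
  votes <- rowSums(cbind(records$ddg_inps3d, records$ddg_foldx,
                         records$ddg_popmusic2) <= threshold)
  out <- data.frame(variant = variant_labels(records), votes = votes,
                    destabilizing = votes >= min_votes)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
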