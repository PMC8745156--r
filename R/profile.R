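# Light profile model of a protein domain from a multiple alignment.
#
# A column is a match column when its gap fraction is at most
# `match_gap_fraction`; emissions are maximum-likelihood frequencies with
# Laplace (+1) pseudocounts; transitions are estimated from the observed
# column-to-column paths. The reference row (the human sequence) gives the
# mapping from sequence positions to match columns. This minimal estimator
# (no Dirichlet mixtures, no sequence weighting) is what the
# architecture-mapping view needs and is fully checkable by hand.

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (via bio3d) and single- or multi-block
#' Stockholm. Gap symbols (`-`, `.`) are normalized to `-`; residues are
#' uppercased. All rows must have equal length.
#'
#' @param path Alignment file.
#' @param format `"auto"` (by extension: `.sto`/`.stk` is Stockholm,
#'   otherwise FASTA), `"fasta"` or `"stockholm"`.
#' @param reference_id Identifier of the reference (human) row; default
#'   the first row.
#' @param ref_start Sequence position of the reference row's first
#'   residue (e.g. 336 for the regulatory-domain alignment).
#' @return An `msa`: list with `ali` (character matrix, rows = sequences),
#'   `ids`, `reference_id` and `ref_start`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm"),
                     reference_id = NULL, ref_start = 1L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(file_ext(path)) %in% c("sto", "stk"))
      "stockholm" else "fasta"
  seqs <- if (format == "stockholm") read_stockholm(path)
          else {
            fa <- Biostrings::readBStringSet(path)
            setNames(as.character(fa), sub("[[:space:]].*$", "", names(fa)))
          }
  if (length(seqs) == 0) stop("no sequences in ", path)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: row '", names(seqs)[which(lens != lens[1])[1]],
         "' has length ", lens[lens != lens[1]][1], ", expected ", lens[1])
  ali <- do.call(rbind, strsplit(toupper(seqs), ""))
  ali[ali == "."] <- "-"
  rownames(ali) <- names(seqs)
  new_msa(ali, reference_id %||% names(seqs)[1], as.integer(ref_start))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_msa <- function(ali, reference_id, ref_start = 1L) {
  if (!reference_id %in% rownames(ali))
    stop("reference row '", reference_id, "' not in alignment")
  structure(list(ali = ali, ids = rownames(ali),
                 reference_id = reference_id,
                 ref_start = as.integer(ref_start)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (reference %s, start %d)\n",
              nrow(x$ali), ncol(x$ali), x$reference_id, x$ref_start))
  invisible(x)
}

# minimal Stockholm reader: data lines "name  aligned-seq", '//' ends the
# file, '#' lines and blank lines are markup; multi-block files are
# concatenated per name
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  seqs <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || grepl("^#", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop("malformed Stockholm line: '", ln, "'")
    nm <- parts[1]
    seqs[nm] <- paste0(if (nm %in% names(seqs)) seqs[nm] else "", parts[2])
  }
  seqs
}

#' Build a profile model from a multiple alignment
#'
#' @param msa An `msa`.
#' @param match_gap_fraction Columns with gap fraction at or below this
#'   value become match columns; default 0.5.
#' @param pseudocount Laplace pseudocount added per residue (emissions)
#'   and per outcome (transitions); default 1.
#' @return A `profile_model`: list with `match_columns` (alignment column
#'   indices), `emissions` (K x 20 matrix of probabilities, rows sum to
#'   1), `transitions` (list per match column 1..K-1 of a 2 x 3 matrix,
#'   source states M/D, outcomes M/D/I, rows sum to 1), `ref_map` (data
#'   frame `position`, `column`, `match_state`; `match_state` is `NA` for
#'   reference residues in insert columns) and the parameters.
#' @export
build_profile <- function(msa, match_gap_fraction = 0.5, pseudocount = 1.0) {
  stopifnot(inherits(msa, "msa"))
  ali <- msa$ali
  gap_frac <- colMeans(ali == "-")
  match_cols <- which(gap_frac <= match_gap_fraction)
  if (length(match_cols) == 0)
    stop("alignment has no match columns at gap fraction <= ",
         match_gap_fraction)
  bad <- setdiff(unique(as.vector(ali)), c(aa_alphabet, "-"))
  if (length(bad))
    stop("non-standard symbol(s) in alignment: ",
         paste(bad, collapse = ", "))

  emis <- t(vapply(match_cols, function(j) {
    obs <- ali[, j]
    counts <- table(factor(obs[obs != "-"], levels = aa_alphabet))
    (as.numeric(counts) + pseudocount) /
      (sum(counts) + 20 * pseudocount)
  }, numeric(20)))
  colnames(emis) <- aa_alphabet

  K <- length(match_cols)
  transitions <- vector("list", max(0, K - 1))
  for (k in seq_len(max(0, K - 1))) {
    j1 <- match_cols[k]
    j2 <- match_cols[k + 1]
    between <- if (j2 - j1 > 1) ali[, (j1 + 1):(j2 - 1), drop = FALSE]
               else NULL
    src <- ifelse(ali[, j1] != "-", "M", "D")
    has_insert <- if (is.null(between)) rep(FALSE, nrow(ali))
                  else rowSums(between != "-") > 0
    outcome <- ifelse(has_insert, "I",
                      ifelse(ali[, j2] != "-", "M", "D"))
    cnt <- table(factor(src, levels = c("M", "D")),
                 factor(outcome, levels = c("M", "D", "I")))
    cnt <- unclass(cnt) + pseudocount
    transitions[[k]] <- cnt / rowSums(cnt)
  }

  ref <- ali[msa$reference_id, ]
  res_cols <- which(ref != "-")
  positions <- msa$ref_start + seq_along(res_cols) - 1L
  ref_map <- data.frame(
    position = positions, column = res_cols,
    match_state = match(res_cols, match_cols))

  structure(list(match_columns = match_cols, emissions = emis,
                 transitions = transitions, ref_map = ref_map,
                 reference_id = msa$reference_id,
                 match_gap_fraction = match_gap_fraction,
                 pseudocount = pseudocount),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  mapped <- sum(!is.na(x$ref_map$match_state))
  cat(sprintf(
    "profile_model: %d match columns; reference %s, positions %d-%d (%d mapped)\n",
    length(x$match_columns), x$reference_id, min(x$ref_map$position),
    max(x$ref_map$position), mapped))
  invisible(x)
}

#' Map variants onto the protein architecture
#'
#' Assigns each variant to a domain model — the catalytic domain
#' represented by its position span, the regulatory domain by a profile
#' model — together with its match column (regulatory only) and its
#' physicochemical variation type. Variants outside both spans, or at
#' reference positions that fall in insert columns, are flagged unmapped.
#'
#' @param records A deduplicated `variant_table`.
#' @param profile_regulatory A `profile_model` of the regulatory domain.
#' @param catalytic_span Two-element integer vector; default `c(1, 335)`.
#' @return Data frame `variant`, `position`, `domain_model`
#'   (`"catalytic"`, `"regulatory"` or `NA`), `match_state`, `type`
#'   (e.g. `"a>c"`), `mapped` (logical).
#' @export
map_variants_to_architecture <- function(records, profile_regulatory,
                                         catalytic_span = c(1L, 335L)) {
  ty <- variation_type(records$wt, records$mut)
  type <- paste0(class_labels[ty$from], ">", class_labels[ty$to])
  rm_ <- profile_regulatory$ref_map
  idx <- match(records$pos, rm_$position)
  in_cat <- records$pos >= catalytic_span[1] & records$pos <= catalytic_span[2]
  match_state <- ifelse(is.na(idx), NA_integer_, rm_$match_state[idx])
  domain_model <- ifelse(in_cat, "catalytic",
                         ifelse(!is.na(idx), "regulatory", NA))
  mapped <- in_cat | (!is.na(idx) & !is.na(match_state))
  data.frame(variant = variant_labels(records), position = records$pos,
             domain_model = domain_model, match_state = match_state,
             type = type, mapped = mapped, stringsAsFactors = FALSE)
}

#' Write a profile model as JSON
#'
#' Layout: `match_columns` (1-based alignment column indices), `emissions`
#' (array per match column of 20 named probabilities), `transitions`
#' (per column, named M/D rows over outcomes M/D/I), `ref_map` (records of
#' position/column/match_state).
#'
#' @param profile A `profile_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(
    reference_id = profile$reference_id,
    match_gap_fraction = profile$match_gap_fraction,
    pseudocount = profile$pseudocount,
    match_columns = profile$match_columns,
    emissions = apply(profile$emissions, 1, as.list),
    transitions = lapply(profile$transitions, function(m)
      apply(m, 1, as.list)),
    ref_map = profile$ref_map)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
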