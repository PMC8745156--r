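# Variant annotation table: parsing, validation, serialization, dedup.

# position of the catalytic/regulatory boundary: last catalytic position
CATALYTIC_LAST <- 335L

table1_columns <- c("variant", "domain", "effect", "ddg_inps3d",
                    "ddg_foldx", "ddg_popmusic2", "ispred4", "rsa_percent")

#' Path to the packaged MTHFR deficiency variant table
#'
#' A transcription of the published annotation of 72 disease-associated
#' MTHFR missense variations: variant, domain (catalytic/regulatory),
#' functional effect when reported, three per-method ddG predictions
#' (INPS3D, FoldX, PoPMuSiC2; kcal/mol), interaction-site call (I/N) and
#' relative solvent accessibility (percent). One variant (M338T) is printed
#' twice in the source table and the transcription preserves the duplicate;
#' use [deduplicate_variants()] before computing statistics.
#'
#' @return Path to the TSV file.
#' @examples
#' vt <- parse_variant_table(mthfr_table1_path())
#' nrow(vt)
#' @export
mthfr_table1_path <- function() {
  system.file("extdata", "mthfr_table1.tsv", package = "mthfrvar",
              mustWork = TRUE)
}

#' Parse a per-variant annotation table
#'
#' Reads a UTF-8 TSV with header columns `variant domain effect ddg_inps3d
#' ddg_foldx ddg_popmusic2 ispred4 rsa_percent`. Variant tokens have the
#' form wild-type letter, 1-based position (UniProt P42898 numbering),
#' mutant letter (e.g. `G387D`). Unicode minus signs are normalized to
#' ASCII hyphens. Rows are returned in file order; duplicated variants are
#' preserved as printed. Parsing is strict: any malformed row aborts with
#' its line number.
#'
#' @param path TSV file path.
#' @return A `variant_table`: a data frame with columns `wt` (character),
#'   `pos` (integer), `mut` (character), `domain` (`"catalytic"` or
#'   `"regulatory"`), `effect` (character, possibly empty), `ddg_inps3d`,
#'   `ddg_foldx`, `ddg_popmusic2` (numeric, kcal/mol), `interaction`
#'   (logical, `I` is `TRUE`) and `rsa_percent` (integer, 0-100).
#' @seealso [deduplicate_variants()], [write_variant_table()]
#' @export
parse_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "", fileEncoding = "UTF-8")
  # normalize unicode minus (U+2212) and non-breaking hyphen
  raw[] <- lapply(raw, function(x) gsub("−|‐", "-", x))
  missing_cols <- setdiff(table1_columns, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  raw <- raw[table1_columns]
  if (nrow(raw) == 0) return(new_variant_table(empty_variant_df()))

  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  problems <- character(0)
  note <- function(i, msg)
    problems <<- c(problems, sprintf("line %d: %s", line[i], msg))

  m <- regmatches(raw$variant,
                  regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", raw$variant))
  wt <- mut <- rep(NA_character_, nrow(raw))
  pos <- rep(NA_integer_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (length(m[[i]]) != 4) {
      note(i, paste0("malformed variant token '", raw$variant[i], "'"))
      next
    }
    wt[i] <- toupper(m[[i]][2])
    pos[i] <- as.integer(m[[i]][3])
    mut[i] <- toupper(m[[i]][4])
    if (!wt[i] %in% aa_alphabet || !mut[i] %in% aa_alphabet)
      note(i, paste0("non-standard residue in '", raw$variant[i], "'"))
    else if (wt[i] == mut[i])
      note(i, paste0("synonymous token '", raw$variant[i], "'"))
  }

  ddg <- lapply(raw[c("ddg_inps3d", "ddg_foldx", "ddg_popmusic2")],
                function(x) suppressWarnings(as.numeric(x)))
  for (nm in names(ddg)) {
    bad <- which(is.na(ddg[[nm]]) | !is.finite(ddg[[nm]]))
    for (i in bad) note(i, paste0("non-numeric ", nm, " value '",
                                  raw[[nm]][i], "'"))
  }

  bad_flag <- which(!raw$ispred4 %in% c("I", "N"))
  for (i in bad_flag)
    note(i, paste0("interaction flag '", raw$ispred4[i],
                   "' not in {I, N}"))

  rsa <- suppressWarnings(as.integer(raw$rsa_percent))
  bad_rsa <- which(is.na(rsa) | rsa < 0 | rsa > 100)
  for (i in bad_rsa)
    note(i, paste0("rsa_percent '", raw$rsa_percent[i],
                   "' not an integer in [0, 100]"))

  bad_dom <- which(!raw$domain %in% c("catalytic", "regulatory"))
  for (i in bad_dom)
    note(i, paste0("domain '", raw$domain[i],
                   "' not catalytic/regulatory"))
  # section label must agree with the position rule (<=335 catalytic)
  ok_dom <- setdiff(seq_len(nrow(raw)), union(bad_dom, which(is.na(pos))))
  for (i in ok_dom) {
    expect <- if (pos[i] <= CATALYTIC_LAST) "catalytic" else "regulatory"
    if (raw$domain[i] != expect)
      note(i, sprintf("domain '%s' inconsistent with position %d (%s)",
                      raw$domain[i], pos[i], expect))
  }

  if (length(problems))
    stop("malformed variant table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  df <- data.frame(
    wt = wt, pos = pos, mut = mut, domain = raw$domain,
    effect = raw$effect,
    ddg_inps3d = ddg$ddg_inps3d, ddg_foldx = ddg$ddg_foldx,
    ddg_popmusic2 = ddg$ddg_popmusic2,
    interaction = raw$ispred4 == "I", rsa_percent = rsa,
    stringsAsFactors = FALSE)
  new_variant_table(df)
}

empty_variant_df <- function() {
  data.frame(wt = character(0), pos = integer(0), mut = character(0),
             domain = character(0), effect = character(0),
             ddg_inps3d = numeric(0), ddg_foldx = numeric(0),
             ddg_popmusic2 = numeric(0), interaction = logical(0),
             rsa_percent = integer(0), stringsAsFactors = FALSE)
}

new_variant_table <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d record(s) (%d catalytic, %d regulatory)\n",
              nrow(x), sum(x$domain == "catalytic"),
              sum(x$domain == "regulatory")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Variant short labels such as "G387D"
#' @param records A `variant_table`.
#' @return Character vector.
#' @export
variant_labels <- function(records) {
  paste0(records$wt, records$pos, records$mut)
}

#' Serialize a variant table back to TSV
#'
#' Writes the same dialect [parse_variant_table()] reads, so that
#' parse -> write -> parse round-trips losslessly.
#'
#' @param records A `variant_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  out <- data.frame(
    variant = variant_labels(records),
    domain = records$domain,
    effect = records$effect,
    ddg_inps3d = format_num(records$ddg_inps3d),
    ddg_foldx = format_num(records$ddg_foldx),
    ddg_popmusic2 = format_num(records$ddg_popmusic2),
    ispred4 = ifelse(records$interaction, "I", "N"),
    rsa_percent = records$rsa_percent,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

format_num <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE),
         character(1))
}

#' Remove duplicated variant rows
#'
#' The printed source table lists M338T twice; downstream statistics must
#' operate on unique variants. The key is (wild-type, position, mutant);
#' the first occurrence is kept and order is preserved. Distinct
#' substitutions at one position (e.g. R46Q and R46W) are not duplicates.
#'
#' @param records A `variant_table`.
#' @return A list with `records` (the deduplicated `variant_table`) and
#'   `removed` (character vector of the variant labels that were dropped,
#'   possibly empty).
#' @export
deduplicate_variants <- function(records) {
  key <- paste(records$wt, records$pos, records$mut)
  dup <- duplicated(key)
  list(records = new_variant_table(records[!dup, , drop = FALSE]),
       removed = variant_labels(records)[dup])
}
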