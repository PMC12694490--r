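# Reading and validating protein sequences and interaction records.

NONSTANDARD_AA <- c("X", "B", "Z", "U", "J", "O", "*")

canonicalize_residues <- function(residues, id,
                                  policy = c("drop_nonstandard", "reject")) {
  policy <- match.arg(policy)
  res <- toupper(residues)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET20)
  if (any(bad)) {
    if (policy == "reject") {
      stop_pbip(sprintf(
        "record '%s' contains non-standard residues (%s) under policy 'reject'",
        id, paste(unique(chars[bad]), collapse = ", ")))
    }
    chars <- chars[!bad]
  }
  paste(chars, collapse = "")
}

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a named character vector of residue strings
#' (names are the record identifiers, first whitespace-delimited token of
#' each header).  Residues are uppercased; letters outside the 20-residue
#' canonical alphabet are either dropped (default) or cause an error,
#' depending on `policy`.
#'
#' @param path Path to a FASTA file.
#' @param policy Canonicalization policy for non-standard residues
#'   (X, B, Z, U, J, O, `*`, ...): `"drop_nonstandard"` removes the
#'   offending positions, `"reject"` fails on the first offending record.
#' @return Named character vector of canonical residue strings, in file
#'   order.
#' @seealso [write_protein_fasta()], [one_hot()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 tail fiber", "ARNDC", ">p2", "ggh"), f)
#' parse_protein_fasta(f)
parse_protein_fasta <- function(path,
                                policy = c("drop_nonstandard", "reject")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop_pbip(sprintf("FASTA file not found: '%s'", path))
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0L || all(!nzchar(trimws(raw)))) {
    stop_pbip(sprintf("empty FASTA input: '%s'", path))
  }
  first <- raw[nzchar(trimws(raw))][1]
  if (!startsWith(first, ">")) {
    stop_pbip(sprintf("malformed FASTA '%s': first record does not start with '>'",
                      path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_pbip(sprintf("malformed FASTA '%s': %s",
                                          path, conditionMessage(e))))
  if (length(set) == 0L) stop_pbip(sprintf("empty FASTA input: '%s'", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- as.character(set)
  out <- character(length(seqs))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      stop_pbip(sprintf("malformed FASTA '%s': record '%s' has no residues",
                        path, ids[i]))
    }
    out[i] <- canonicalize_residues(seqs[i], ids[i], policy)
  }
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of residue strings.
#' @param path Output file path.
#' @param width Line width for wrapping residue lines.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path, width = 70L) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Bundle proteins into an organism proteome
#'
#' @param id Organism identifier.
#' @param role `"phage"` or `"bacterium"`.
#' @param proteins Named character vector of canonical residue strings
#'   (as returned by [parse_protein_fasta()]); at least one protein.
#' @return An object of class `pbip_proteome`.
#' @export
proteome <- function(id, role = c("phage", "bacterium"), proteins) {
  role <- match.arg(role)
  stopifnot(is.character(proteins), length(proteins) >= 1L)
  if (any(!nzchar(proteins))) stop_pbip("proteome contains an empty protein")
  structure(list(id = as.character(id), role = role, proteins = proteins,
                 count = length(proteins)),
            class = "pbip_proteome")
}

#' @export
print.pbip_proteome <- function(x, ...) {
  cat(sprintf("<pbip_proteome> %s (%s): %d proteins, %d residues total\n",
              x$id, x$role, x$count, sum(nchar(x$proteins))))
  invisible(x)
}

#' Consensus interaction label from replicate plaque scores
#'
#' An interaction is called positive when at least `min_positive_replicates`
#' replicate composite plaque scores are strictly greater than
#' `score_threshold`; a score exactly at the threshold does not count as
#' positive.
#'
#' @param replicate_scores Numeric vector of composite plaque scores
#'   (one per replicate assay; any count >= 1).
#' @param score_threshold Positivity cut-off on the composite score.
#' @param min_positive_replicates Minimum number of replicates above the
#'   threshold for a positive call.
#' @return Integer label, `1L` (positive) or `0L` (negative).
#' @export
#' @examples
#' consensus_label(c(1.6, 1.7, 0.2))  # 1
#' consensus_label(c(1.5, 1.5, 1.5))  # 0: ties at the threshold are negative
consensus_label <- function(replicate_scores, score_threshold = 1.5,
                            min_positive_replicates = 2L) {
  if (length(replicate_scores) == 0L) {
    stop_pbip("consensus_label needs at least one replicate score")
  }
  if (any(!is.finite(replicate_scores))) {
    stop_pbip("replicate scores must be finite")
  }
  as.integer(sum(replicate_scores > score_threshold) >= min_positive_replicates)
}

#' Construct a validated interaction table
#'
#' @param records Data frame with columns `phage_id`, `bacterium_id` and
#'   `label` (0/1).
#' @return The data frame with class `pbip_interactions` and id levels
#'   recorded in attributes `phage_ids` / `bacterium_ids` (first-appearance
#'   order).
#' @export
interaction_table <- function(records) {
  need <- c("phage_id", "bacterium_id", "label")
  if (!all(need %in% names(records))) {
    stop_pbip("interaction table needs columns phage_id, bacterium_id, label")
  }
  records$phage_id <- as.character(records$phage_id)
  records$bacterium_id <- as.character(records$bacterium_id)
  key <- paste(records$phage_id, records$bacterium_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop_pbip(sprintf("duplicate phage-bacterium pair(s): %s",
                      paste(unique(gsub("\r", " x ", key[dup])), collapse = "; ")))
  }
  if (!all(records$label %in% c(0L, 1L))) {
    stop_pbip("labels must be 0 or 1")
  }
  records$label <- as.integer(records$label)
  structure(records,
            phage_ids = unique(records$phage_id),
            bacterium_ids = unique(records$bacterium_id),
            class = c("pbip_interactions", "data.frame"))
}

#' Load an interaction table from CSV/TSV
#'
#' Accepts either explicit labels (`phage_id,bacterium_id,label`) or
#' replicate plaque score columns (`phage_id,bacterium_id,score_1,...`),
#' in which case labels are derived with [consensus_label()].
#'
#' @param path CSV (or TSV) file with a header.
#' @param score_threshold,min_positive_replicates Passed to
#'   [consensus_label()] when score columns are present.
#' @return A `pbip_interactions` data frame.
#' @export
load_interaction_table <- function(path, score_threshold = 1.5,
                                   min_positive_replicates = 2L) {
  if (!file.exists(path)) stop_pbip(sprintf("file not found: '%s'", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("phage_id", "bacterium_id") %in% names(df))) {
    stop_pbip("interaction file must have columns phage_id and bacterium_id")
  }
  score_cols <- grep("^score(_|$)", names(df), value = TRUE)
  if ("label" %in% names(df)) {
    if (any(is.na(df$label))) stop_pbip("missing labels in interaction file")
  } else if (length(score_cols) > 0L) {
    scores <- as.matrix(df[, score_cols, drop = FALSE])
    if (any(is.na(scores))) stop_pbip("missing replicate scores")
    df$label <- apply(scores, 1L, consensus_label,
                      score_threshold = score_threshold,
                      min_positive_replicates = min_positive_replicates)
  } else {
    stop_pbip("interaction file needs a 'label' column or score_* columns")
  }
  interaction_table(df)
}

complete_matrix_or_stop <- function(table) {
  phages <- attr(table, "phage_ids")
  bacteria <- attr(table, "bacterium_ids")
  expected <- length(phages) * length(bacteria)
  if (nrow(table) != expected) {
    have <- paste(table$phage_id, table$bacterium_id, sep = "\r")
    all_pairs <- as.vector(outer(phages, bacteria, paste, sep = "\r"))
    missing <- setdiff(all_pairs, have)
    stop_pbip(sprintf("incomplete interaction matrix; %d missing pair(s), e.g. %s",
                      length(missing),
                      paste(gsub("\r", " x ", utils::head(missing, 3L)),
                            collapse = "; ")))
  }
  invisible(list(phages = phages, bacteria = bacteria))
}

#' Interaction-matrix summary statistics
#'
#' For a complete phage x bacterium matrix, reports the totals that
#' characterize strain-level infection data: the number of pairs, positive
#' count and percentage, and the mean number of positives per phage and per
#' bacterium (all rounded to 2 decimals in the report).
#'
#' @param table A complete `pbip_interactions` table (every phage x
#'   bacterium pair present).
#' @return A list of class `pbip_matrix_stats` with elements `n_phages`,
#'   `n_bacteria`, `total`, `positives`, `positive_pct`,
#'   `positives_per_phage`, `positives_per_bacterium`.
#' @export
matrix_statistics <- function(table) {
  ids <- complete_matrix_or_stop(table)
  total <- nrow(table)
  pos <- sum(table$label == 1L)
  structure(list(
    n_phages = length(ids$phages),
    n_bacteria = length(ids$bacteria),
    total = total,
    positives = pos,
    positive_pct = round(100 * pos / total, 2L),
    positives_per_phage = round(pos / length(ids$phages), 2L),
    positives_per_bacterium = round(pos / length(ids$bacteria), 2L)
  ), class = "pbip_matrix_stats")
}

#' @export
print.pbip_matrix_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Interaction matrix: %d phages x %d bacteria = %d pairs\n",
           "  positives: %d (%.2f%%)\n",
           "  mean positives per phage: %.2f; per bacterium: %.2f\n"),
    x$n_phages, x$n_bacteria, x$total, x$positives, x$positive_pct,
    x$positives_per_phage, x$positives_per_bacterium))
  invisible(x)
}

#' Remove fully resistant bacterial strains
#'
#' Drops bacteria with zero positive interactions (completely resistant to
#' every tested phage), together with all their records.  Idempotent.
#'
#' @param table A complete `pbip_interactions` table.
#' @return The filtered `pbip_interactions` table.
#' @export
drop_fully_resistant_strains <- function(table) {
  complete_matrix_or_stop(table)
  pos_by_bact <- tapply(table$label, table$bacterium_id, sum)
  keep <- names(pos_by_bact)[pos_by_bact > 0L]
  out <- table[table$bacterium_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(as.data.frame(out),
            phage_ids = attr(table, "phage_ids"),
            bacterium_ids = intersect(attr(table, "bacterium_ids"), keep),
            class = c("pbip_interactions", "data.frame"))
}
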