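## io_formats: strict readers/writers for every external file the pipeline
## touches. FASTA goes through Biostrings; validation and error reporting are
## done here so malformed inputs fail loudly with the offending record named.

AMBIGUITY_CODES <- c("X", "B", "Z", "J", "U", "O")

#' Derive a normalized species key from an organism name
#'
#' Lower-cases the organism name and joins its first two whitespace-delimited
#' tokens, so strain-level records ("Escherichia coli K-12", "Escherichia
#' coli O157:H7") collapse onto one species key and strain duplicates become
#' detectable. Override per record with [set_species_keys()] when a curated
#' metadata table is available.
#'
#' @param organism character vector of free-text organism names.
#' @return character vector of species keys ("" for empty names).
#' @export
#' @examples
#' species_key_from_organism("Escherichia coli K-12") # "escherichia coli"
species_key_from_organism <- function(organism) {
  vapply(organism, function(o) {
    toks <- strsplit(tolower(trimws(o)), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) return("")
    paste(toks[seq_len(min(2L, length(toks)))], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

## Read a FASTA file, refusing the silent dropping of invalid letters that
## the underlying parser would otherwise do (no row/residue is ever lost
## without an error).
read_aa_strict <- function(path) {
  withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence code", conditionMessage(w))) {
        abort(sprintf("invalid sequence characters in %s: %s",
                      path, conditionMessage(w)),
              class = "coevkit_bad_residue")
      }
      invokeRestart("muffleWarning")
    })
}

validate_protein_seq <- function(seq, id, lenient = FALSE, allow_gap = FALSE) {
  if (!nzchar(seq)) abort(sprintf("sequence '%s' is empty", id))
  allowed <- AA20
  if (lenient) allowed <- c(allowed, AMBIGUITY_CODES)
  if (allow_gap) allowed <- c(allowed, "-")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    abort(sprintf("illegal residue '%s' at position %d in sequence '%s'",
                  chars[bad[1]], bad[1], id),
          class = "coevkit_bad_residue")
  }
  invisible(TRUE)
}

new_seq_records <- function(id, organism, sequence, species_key = NULL) {
  if (is.null(species_key)) species_key <- species_key_from_organism(organism)
  tibble::tibble(id = as.character(id), organism = as.character(organism),
                 species_key = as.character(species_key),
                 sequence = as.character(sequence))
}

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace is the record id; the
#' remainder is the organism name, from which a species key is derived (see
#' [species_key_from_organism()]). Sequences must be gap-free and drawn from
#' the 20 standard amino acids; ambiguity codes (X, B, Z, J, U, O) are
#' rejected unless `lenient = TRUE`, in which case they are retained in the
#' sequence but masked (treated as missing) by downstream frequency counts.
#'
#' @param path path to a FASTA file.
#' @param lenient accept ambiguity codes instead of erroring.
#' @return A tibble with columns `id`, `organism`, `species_key`, `sequence`.
#' @export
read_fasta <- function(path, lenient = FALSE) {
  check_flag(lenient, "lenient")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- read_aa_strict(path)
  if (length(ss) == 0L) abort(sprintf("no sequences in %s", path))
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  organism <- trimws(sub("^\\S+\\s*", "", headers))
  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "coevkit_duplicate_id")
  }
  seqs <- toupper(as.character(ss))
  for (i in seq_along(seqs)) validate_protein_seq(seqs[i], id[i], lenient)
  new_seq_records(id, organism, seqs)
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id organism` and reparsing
#' recovers the records exactly (modulo line wrapping).
#'
#' @param records tibble as returned by [read_fasta()].
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  headers <- ifelse(nzchar(records$organism),
                    paste(records$id, records$organism), records$id)
  ss <- Biostrings::AAStringSet(records$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a validated multiple alignment
#'
#' @param ids character vector of unique sequence ids.
#' @param seqs character vector of equal-length aligned sequences with '-'
#'   gaps ('.' is rejected: one gap dialect only).
#' @return An object of class `msa`: list with `ids`, `seqs`, `mat` (integer
#'   matrix, rows = sequences, gap = 0), `n_seq`, `n_col` and a
#'   `degenerate_cols` attribute marking all-gap columns.
#' @export
new_msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 2L) abort("an alignment needs at least 2 sequences")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "coevkit_duplicate_id")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != stats::median(lens)]
    if (length(off) == 0L) off <- ids
    abort(sprintf("ragged alignment: sequences of unequal length (%s)",
                  paste(off, collapse = ", ")),
          class = "coevkit_ragged_alignment")
  }
  if (lens[1] < 1L) abort("alignment has zero columns")
  if (any(grepl(".", seqs, fixed = TRUE))) {
    abort("'.' gaps are not supported; use '-'")
  }
  for (i in seq_along(seqs)) {
    validate_protein_seq(seqs[i], ids[i], lenient = TRUE, allow_gap = TRUE)
  }
  mat <- do.call(rbind, lapply(seqs, encode_seq))
  mat[is.na(mat)] <- 0L  # masked ambiguity codes drop out of counts
  rownames(mat) <- ids
  degenerate <- which(colSums(mat > 0L) == 0L)
  structure(
    list(ids = ids, seqs = seqs, mat = mat,
         n_seq = length(ids), n_col = ncol(mat)),
    degenerate_cols = degenerate, class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", x$n_seq, x$n_col))
  invisible(x)
}

#' Read a multiple alignment from gapped FASTA
#'
#' @inheritParams read_fasta
#' @return An `msa` object (see [new_msa()]).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- read_aa_strict(path)
  if (length(ss) == 0L) abort(sprintf("no sequences in %s", path))
  id <- sub("\\s.*$", "", names(ss))
  new_msa(id, as.character(ss))
}

#' Write a multiple alignment to gapped FASTA
#' @param aln an `msa` object.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::AAStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## Build an msa from gap-free equal-length sequence records (the synthetic
## families are columnwise-alignable by construction).
msa_from_records <- function(records) {
  new_msa(records$id, records$sequence)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("missing required column(s) %s in %s",
                  paste(missing, collapse = ", "), path),
          class = "coevkit_missing_column")
  }
}

#' Read a differential-expression table
#'
#' Expects a TSV with named columns `gene`, `log2fc`, and one of `padj` /
#' `significant`. When `padj` is supplied, significance is called at
#' `alpha` (default 0.05, the source resource's convention) and the raw
#' values are kept.
#'
#' @param path TSV path ('#' comment lines are ignored).
#' @param condition_label free-text label attached to the table.
#' @param alpha adjusted-p significance threshold.
#' @return A tibble with columns `gene`, `log2fc`, `significant` (and `padj`
#'   when present), with attribute `condition_label`.
#' @export
read_de_table <- function(path, condition_label, alpha = 0.05) {
  check_number(alpha, "alpha", 0, 1)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read_tsv_table(path)
  require_columns(df, c("gene", "log2fc"), path)
  if (!("padj" %in% names(df)) && !("significant" %in% names(df))) {
    abort(sprintf("missing required column(s) padj or significant in %s", path),
          class = "coevkit_missing_column")
  }
  as_de_table(df, condition_label, alpha = alpha, source = path)
}

## Validate/type a DE data frame (shared by the reader and the simulator).
as_de_table <- function(df, condition_label, alpha = 0.05, source = "<memory>") {
  df$gene <- as.character(df$gene)
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate gene symbol(s) in %s: %s", source,
                  paste(dup, collapse = ", ")),
          class = "coevkit_duplicate_gene")
  }
  lfc <- suppressWarnings(as.numeric(df$log2fc))
  bad <- which(!is.finite(lfc))
  if (length(bad) > 0L) {
    abort(sprintf("non-finite log2fc at row %d of %s", bad[1], source))
  }
  out <- tibble::tibble(gene = df$gene, log2fc = lfc)
  if ("padj" %in% names(df)) {
    padj <- suppressWarnings(as.numeric(df$padj))
    if (any(!is.finite(padj) | padj < 0 | padj > 1)) {
      abort(sprintf("padj outside [0, 1] in %s", source))
    }
    out$padj <- padj
    out$significant <- padj <= alpha
  }
  if ("significant" %in% names(df)) {
    out$significant <- as.logical(df$significant)
    if (anyNA(out$significant)) {
      abort(sprintf("significant column not interpretable as logical in %s",
                    source))
    }
  }
  attr(out, "condition_label") <- condition_label
  class(out) <- c("de_table", class(out))
  out
}

#' Write a differential-expression table as TSV
#' @param de a `de_table` tibble.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  write_tsv_report(as.data.frame(de), path,
                   params = list(condition_label = attr(de, "condition_label")))
}

#' Read a literature target list
#'
#' TSV with columns `gene` and `direction` (values `up` / `down`): genes with
#' documented direction of regulation (here, retinoic-acid-responsive
#' targets).
#'
#' @param path TSV path.
#' @return tibble with columns `gene`, `direction`.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read_tsv_table(path)
  require_columns(df, c("gene", "direction"), path)
  as_target_list(df, source = path)
}

as_target_list <- function(df, source = "<memory>") {
  df$gene <- as.character(df$gene)
  df$direction <- as.character(df$direction)
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate gene symbol(s) in %s: %s", source,
                  paste(dup, collapse = ", ")),
          class = "coevkit_duplicate_gene")
  }
  bad <- which(!(df$direction %in% c("up", "down")))
  if (length(bad) > 0L) {
    abort(sprintf("invalid direction '%s' for gene '%s' (must be up or down)",
                  df$direction[bad[1]], df$gene[bad[1]]))
  }
  tibble::tibble(gene = df$gene, direction = df$direction)
}

#' Write a target list as TSV
#' @param targets target-list tibble.
#' @param path output path.
#' @export
write_target_list <- function(targets, path) {
  write_tsv_report(as.data.frame(targets), path)
}

#' Read plate-reader time courses from CSV
#'
#' Expects columns `condition`, `replicate`, `time_min`, `reading` plus a
#' `reading_kind` argument or column declaring the measurement unit. Within
#' each (condition, replicate) series, times must be strictly increasing
#' with at least 3 points and finite readings.
#'
#' @param path CSV path ('#' comment lines ignored).
#' @param reading_kind `"concentration"` (uM NADH) or `"absorbance"` (AU at
#'   340 nm); overridden by a `reading_kind` column if present.
#' @return tibble with attribute `reading_kind`.
#' @export
read_timecourse <- function(path, reading_kind = c("concentration",
                                                   "absorbance")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  require_columns(df, c("condition", "replicate", "time_min", "reading"), path)
  if ("reading_kind" %in% names(df)) {
    reading_kind <- unique(as.character(df$reading_kind))
    if (length(reading_kind) != 1L) abort("mixed reading_kind values")
  }
  reading_kind <- match.arg(reading_kind,
                            c("concentration", "absorbance"))
  as_timecourse(df, reading_kind, source = path)
}

as_timecourse <- function(df, reading_kind, source = "<memory>") {
  out <- tibble::tibble(condition = as.character(df$condition),
                        replicate = as.character(df$replicate),
                        time_min = as.numeric(df$time_min),
                        reading = as.numeric(df$reading))
  if ("dose" %in% names(df)) out$dose <- as.numeric(df$dose)
  for (key in unique(paste(out$condition, out$replicate, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sel <- out$condition == parts[1] & out$replicate == parts[2]
    tt <- out$time_min[sel]
    if (length(tt) < 3L) {
      abort(sprintf("series %s/%s has fewer than 3 points in %s",
                    parts[1], parts[2], source))
    }
    if (any(diff(tt) <= 0)) {
      abort(sprintf("times not strictly increasing in series %s/%s of %s",
                    parts[1], parts[2], source))
    }
    if (any(!is.finite(out$reading[sel]))) {
      abort(sprintf("non-finite reading in series %s/%s of %s",
                    parts[1], parts[2], source))
    }
  }
  attr(out, "reading_kind") <- reading_kind
  class(out) <- c("timecourse", class(out))
  out
}

#' Write time courses as CSV
#' @param tc a `timecourse` tibble.
#' @param path output path.
#' @export
write_timecourse <- function(tc, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# reading_kind: %s", attr(tc, "reading_kind")), con)
  utils::write.csv(as.data.frame(tc), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach curated species keys from a metadata table
#'
#' @param records sequence-record tibble.
#' @param meta data frame with columns `id`, `species_key`; records not
#'   listed keep their derived key.
#' @return updated records.
#' @export
set_species_keys <- function(records, meta) {
  require_columns(meta, c("id", "species_key"), "<meta>")
  idx <- match(records$id, meta$id)
  hit <- !is.na(idx)
  records$species_key[hit] <- as.character(meta$species_key[idx[hit]])
  records
}
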