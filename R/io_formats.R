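#' Read miRNA sequences from a FASTA file
#'
#' Loads miRBase-style RNA sequences. Sequences are uppercased and DNA-style
#' `T` is converted to `U` at load time; any residue outside `{A,C,G,U}`
#' (ambiguity codes such as `N` included) is rejected, because the downstream
#' k-mer and pattern spaces assume a strict 4-letter alphabet. Identifiers are
#' lowercased and whitespace-trimmed and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of RNA sequences (names are miRNA ids).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1", "ACGT", ">m2", "uuuu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(trimws(lines[nonempty[1]]), ">"))
    stopf("malformed FASTA: line %d does not start a '>' header", nonempty[1])
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("malformed FASTA (%s): %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- norm_id(sub("\\s.*$", "", names(set)))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate sequence id(s) in %s: %s", path, paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) {
    stopf("empty sequence(s): %s", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stopf("sequence(s) contain characters outside {A,C,G,U,T}: %s",
          paste(ids[bad], collapse = ", "))
  }
  hetmda_log("io_formats", "read %d sequences from %s", length(ids), path)
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector of RNA sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Read an association table (e.g. miRNA-disease or disease-gene pairs)
#'
#' Reads a two-column tab- or comma-separated file of `source`/`target`
#' identifier pairs. Identifiers are lowercased and trimmed; duplicate pairs
#' are dropped with a logged count; otherwise row order is preserved.
#'
#' @param path path to a TSV/CSV file with at least two columns.
#' @param relation_name one of `"mirna_disease"`, `"mirna_mirna"`,
#'   `"disease_gene"`, `"mirna_pattern"`, `"pattern_disease"`.
#' @param header logical; does the file carry a header row?
#' @param sep field separator; `NULL` auto-detects tab then comma.
#' @return an object of class `association_table`: a list with
#'   `relation_name` and `pairs` (data.frame with columns `source`, `target`).
#' @export
read_association_table <- function(path, relation_name, header = TRUE,
                                   sep = NULL) {
  relation_name <- match.arg(relation_name, names(canonical_relations()))
  if (!file.exists(path)) stopf("association file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(association_table(relation_name,
                                               character(0), character(0)))
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  n_fields <- lengths(fields)
  src <- vapply(fields, function(f) if (length(f) >= 1) trimws(f[[1]]) else "", "")
  tgt <- vapply(fields, function(f) if (length(f) >= 2) trimws(f[[2]]) else "", "")
  bad <- which(n_fields < 2L | !nzchar(src) | !nzchar(tgt))
  if (length(bad)) {
    stopf("rows with missing fields in %s: row(s) %s", path,
          paste(bad + as.integer(header), collapse = ", "))
  }
  association_table(relation_name, norm_id(src), norm_id(tgt))
}

#' Construct an association table from id vectors
#'
#' @param relation_name relation label (see [read_association_table()]).
#' @param source,target equal-length character vectors of identifiers.
#' @return an `association_table` object with duplicates removed.
#' @export
association_table <- function(relation_name, source, target) {
  relation_name <- match.arg(relation_name, names(canonical_relations()))
  stopifnot(length(source) == length(target))
  if (any(!nzchar(source)) || any(!nzchar(target)))
    stopf("empty identifiers in %s association table", relation_name)
  pairs <- data.frame(source = as.character(source),
                      target = as.character(target),
                      stringsAsFactors = FALSE)
  dup <- duplicated(paste(pairs$source, pairs$target, sep = "\r"))
  if (any(dup)) {
    hetmda_log("io_formats", "%s: removed %d duplicate pair(s)",
               relation_name, sum(dup))
    pairs <- pairs[!dup, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(relation_name = relation_name, pairs = pairs),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> %s: %d pairs\n",
              x$relation_name, nrow(x$pairs)))
  invisible(x)
}

#' Write scored miRNA-disease pairs to TSV
#'
#' Columns are `miRNA`, `disease`, `logit`, `probability`; values are written
#' with full double precision so a round-trip read reproduces them.
#'
#' @param scores a `pair_scores` object (see [score_pairs()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_predictions <- function(scores, path) {
  stopifnot(inherits(scores, "pair_scores"))
  if (nrow(scores) == 0L) stopf("refusing to write empty predictions")
  out <- data.frame(miRNA = scores$mirna, disease = scores$disease,
                    logit = format(scores$logit, digits = 17, trim = TRUE,
                                   scientific = FALSE),
                    probability = format(scores$probability, digits = 17,
                                         trim = TRUE, scientific = FALSE))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write predictions to %s", path)
  invisible(path)
}

#' Read scored pairs written by [write_predictions()]
#'
#' @param path path to a predictions TSV.
#' @return a `pair_scores` data.frame.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stopf("predictions file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  pair_scores(df$miRNA, df$disease, df$logit)
}
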