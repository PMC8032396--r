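#' Construct an aligned sequence set with per-sample metadata
#'
#' An `aligned_set` bundles an equal-length DNA alignment with the per-sample
#' curation labels the downstream analyses need: time stratum (`ancient` or
#' `modern`), a free-form taxon label, a morphological size class (`big`,
#' `small` or `unknown`) and a site label.
#'
#' @param seqs Character matrix, one row per sample and one column per
#'   alignment position, entries in `A,C,G,T,N,-` (lower case is accepted and
#'   converted). Row names, if present, must equal `meta$id`.
#' @param meta Data frame with columns `id`, `stratum`, `taxon`, `size_class`,
#'   `site`. One row per sequence, same order as `seqs`.
#' @return An object of class `aligned_set`: a list with elements `ids`,
#'   `seqs` (uppercase character matrix with row names), `L` (alignment
#'   length) and `meta`.
#' @examples
#' m <- matrix(strsplit(c("ACGT", "ACGA"), "")[[1]], nrow = 1)
#' seqs <- do.call(rbind, strsplit(c("ACGT", "ACGA"), ""))
#' meta <- data.frame(id = c("s1", "s2"), stratum = c("ancient", "modern"),
#'                    taxon = "V_vicugna", size_class = "small", site = "T54")
#' aligned_set(seqs, meta)
#' @export
aligned_set <- function(seqs, meta) {
  if (!is.matrix(seqs) || !is.character(seqs))
    stopf("'seqs' must be a character matrix of single bases")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("id", "stratum", "taxon", "size_class", "site")
  if (!all(need %in% names(meta)))
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  meta <- meta[, need]
  for (cl in need) meta[[cl]] <- as.character(meta[[cl]])
  if (nrow(meta) != nrow(seqs))
    stopf("metadata has %d rows but alignment has %d", nrow(meta), nrow(seqs))
  if (anyDuplicated(meta$id))
    stopf("duplicated sample ids: %s",
          paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  seqs <- toupper(seqs)
  bad <- which(!(seqs %in% DNA_ALPHA))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(seqs)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(seqs)) + 1L
    stopf("illegal character '%s' in sequence '%s' at column %d (alphabet is A,C,G,T,N,-)",
          seqs[bad[1L]], meta$id[i], j)
  }
  bad_str <- setdiff(unique(meta$stratum), STRATA)
  if (length(bad_str))
    stopf("stratum must be one of %s; found: %s",
          paste(STRATA, collapse = "/"), paste(bad_str, collapse = ", "))
  bad_sc <- setdiff(unique(meta$size_class), SIZE_CLASS)
  if (length(bad_sc))
    stopf("size_class must be one of %s; found: %s",
          paste(SIZE_CLASS, collapse = "/"), paste(bad_sc, collapse = ", "))
  rownames(seqs) <- meta$id
  rownames(meta) <- NULL
  structure(list(ids = meta$id, seqs = seqs, L = ncol(seqs), meta = meta),
            class = "aligned_set")
}

#' Read an aligned FASTA file plus its sample metadata table
#'
#' The FASTA must be a true alignment (all records the same length) over the
#' alphabet `A,C,G,T,N,-` (case-insensitive; `U` and IUPAC ambiguity codes are
#' rejected). Metadata is a tab-separated file with the exact header
#' `id  stratum  taxon  size_class  site`; every FASTA record must have a
#' metadata row and vice versa. Record order of the FASTA is preserved.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param meta_path Path to the metadata TSV.
#' @return An [aligned_set()].
#' @seealso [write_alignment()] for the inverse operation.
#' @export
read_alignment <- function(fasta_path, meta_path) {
  if (!file.exists(fasta_path)) stopf("FASTA file not found: %s", fasta_path)
  if (!file.exists(meta_path)) stopf("metadata file not found: %s", meta_path)
  # BStringSet preserves every input character, so the strict alphabet check
  # below sees exactly what the file contains (DNAStringSet would not keep,
  # e.g., a stray "U" around for a precise error message).
  dna <- Biostrings::readBStringSet(fasta_path)
  if (length(dna) == 0L) stopf("no sequences in %s", fasta_path)
  lens <- Biostrings::width(dna)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1L])[1L]
    stopf("ragged alignment: sequence '%s' has length %d but '%s' has length %d",
          names(dna)[off], lens[off], names(dna)[1L], lens[1L])
  }
  seqs <- do.call(rbind, strsplit(as.character(dna), ""))
  rownames(seqs) <- names(dna)

  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("id", "stratum", "taxon", "size_class", "site")
  if (!identical(names(meta), need))
    stopf("metadata header must be exactly: %s", paste(need, collapse = "\\t"))
  only_fa <- setdiff(rownames(seqs), meta$id)
  only_tsv <- setdiff(meta$id, rownames(seqs))
  if (length(only_fa) || length(only_tsv))
    stopf("FASTA/metadata mismatch%s%s",
          if (length(only_fa))
            sprintf("; in FASTA only: %s", paste(only_fa, collapse = ", ")) else "",
          if (length(only_tsv))
            sprintf("; in metadata only: %s", paste(only_tsv, collapse = ", ")) else "")
  meta <- meta[match(rownames(seqs), meta$id), , drop = FALSE]
  aligned_set(seqs, meta)
}

#' Write an aligned set back to FASTA + metadata TSV
#'
#' @param aset An [aligned_set()].
#' @param fasta_path,meta_path Output paths.
#' @return Invisibly, `aset`. Reading the two files back with
#'   [read_alignment()] reproduces the object exactly.
#' @export
write_alignment <- function(aset, fasta_path, meta_path) {
  stopifnot(inherits(aset, "aligned_set"))
  dna <- Biostrings::BStringSet(apply(aset$seqs, 1L, paste, collapse = ""))
  names(dna) <- aset$ids
  Biostrings::writeXStringSet(dna, fasta_path)
  utils::write.table(aset$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(aset)
}

#' Subset an aligned set by metadata labels
#'
#' Selects the samples matching *all* supplied filters; a call with no filters
#' returns the set unchanged. This supports the partitions used by the
#' temporal comparison (all samples, modern Lama vs ancient big,
#' modern Vicugna vs ancient small).
#'
#' @param x An [aligned_set()].
#' @param stratum Optional, `"ancient"` or `"modern"`.
#' @param taxa Optional character vector of taxon labels to keep.
#' @param size_class Optional, one or more of `"big"`, `"small"`, `"unknown"`.
#' @param ... Ignored.
#' @return An [aligned_set()] with the matching rows, same alignment length.
#'   Selecting zero samples is an error (the downstream statistics are
#'   undefined on an empty cohort).
#' @export
subset.aligned_set <- function(x, stratum = NULL, taxa = NULL,
                               size_class = NULL, ...) {
  keep <- rep(TRUE, length(x$ids))
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, STRATA)
    keep <- keep & x$meta$stratum == stratum
  }
  if (!is.null(taxa)) keep <- keep & x$meta$taxon %in% taxa
  if (!is.null(size_class)) {
    size_class <- match.arg(size_class, SIZE_CLASS, several.ok = TRUE)
    keep <- keep & x$meta$size_class %in% size_class
  }
  if (!any(keep))
    stopf("filter selects no samples (stratum=%s, taxa=%s, size_class=%s)",
          stratum %||% "*", if (is.null(taxa)) "*" else paste(taxa, collapse = "|"),
          if (is.null(size_class)) "*" else paste(size_class, collapse = "|"))
  aligned_set(x$seqs[keep, , drop = FALSE], x$meta[keep, , drop = FALSE])
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d samples x %d bp\n", length(x$ids), x$L))
  tab <- table(x$meta$stratum)
  cat("  strata: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  tax <- table(x$meta$taxon)
  cat("  taxa:   ", paste(sprintf("%s=%d", names(tax), tax), collapse = ", "), "\n")
  invisible(x)
}

# ---- result serialization ----------------------------------------------

#' Write a pipeline result object to disk
#'
#' Serializes any of the package's result objects (`diversity_summary`,
#' `resampling_result`, `temporal_comparison`, `haplotype_table`,
#' `morpho_grouping`) as JSON, or as TSV for the tabular ones. The JSON form
#' round-trips through [read_results()]: integers and strings bit-exactly,
#' reals to full double precision.
#'
#' @param x A result object.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  UseMethod("write_results")
}

#' @export
write_results.default <- function(x, path, format = c("json", "tsv")) {
  stopf("write_results: unsupported object of class '%s'", class(x)[1L])
}

json_dump <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- c(list(.class = class(x)[1L]), unclass(x))
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stopf("could not write %s", path)
  invisible(path)
}

tsv_dump <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.diversity_summary <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") return(json_dump(x, path))
  tsv_dump(as.data.frame(unclass(x)[c("n", "h", "Hd", "S", "pi")]), path)
}

#' @export
write_results.resampling_result <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") return(json_dump(x, path))
  # TSV dump of the null vectors, one replicate per row
  tsv_dump(data.frame(replicate = seq_along(x$stats$Hd$null),
                      Hd = x$stats$Hd$null, S = x$stats$S$null), path)
}

#' @export
write_results.temporal_comparison <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") return(json_dump(x, path))
  tsv_dump(summary(x), path)
}

#' @export
write_results.haplotype_table <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") return(json_dump(x, path))
  df <- data.frame(haplotype = x$keys,
                   total = x$counts$total,
                   count_ancient = x$counts$ancient,
                   count_modern = x$counts$modern,
                   members = vapply(x$members, paste, "", collapse = ","))
  tsv_dump(df, path)
}

#' @export
write_results.morpho_grouping <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") return(json_dump(x, path))
  tsv_dump(data.frame(id = names(x$assignment), group = unname(x$assignment)), path)
}

#' Read back a JSON result written by [write_results()]
#'
#' @param path Path to a JSON file produced by [write_results()].
#' @return The result object with its class restored.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  structure(obj, class = cls)
}
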