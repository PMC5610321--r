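#' Read a multi-FASTA file into a sequence table
#'
#' Parses a (possibly multi-record) FASTA file of DNA or RNA and returns one
#' cleaned record per header. Cleaning uppercases the residues, maps RNA `U`
#' to `T`, and removes every other non-`ACGT` character (ambiguity codes such
#' as `N`, `R`, `Y`, gaps, digits); the number of characters dropped from each
#' record is reported in `n_removed` and a warning is emitted for any record
#' that lost characters. Positional features index only classified bases, so
#' unclassifiable residues are removed rather than kept as phantom positions.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record, in file order, and columns
#'   `id` (first whitespace-delimited token of the header), `description`
#'   (remainder of the header, possibly `""`), `sequence` (cleaned `ACGT`
#'   string) and `n_removed` (count of residue characters dropped).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 first", "ACGT", ">s2", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (", conditionMessage(e), ")")
  )
  if (length(set) == 0) stop("FASTA format error: no records ('>' headers) in ", path)

  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA format error: record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids (ids label matrix rows and tree leaves): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  raw <- gsub("[[:space:]]", "", as.character(set))
  cleaned <- clean_sequence(raw)
  n_removed <- nchar(raw) - nchar(cleaned)

  if (any(cleaned == "")) {
    stop("FASTA format error: record(s) empty after cleaning: ",
         paste(ids[cleaned == ""], collapse = ", "))
  }
  for (i in which(n_removed > 0)) {
    warning(sprintf("record '%s': removed %d non-ACGT character(s)", ids[i], n_removed[i]),
            call. = FALSE)
  }

  tibble::tibble(id = ids, description = unname(desc),
                 sequence = unname(cleaned), n_removed = unname(n_removed))
}

# uppercase, U->T, drop everything outside ACGT (vectorised over records)
clean_sequence <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  gsub("[^ACGT]", "", x)
}

#' Write a sequence table to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `sequence` (e.g. from
#'   [read_fasta()] or [simulate_clades()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- validate_seq_table(seqs)
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# shared contract for every function taking a sequence table
validate_seq_table <- function(seqs, require_n = 1) {
  if (!is.data.frame(seqs) || !all(c("id", "sequence") %in% names(seqs))) {
    stop("expected a data frame with columns 'id' and 'sequence'")
  }
  if (nrow(seqs) < require_n) {
    stop("need at least ", require_n, " sequence record(s), got ", nrow(seqs))
  }
  if (anyDuplicated(seqs$id)) {
    stop("duplicate sequence ids: ",
         paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", "))
  }
  bad <- grepl("[^ACGT]", seqs$sequence) | seqs$sequence == ""
  if (any(bad)) {
    stop("sequence(s) not cleaned to non-empty ACGT: ",
         paste(seqs$id[bad], collapse = ", "))
  }
  tibble::as_tibble(seqs)
}
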