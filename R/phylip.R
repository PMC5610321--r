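#' Write a distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each following line is the taxon name padded
#' or truncated to 10 characters, then the full row of distances with 10
#' significant digits. Output is byte-identical across runs for the same
#' matrix.
#'
#' @param m A labelled square symmetric matrix (e.g. a `mev_dist`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path) {
  m <- as.matrix(m)
  validate_dist_matrix(m)
  names10 <- formatC(substr(rownames(m), 1, 10), width = -10)
  if (anyDuplicated(names10)) {
    stop("taxon labels collide after truncation to 10 characters: ",
         paste(unique(names10[duplicated(names10)]), collapse = ", "))
  }
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(names10[i], " ",
           paste(sprintf("%.10g", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(as.character(nrow(m)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Counterpart of [write_phylip_matrix()]; also accepts other whitespace
#' spacing as long as each row holds a name followed by a full row of
#' distances.
#'
#' @param path Input path.
#' @return A `mev_dist` labelled symmetric matrix.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a PHYLIP distance matrix: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2) stop("bad taxon count in PHYLIP header: ", lines[1])
  if (length(lines) != n + 1) {
    stop("expected ", n, " matrix rows, found ", length(lines) - 1)
  }
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    if (length(tok) != n + 1) {
      stop("row ", i, ": expected a name and ", n, " distances, found ",
           length(tok) - 1)
    }
    labs[i] <- tok[1]
    m[i, ] <- as.numeric(tok[-1])
  }
  if (anyDuplicated(labs)) stop("duplicate taxon names in matrix")
  dimnames(m) <- list(labs, labs)
  validate_dist_matrix(m)
  new_mev_dist(m, method = "phylip-file")
}

#' Write a tree to a Newick file
#'
#' @param tree A rooted `phylo` tree with non-negative branch lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("every edge must carry a non-negative length")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
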