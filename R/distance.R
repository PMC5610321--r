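#' Euclidean distance between two encoding vectors
#'
#' @param v1,v2 Numeric vectors of the 18 features (e.g. one row of
#'   [mev_encode()] output, feature columns only).
#' @return Non-negative scalar, `sqrt(sum((v1 - v2)^2))`.
#' @export
euclidean <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != length(v2)) stop("vectors differ in length")
  sqrt(sum((v1 - v2)^2))
}

#' Pairwise Euclidean distance matrix over encoding vectors
#'
#' @param vectors A tibble from [mev_encode()] (columns `id` and the 18
#'   features), with at least two rows and unique ids.
#' @return A `mev_dist` object: a labelled symmetric numeric matrix with zero
#'   diagonal, rows/columns in input order. Attribute `method` records the
#'   metric. Use [tidy()] for a long tibble of pairs, [autoplot()] for a
#'   heatmap, and [mev_upgma()] to cluster.
#' @examples
#' vecs <- mev_encode(simulate_clades(2, 2, 200, 0.01, 0.2, seed = 1))
#' mev_distance(vecs)
#' @export
mev_distance <- function(vectors) {
  validate_vector_table(vectors)
  if (nrow(vectors) < 2) stop("need at least 2 vectors")
  if (anyDuplicated(vectors$id)) {
    stop("duplicate labels: ",
         paste(unique(vectors$id[duplicated(vectors$id)]), collapse = ", "))
  }
  x <- as.matrix(vectors[, mev_feature_names()])
  rownames(x) <- vectors$id
  m <- as.matrix(stats::dist(x, method = "euclidean"))
  new_mev_dist(m, method = "euclidean-mev")
}

new_mev_dist <- function(m, method) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  structure(m, method = method, class = c("mev_dist", class(m)))
}

validate_dist_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (any(!is.finite(m))) stop("distance matrix contains non-finite entries")
  if (any(m < 0)) stop("distance matrix contains negative entries")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) stop("distance matrix not symmetric")
  if (any(abs(diag(m)) > 1e-12 * max(1, max(abs(m))))) stop("distance matrix diagonal not zero")
  invisible(m)
}

#' @export
print.mev_dist <- function(x, ...) {
  cat("Pairwise distance matrix (", attr(x, "method"), "), ",
      nrow(x), " taxa\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Tidy a distance matrix into a long pair table
#'
#' @param x A `mev_dist` object.
#' @param upper Keep only each unordered pair once? Default `TRUE`.
#' @param ... Unused.
#' @return A tibble with columns `item1`, `item2`, `distance`.
#' @method tidy mev_dist
#' @export
tidy.mev_dist <- function(x, upper = TRUE, ...) {
  labs <- rownames(x)
  tb <- tibble::as_tibble(as.table(unclass(x)), .name_repair = ~ c("item1", "item2", "distance"))
  tb$item1 <- factor(tb$item1, levels = labs)
  tb$item2 <- factor(tb$item2, levels = labs)
  if (upper) tb <- dplyr::filter(tb, as.integer(.data$item1) < as.integer(.data$item2))
  dplyr::arrange(tb, .data$item1, .data$item2)
}

#' One-row summary of a distance matrix
#'
#' @param x A `mev_dist` object.
#' @param ... Unused.
#' @return A tibble with `n_taxa`, `min_distance`, `mean_distance`,
#'   `max_distance` over off-diagonal pairs.
#' @method glance mev_dist
#' @export
glance.mev_dist <- function(x, ...) {
  off <- unclass(x)[upper.tri(x)]
  tibble::tibble(n_taxa = nrow(x), min_distance = min(off),
                 mean_distance = mean(off), max_distance = max(off))
}

#' Heatmap of a pairwise distance matrix
#'
#' @param object A `mev_dist` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mev_dist
#' @export
autoplot.mev_dist <- function(object, ...) {
  tb <- tidy(object, upper = FALSE)
  ggplot2::ggplot(tb, ggplot2::aes(.data$item1, .data$item2, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "distance") +
    ggplot2::scale_y_discrete(limits = rev(levels(tb$item2))) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Pairwise distances (", attr(object, "method"), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
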