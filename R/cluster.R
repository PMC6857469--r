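#' Breed clustering on frequency vectors
#'
#' Breeds are compared by the Euclidean distance between their frequency
#' vectors (protein-variant frequencies, haplotype frequencies, or
#' per-SNP alternative-allele frequencies -- all run through the same code
#' path), and clustered agglomeratively with unweighted average linkage
#' (UPGMA). Frequencies enter raw, without standardization.
#'
#' @name breed-cluster
NULL

#' Euclidean distance matrix between breeds
#'
#' @param freq_table numeric matrix, features (haplotypes, variants or
#'   SNPs) x breeds; absent features must be 0, NA is an error.
#' @return symmetric numeric matrix breeds x breeds with zero diagonal.
#' @export
euclidean_distances <- function(freq_table) {
  if (anyNA(freq_table)) stop("NA frequencies in distance input")
  d <- as.matrix(stats::dist(t(freq_table), method = "euclidean"))
  dimnames(d) <- list(colnames(freq_table), colnames(freq_table))
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Iteratively merges the closest pair of clusters; the distance between
#' clusters is the unweighted mean of all member pairwise distances. Ties
#' are broken deterministically towards the lexicographically smallest
#' pair of cluster labels (a cluster is labelled by its smallest member).
#'
#' @param d symmetric distance matrix with labels (>= 2 items).
#' @return object of class `upgma`: fields `merge`, `height`, `labels`,
#'   `order` as in [stats::hclust()].
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two items to cluster")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: id (negative leaf / positive merge row), members, label
  act <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, label = labels[i]))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(act)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(d[act[[i]]$members, act[[j]]$members])
      lab <- sort(c(act[[i]]$label, act[[j]]$label))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
        best <- list(i = i, j = j, d = dij, lab = lab)
      }
    }
    a <- act[[best$i]]; b <- act[[best$j]]
    merge[step, ] <- sort(c(a$id, b$id))
    height[step] <- best$d
    act[[best$i]] <- list(id = step, members = c(a$members, b$members),
                          label = min(a$label, b$label))
    act[[best$j]] <- NULL
  }
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) ord <<- c(ord, -node)
    else { walk(merge[node, 1]); walk(merge[node, 2]) }
  }
  walk(n - 1)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, method = "average"),
            class = "upgma")
}

#' @export
as.hclust.upgma <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' @export
print.upgma <- function(x, ...) {
  cat(sprintf("<upgma> %d leaves, %d merges, height range [%.4g, %.4g]\n",
              length(x$labels), nrow(x$merge), min(x$height), max(x$height)))
  invisible(x)
}

#' Newick serialization of a UPGMA tree
#'
#' Uses the ultrametric convention: leaf-to-leaf patristic distance equals
#' the merge height of their most recent common ancestor (node heights are
#' half the merge heights).
#'
#' @param tree an `upgma` tree (or `hclust`).
#' @return Newick string, terminated with ";".
#' @export
to_newick <- function(tree) {
  ph <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(ph)
}

#' Nearest breed by Euclidean distance
#'
#' @param d distance matrix from [euclidean_distances()].
#' @param breed row label.
#' @return name of the closest other breed.
#' @export
nearest_breed <- function(d, breed) {
  v <- d[breed, ]
  v <- v[names(v) != breed]
  names(v)[which.min(v)]
}
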