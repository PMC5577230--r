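# Jaccard similarity of binary fingerprint profiles, UPGMA dendrograms with
# deterministic tie-breaking, and similarity-threshold grouping.

#' Jaccard similarity of two binary profiles
#'
#' `a / (a + b + c)` with `a` = shared presences and `b`, `c` the presences
#' unique to each profile; joint absences are ignored.
#'
#' @param rowA,rowB equal-length binary (0/1 or logical) vectors.
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(rowA, rowB) {
  rowA <- as.logical(rowA)
  rowB <- as.logical(rowB)
  if (length(rowA) != length(rowB)) stop_param("profiles must have equal length")
  union <- sum(rowA | rowB)
  if (union == 0) {
    stop_param("undefined similarity: both profiles are all-zero (empty lanes)")
  }
  sum(rowA & rowB) / union
}

#' All-pairs Jaccard similarity matrix
#'
#' @param m binary matrix (rows = profiles) with unique row names.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
jaccard_matrix <- function(m) {
  m <- (m > 0) + 0
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop_param("matrix needs unique row names")
  }
  zero <- rownames(m)[rowSums(m) == 0]
  if (length(zero) > 1) {
    stop_param(
      "undefined similarity between empty profiles: ",
      paste(zero, collapse = ", ")
    )
  }
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  s <- ifelse(union == 0, 1, inter / union)
  diag(s) <- 1
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Agglomerative clustering on distance `1 - similarity`: at each step the
#' closest pair of clusters merges (ties broken by the lexicographically
#' smallest pair of cluster labels, a cluster's label being its smallest
#' leaf id), and the distance from the merged cluster to any other is the
#' unweighted arithmetic mean over all cross pairs of leaves. Merge heights
#' are cophenetic distances, so the result is `stats::hclust`-compatible
#' (`cutree`, `cophenetic`, `as.dendrogram` all work); the ultrametric tree
#' convention (node height = merge distance / 2) is applied on Newick
#' export.
#'
#' @param similarities symmetric matrix in \[0, 1\] with unique dimnames,
#'   n >= 2.
#' @return object of class `c("upgma", "hclust")`.
#' @export
upgma <- function(similarities) {
  s <- as.matrix(similarities)
  n <- nrow(s)
  if (n < 2) stop_param("need at least 2 profiles")
  if (!isSymmetric(unname(s), tol = 1e-8)) stop_param("similarity matrix must be symmetric")
  if (any(s < -1e-12 | s > 1 + 1e-12)) stop_param("similarities must lie in [0, 1]")
  labels <- rownames(s)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop_param("similarity matrix needs unique dimnames")
  }
  d <- 1 - s
  # active clusters: negative = singleton leaf index, positive = merge row
  active <- as.list(-seq_len(n))
  sizes <- rep(1L, n)
  labmin <- labels # lexicographically smallest leaf label per cluster
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        key <- sort(c(labmin[i], labmin[j]))
        if (is.null(best) ||
          D[i, j] < best$d - 1e-12 ||
          (abs(D[i, j] - best$d) <= 1e-12 &&
            (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = D[i, j], i = i, j = j, key = key)
        }
      }
    }
    i <- best$i
    j <- best$j
    merge[step, ] <- c(active[[i]], active[[j]])
    height[step] <- best$d
    new_size <- sizes[i] + sizes[j]
    new_row <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / new_size
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(
      cbind(D[keep, keep, drop = FALSE], new_row[keep]),
      c(new_row[keep], 0),
      deparse.level = 0
    )
    active <- c(active[keep], list(step))
    sizes <- c(sizes[keep], new_size)
    labmin <- c(labmin[keep], min(best$key))
  }
  # UPGMA guarantees monotone heights; assert, then absorb float-epsilon
  # wobble so downstream cutree/cophenetic see a sorted sequence
  if (any(diff(height) < -1e-8)) {
    stop("internal error: UPGMA merge heights decreased")
  }
  height <- cummax(height)
  # leaf order for plotting: recursive left-to-right traversal
  ord <- integer(0)
  walk <- function(node) {
    if (node < 0) {
      ord <<- c(ord, -node)
    } else {
      walk(merge[node, 1])
      walk(merge[node, 2])
    }
  }
  walk(n - 1L)
  structure(
    list(
      merge = merge, height = height, order = ord, labels = labels,
      method = "upgma", call = match.call(),
      dist.method = "1 - Jaccard"
    ),
    class = c("upgma", "hclust")
  )
}

#' Cut a dendrogram at a similarity threshold
#'
#' Leaves connected below cophenetic distance `1 - s` form one group; a
#' pair merging at exactly the threshold similarity is kept together.
#'
#' @param dend an `upgma` dendrogram (or any `hclust`).
#' @param s similarity threshold in \[0, 1\].
#' @return named integer vector of group memberships (groups numbered by
#'   first appearance in label order).
#' @export
cut_at_similarity <- function(dend, s) {
  if (s < 0 || s > 1) stop_param("similarity threshold must be in [0, 1]")
  stats::cutree(dend, h = (1 - s) + 1e-9)
}

#' Fingerprint grouping report
#'
#' Distinct-fragment count (matrix columns) and UPGMA groups of the
#' isolates' restriction profiles at a similarity cut.
#'
#' @param matrix binary band matrix (isolates x fragment bins).
#' @param s similarity threshold (default 0.93).
#' @return list with `n_fragments`, `n_groups`, `groups` (named
#'   memberships), and `dendrogram`.
#' @export
fingerprint_report <- function(matrix, s = 0.93) {
  if (nrow(matrix) == 1) {
    groups <- stats::setNames(1L, rownames(matrix))
    return(list(
      n_fragments = ncol(matrix), n_groups = 1L,
      groups = groups, dendrogram = NULL
    ))
  }
  sim <- jaccard_matrix(matrix)
  dend <- upgma(sim)
  groups <- cut_at_similarity(dend, s)
  list(
    n_fragments = ncol(matrix),
    n_groups = length(unique(groups)),
    groups = groups,
    dendrogram = dend
  )
}
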