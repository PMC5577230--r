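# Distance-based neighbor-joining phylogenetics with bootstrap support, for
# 16S alignments and translated biosynthetic gene fragments.

# Coerce an alignment (named equal-length character vector, XStringSet, or
# character matrix rows=taxa) to a character matrix of single residues.
.aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) stop_param("alignment rows must be named")
    return(aln)
  }
  nms <- names(aln)
  aln <- stats::setNames(as.character(aln), nms)
  if (is.null(names(aln))) stop_param("alignment sequences must be named")
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) {
    stop_param("aligned sequences must have equal length")
  }
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

.comparable_codes <- function(model) {
  if (model == "protein-p") {
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  } else {
    c("A", "C", "G", "T")
  }
}

#' Proportion of differing sites between two aligned sequences
#'
#' Columns with a gap or ambiguity code in either sequence are excluded;
#' the distance is mismatching comparable columns / comparable columns.
#'
#' @param a,b aligned residue strings of equal length.
#' @param model `"p-distance"` (nucleotide) or `"protein-p"`.
#' @return fraction in \[0, 1\].
#' @export
p_distance <- function(a, b, model = c("p-distance", "protein-p")) {
  model <- match.arg(model)
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y)) stop_param("sequences must be aligned (equal length)")
  ok <- .comparable_codes(model)
  keep <- x %in% ok & y %in% ok
  if (!any(keep)) stop_param("undefined distance: zero comparable columns")
  sum(x[keep] != y[keep]) / sum(keep)
}

#' Jukes–Cantor correction of a p-distance
#'
#' @param p observed proportion of differing sites, `0 <= p < 0.75`.
#' @return `-(3/4) * log(1 - 4p/3)`.
#' @export
jc_correct <- function(p) {
  if (any(p < 0) || any(p >= 0.75)) {
    stop_param("saturation: Jukes-Cantor correction requires 0 <= p < 0.75")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' All-pairs distance matrix from an alignment
#'
#' Vectorized over one-hot residue indicators, so it matches [p_distance()]
#' applied to every pair but runs in matrix-multiply time (used heavily by
#' the bootstrap).
#'
#' @param aln alignment (named character vector, XStringSet, or character
#'   matrix).
#' @param model `"p-distance"`, `"jukes-cantor"`, or `"protein-p"`.
#' @return symmetric distance matrix with a `model` attribute.
#' @export
distance_matrix <- function(aln,
                            model = c("p-distance", "jukes-cantor", "protein-p")) {
  model <- match.arg(model)
  m <- .aln_matrix(aln)
  codes <- .comparable_codes(if (model == "protein-p") "protein-p" else "p-distance")
  comp <- matrix(m %in% codes, nrow(m), ncol(m))
  shared <- comp %*% t(comp) # comparable columns per pair
  same <- matrix(0, nrow(m), nrow(m))
  for (b in codes) {
    ind <- matrix(m == b, nrow(m), ncol(m))
    same <- same + ind %*% t(ind)
  }
  if (any(shared == 0)) stop_param("undefined distance: zero comparable columns")
  d <- (shared - same) / shared
  if (model == "jukes-cantor") d[] <- jc_correct(pmin(d, 0.749999))
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Standard saitou-nei neighbor joining on a distance matrix: at each step
#' the pair minimizing the Q criterion is joined (ties broken by the
#' smallest index pair in current matrix order); negative branch lengths are
#' clamped to zero with the total deficit recorded in the
#' `clamped_deficit` attribute. On additive distances the input tree is
#' recovered exactly.
#'
#' @param d symmetric distance matrix with unique dimnames, n >= 3.
#' @return an unrooted `phylo` tree with a trifurcating root.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop_param("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(d))) stop_param("non-finite distances")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop_param("distance matrix needs unique row names")
  }
  n_internal <- n - 2L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  deficit <- 0
  # active cluster -> ape node id; internal ids assigned top-down so the
  # final (root) join receives n+1, as the phylo convention expects
  nodes <- seq_len(n)
  next_internal <- n + n_internal # counts down to n+1
  D <- d
  clamp <- function(x) {
    if (x < 0) {
      deficit <<- deficit + (-x)
      0
    } else {
      x
    }
  }
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]
    j <- hits[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_id <- next_internal
    next_internal <- next_internal - 1L
    edges <- rbind(edges, c(new_id, nodes[i]), c(new_id, nodes[j]))
    lens <- c(lens, clamp(li), clamp(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
      c(dnew[keep], 0),
      deparse.level = 0
    )
    nodes <- c(nodes[keep], new_id)
  }
  # final trifurcation: three-point formulas
  root <- n + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(
    edges,
    c(root, nodes[1]), c(root, nodes[2]), c(root, nodes[3])
  )
  lens <- c(lens, clamp(l1), clamp(l2), clamp(l3))
  tree <- structure(
    list(
      edge = edges, edge.length = lens,
      tip.label = labels, Nnode = n_internal
    ),
    class = "phylo"
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports the percentage of replicates containing each
#' internal bipartition of the full-alignment tree (as `node.label`).
#'
#' @param aln alignment (see [distance_matrix()]).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; supports are a pure function of it.
#' @param model distance model passed to [distance_matrix()].
#' @return the NJ tree on the full alignment with `node.label` holding
#'   supports in \[0, 100\] (root label `NA`).
#' @export
bootstrap_support <- function(aln, n_reps, seed = 1,
                              model = "p-distance") {
  if (n_reps < 1) stop_param("n_reps must be >= 1")
  m <- .aln_matrix(aln)
  if (ncol(m) < 2) stop_param("alignment must have at least 2 columns")
  tree <- neighbor_joining(distance_matrix(m, model))
  reps <- with_local_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample(ncol(m), ncol(m), replace = TRUE)
      neighbor_joining(distance_matrix(m[, cols, drop = FALSE], model))
    })
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  support[1] <- NA # root of an unrooted tree carries no bipartition
  tree$node.label <- support
  tree
}

#' Translate a biosynthetic gene fragment
#'
#' Translates all six reading frames with the standard genetic code and
#' returns the frame with the longest stop-free stretch (ties broken in
#' frame order +1, +2, +3, -1, -2, -3). A warning is emitted when no frame
#' has at least 10 consecutive stop-free residues.
#'
#' @param nt DNA string, length >= 3.
#' @return the translation of the chosen frame (may contain `*`), with the
#'   frame name in attribute `frame`.
#' @export
translate_fragment <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) < 3) stop_param("sequence must be at least 3 nt")
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- list()
  for (off in 0:2) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      if (length(s) - off < 3) next
      sub <- Biostrings::subseq(s, off + 1)
      sub <- Biostrings::subseq(sub, 1, 3 * (length(sub) %/% 3))
      aa <- as.character(Biostrings::translate(
        sub,
        if.fuzzy.codon = "solve", no.init.codon = TRUE
      ))
      frames[[paste0(strand, off + 1)]] <- aa
    }
  }
  order_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  order_names <- order_names[order_names %in% names(frames)]
  stretch <- vapply(order_names, function(f) {
    runs <- strsplit(frames[[f]], "*", fixed = TRUE)[[1]]
    if (length(runs) == 0) 0L else max(nchar(runs))
  }, integer(1))
  best <- order_names[which.max(stretch)]
  if (max(stretch) < 10) {
    warning("low-quality translation: longest stop-free stretch is ",
      max(stretch), " residues",
      call. = FALSE
    )
  }
  structure(frames[[best]], frame = best)
}
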