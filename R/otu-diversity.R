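# Pairwise 16S identity, threshold OTU clustering, dereplication and
# composition summaries.

#' Alignment parameters for identity computation
#'
#' @param match,mismatch substitution scores (IUPAC-compatible positions,
#'   i.e. intersecting base sets, score as matches).
#' @param gap_opening,gap_extension gap penalties (positive costs).
#' @return list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1,
                         gap_opening = 2, gap_extension = 0.5) {
  structure(
    list(
      match = match, mismatch = mismatch,
      gap_opening = gap_opening, gap_extension = gap_extension
    ),
    class = "align_params"
  )
}

.identity_cache <- new.env(parent = emptyenv())

# IUPAC code-pair compatibility (intersecting base sets), with "-" never
# compatible; cached since it is hit once per alignment column.
.iupac_compat <- function() {
  if (is.null(.identity_cache$compat)) {
    sets <- iupac_sets()
    codes <- c(names(sets), "-")
    m <- matrix(FALSE, length(codes), length(codes),
      dimnames = list(codes, codes)
    )
    for (i in names(sets)) {
      for (j in names(sets)) {
        m[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0
      }
    }
    .identity_cache$compat <- m
  }
  .identity_cache$compat
}

# Substitution matrix over the IUPAC alphabet: +match when the base sets of
# the two codes intersect, else mismatch; cached per score pair.
.iupac_submat <- function(params) {
  key <- paste0("sub_", params$match, "_", params$mismatch)
  if (is.null(.identity_cache[[key]])) {
    compat <- .iupac_compat()
    codes <- setdiff(rownames(compat), "-")
    m <- ifelse(
      compat[codes, codes], params$match, params$mismatch
    )
    .identity_cache[[key]] <- m
  }
  .identity_cache[[key]]
}

.iupac_compatible_chars <- function(a, b) {
  .iupac_compat()[cbind(a, b)]
}

# Identity from two gapped alignment rows: terminal-gap columns (leading or
# trailing gap runs in either row) are excluded from the denominator;
# internal gap columns count as mismatches; IUPAC-compatible pairs as matches.
.identity_from_alignment <- function(p, s) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(pc)
  term <- rep(FALSE, n)
  for (ch in list(pc, sc)) {
    r <- rle(ch == "-")
    if (r$values[1]) term[seq_len(r$lengths[1])] <- TRUE
    if (r$values[length(r$values)]) {
      term[seq(n - r$lengths[length(r$lengths)] + 1, n)] <- TRUE
    }
  }
  keep <- which(!term)
  if (length(keep) == 0) {
    stop_param("alignment has no non-terminal columns")
  }
  matches <- sum(.iupac_compatible_chars(pc[keep], sc[keep]))
  matches / length(keep)
}

#' Pairwise sequence identity
#'
#' Global (Needleman–Wunsch) alignment under the configured scores with end
#' gaps penalized, then identity = matched columns / alignment columns,
#' excluding columns that fall in a terminal gap run of either sequence (so
#' a sequence fully contained in a longer one scores 1.0). Positions whose
#' IUPAC base sets intersect count as matches; internal gap columns count as
#' mismatch columns.
#'
#' @param a,b DNA strings (IUPAC codes allowed).
#' @param params an [align_params()].
#' @return identity fraction in \[0, 1\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop_param("sequences must be non-empty")
  # co-optimal alignments can differ between argument orders; align the
  # canonically ordered pair so the result is exactly symmetric
  if (a > b) {
    tmp <- a
    a <- b
    b <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    substitutionMatrix = .iupac_submat(params),
    gapOpening = params$gap_opening, gapExtension = params$gap_extension,
    type = "global"
  )
  .identity_from_alignment(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln))
  )
}

#' All-pairs identity matrix
#'
#' @param seqs named character vector or DNAStringSet with unique ids.
#' @param params an [align_params()].
#' @return symmetric matrix of identity fractions with unit diagonal.
#' @export
identity_matrix <- function(seqs, params = align_params()) {
  ids <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), ids)
  if (is.null(ids)) stop_param("sequences must be named")
  if (anyDuplicated(ids)) stop_param("duplicate sequence ids")
  n <- length(seqs)
  if (n < 2) stop_param("need at least 2 sequences")
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  submat <- .iupac_submat(params)
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    # canonical pair order (see pairwise_identity) keeps the matrix exactly
    # symmetric and equal to the scalar function on every pair
    pat <- ifelse(seqs[i] <= seqs[rest], seqs[i], seqs[rest])
    sub <- ifelse(seqs[i] <= seqs[rest], seqs[rest], seqs[i])
    alns <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(pat), Biostrings::DNAStringSet(sub),
      substitutionMatrix = submat,
      gapOpening = params$gap_opening, gapExtension = params$gap_extension,
      type = "global"
    )
    ps <- as.character(Biostrings::alignedPattern(alns))
    ss <- as.character(Biostrings::alignedSubject(alns))
    for (k in seq_along(ps)) {
      v <- .identity_from_alignment(ps[k], ss[k])
      m[i, i + k] <- v
      m[i + k, i] <- v
    }
  }
  m
}

#' Cluster sequences into OTUs at an identity threshold
#'
#' Complete-linkage agglomerative clustering on distance `1 - identity`, cut
#' so that every within-cluster pair has identity >= `threshold`. The
#' representative of each cluster is its longest member (ties broken by
#' lexicographic id).
#'
#' @param m identity matrix from [identity_matrix()].
#' @param threshold identity threshold in (0, 1].
#' @param sequences optional named sequences (used to pick the longest-member
#'   representative; without them ties fall back to lexicographic id).
#' @return an `otu_partition`: list with `threshold`, `clusters` (named list
#'   of id vectors, `OTU01`, `OTU02`, ...), `representatives`, and
#'   `membership` (named integer vector).
#' @export
cluster_otus <- function(m, threshold, sequences = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_param("threshold must be in (0, 1]")
  }
  ids <- rownames(m)
  stopifnot(!is.null(ids), isSymmetric(unname(m)))
  hc <- stats::hclust(stats::as.dist(1 - m), method = "complete")
  membership <- stats::cutree(hc, h = (1 - threshold) + 1e-9)
  membership <- membership[ids]
  # renumber clusters by first appearance in input order
  relabel <- stats::setNames(seq_along(unique(membership)), unique(membership))
  membership <- stats::setNames(
    as.integer(relabel[as.character(membership)]), ids
  )
  cluster_ids <- split(ids, membership)
  names(cluster_ids) <- sprintf("OTU%02d", as.integer(names(cluster_ids)))
  lens <- if (!is.null(sequences)) {
    nchar(as.character(sequences))[match(ids, names(sequences))]
  } else {
    rep(0L, length(ids))
  }
  names(lens) <- ids
  reps <- vapply(cluster_ids, function(members) {
    members[order(-lens[members], members)][1]
  }, character(1))
  structure(
    list(
      threshold = threshold, clusters = cluster_ids,
      representatives = reps, membership = membership
    ),
    class = "otu_partition"
  )
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(
    "OTU partition at", sprintf("%.0f%%", 100 * x$threshold), "identity:",
    length(x$clusters), "OTUs over", length(x$membership), "sequences\n"
  )
  invisible(x)
}

#' Dereplicate a 100%-identity partition
#'
#' @param p an `otu_partition` built at threshold 1.0.
#' @return list with `representatives` (in input order) and `duplicates`
#'   (total ids minus number of clusters).
#' @export
dereplicate <- function(p) {
  if (!inherits(p, "otu_partition") || p$threshold != 1.0) {
    stop_param("dereplicate() requires a partition built at threshold 1.0")
  }
  ids <- names(p$membership)
  reps <- p$representatives[order(match(p$representatives, ids))]
  list(
    representatives = unname(reps),
    duplicates = length(ids) - length(p$clusters)
  )
}

#' Per-genus OTU composition
#'
#' An OTU's genus is the genus of its representative; percentages use the
#' shared round-half-up one-decimal rule.
#'
#' @param p an `otu_partition`.
#' @param genus_of named character vector id -> genus.
#' @return data.frame (genus, n_otus, pct), sorted by decreasing count.
#' @export
composition_summary <- function(p, genus_of) {
  reps <- p$representatives
  missing <- reps[!reps %in% names(genus_of)]
  if (length(missing) > 0) {
    stop_param(
      "missing genus label for: ", paste(missing, collapse = ", ")
    )
  }
  genera <- genus_of[reps]
  tab <- sort(table(genera), decreasing = TRUE)
  data.frame(
    genus = names(tab),
    n_otus = as.integer(tab),
    pct = percent_of(as.integer(tab), length(reps)),
    row.names = NULL
  )
}
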