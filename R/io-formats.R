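# Readers/writers for the plain-text formats the pipeline touches:
# FASTA, Newick, and named TSV matrices.

.alphabet_chars <- list(
  dna = c(names(Biostrings::IUPAC_CODE_MAP), "-"),
  protein = c(strsplit("ACDEFGHIKLMNPQRSTVWYBJZXUO", "")[[1]], "*", "-")
)

#' Read a FASTA file with alphabet validation
#'
#' Wrapped lines are joined, residues are upper-cased, and every residue is
#' validated against the declared alphabet; a violation is reported with the
#' offending record id and 1-based residue position.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` (IUPAC nucleotide codes) or `"protein"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet]; names
#'   hold the record ids, the `description` metadata column holds any text
#'   after the first whitespace of each header.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_param("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop_param("format error: empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(raw))
  legal <- .alphabet_chars[[alphabet]]
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    if (length(ch) == 0) {
      stop_param("format error: empty sequence for record '", ids[[i]], "'")
    }
    bad <- which(!ch %in% legal)
    if (length(bad) > 0) {
      stop_param(
        "format error: illegal ", alphabet, " character '", ch[bad[1]],
        "' in record '", ids[[i]], "' at position ", bad[1]
      )
    }
  }
  out <- if (alphabet == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector or XStringSet.
#' @param path output path.
#' @param width line-wrap column (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  nms <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), nms)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop_param("all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# Quote a Newick label if it contains metacharacters.
.newick_label <- function(x) {
  if (grepl("[][():;,'\" \t]", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}

#' Serialize a tree as Newick text
#'
#' Handles both `phylo` trees (e.g. from [neighbor_joining()]; written as-is,
#' unrooted trees keep their trifurcating root) and ultrametric UPGMA
#' dendrograms from [upgma()] (rooted; node height = merge distance / 2 so
#' leaf-to-leaf path length equals the cophenetic distance). Branch lengths
#' are printed with six decimals; labels containing metacharacters are
#' single-quoted.
#'
#' @param tree a `phylo` object or an `upgma` dendrogram.
#' @param path optional file path; when given the text is also written there.
#' @return the Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  text <- if (inherits(tree, "phylo")) {
    .newick_phylo(tree)
  } else if (inherits(tree, "hclust")) {
    .newick_upgma(tree)
  } else {
    stop_param("unsupported tree class: ", paste(class(tree), collapse = "/"))
  }
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

.newick_phylo <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    stop_param("serialization error: duplicate leaf names")
  }
  n <- length(tree$tip.label)
  if (n == 1) {
    return(paste0(.newick_label(tree$tip.label), ":0.000000;"))
  }
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lens <- tree$edge.length %||% rep(0, nrow(tree$edge))
  rec <- function(node, edge_idx) {
    lab <- if (node <= n) {
      .newick_label(tree$tip.label[node])
    } else {
      kid_edges <- children[[as.character(node)]]
      inner <- vapply(
        kid_edges,
        function(e) rec(tree$edge[e, 2], e),
        character(1)
      )
      nl <- tree$node.label[node - n]
      nl <- if (is.null(tree$node.label) || is.na(nl)) "" else as.character(nl)
      paste0("(", paste(inner, collapse = ","), ")", nl)
    }
    if (is.na(edge_idx)) lab else sprintf("%s:%.6f", lab, lens[edge_idx])
  }
  root <- n + 1L
  paste0(rec(root, NA), ";")
}

.newick_upgma <- function(hc) {
  if (anyDuplicated(hc$labels)) {
    stop_param("serialization error: duplicate leaf names")
  }
  n <- length(hc$labels)
  if (n == 1) {
    return(paste0(.newick_label(hc$labels), ":0.000000;"))
  }
  # node heights on the tree scale are merge heights / 2 (ultrametric)
  rec <- function(i) {
    # i < 0: leaf -i ; i > 0: merge row i
    if (i < 0) {
      list(text = .newick_label(hc$labels[-i]), height = 0)
    } else {
      h <- hc$height[i] / 2
      a <- rec(hc$merge[i, 1])
      b <- rec(hc$merge[i, 2])
      list(
        text = sprintf(
          "(%s:%.6f,%s:%.6f)",
          a$text, h - a$height, b$text, h - b$height
        ),
        height = h
      )
    }
  }
  paste0(rec(nrow(hc$merge))$text, ";")
}

#' Parse Newick text
#'
#' Thin wrapper over [ape::read.tree()] so `write_newick()` round-trips.
#'
#' @param text Newick string (or use `file`).
#' @param file optional path to read from instead.
#' @return a `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) {
    ape::read.tree(file)
  } else {
    ape::read.tree(text = text)
  }
}

#' Write / read a named matrix as TSV
#'
#' Tab-separated with a header row and a leading row-name column; the pair is
#' inverse on valid data (numeric or 0/1 matrices with unique dimnames).
#'
#' @param m matrix with unique row and column names.
#' @param path output path.
#' @return `path` invisibly (`write_matrix`); the matrix (`read_matrix`).
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) && nrow(m) > 0) stop_param("matrix must have row names")
  if (is.null(colnames(m)) && ncol(m) > 0) stop_param("matrix must have column names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_param("row/column names must be unique")
  }
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    colClasses = NA, stringsAsFactors = FALSE
  )
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
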