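# Antibacterial-activity summaries, activity x biosynthetic-gene
# cross-tabulation, and export of the relationship as a tripartite network.

#' Summarize an activity table
#'
#' @param t logical matrix, isolates x test strains.
#' @param gram_map named character vector strain -> `"positive"`/`"negative"`
#'   for the Gram-class rollup (default panel mapping); every strain column
#'   must be mapped.
#' @return list with `n_isolates`, `n_active`, `per_strain` (count and
#'   percentage of active isolates inhibiting each strain), and `per_class`
#'   (active isolates inhibiting >= 1 strain of each Gram class). All
#'   percentages are relative to the active-isolate count; the summary is
#'   empty when no isolate is active.
#' @export
activity_summary <- function(t, gram_map = default_gram_classes()) {
  strains <- colnames(t)
  unmapped <- strains[!strains %in% names(gram_map)]
  if (length(unmapped) > 0) {
    stop_param(
      "no Gram class for test strain: ", paste(unmapped, collapse = ", ")
    )
  }
  t <- t > 0
  active <- rowSums(t) > 0
  n_active <- sum(active)
  if (n_active == 0) {
    return(list(
      n_isolates = nrow(t), n_active = 0L,
      per_strain = data.frame(
        strain = character(0), count = integer(0), pct = numeric(0)
      ),
      per_class = data.frame(
        gram_class = character(0), count = integer(0), pct = numeric(0)
      )
    ))
  }
  ta <- t[active, , drop = FALSE]
  per_strain <- data.frame(
    strain = strains,
    count = as.integer(colSums(ta)),
    pct = percent_of(as.integer(colSums(ta)), n_active),
    row.names = NULL
  )
  classes <- sort(unique(gram_map[strains]))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    hit <- rowSums(ta[, gram_map[strains] == cl, drop = FALSE]) > 0
    data.frame(gram_class = cl, count = sum(hit), pct = percent_of(sum(hit), n_active))
  }))
  rownames(per_class) <- NULL
  list(
    n_isolates = nrow(t), n_active = as.integer(n_active),
    per_strain = per_strain, per_class = per_class
  )
}

#' Cross-tabulate activity with biosynthetic-gene presence
#'
#' Active isolates are partitioned into three categories: carrying both
#' loci, exactly one, or neither; the count of gene-positive but inactive
#' isolates is reported alongside.
#'
#' @param t logical activity matrix (isolates x strains).
#' @param g logical presence matrix (isolates x loci) over the same
#'   isolates.
#' @return list of class `correlation_summary` with `n_active`, `counts`
#'   (both/one/neither), `pct`, `inactive_gene_positive`, and the per-isolate
#'   `category` vector (`both`/`one`/`neither` for every isolate).
#' @export
crosstab_activity_genes <- function(t, g) {
  if (!setequal(rownames(t), rownames(g))) {
    stop_param(
      "isolate universes differ: ",
      paste(
        c(setdiff(rownames(t), rownames(g)), setdiff(rownames(g), rownames(t))),
        collapse = ", "
      )
    )
  }
  g <- g[rownames(t), , drop = FALSE] > 0
  t <- t > 0
  n_genes <- rowSums(g)
  category <- c("neither", "one", "both")[pmin(n_genes, 2) + 1]
  names(category) <- rownames(t)
  active <- rowSums(t) > 0
  counts <- c(
    both = sum(active & category == "both"),
    one = sum(active & category == "one"),
    neither = sum(active & category == "neither")
  )
  n_active <- sum(active)
  pct <- if (n_active > 0) {
    stats::setNames(percent_of(as.integer(counts), n_active), names(counts))
  } else {
    stats::setNames(rep(NA_real_, 3), names(counts))
  }
  structure(
    list(
      n_active = as.integer(n_active),
      counts = counts,
      pct = pct,
      inactive_gene_positive = sum(!active & n_genes > 0),
      category = category
    ),
    class = "correlation_summary"
  )
}

#' Build the tripartite activity/gene network
#'
#' Nodes are isolates, loci, and test strains; an isolate is connected to
#' every locus it carries and every strain it inhibits.
#'
#' @param t logical activity matrix.
#' @param g logical presence matrix over the same isolates.
#' @param genus_of optional named genus lookup stored as a node attribute.
#' @return list with `edges` (data.frame from/to/type, sorted) and `nodes`
#'   (data.frame id/kind/genus/category).
#' @export
build_network <- function(t, g, genus_of = NULL) {
  xt <- crosstab_activity_genes(t, g)
  g <- g[rownames(t), , drop = FALSE] > 0
  t <- t > 0
  gene_idx <- which(g, arr.ind = TRUE)
  act_idx <- which(t, arr.ind = TRUE)
  edges <- rbind(
    if (nrow(gene_idx) > 0) {
      data.frame(
        from = rownames(g)[gene_idx[, 1]],
        to = colnames(g)[gene_idx[, 2]],
        type = "gene"
      )
    },
    if (nrow(act_idx) > 0) {
      data.frame(
        from = rownames(t)[act_idx[, 1]],
        to = colnames(t)[act_idx[, 2]],
        type = "activity"
      )
    }
  )
  if (is.null(edges)) {
    edges <- data.frame(
      from = character(0), to = character(0), type = character(0)
    )
  }
  edges <- edges[order(edges$from, edges$type, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(
      id = rownames(t), kind = "isolate",
      genus = if (is.null(genus_of)) NA_character_ else unname(genus_of[rownames(t)]),
      category = unname(xt$category[rownames(t)])
    ),
    data.frame(id = colnames(g), kind = "locus", genus = NA, category = NA),
    data.frame(id = colnames(t), kind = "strain", genus = NA, category = NA)
  )
  list(edges = edges, nodes = nodes)
}

#' Export a network
#'
#' Writes either a sorted edge-list TSV (columns from/to/type/multiplicity;
#' duplicate edges collapsed with a multiplicity count) or GraphML via
#' igraph.
#'
#' @param network result of [build_network()] (or a bare `edges`
#'   data.frame).
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  edges <- if (is.data.frame(network)) network else network$edges
  nodes <- if (is.data.frame(network)) NULL else network$nodes
  key <- paste(edges$from, edges$to, edges$type, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  if (nrow(agg) > 0) {
    parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
    edges <- data.frame(
      from = parts[, 1], to = parts[, 2], type = parts[, 3],
      multiplicity = agg$Freq
    )
    edges <- edges[order(edges$from, edges$type, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(
      from = character(0), to = character(0), type = character(0),
      multiplicity = integer(0)
    )
  }
  if (format == "tsv") {
    utils::write.table(edges, path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    vertices <- if (!is.null(nodes)) {
      nodes[order(nodes$id), , drop = FALSE]
    } else {
      ids <- sort(unique(c(edges$from, edges$to)))
      data.frame(id = ids)
    }
    vertices[] <- lapply(vertices, function(col) {
      col[is.na(col)] <- ""
      as.character(col)
    })
    gr <- igraph::graph_from_data_frame(
      edges,
      directed = FALSE, vertices = vertices
    )
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}
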