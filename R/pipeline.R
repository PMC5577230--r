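# End-to-end orchestration: synthetic community (or ingested FASTA/TSV
# inputs) -> OTU clustering -> NJ tree -> biosynthetic screen ->
# restriction fingerprints -> Jaccard/UPGMA grouping -> activity network ->
# summary report. Deterministic under a single seed; every artifact is
# stamped with the config hash.

#' Pipeline configuration
#'
#' Aggregates every stage parameter. Defaults follow the study conditions
#' the package emulates: identity thresholds 1.0/0.99/0.98, the NRPS/PKS-II
#' degenerate primer pairs, AluI + HaeIII digestion, the 5% densitometry
#' area rule, and the 0.93 similarity cut.
#'
#' @param community a [community_config()] for the simulate stage.
#' @param thresholds OTU identity thresholds (must include 1.0 for
#'   dereplication).
#' @param composition_threshold threshold whose partition is summarized per
#'   genus.
#' @param primer_pairs list of [primer_pair()]s for the screen stage.
#' @param enzymes list of [restriction_enzyme()]s.
#' @param gel a [gel_model()].
#' @param min_area densitometry area threshold (default 0.05).
#' @param similarity_cut UPGMA grouping similarity (default 0.93).
#' @param bootstrap_reps NJ bootstrap replicates (default 100).
#' @param stages character vector of stages to run, in dependency order.
#' @param dereplicate_before_screen screen only distinct (dereplicated)
#'   isolates, as the study did (default TRUE).
#' @param seed master seed; stage streams derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(community = community_config(seed = seed),
                            thresholds = c(1.0, 0.99, 0.98),
                            composition_threshold = 0.99,
                            primer_pairs = default_primer_pairs(),
                            enzymes = default_enzymes(),
                            gel = gel_model(),
                            min_area = 0.05,
                            similarity_cut = 0.93,
                            bootstrap_reps = 100,
                            stages = c(
                              "simulate", "otu", "tree", "screen",
                              "fingerprint", "cluster", "network", "report"
                            ),
                            dereplicate_before_screen = TRUE,
                            seed = 7) {
  if (!1.0 %in% thresholds) thresholds <- c(1.0, thresholds)
  structure(
    list(
      community = community, thresholds = sort(thresholds, decreasing = TRUE),
      composition_threshold = composition_threshold,
      primer_pairs = primer_pairs, enzymes = enzymes, gel = gel,
      min_area = min_area, similarity_cut = similarity_cut,
      bootstrap_reps = bootstrap_reps, stages = stages,
      dereplicate_before_screen = dereplicate_before_screen,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# Stable hash of the configuration, recorded in every artifact.
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

.stamp <- function(path, config) {
  writeLines(
    c(
      paste0("# config_hash: ", config_hash(config)),
      paste0("# seed: ", config$seed)
    ),
    paste0(path, ".stamp")
  )
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order, writing per-stage
#' outputs under `out_dir` and returning all in-memory results. A rerun
#' with an identical configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with one entry per executed stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config, out_dir = out_dir)
  on <- function(stage) stage %in% config$stages
  run_stage <- function(stage, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf(
      "[%s] done in %.1fs", stage,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ))
    out
  }

  if (on("simulate")) {
    res$community <- run_stage("simulate", function() {
      comm <- generate_community(config$community)
      write_community(comm, file.path(out_dir, "community"))
      .stamp(file.path(out_dir, "community"), config)
      comm
    })
  }
  comm <- res$community
  seqs <- stats::setNames(comm$sixteenS, comm$isolate_id)

  if (on("otu")) {
    res$otu <- run_stage("otu", function() {
      idm <- identity_matrix(seqs)
      partitions <- lapply(config$thresholds, function(th) {
        cluster_otus(idm, th, sequences = seqs)
      })
      names(partitions) <- sprintf("%g", config$thresholds)
      derep <- dereplicate(partitions[["1"]])
      comp <- composition_summary(
        partitions[[sprintf("%g", config$composition_threshold)]],
        genus_map(comm)
      )
      member <- do.call(cbind, lapply(partitions, function(p) p$membership))
      colnames(member) <- paste0("otu_", names(partitions))
      write_matrix(member, file.path(out_dir, "otu_membership.tsv"))
      utils::write.table(comp, file.path(out_dir, "otu_composition.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      list(
        identity = idm, partitions = partitions,
        dereplication = derep, composition = comp
      )
    })
  }

  if (on("tree")) {
    res$tree <- run_stage("tree", function() {
      tr <- bootstrap_support(
        seqs, config$bootstrap_reps,
        seed = derive_seed(config$seed, 1, 101)
      )
      write_newick(tr, file.path(out_dir, "tree_16S.nwk"))
      tr
    })
  }

  distinct_ids <- if (!is.null(res$otu) && config$dereplicate_before_screen) {
    res$otu$dereplication$representatives
  } else {
    comm$isolate_id
  }
  distinct <- comm[match(distinct_ids, comm$isolate_id), , drop = FALSE]

  if (on("screen")) {
    res$screen <- run_stage("screen", function() {
      tab <- screen_isolates(distinct, config$primer_pairs)
      summ <- screen_summary(tab, genus_map(comm))
      write_matrix(tab + 0L, file.path(out_dir, "screen_table.tsv"))
      utils::write.table(summ$overall, file.path(out_dir, "screen_summary.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      list(table = tab, summary = summ)
    })
  }

  if (on("fingerprint")) {
    res$fingerprint <- run_stage("fingerprint", function() {
      out <- list()
      for (pair in config$primer_pairs) {
        pos <- rownames(res$screen$table)[res$screen$table[, pair$locus]]
        if (length(pos) < 2) next
        amplicons <- vapply(pos, function(id) {
          tpl <- comm$markers[[match(id, comm$isolate_id)]][[pair$locus]]
          call <- insilico_pcr(tpl, pair)
          call$amplicons$sequence[call$amplicons$in_window][1]
        }, character(1))
        fp <- fingerprint_amplicons(
          amplicons, config$enzymes, config$gel, config$min_area
        )
        tag <- gsub("[^A-Za-z0-9]", "", pair$locus)
        for (nm in names(fp$matrices)) {
          write_matrix(
            fp$matrices[[nm]],
            file.path(out_dir, paste0("bands_", tag, "_", nm, ".tsv"))
          )
        }
        write_matrix(
          fp$combined, file.path(out_dir, paste0("bands_", tag, "_combined.tsv"))
        )
        out[[pair$locus]] <- fp
      }
      out
    })
  }

  if (on("cluster")) {
    res$cluster <- run_stage("cluster", function() {
      out <- list()
      for (locus in names(res$fingerprint)) {
        fp <- res$fingerprint[[locus]]
        rep <- fingerprint_report(fp$combined, config$similarity_cut)
        tag <- gsub("[^A-Za-z0-9]", "", locus)
        utils::write.table(
          data.frame(isolate_id = names(rep$groups), group = rep$groups),
          file.path(out_dir, paste0("groups_", tag, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
        if (!is.null(rep$dendrogram)) {
          write_newick(
            rep$dendrogram,
            file.path(out_dir, paste0("dendrogram_", tag, ".nwk"))
          )
        }
        out[[locus]] <- rep
      }
      out
    })
  }

  if (on("network")) {
    res$network <- run_stage("network", function() {
      act <- activity_table(comm)[distinct$isolate_id, , drop = FALSE]
      gene <- if (!is.null(res$screen)) {
        res$screen$table
      } else {
        screen_isolates(distinct, config$primer_pairs)
      }
      summ <- activity_summary(act)
      xt <- crosstab_activity_genes(act, gene)
      net <- build_network(act, gene, genus_map(comm))
      export_graph(net, file.path(out_dir, "network_edges.tsv"), "tsv")
      export_graph(net, file.path(out_dir, "network.graphml"), "graphml")
      list(activity = act, summary = summ, crosstab = xt, network = net)
    })
  }

  if (on("report")) {
    res$report <- run_stage("report", function() {
      rep <- render_report(res)
      writeLines(rep$lines, file.path(out_dir, "report.md"))
      .stamp(file.path(out_dir, "report.md"), config)
      rep
    })
  }
  invisible(res)
}

#' Render the pipeline summary report
#'
#' Tabulates isolate counts, per-threshold OTU counts, biosynthetic-gene
#' prevalence, fingerprint group counts, and the activity/gene
#' cross-tabulation; all percentages use the shared round-half-up
#' one-decimal rule.
#'
#' @param res the result list of [run_pipeline()] (at least one stage
#'   present).
#' @return list with `lines` (markdown text) and `stats` (named numeric
#'   vector of every reported quantity).
#' @export
render_report <- function(res) {
  if (is.null(res$community) && is.null(res$otu) && is.null(res$screen)) {
    stop_param("no stage outputs to report")
  }
  stats_out <- c()
  lines <- c("# Pipeline summary", "")
  if (!is.null(res$community)) {
    n <- nrow(res$community)
    aerial <- sum(res$community$aerial_mycelium)
    stats_out["n_isolates"] <- n
    stats_out["aerial_mycelium_pct"] <- percent_of(aerial, n)
    lines <- c(
      lines,
      sprintf("- Isolates: %d; %d (%s%%) with aerial mycelium.",
        n, aerial, format(percent_of(aerial, n))
      )
    )
  }
  if (!is.null(res$otu)) {
    for (nm in names(res$otu$partitions)) {
      k <- length(res$otu$partitions[[nm]]$clusters)
      stats_out[paste0("otus_", nm)] <- k
      lines <- c(lines, sprintf(
        "- OTUs at %s%% identity: %d", format(100 * as.numeric(nm)), k
      ))
    }
    stats_out["duplicates"] <- res$otu$dereplication$duplicates
    lines <- c(lines, sprintf(
      "- Duplicate isolates removed by dereplication: %d",
      res$otu$dereplication$duplicates
    ))
    top <- res$otu$composition[1, ]
    stats_out["top_genus_otu_pct"] <- top$pct
    lines <- c(lines, sprintf(
      "- %s accounts for %s%% of OTUs at the composition threshold.",
      top$genus, format(top$pct)
    ))
  }
  if (!is.null(res$screen)) {
    ov <- res$screen$summary$overall
    for (r in seq_len(nrow(ov))) {
      stats_out[paste0("screen_", ov$category[r], "_pct")] <- ov$pct[r]
    }
    lines <- c(lines, sprintf(
      "- Biosynthetic screen (%d distinct isolates): NRPS %s%%, PKS-II %s%%, either or both %s%%.",
      nrow(res$screen$table),
      format(ov$pct[ov$category == "nrps_positive"]),
      format(ov$pct[ov$category == "pks2_positive"]),
      format(ov$pct[ov$category == "either_or_both"])
    ))
  }
  if (!is.null(res$cluster)) {
    for (locus in names(res$cluster)) {
      rep <- res$cluster[[locus]]
      key <- gsub("[^A-Za-z0-9]", "", tolower(locus))
      stats_out[paste0(key, "_fragments")] <- rep$n_fragments
      stats_out[paste0(key, "_groups")] <- rep$n_groups
      lines <- c(lines, sprintf(
        "- %s fingerprints: %d distinct restriction fragments, %d groups at the %s similarity cut.",
        locus, rep$n_fragments, rep$n_groups,
        format(res$config$similarity_cut %||% 0.93)
      ))
    }
  }
  if (!is.null(res$network)) {
    xt <- res$network$crosstab
    stats_out["n_active"] <- xt$n_active
    stats_out["active_both_genes"] <- unname(xt$counts["both"])
    stats_out["active_one_gene"] <- unname(xt$counts["one"])
    stats_out["active_no_gene"] <- unname(xt$counts["neither"])
    stats_out["inactive_gene_positive"] <- xt$inactive_gene_positive
    lines <- c(lines, sprintf(
      "- Antibacterial activity: %d active isolates (both genes: %d, one: %d, neither: %d); %d gene-positive isolates inactive.",
      xt$n_active, xt$counts["both"], xt$counts["one"], xt$counts["neither"],
      xt$inactive_gene_positive
    ))
    if (xt$n_active > 0) {
      pc <- res$network$summary$per_class
      gp <- pc$pct[pc$gram_class == "positive"]
      if (length(gp) == 1) {
        stats_out["active_gram_positive_pct"] <- gp
        lines <- c(lines, sprintf(
          "- %s%% of active isolates inhibit at least one Gram-positive strain.",
          format(gp)
        ))
      }
    }
  }
  list(lines = lines, stats = stats_out)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar stage parameters (thresholds, min_area, similarity_cut,
#' bootstrap_reps, seed, stages, community scalars) may be given in a YAML
#' file; unspecified values keep their defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 7
  comm_args <- y$community %||% list()
  comm_args$seed <- comm_args$seed %||% seed
  community <- do.call(community_config, comm_args)
  args <- y[setdiff(names(y), c("community", "seed"))]
  do.call(pipeline_config, c(
    list(community = community, seed = seed), args
  ))
}
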