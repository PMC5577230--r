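# Seeded generator for synthetic actinobacterial isolate collections.
# Every downstream stage (OTU clustering, phylogeny, gene screening,
# fingerprinting, bioactivity correlation) can be exercised on communities
# with known planted structure: genus-level 16S clusters, configurable
# biosynthetic-gene prevalence, and activity labels whose association with
# gene presence is set by the configuration.

DNA_BASES <- c("A", "C", "G", "T")

#' Substitute bases along a sequence
#'
#' Each site is independently substituted with probability `divergence`,
#' uniformly over the three alternative bases; no indels, so the expected
#' identity to the template is 1 - divergence and analytically checkable.
#'
#' @param template DNA string over A/C/G/T.
#' @param divergence per-site substitution probability in \[0, 0.25\].
#' @param seed integer seed; the result is a pure function of
#'   (template, divergence, seed).
#' @return a character string of the same length as `template`.
#' @export
mutate_sequence <- function(template, divergence, seed) {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.25) {
    stop_param("divergence must be in [0, 0.25]")
  }
  if (nchar(template) < 1) stop_param("template must be non-empty")
  bases <- strsplit(toupper(template), "")[[1]]
  if (!all(bases %in% DNA_BASES)) {
    stop_param("template must contain only A/C/G/T")
  }
  with_local_seed(seed, {
    hit <- which(stats::runif(length(bases)) < divergence)
    for (i in hit) {
      bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1)
    }
  })
  paste(bases, collapse = "")
}

# Uniform random A/C/G/T string (caller manages the RNG stream).
.random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# One concrete realization of a degenerate IUPAC pattern (caller manages RNG).
.realize_iupac <- function(pattern) {
  sets <- iupac_sets()
  ch <- strsplit(toupper(pattern), "")[[1]]
  bad <- which(!ch %in% names(sets))
  if (length(bad) > 0) stop_param("illegal IUPAC character: ", ch[bad[1]])
  paste(
    vapply(ch, function(c) {
      s <- sets[[c]]
      if (length(s) == 1) s else sample(s, 1)
    }, character(1)),
    collapse = ""
  )
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Build a template carrying one amplifiable marker locus
#'
#' Constructs flank + concrete realization of the forward primer + random
#' insert + reverse complement of a concrete realization of the reverse
#' primer + flank. In-silico PCR with the same primer pair then recovers
#' exactly one amplicon of length
#' `nchar(forward) + insert_length + nchar(reverse)` (product size measured
#' 5'-end to 5'-end, both primer footprints included).
#'
#' @param insert_length inter-primer insert length in bp (>= 0).
#' @param primer_forward,primer_reverse degenerate IUPAC primers.
#' @param seed integer seed.
#' @param flank_length length of random flanking sequence on each side.
#' @return character string (the template).
#' @export
plant_marker_locus <- function(insert_length, primer_forward, primer_reverse,
                               seed, flank_length = 30) {
  if (insert_length < 0) stop_param("insert_length must be >= 0")
  if (nchar(primer_forward) == 0 || nchar(primer_reverse) == 0) {
    stop_param("primers must be non-empty")
  }
  with_local_seed(seed, {
    fwd <- .realize_iupac(primer_forward)
    rev <- .realize_iupac(primer_reverse)
    insert <- .random_dna(insert_length)
    left <- .random_dna(flank_length)
    right <- .random_dna(flank_length)
    paste0(left, fwd, insert, .revcomp(rev), right)
  })
}

#' Derive divergent genus-level 16S templates
#'
#' Templates descend from one random ancestor, each lineage mutated at
#' `radiation` per site, so any two templates differ at about
#' `2 * radiation * (1 - 4 * radiation / 3)` of sites (about 9.3% at the
#' default), comfortably past the species-level identity thresholds the
#' OTU stage uses.
#'
#' @param genera character vector of genus names.
#' @param length template length in bp (default 1300, a typical trimmed
#'   near-full-length 16S contig).
#' @param radiation per-lineage substitution fraction (default 0.05).
#' @param seed integer seed.
#' @return named character vector, one template per genus.
#' @export
make_genus_templates <- function(genera, length = 1300, radiation = 0.05,
                                 seed = 1) {
  ancestor <- with_local_seed(derive_seed(seed, 0, 11), .random_dna(length))
  out <- vapply(
    seq_along(genera),
    function(i) mutate_sequence(ancestor, radiation, derive_seed(seed, i, 11)),
    character(1)
  )
  names(out) <- genera
  out
}

#' Community generator configuration
#'
#' Defaults emulate the structure of a cultivable intertidal-sediment
#' Actinobacteria collection: 66 sequenced isolates over seven genera
#' dominated by *Streptomyces*, NRPS carried by about two thirds of isolates
#' and PKS-II by slightly under half (restricted to the four genera where
#' the locus occurs), and antibacterial activity more likely in isolates
#' carrying biosynthetic genes.
#'
#' @param n_isolates number of isolates (>= 1).
#' @param genus_spec data.frame with columns `genus`, `proportion` (summing
#'   to 1), and optionally `nrps`, `pks2` per-genus gene prevalences in
#'   \[0,1\] (overriding `gene_prevalence`).
#' @param divergence_within_genus expected pairwise substitution fraction
#'   between two isolates of the same genus, in \[0, 0.25\]. Each isolate is
#'   mutated from its genus template at half this rate, so two random
#'   members of a genus differ at about this fraction of sites.
#' @param gene_prevalence length-2 named numeric `c(nrps=, pks2=)`: default
#'   per-genus probability of carrying each locus.
#' @param insert_length_range integer 2-vector: inter-primer insert lengths
#'   are chosen so amplicons land on each pair's expected size; the range is
#'   used only for decoy loci when `decoy_rate > 0`.
#' @param activity_model named numeric `c(both=, one=, none=)`: probability
#'   that an isolate is active against at least one test strain given it
#'   carries both loci, exactly one, or neither.
#' @param strain_profile named numeric: per-test-strain hit probability for
#'   an active isolate (at least one hit is guaranteed).
#' @param aerial_mycelium_prob probability an isolate forms aerial mycelium.
#' @param templates optional named character vector of genus 16S templates;
#'   generated via [make_genus_templates()] when omitted.
#' @param primer_pairs list of primer pairs (see [primer_pair()]) defining
#'   the marker loci planted into gene-positive isolates.
#' @param decoy_rate probability that a gene-negative isolate still carries
#'   an unrelated random template (never amplifiable); default 0.
#' @param seed integer master seed; all randomness derives from it.
#' @return a `community_config` list, validated.
#' @export
community_config <- function(n_isolates = 66,
                             genus_spec = default_genus_spec(),
                             divergence_within_genus = 0.01,
                             gene_prevalence = c(nrps = 0.68, pks2 = 0.45),
                             insert_length_range = c(250, 450),
                             activity_model = c(both = 0.50, one = 0.27, none = 0.42),
                             strain_profile = default_strain_profile(),
                             aerial_mycelium_prob = 0.851,
                             templates = NULL,
                             primer_pairs = default_primer_pairs(),
                             decoy_rate = 0,
                             seed = 1) {
  cfg <- list(
    n_isolates = as.integer(n_isolates),
    genus_spec = genus_spec,
    divergence_within_genus = divergence_within_genus,
    gene_prevalence = gene_prevalence,
    insert_length_range = as.integer(insert_length_range),
    activity_model = activity_model,
    strain_profile = strain_profile,
    aerial_mycelium_prob = aerial_mycelium_prob,
    templates = templates,
    primer_pairs = primer_pairs,
    decoy_rate = decoy_rate,
    seed = as.integer(seed)
  )
  validate_community_config(cfg)
  class(cfg) <- "community_config"
  cfg
}

validate_community_config <- function(cfg) {
  if (cfg$n_isolates < 1) stop_param("n_isolates must be >= 1")
  gs <- cfg$genus_spec
  if (!all(c("genus", "proportion") %in% names(gs))) {
    stop_param("genus_spec needs columns 'genus' and 'proportion'")
  }
  if (abs(sum(gs$proportion) - 1) > 1e-9) {
    stop_param("genus proportions must sum to 1 (within 1e-9)")
  }
  probs <- c(
    cfg$gene_prevalence, cfg$activity_model, cfg$strain_profile,
    cfg$aerial_mycelium_prob, cfg$decoy_rate,
    unlist(gs[intersect(c("nrps", "pks2"), names(gs))])
  )
  if (any(probs < 0 | probs > 1)) stop_param("all probabilities must be in [0, 1]")
  if (cfg$divergence_within_genus < 0 || cfg$divergence_within_genus > 0.25) {
    stop_param("divergence_within_genus must be in [0, 0.25]")
  }
  if (!all(c("both", "one", "none") %in% names(cfg$activity_model))) {
    stop_param("activity_model needs named entries both/one/none")
  }
  if (!is.null(cfg$templates) && !all(gs$genus %in% names(cfg$templates))) {
    missing <- setdiff(gs$genus, names(cfg$templates))
    stop_param("configuration error: no template for genus: ",
               paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

#' Default genus composition
#'
#' Seven genera with proportions matching a 66-isolate collection of 41
#' *Streptomyces*, 8 *Micromonospora*, 8 *Nocardiopsis*, 5
#' *Saccharomonospora*, 2 *Actinomadura*, 1 *Glycomyces* and 1 *Nocardia*.
#' The `pks2` column restricts the PKS-II locus to the four genera where it
#' is observed.
#'
#' @return data.frame with columns genus, proportion, nrps, pks2.
#' @export
default_genus_spec <- function() {
  data.frame(
    genus = c(
      "Streptomyces", "Micromonospora", "Nocardiopsis",
      "Saccharomonospora", "Actinomadura", "Glycomyces", "Nocardia"
    ),
    proportion = c(41, 8, 8, 5, 2, 1, 1) / 66,
    nrps = c(0.68, 0.68, 0.68, 0.68, 0.68, 0.68, 0.68),
    pks2 = c(0.60, 0, 0.50, 0.50, 0.50, 0, 0)
  )
}

#' Default antibacterial test-strain panel
#'
#' Five test strains: two multi-drug-resistant clinical isolates and three
#' type cultures. Values are per-strain hit probabilities for an active
#' isolate, biased towards the Gram-positive strains.
#'
#' @return named numeric vector.
#' @export
default_strain_profile <- function() {
  c(
    "Enterococcus sp." = 0.35,
    "Klebsiella pneumoniae" = 0.17,
    "Bacillus subtilis ATCC 6051" = 0.45,
    "Staphylococcus aureus ATCC 25923" = 0.45,
    "Escherichia coli ATCC 8739" = 0.13
  )
}

#' Gram classification of the default test-strain panel
#' @return named character vector mapping strain name to "positive"/"negative".
#' @export
default_gram_classes <- function() {
  c(
    "Enterococcus sp." = "positive",
    "Klebsiella pneumoniae" = "negative",
    "Bacillus subtilis ATCC 6051" = "positive",
    "Staphylococcus aureus ATCC 25923" = "positive",
    "Escherichia coli ATCC 8739" = "negative"
  )
}

# Largest-remainder apportionment of n among proportions; ties by order.
largest_remainder <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- quota - counts
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic isolate community
#'
#' Genus counts follow largest-remainder apportionment of the configured
#' proportions; each isolate's 16S derives from its genus template
#' (substitution rate `divergence_within_genus / 2`), marker loci are
#' planted per-genus with the configured prevalence, and activity calls are
#' drawn conditional on gene carriage. Per-isolate RNG streams are derived
#' from the master seed by counter splitting, so earlier isolates are
#' invariant to community size.
#'
#' @param config a [community_config()].
#' @return a data.frame of class `isolate_community` with columns
#'   `isolate_id`, `genus`, `aerial_mycelium`, `sixteenS`, plus list-columns
#'   `markers` (named character vector of marker templates per isolate) and
#'   `activity` (named logical vector per isolate).
#' @export
generate_community <- function(config) {
  validate_community_config(config)
  gs <- config$genus_spec
  counts <- largest_remainder(config$n_isolates, gs$proportion)
  genera <- rep(gs$genus, counts)
  templates <- config$templates %||%
    make_genus_templates(gs$genus, seed = derive_seed(config$seed, 0, 1))
  pairs <- config$primer_pairs
  loci <- vapply(pairs, function(p) p$locus, character(1))
  prev_default <- config$gene_prevalence
  strain_names <- names(config$strain_profile)

  n <- length(genera)
  width <- max(3, nchar(as.character(n)))
  ids <- sprintf(paste0("SYN%0", width, "d"), seq_len(n))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genera[i]
    gi <- match(g, gs$genus)
    s16 <- mutate_sequence(
      templates[[g]], config$divergence_within_genus / 2,
      derive_seed(config$seed, i, 2)
    )
    markers <- character(0)
    gene_flags <- logical(length(pairs))
    names(gene_flags) <- loci
    for (k in seq_along(pairs)) {
      key <- unname(c(NRPS = "nrps", `PKS-II` = "pks2")[pairs[[k]]$locus])
      p <- if (!is.na(key) && key %in% names(gs)) {
        gs[[key]][gi]
      } else if (!is.na(key) && key %in% names(prev_default)) {
        prev_default[[key]]
      } else {
        0.5
      }
      carry <- with_local_seed(
        derive_seed(config$seed, i, 20 + k),
        stats::runif(1) < p
      )
      gene_flags[k] <- carry
      if (carry) {
        insert <- pairs[[k]]$expected_size -
          nchar(pairs[[k]]$forward) - nchar(pairs[[k]]$reverse)
        markers[[pairs[[k]]$locus]] <- plant_marker_locus(
          insert, pairs[[k]]$forward, pairs[[k]]$reverse,
          derive_seed(config$seed, i, 40 + k)
        )
      }
    }
    if (config$decoy_rate > 0 && !any(gene_flags)) {
      decoy <- with_local_seed(derive_seed(config$seed, i, 60), {
        if (stats::runif(1) < config$decoy_rate) {
          .random_dna(sample(
            seq(config$insert_length_range[1], config$insert_length_range[2]),
            1
          ))
        } else {
          NULL
        }
      })
      if (!is.null(decoy)) markers[["decoy"]] <- decoy
    }
    n_genes <- sum(gene_flags)
    p_active <- config$activity_model[[
      c("none", "one", "both")[n_genes + 1]
    ]]
    activity <- with_local_seed(derive_seed(config$seed, i, 3), {
      act <- stats::setNames(
        rep(FALSE, length(strain_names)), strain_names
      )
      if (stats::runif(1) < p_active) {
        act[] <- stats::runif(length(act)) < config$strain_profile
        if (!any(act)) {
          act[sample(seq_along(act), 1, prob = config$strain_profile)] <- TRUE
        }
      }
      act
    })
    aerial <- with_local_seed(
      derive_seed(config$seed, i, 4),
      stats::runif(1) < config$aerial_mycelium_prob
    )
    rows[[i]] <- list(
      isolate_id = ids[i], genus = g, aerial_mycelium = aerial,
      sixteenS = s16, markers = list(markers), activity = list(activity)
    )
  }
  out <- data.frame(
    isolate_id = vapply(rows, `[[`, character(1), "isolate_id"),
    genus = vapply(rows, `[[`, character(1), "genus"),
    aerial_mycelium = vapply(rows, `[[`, logical(1), "aerial_mycelium"),
    sixteenS = vapply(rows, `[[`, character(1), "sixteenS"),
    stringsAsFactors = FALSE
  )
  out$markers <- lapply(rows, function(r) r$markers[[1]])
  out$activity <- lapply(rows, function(r) r$activity[[1]])
  attr(out, "config") <- config
  class(out) <- c("isolate_community", class(out))
  out
}

#' Activity calls of a community as a logical matrix
#' @param community an `isolate_community`.
#' @return logical matrix, isolates x test strains.
#' @export
activity_table <- function(community) {
  m <- do.call(rbind, community$activity)
  rownames(m) <- community$isolate_id
  m
}

#' Named genus lookup for a community
#' @param community an `isolate_community`.
#' @return named character vector isolate_id -> genus.
#' @export
genus_map <- function(community) {
  stats::setNames(community$genus, community$isolate_id)
}

#' Write a community to disk
#'
#' Emits `<prefix>_16S.fasta` (one record per isolate),
#' `<prefix>_markers.fasta` (ids `isolate|locus`) and `<prefix>_metadata.tsv`
#' (isolate_id, genus, aerial_mycelium, one 0/1 column per test strain).
#'
#' @param community an `isolate_community`.
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_community <- function(community, prefix) {
  f16 <- paste0(prefix, "_16S.fasta")
  fmk <- paste0(prefix, "_markers.fasta")
  fmd <- paste0(prefix, "_metadata.tsv")
  write_fasta(
    stats::setNames(community$sixteenS, community$isolate_id), f16
  )
  mk <- unlist(lapply(seq_len(nrow(community)), function(i) {
    m <- community$markers[[i]]
    if (length(m) == 0) return(NULL)
    stats::setNames(m, paste0(community$isolate_id[i], "|", names(m)))
  }))
  if (length(mk) > 0) write_fasta(mk, fmk) else writeLines(character(0), fmk)
  act <- activity_table(community)
  md <- data.frame(
    isolate_id = community$isolate_id,
    genus = community$genus,
    aerial_mycelium = as.integer(community$aerial_mycelium),
    act + 0L,
    check.names = FALSE
  )
  utils::write.table(md, fmd,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(sixteenS = f16, markers = fmk, metadata = fmd))
}
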