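# In-silico PCR with degenerate primers, presence/absence calls for
# biosynthetic loci (NRPS adenylation domain, PKS-II ketosynthase-alpha
# domain), and prevalence summaries.

#' Test a degenerate base code against a concrete base
#'
#' @param pattern_char single IUPAC nucleotide code.
#' @param base single base, one of A/C/G/T.
#' @return `TRUE` iff `base` belongs to the expansion of `pattern_char`.
#' @export
iupac_match <- function(pattern_char, base) {
  sets <- iupac_sets()
  if (!pattern_char %in% names(sets)) {
    stop_param("illegal IUPAC code: '", pattern_char, "'")
  }
  if (!base %in% c("A", "C", "G", "T")) {
    stop_param("base must be one of A/C/G/T, got '", base, "'")
  }
  base %in% sets[[pattern_char]]
}

#' Define a degenerate primer pair
#'
#' @param locus locus name (e.g. `"NRPS"`, `"PKS-II"`).
#' @param forward,reverse IUPAC primer sequences (reverse given 5'->3' on the
#'   opposite strand, as synthesized).
#' @param expected_size expected amplicon size in bp, 5'-end to 5'-end;
#'   must exceed the summed primer lengths.
#' @param size_tolerance half-width of the accepted size window as a
#'   fraction of `expected_size` (default 0.2).
#' @return list of class `primer_pair`.
#' @export
primer_pair <- function(locus, forward, reverse, expected_size,
                        size_tolerance = 0.2) {
  forward <- gsub("[ -]", "", toupper(forward))
  reverse <- gsub("[ -]", "", toupper(reverse))
  sets <- iupac_sets()
  for (p in c(forward, reverse)) {
    ch <- strsplit(p, "")[[1]]
    if (length(ch) == 0) stop_param("primers must be non-empty")
    if (!all(ch %in% names(sets))) {
      stop_param("primer contains non-IUPAC characters: ", p)
    }
  }
  if (expected_size <= nchar(forward) + nchar(reverse)) {
    stop_param("expected_size must exceed total primer length")
  }
  structure(
    list(
      locus = locus, forward = forward, reverse = reverse,
      expected_size = as.integer(expected_size),
      size_tolerance = size_tolerance
    ),
    class = "primer_pair"
  )
}

#' Default degenerate primer pairs for NRPS and PKS-II screening
#'
#' The NRPS pair targets the adenylation domain (480 bp product); the
#' PKS-II pair targets the ketosynthase-alpha domain (350 bp product).
#'
#' @return named list of [primer_pair()] objects.
#' @export
default_primer_pairs <- function() {
  list(
    NRPS = primer_pair(
      "NRPS",
      forward = "CGCGCGCATGTACTGGACNGGNGAYYT",
      reverse = "GGAGTGGCCGCCCARNYBRAARAA",
      expected_size = 480
    ),
    `PKS-II` = primer_pair(
      "PKS-II",
      forward = "GGCAACGCCTACCACATGCANGGNYT",
      reverse = "GGTCCGCGGGACGTARTCNARRTC",
      expected_size = 350
    )
  )
}

#' Locate degenerate-primer binding sites
#'
#' Scans the plus strand of `template` for the primer and for its reverse
#' complement; a window is a site when the number of positions failing the
#' IUPAC compatibility test is at most `max_mismatch`. Ambiguity codes in
#' the template match a primer code whenever their base sets intersect.
#'
#' @param template DNA string (IUPAC codes allowed).
#' @param primer degenerate IUPAC primer.
#' @param max_mismatch maximum tolerated mismatches (default 0).
#' @return data.frame with `position` (0-based at the 5'-most template base
#'   of the window) and `strand` (`"+"` for the primer itself, `"-"` for
#'   its reverse complement).
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 0) {
  template <- Biostrings::DNAString(toupper(template))
  primer <- Biostrings::DNAString(toupper(primer))
  if (length(template) < length(primer)) {
    return(data.frame(position = integer(0), strand = character(0)))
  }
  plus <- Biostrings::matchPattern(
    primer, template,
    max.mismatch = max_mismatch, fixed = FALSE
  )
  minus <- Biostrings::matchPattern(
    Biostrings::reverseComplement(primer), template,
    max.mismatch = max_mismatch, fixed = FALSE
  )
  out <- rbind(
    data.frame(
      position = BiocGenerics::start(plus) - 1L,
      strand = rep("+", length(plus))
    ),
    data.frame(
      position = BiocGenerics::start(minus) - 1L,
      strand = rep("-", length(minus))
    )
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

# All (start0, end0-exclusive) products for one template orientation:
# forward site on the plus strand paired with a downstream, non-overlapping
# reverse-complemented reverse-primer site.
.pcr_products_plus <- function(template, pair, max_mismatch) {
  t <- Biostrings::DNAString(template)
  if (length(t) < nchar(pair$forward) || length(t) < nchar(pair$reverse)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  fwd <- Biostrings::matchPattern(
    Biostrings::DNAString(pair$forward), t,
    max.mismatch = max_mismatch, fixed = FALSE
  )
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(pair$reverse)), t,
    max.mismatch = max_mismatch, fixed = FALSE
  )
  fs <- BiocGenerics::start(fwd)
  fe <- BiocGenerics::end(fwd)
  rs <- BiocGenerics::start(rev)
  re <- BiocGenerics::end(rev)
  out <- list()
  for (i in seq_along(fs)) {
    for (j in seq_along(rs)) {
      if (rs[j] > fe[i]) {
        out[[length(out) + 1]] <- c(fs[i] - 1L, re[j]) # 0-based half-open
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' In-silico PCR on a template
#'
#' Reports every pairing of a forward-primer site with a downstream
#' reverse-primer site (the reverse complement of the reverse primer on the
#' same strand), on both template orientations; product length is measured
#' 5'-end to 5'-end inclusive of both primer footprints. The call is
#' positive iff at least one product length lies within
#' `expected_size * (1 +/- size_tolerance)`.
#'
#' @param template DNA string.
#' @param pair a [primer_pair()].
#' @param max_mismatch tolerated mismatches per primer site (default 0).
#' @param isolate_id optional id recorded in the call.
#' @return an `amplicon_call`: list with `isolate_id`, `locus`, `positive`,
#'   and `amplicons` (data.frame start/end \[0-based half-open, plus
#'   strand\], length, sequence).
#' @export
insilico_pcr <- function(template, pair, max_mismatch = 0, isolate_id = NA) {
  template <- toupper(template)
  n <- nchar(template)
  plus <- .pcr_products_plus(template, pair, max_mismatch)
  rc <- .revcomp(template)
  minus <- .pcr_products_plus(rc, pair, max_mismatch)
  if (nrow(minus) > 0) {
    # map coordinates back to the plus strand
    mapped <- data.frame(start = n - minus$end, end = n - minus$start)
    minus <- mapped
  }
  prods <- unique(rbind(
    cbind(plus, strand = rep("+", nrow(plus))),
    cbind(minus, strand = rep("-", nrow(minus)))
  ))
  if (nrow(prods) > 0) {
    prods$length <- prods$end - prods$start
    prods$sequence <- substring(template, prods$start + 1, prods$end)
    lo <- pair$expected_size * (1 - pair$size_tolerance)
    hi <- pair$expected_size * (1 + pair$size_tolerance)
    prods$in_window <- prods$length >= lo & prods$length <= hi
    prods <- prods[order(prods$start, prods$end), , drop = FALSE]
    rownames(prods) <- NULL
  } else {
    prods <- data.frame(
      start = integer(0), end = integer(0), strand = character(0),
      length = integer(0), sequence = character(0), in_window = logical(0)
    )
  }
  structure(
    list(
      isolate_id = isolate_id, locus = pair$locus,
      positive = any(prods$in_window), amplicons = prods
    ),
    class = "amplicon_call"
  )
}

#' Screen a community for biosynthetic loci
#'
#' @param community an `isolate_community` (or any data.frame with
#'   `isolate_id` and a `markers` list-column).
#' @param pairs list of [primer_pair()]s (default NRPS + PKS-II).
#' @param max_mismatch tolerated mismatches.
#' @return logical matrix, isolates x loci; an isolate is positive for a
#'   locus iff any of its marker templates yields a positive call.
#' @export
screen_isolates <- function(community, pairs = default_primer_pairs(),
                            max_mismatch = 0) {
  ids <- community$isolate_id
  if (anyDuplicated(ids)) stop_param("duplicate isolate ids")
  loci <- vapply(pairs, function(p) p$locus, character(1))
  m <- matrix(FALSE, length(ids), length(loci), dimnames = list(ids, loci))
  for (i in seq_along(ids)) {
    templates <- community$markers[[i]]
    for (k in seq_along(pairs)) {
      for (tpl in templates) {
        call <- insilico_pcr(tpl, pairs[[k]], max_mismatch, ids[i])
        if (call$positive) {
          m[i, k] <- TRUE
          break
        }
      }
    }
  }
  m
}

#' Prevalence summary of a presence table
#'
#' @param table logical matrix isolates x loci (needs columns `NRPS` and
#'   `PKS-II` for the combined categories).
#' @param genus_of named character vector isolate -> genus.
#' @return list with `overall` (data.frame category/count/pct over all
#'   isolates) and `per_genus` (data.frame of per-genus counts and
#'   percentages). Percentages use the shared one-decimal rule.
#' @export
screen_summary <- function(table, genus_of) {
  ids <- rownames(table)
  missing <- ids[!ids %in% names(genus_of)]
  if (length(missing) > 0) {
    stop_param("missing genus label for: ", paste(missing, collapse = ", "))
  }
  n <- nrow(table)
  nrps <- table[, "NRPS"]
  pks <- table[, "PKS-II"]
  cats <- c(
    nrps_positive = sum(nrps),
    pks2_positive = sum(pks),
    either_or_both = sum(nrps | pks),
    neither = sum(!nrps & !pks)
  )
  overall <- data.frame(
    category = names(cats),
    count = as.integer(cats),
    pct = percent_of(as.integer(cats), n),
    row.names = NULL
  )
  genera <- genus_of[ids]
  per_genus <- do.call(rbind, lapply(unique(genera), function(g) {
    sel <- genera == g
    data.frame(
      genus = g,
      n_isolates = sum(sel),
      nrps_positive = sum(nrps[sel]),
      nrps_pct = percent_of(sum(nrps[sel]), sum(sel)),
      pks2_positive = sum(pks[sel]),
      pks2_pct = percent_of(sum(pks[sel]), sum(sel))
    )
  }))
  rownames(per_genus) <- NULL
  list(overall = overall, per_genus = per_genus)
}
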