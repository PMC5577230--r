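# Amplified-fragment restriction fingerprinting: in-silico digestion,
# a polyacrylamide gel / densitometry model with mass-proportional band
# intensity, the >5%-of-lane-area scoring rule, and binary band matrices.

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param site concrete recognition sequence (A/C/G/T), length >= 4.
#' @param offset cut offset in bp from the site start (`0 <= offset <=
#'   nchar(site)`); e.g. AG^CT cuts at offset 2.
#' @return list of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, site, offset) {
  site <- toupper(site)
  if (nchar(site) < 4) stop_param("recognition site must be >= 4 bp")
  if (!all(strsplit(site, "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop_param("recognition site must be a concrete A/C/G/T string")
  }
  if (offset < 0 || offset > nchar(site)) {
    stop_param("cut offset must lie within the site")
  }
  structure(
    list(name = name, site = site, offset = as.integer(offset)),
    class = "restriction_enzyme"
  )
}

#' The two 4-bp cutters used for fingerprinting
#'
#' AluI (AG^CT) and HaeIII (GG^CC), both blunt cutters at offset 2 per the
#' standard enzyme catalogue.
#'
#' @return named list of [restriction_enzyme()] objects.
#' @export
default_enzymes <- function() {
  list(
    AluI = restriction_enzyme("AluI", "AGCT", 2),
    HaeIII = restriction_enzyme("HaeIII", "GGCC", 2)
  )
}

#' Digest a linear DNA molecule
#'
#' Cuts at every occurrence of the recognition site (all positions scanned,
#' overlapping sites included) at `site start + offset`; fragment lengths
#' always sum to the template length.
#'
#' @param seq DNA string.
#' @param enzyme a [restriction_enzyme()].
#' @return integer vector of fragment lengths in 5'->3' order.
#' @export
digest <- function(seq, enzyme) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0) stop_param("sequence must be non-empty")
  if (n < nchar(enzyme$site)) {
    return(n)
  }
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(enzyme$site), Biostrings::DNAString(seq)
  )
  cuts <- BiocGenerics::start(hits) - 1L + enzyme$offset
  cuts <- sort(unique(cuts[cuts > 0 & cuts < n]))
  diff(c(0L, cuts, n))
}

#' Gel / densitometry model parameters
#'
#' @param min_detectable smallest detectable fragment in bp (default 50).
#' @param resolution_bp absolute co-migration tolerance in bp (default 5).
#' @param resolution_frac relative co-migration tolerance (default 0.02);
#'   two sizes co-migrate when they differ by at most
#'   `max(resolution_bp, resolution_frac * larger size)`.
#' @return list of class `gel_model`.
#' @export
gel_model <- function(min_detectable = 50, resolution_bp = 5,
                      resolution_frac = 0.02) {
  structure(
    list(
      min_detectable = min_detectable, resolution_bp = resolution_bp,
      resolution_frac = resolution_frac
    ),
    class = "gel_model"
  )
}

# Single-linkage grouping of sorted-descending sizes under the co-migration
# rule; returns a group index vector.
.comigration_groups <- function(sizes_desc, gel) {
  n <- length(sizes_desc)
  if (n == 0) return(integer(0))
  grp <- integer(n)
  grp[1] <- 1L
  for (i in seq_len(n - 1)) {
    a <- sizes_desc[i]
    b <- sizes_desc[i + 1]
    tol <- max(gel$resolution_bp, gel$resolution_frac * a)
    grp[i + 1] <- if (a - b <= tol) grp[i] else grp[i] + 1L
  }
  grp
}

#' Simulate a gel lane from digestion fragments
#'
#' Fragments below the detection limit are dropped; co-migrating fragments
#' are merged (merged size = mass-weighted mean); band area is proportional
#' to the total bp in the band (ethidium-bromide staining is
#' mass-proportional) and normalized to the whole-lane total over detected
#' fragments.
#'
#' @param fragments integer vector of fragment lengths.
#' @param gel a [gel_model()].
#' @param isolate_id,enzyme identifiers recorded in the lane.
#' @return a `lane_profile`: list with `isolate_id`, `enzyme`, and `bands`
#'   (data.frame size/area, sorted by decreasing size; empty when all
#'   fragments are undetectable).
#' @export
lane_from_fragments <- function(fragments, gel = gel_model(),
                                isolate_id = NA, enzyme = NA) {
  if (length(fragments) < 1) stop_param("need at least one fragment")
  detected <- fragments[fragments >= gel$min_detectable]
  if (length(detected) == 0) {
    return(structure(
      list(
        isolate_id = isolate_id, enzyme = enzyme,
        bands = data.frame(size = numeric(0), area = numeric(0))
      ),
      class = "lane_profile"
    ))
  }
  sizes <- sort(detected, decreasing = TRUE)
  grp <- .comigration_groups(sizes, gel)
  total <- sum(sizes)
  bands <- do.call(rbind, lapply(split(sizes, grp), function(s) {
    data.frame(size = sum(s * s) / sum(s), area = sum(s) / total)
  }))
  bands <- bands[order(-bands$size), , drop = FALSE]
  rownames(bands) <- NULL
  structure(
    list(isolate_id = isolate_id, enzyme = enzyme, bands = bands),
    class = "lane_profile"
  )
}

#' Apply the densitometry area rule
#'
#' Retains bands whose area fraction is strictly greater than
#' `min_fraction` of the whole (pre-filter) lane area; retained bands keep
#' their original fractions, so the operation is idempotent.
#'
#' @param lane a `lane_profile`.
#' @param min_fraction area threshold (default 0.05).
#' @return the filtered `lane_profile`.
#' @export
apply_area_filter <- function(lane, min_fraction = 0.05) {
  lane$bands <- lane$bands[lane$bands$area > min_fraction, , drop = FALSE]
  rownames(lane$bands) <- NULL
  lane
}

#' Build a binary band matrix from lanes
#'
#' Pools all retained band sizes across lanes, sorts them descending, forms
#' bins by single linkage under the same co-migration tolerance used on the
#' gel, and scores each lane 1/0 for each bin. Binning works on the sorted
#' pool, so the result is invariant to lane order (up to row order).
#'
#' @param lanes list of `lane_profile`s, all from the same enzyme.
#' @param gel a [gel_model()] supplying the binning tolerance.
#' @return binary matrix (isolates x bins) with column names
#'   `<enzyme>_<representative size>`; bin representatives (mean member
#'   size) are strictly decreasing and stored in attribute `bins`.
#' @export
band_matrix <- function(lanes, gel = gel_model()) {
  enzymes <- unique(vapply(lanes, function(l) as.character(l$enzyme), character(1)))
  if (length(enzymes) != 1) {
    stop_param("all lanes must come from the same enzyme, got: ",
               paste(enzymes, collapse = ", "))
  }
  ids <- vapply(lanes, function(l) as.character(l$isolate_id), character(1))
  if (anyDuplicated(ids)) stop_param("duplicate lane isolate ids")
  pool <- do.call(rbind, lapply(seq_along(lanes), function(i) {
    b <- lanes[[i]]$bands
    if (nrow(b) == 0) return(NULL)
    data.frame(lane = i, size = b$size)
  }))
  if (is.null(pool)) {
    m <- matrix(0L, length(ids), 0, dimnames = list(ids, character(0)))
    attr(m, "bins") <- numeric(0)
    return(m)
  }
  pool <- pool[order(-pool$size), , drop = FALSE]
  grp <- .comigration_groups(pool$size, gel)
  reps <- vapply(split(pool$size, grp), mean, numeric(1))
  m <- matrix(0L, length(ids), length(reps),
    dimnames = list(ids, paste0(enzymes, "_", round(reps)))
  )
  for (r in seq_len(nrow(pool))) {
    m[pool$lane[r], grp[r]] <- 1L
  }
  attr(m, "bins") <- unname(reps)
  attr(m, "enzyme") <- enzymes
  m
}

#' Concatenate band matrices from two enzymes
#'
#' @param mA,mB band matrices over the same isolates (columns already carry
#'   enzyme-tagged names).
#' @return column-wise concatenation, rows in `mA` order.
#' @export
combine_matrices <- function(mA, mB) {
  if (!setequal(rownames(mA), rownames(mB))) {
    stop_param(
      "row-id mismatch: ",
      paste(
        c(setdiff(rownames(mA), rownames(mB)),
          setdiff(rownames(mB), rownames(mA))),
        collapse = ", "
      )
    )
  }
  out <- cbind(mA, mB[rownames(mA), , drop = FALSE])
  attr(out, "bins") <- c(attr(mA, "bins"), attr(mB, "bins"))
  out
}

#' Digest amplicons and produce per-enzyme band matrices
#'
#' Convenience wrapper running the full fingerprint stage for one locus:
#' digestion of each isolate's amplicon with each enzyme, gel simulation,
#' the area rule, and band-matrix construction.
#'
#' @param amplicons named character vector (isolate -> amplicon sequence).
#' @param enzymes list of [restriction_enzyme()]s.
#' @param gel a [gel_model()].
#' @param min_fraction densitometry area threshold.
#' @return list with per-enzyme matrices (`matrices`), the combined matrix
#'   (`combined`), and all filtered lanes (`lanes`).
#' @export
fingerprint_amplicons <- function(amplicons, enzymes = default_enzymes(),
                                  gel = gel_model(), min_fraction = 0.05) {
  matrices <- list()
  lanes_all <- list()
  for (e in enzymes) {
    lanes <- lapply(names(amplicons), function(id) {
      apply_area_filter(
        lane_from_fragments(digest(amplicons[[id]], e), gel, id, e$name),
        min_fraction
      )
    })
    matrices[[e$name]] <- band_matrix(lanes, gel)
    lanes_all[[e$name]] <- lanes
  }
  combined <- Reduce(combine_matrices, matrices)
  list(matrices = matrices, combined = combined, lanes = lanes_all)
}
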