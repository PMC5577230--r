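# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately takes a different route from the implementation
# it checks (position scans, set arithmetic, brute-force expansion,
# stats::hclust, ape::nj).

unrowname <- function(d) {
  rownames(d) <- NULL
  d
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Position-by-position scan digestion (no pattern-matching library).
naive_digest <- function(seq, site, offset) {
  n <- nchar(seq)
  w <- nchar(site)
  cuts <- integer(0)
  for (p in seq_len(max(0, n - w + 1))) {
    if (substring(seq, p, p + w - 1) == site) {
      cut <- p - 1 + offset
      if (cut > 0 && cut < n) cuts <- c(cuts, cut)
    }
  }
  diff(c(0L, sort(unique(cuts)), n))
}

# All concrete expansions of a degenerate IUPAC pattern.
iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

expand_pattern <- function(pattern) {
  sets <- iupac_table[strsplit(pattern, "")[[1]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force binding-site search: expand the pattern, substring-search
# every expansion on both orientations (exact matching only).
naive_find_sites <- function(template, primer) {
  hits <- data.frame(position = integer(0), strand = character(0))
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp_chr_iupac(primer)
    for (concrete in expand_pattern(pat)) {
      p <- 1
      repeat {
        at <- regexpr(concrete, substring(template, p), fixed = TRUE)
        if (at < 0) break
        pos <- p + at - 1
        hits <- rbind(hits, data.frame(position = pos - 1L, strand = strand))
        p <- pos + 1
      }
    }
  }
  hits <- unique(hits)
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

# Reverse complement of a degenerate pattern.
revcomp_chr_iupac <- function(x) {
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
    S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V", N = "N"
  )
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# A random degenerate pattern with at most `max_expansions` expansions.
random_degenerate <- function(len, max_expansions = 64) {
  repeat {
    ch <- sample(names(iupac_table), len,
      replace = TRUE,
      prob = c(rep(8, 4), rep(1, 11))
    )
    n_exp <- prod(vapply(iupac_table[ch], length, integer(1)))
    if (n_exp <= max_expansions) {
      return(paste(ch, collapse = ""))
    }
  }
}

# Jaccard by explicit set arithmetic.
naive_jaccard <- function(a, b) {
  sa <- which(as.logical(a))
  sb <- which(as.logical(b))
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# Random symmetric similarity matrix in [0, 1] with unit diagonal.
random_similarity <- function(n) {
  s <- matrix(stats::runif(n * n), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  s
}

# Small planted-cluster community configuration: g genera, two isolates
# each, genus templates radiating far past the clustering threshold.
planted_config <- function(g, seed, divergence = 0.004) {
  genera <- sprintf("G%02d", seq_len(g))
  community_config(
    n_isolates = 2 * g,
    genus_spec = data.frame(
      genus = genera, proportion = rep(1 / g, g),
      nrps = 0, pks2 = 0
    ),
    divergence_within_genus = divergence,
    activity_model = c(both = 0, one = 0, none = 0),
    seed = seed
  )
}
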