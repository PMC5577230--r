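test_that("p-distance counts mismatches over comparable columns only", {
  expect_equal(p_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  expect_equal(p_distance("ACGTACGTAC", "ACGTACGTAT"), 0.1)
  expect_equal(p_distance("AC-T", "ACGT"), 0) # gap column excluded
  expect_equal(p_distance("ACNT", "ACGT"), 0) # ambiguity column excluded
  expect_error(p_distance("AC", "ACGT"), "equal length")
  expect_error(p_distance("--", "AC"), "comparable")
})

test_that("Jukes-Cantor correction matches the closed form", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), 0.1073256, tolerance = 1e-6)
  grid <- seq(0, 0.7, by = 0.01)
  expect_true(all(diff(jc_correct(grid)) > 0)) # monotone increasing
  expect_error(jc_correct(0.75), "aturation")
})

test_that("distance_matrix agrees with per-pair p_distance", {
  set.seed(5)
  aln <- setNames(
    vapply(1:6, function(i) random_dna(150), character(1)), paste0("t", 1:6)
  )
  d <- distance_matrix(aln)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(d[i, j], p_distance(aln[[i]], aln[[j]]))
    }
  }
  expect_equal(unname(diag(d)), rep(0, 6))
  djc <- distance_matrix(aln, "jukes-cantor")
  expect_true(all(djc[upper.tri(djc)] >= d[upper.tri(d)]))
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive trees exactly and agrees with ape", {
  set.seed(6)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n)
    d <- ape::cophenetic.phylo(true)
    mine <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), mine)), 0)
    expect_lt(
      max(abs(ape::cophenetic.phylo(mine)[rownames(d), rownames(d)] - d)),
      1e-9
    )
    ref <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(ref, mine)), 0)
  }
})

test_that("NJ clamps negative branch lengths to zero", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.01
  d["a", "c"] <- d["c", "a"] <- 1
  d["b", "c"] <- d["c", "b"] <- 1
  d["a", "d"] <- d["d", "a"] <- 1
  d["b", "d"] <- d["d", "b"] <- 1
  d["c", "d"] <- d["d", "c"] <- 0.01
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ on an ultrametric matrix matches the UPGMA topology", {
  set.seed(8)
  for (rep in 1:5) {
    s <- random_similarity(7)
    u <- upgma(s)
    coph <- as.matrix(stats::cophenetic(u))[rownames(s), rownames(s)]
    tr <- neighbor_joining(coph)
    utree <- ape::as.phylo(u)
    expect_equal(as.numeric(ape::dist.topo(tr, ape::unroot(utree))), 0)
  }
})

test_that("bootstrap supports are deterministic and bounded", {
  set.seed(9)
  # two clearly separated clades with many diagnostic columns
  a <- random_dna(400)
  b <- mutate_sequence(a, 0.2, 1)
  aln <- c(
    A1 = mutate_sequence(a, 0.01, 2), A2 = mutate_sequence(a, 0.01, 3),
    A3 = mutate_sequence(a, 0.01, 4),
    B1 = mutate_sequence(b, 0.01, 5), B2 = mutate_sequence(b, 0.01, 6),
    B3 = mutate_sequence(b, 0.01, 7)
  )
  t1 <- bootstrap_support(aln, 50, seed = 3)
  t2 <- bootstrap_support(aln, 50, seed = 3)
  expect_identical(t1$node.label, t2$node.label)
  sup <- t1$node.label[!is.na(t1$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the A|B bipartition is supported in every replicate
  expect_true(any(sup >= 95))

  tiny <- bootstrap_support(aln, 1, seed = 1)
  sup1 <- tiny$node.label[!is.na(tiny$node.label)]
  expect_true(all(sup1 %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to taxon order", {
  set.seed(10)
  a <- random_dna(300)
  aln <- setNames(
    vapply(1:5, function(i) mutate_sequence(a, 0.05, i), character(1)),
    paste0("t", 1:5)
  )
  t1 <- bootstrap_support(aln, 30, seed = 2)
  t2 <- bootstrap_support(aln[c(3, 1, 5, 2, 4)], 30, seed = 2)
  s1 <- setNames(t1$node.label, vapply(
    (length(t1$tip.label) + 1):(length(t1$tip.label) + t1$Nnode),
    function(n) paste(sort(ape::extract.clade(t1, n)$tip.label), collapse = ","),
    character(1)
  ))
  s2 <- setNames(t2$node.label, vapply(
    (length(t2$tip.label) + 1):(length(t2$tip.label) + t2$Nnode),
    function(n) paste(sort(ape::extract.clade(t2, n)$tip.label), collapse = ","),
    character(1)
  ))
  shared <- intersect(names(s1), names(s2))
  expect_gt(length(shared), 0)
  expect_equal(s1[shared], s2[shared])
})

test_that("translate_fragment picks the frame with the longest open stretch", {
  expect_equal(as.character(suppressWarnings(translate_fragment("ATGAAA"))), "MK")
  expect_equal(attr(suppressWarnings(translate_fragment("ATGAAA")), "frame"), "+1")

  # frozen fragment whose unique longest stop-free stretch lies on the
  # minus strand (frame -1)
  nt <- paste0(
    "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTG",
    "AACCCCCTGCACGCCCTAAAGTACAATTAGG"
  )
  got <- translate_fragment(nt)
  expect_equal(attr(got, "frame"), "-1")
  expect_equal(
    as.character(got), "PNCTLGRAGGSRDMERPSARFYFRSYTWSF"
  )
  # and the minus-strand call equals the plus-strand call on the
  # reverse complement
  flipped <- translate_fragment(revcomp_chr(nt))
  expect_equal(attr(flipped, "frame"), "+1")
  expect_equal(as.character(flipped), as.character(got))
  expect_error(translate_fragment("AC"), "at least 3")
})

test_that("translate_fragment equals a brute-force six-frame scan", {
  gc <- Biostrings::GENETIC_CODE
  codon_translate <- function(s) {
    s <- substring(s, 1, 3 * (nchar(s) %/% 3))
    if (nchar(s) < 3) return(NULL)
    paste(
      gc[substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))],
      collapse = ""
    )
  }
  set.seed(12)
  for (rep in 1:10) {
    nt <- random_dna(300)
    frames <- list()
    for (off in 0:2) {
      frames[[paste0("+", off + 1)]] <- codon_translate(substring(nt, off + 1))
      frames[[paste0("-", off + 1)]] <-
        codon_translate(substring(revcomp_chr(nt), off + 1))
    }
    stretch <- vapply(
      c("+1", "+2", "+3", "-1", "-2", "-3"),
      function(f) {
        runs <- strsplit(frames[[f]], "*", fixed = TRUE)[[1]]
        if (length(runs) == 0) 0L else max(nchar(runs))
      },
      integer(1)
    )
    best <- names(stretch)[which.max(stretch)]
    got <- suppressWarnings(translate_fragment(nt))
    expect_equal(attr(got, "frame"), best)
    expect_equal(as.character(got), frames[[best]])
  }
})
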