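test_that("iupac_match reproduces the standard ambiguity table", {
  for (code in names(iupac_table)) {
    for (base in c("A", "C", "G", "T")) {
      expect_equal(
        iupac_match(code, base), base %in% iupac_table[[code]],
        info = paste(code, base)
      )
    }
  }
  expect_true(iupac_match("N", "G"))
  expect_false(iupac_match("Y", "A"))
  expect_error(iupac_match("Z", "A"), "illegal")
  expect_error(iupac_match("N", "N"), "base")
})

test_that("find_binding_sites locates degenerate sites on both strands", {
  # exact realization of CANGG at position 3 (0-based 2)
  hits <- find_binding_sites("TTCATGGTT", "CANGG")
  expect_equal(hits$position, 2)
  expect_equal(hits$strand, "+")
  # the reverse complement CCNTG appears on the minus strand
  hits2 <- find_binding_sites("TTCCATGTT", "CANGG")
  expect_equal(hits2$strand, "-")
  none <- find_binding_sites("AAAAAAAA", "CANGG")
  expect_equal(nrow(none), 0)
})

test_that("find_binding_sites equals brute-force pattern expansion", {
  set.seed(14)
  for (rep in 1:20) {
    primer <- random_degenerate(6, 64)
    tpl <- random_dna(400)
    # plant one guaranteed site to avoid vacuous comparisons
    site <- expand_pattern(primer)[1]
    pos <- sample(1:(400 - 6), 1)
    tpl <- paste0(
      substring(tpl, 1, pos - 1), site, substring(tpl, pos + 6)
    )
    expect_equal(
      unrowname(find_binding_sites(tpl, primer)),
      unrowname(naive_find_sites(tpl, primer)),
      info = primer
    )
  }
})

test_that("in-silico PCR calls amplicons in the size window", {
  pair <- default_primer_pairs()$NRPS
  insert <- pair$expected_size - nchar(pair$forward) - nchar(pair$reverse)
  tpl <- plant_marker_locus(insert, pair$forward, pair$reverse, seed = 15)
  call <- insilico_pcr(tpl, pair)
  expect_true(call$positive)
  expect_equal(call$amplicons$length[call$amplicons$in_window], 480)

  # missing reverse site -> negative
  fwd_only <- paste0(
    strrep("A", 20), gsub("[NRYBKWSMVHD]", "A", pair$forward), strrep("A", 500)
  )
  neg <- insilico_pcr(fwd_only, pair)
  expect_false(neg$positive)
  expect_equal(nrow(neg$amplicons), 0)
})

test_that("multiple compatible site pairings are all reported", {
  fwd <- "ACGTACGTAA"
  rev <- "TTGGCCAATT"
  pair <- primer_pair("X", fwd, rev, 60, size_tolerance = 0.9)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  tpl <- paste0(
    "GG", fwd, strrep("C", 10), fwd, strrep("C", 15), rc, "GG"
  )
  call <- insilico_pcr(tpl, pair)
  expect_equal(nrow(call$amplicons), 2) # two forward sites, one reverse
  expect_equal(sum(call$amplicons$in_window), 2)
})

test_that("PCR calls are strand-symmetric and monotone in mismatches", {
  pair <- default_primer_pairs()$`PKS-II`
  insert <- pair$expected_size - nchar(pair$forward) - nchar(pair$reverse)
  tpl <- plant_marker_locus(insert, pair$forward, pair$reverse, seed = 16)
  call_f <- insilico_pcr(tpl, pair)
  call_r <- insilico_pcr(revcomp_chr(tpl), pair)
  expect_equal(sort(call_f$amplicons$length), sort(call_r$amplicons$length))

  # one mismatch in the forward footprint: lost at 0, recovered at 1
  broken <- tpl
  pos <- 31 # inside the forward primer (30-nt flank before it)
  ch <- substring(broken, pos, pos)
  substr(broken, pos, pos) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  expect_false(insilico_pcr(broken, pair, max_mismatch = 0)$positive)
  expect_true(insilico_pcr(broken, pair, max_mismatch = 1)$positive)
})

test_that("screen_isolates aggregates over marker templates", {
  pairs <- default_primer_pairs()
  nrps_tpl <- plant_marker_locus(
    480 - nchar(pairs$NRPS$forward) - nchar(pairs$NRPS$reverse),
    pairs$NRPS$forward, pairs$NRPS$reverse,
    seed = 17
  )
  comm <- data.frame(isolate_id = c("i1", "i2"))
  comm$markers <- list(c(NRPS = nrps_tpl), character(0))
  tab <- screen_isolates(comm, pairs)
  expect_true(tab["i1", "NRPS"])
  expect_false(tab["i1", "PKS-II"])
  expect_false(any(tab["i2", ]))

  full <- generate_community(community_config(
    n_isolates = 10,
    genus_spec = data.frame(
      genus = "Streptomyces", proportion = 1, nrps = 1, pks2 = 1
    ),
    seed = 18
  ))
  expect_true(all(screen_isolates(full, pairs)))
})

test_that("screen_summary reproduces worked percentages", {
  # 50 of 62 isolates positive for either or both -> 80.6%
  ids <- sprintf("i%02d", 1:62)
  tab <- matrix(FALSE, 62, 2, dimnames = list(ids, c("NRPS", "PKS-II")))
  tab[1:42, "NRPS"] <- TRUE
  tab[15:42, "PKS-II"] <- TRUE # 28 PKS-II, all within NRPS+ here
  tab[43:50, "PKS-II"] <- TRUE # 8 more -> 50 either-or-both
  genus_of <- setNames(rep(c("Streptomyces", "Other"), c(40, 22)), ids)
  s <- screen_summary(tab, genus_of)
  ov <- s$overall
  expect_equal(ov$count[ov$category == "either_or_both"], 50)
  expect_equal(ov$pct[ov$category == "either_or_both"], 80.6)
  expect_equal(ov$pct[ov$category == "nrps_positive"], percent_of(42, 62))

  allfalse <- matrix(FALSE, 4, 2,
    dimnames = list(paste0("x", 1:4), c("NRPS", "PKS-II"))
  )
  s0 <- screen_summary(allfalse, setNames(rep("G", 4), paste0("x", 1:4)))
  expect_true(all(s0$overall$pct[s0$overall$category != "neither"] == 0))

  # per-genus percentages recompute from column sums
  for (r in seq_len(nrow(s$per_genus))) {
    g <- s$per_genus$genus[r]
    sel <- names(genus_of)[genus_of == g]
    expect_equal(s$per_genus$nrps_positive[r], sum(tab[sel, "NRPS"]))
    expect_equal(
      s$per_genus$nrps_pct[r],
      percent_of(sum(tab[sel, "NRPS"]), length(sel))
    )
  }
})

test_that("screen prevalence converges to the configured rates", {
  comm <- generate_community(community_config(
    n_isolates = 400,
    genus_spec = data.frame(
      genus = "Streptomyces", proportion = 1, nrps = 0.6, pks2 = 0.3
    ),
    templates = c(Streptomyces = strrep("ACGT", 20)),
    seed = 19
  ))
  tab <- screen_isolates(comm)
  expect_lt(abs(mean(tab[, "NRPS"]) - 0.6), 3 * sqrt(0.6 * 0.4 / 400))
  expect_lt(abs(mean(tab[, "PKS-II"]) - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})
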