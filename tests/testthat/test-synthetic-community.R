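test_that("mutate_sequence is a seeded site-wise substitution process", {
  tpl <- strrep("ACGT", 25)
  expect_identical(mutate_sequence(tpl, 0, seed = 1), tpl)
  expect_identical(
    mutate_sequence(tpl, 0.1, seed = 42),
    mutate_sequence(tpl, 0.1, seed = 42)
  )
  mut <- mutate_sequence(tpl, 0.1, seed = 7)
  expect_equal(nchar(mut), nchar(tpl))
  expect_error(mutate_sequence(tpl, 0.3, 1), "divergence")
  expect_error(mutate_sequence(tpl, -0.01, 1), "divergence")
  expect_error(mutate_sequence("", 0.1, 1), "non-empty")
})

test_that("substitution counts follow the binomial sampling model", {
  tpl <- strrep("ACGT", 250) # 1000 nt
  n <- nchar(tpl)
  interval <- qbinom(c(0.005, 0.995), n, 0.02)
  mism <- vapply(1:300, function(s) {
    mut <- mutate_sequence(tpl, 0.02, seed = s)
    sum(strsplit(mut, "")[[1]] != strsplit(tpl, "")[[1]])
  }, numeric(1))
  inside <- mean(mism >= interval[1] & mism <= interval[2])
  # 99% of seeds should land in the central 99% binomial interval
  expect_gte(inside, 0.96)
  # and the mean substitution rate should match 0.02 within 4 sigma
  se <- sqrt(0.02 * 0.98 / (n * 300))
  expect_lt(abs(mean(mism) / n - 0.02), 4 * se)
})

test_that("a single base mutates with the configured probability", {
  changed <- vapply(1:10000, function(s) {
    mutate_sequence("A", 0.25, seed = s) != "A"
  }, logical(1))
  sigma <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(changed) - 0.25), 3 * sigma)
  expect_true(all(vapply(
    1:50, function(s) mutate_sequence("A", 0.25, seed = s) %in% c("A", "C", "G", "T"),
    logical(1)
  )))
})

test_that("planted marker loci amplify at the designed product size", {
  pairs <- default_primer_pairs()
  for (pair in pairs) {
    insert <- pair$expected_size - nchar(pair$forward) - nchar(pair$reverse)
    tpl <- plant_marker_locus(insert, pair$forward, pair$reverse, seed = 11)
    call <- insilico_pcr(tpl, pair)
    expect_true(call$positive)
    expect_equal(sum(call$amplicons$in_window), 1)
    expect_equal(
      call$amplicons$length[call$amplicons$in_window],
      pair$expected_size
    )
  }
  # degenerate-free core with no flanks is fully determined
  expect_identical(
    plant_marker_locus(0, "AAA", "TTT", seed = 1, flank_length = 0),
    "AAAAAA"
  )
  expect_error(plant_marker_locus(-1, "AAA", "TTT", 1), "insert_length")
})

test_that("generate_community honours counts, prevalence and activity config", {
  cfg <- community_config(n_isolates = 66, seed = 1)
  comm <- generate_community(cfg)
  expect_equal(nrow(comm), 66)
  expect_equal(length(unique(comm$genus)), 7)
  counts <- table(comm$genus)[default_genus_spec()$genus]
  expect_equal(unname(as.integer(counts)), c(41, 8, 8, 5, 2, 1, 1))
  expect_false(anyDuplicated(comm$isolate_id) > 0)

  # zero prevalence -> no marker templates
  gs <- default_genus_spec()
  gs$nrps <- 0
  gs$pks2 <- 0
  none <- generate_community(community_config(
    n_isolates = 20, genus_spec = gs, seed = 2
  ))
  expect_true(all(lengths(none$markers) == 0))

  # zero prevalence + P(active | no gene) = 0 -> all activity calls false
  inert <- generate_community(community_config(
    n_isolates = 20, genus_spec = gs,
    activity_model = c(both = 1, one = 1, none = 0), seed = 3
  ))
  expect_false(any(activity_table(inert)))
})

test_that("identical config and seed give byte-identical communities", {
  c1 <- generate_community(community_config(n_isolates = 12, seed = 9))
  c2 <- generate_community(community_config(n_isolates = 12, seed = 9))
  expect_identical(c1, c2)
  c3 <- generate_community(community_config(n_isolates = 12, seed = 10))
  expect_false(identical(c1$sixteenS, c3$sixteenS))
})

test_that("early isolates are invariant to community growth", {
  small <- generate_community(community_config(
    n_isolates = 10,
    genus_spec = data.frame(genus = "Streptomyces", proportion = 1),
    seed = 5
  ))
  big <- generate_community(community_config(
    n_isolates = 30,
    genus_spec = data.frame(genus = "Streptomyces", proportion = 1),
    seed = 5
  ))
  expect_identical(small$sixteenS, big$sixteenS[1:10])
})

test_that("empirical gene prevalence calibrates to the configured rates", {
  tpl <- c(G1 = strrep("ACGT", 15))
  cfg <- community_config(
    n_isolates = 10000,
    genus_spec = data.frame(
      genus = "G1", proportion = 1, nrps = 0.3, pks2 = 0.7
    ),
    templates = tpl,
    activity_model = c(both = 0, one = 0, none = 0),
    seed = 21
  )
  comm <- generate_community(cfg)
  has <- function(locus) {
    mean(vapply(comm$markers, function(m) locus %in% names(m), logical(1)))
  }
  expect_lt(abs(has("NRPS") - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_lt(abs(has("PKS-II") - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
})

test_that("config validation rejects inconsistent specifications", {
  expect_error(community_config(n_isolates = 0), "n_isolates")
  expect_error(
    community_config(genus_spec = data.frame(
      genus = c("A", "B"), proportion = c(0.6, 0.5)
    )),
    "sum to 1"
  )
  expect_error(
    community_config(activity_model = c(both = 1.2, one = 0, none = 0)),
    "probabilities"
  )
  expect_error(
    generate_community(community_config(
      templates = c(Wrong = "ACGT"),
      genus_spec = data.frame(genus = "Right", proportion = 1)
    )),
    "no template"
  )
})

test_that("largest-remainder apportionment is exact and order-stable", {
  cfg <- community_config(
    n_isolates = 10,
    genus_spec = data.frame(
      genus = c("A", "B", "C"), proportion = c(1 / 3, 1 / 3, 1 / 3)
    ),
    seed = 1
  )
  counts <- table(generate_community(cfg)$genus)
  # 10/3: quotas 3.33 each, remainder seat goes to the first listed genus
  expect_equal(as.integer(counts[c("A", "B", "C")]), c(4, 3, 3))
})
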