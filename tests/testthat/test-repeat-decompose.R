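test_that("detect_period finds exact tandems and matches the brute-force score", {
  set.seed(11)
  u <- rand_dna(30)
  tandem <- paste0(strrep(u, 5))
  top <- detect_period(tandem)
  expect_equal(top$period[1], 30L)
  expect_equal(top$score[1], 1.0)
  # random sequence: no period passes 0.8, and scores agree with the oracle
  rnd <- rand_dna(300)
  ranked <- detect_period(rnd)
  expect_true(all(ranked$score < 0.8))
  for (p in c(24, 30, 39)) {
    expect_equal(ranked$score[ranked$period == p], oracle_period_score(rnd, p))
  }
  # mixed 33/30 array from one consensus still shows the 30-nt period
  u33 <- paste0(substr(u, 1, 15), "GCA", substr(u, 16, 30))
  arr <- paste0(u33, strrep(u, 5), u33, u, u33)
  expect_equal(detect_period(arr)$period[1], 30L)
  expect_gt(detect_period(arr)$score[1], 0.8)
  # too short
  expect_equal(nrow(detect_period("ACGTACGT")), 0)
})

test_that("build_consensus takes per-column majority with alphabetical ties", {
  set.seed(12)
  u <- rand_dna(30)
  expect_equal(build_consensus(strrep(u, 4), 30), u)
  # one substitution in one copy is outvoted
  mutated <- u
  substr(mutated, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(u, 7, 7))[1]
  expect_equal(build_consensus(paste0(u, mutated, u), 30), u)
  # two-copy tie resolves to the alphabetically first base
  a <- paste0("A", substr(u, 2, 30)); g <- paste0("G", substr(u, 2, 30))
  expect_equal(substr(build_consensus(paste0(a, g), 30), 1, 1), "A")
})

test_that("segment_units recovers exact embedded arrays with exact flanks", {
  set.seed(13)
  u <- rand_cds_codons(11) # 33-mer
  flank5 <- rand_dna(40); flank3 <- rand_dna(55)
  cds <- paste0(flank5, strrep(u, 4), flank3)
  arr <- segment_units(cds, u)
  expect_equal(arr$unit_lengths, rep(33L, 4))
  expect_equal(arr$flank5, flank5)
  expect_equal(arr$flank3, flank3)
  expect_equal(arr$identity, rep(1, 4))
  # no resemblance: empty array, whole CDS as flank
  junk <- rand_dna(200)
  none <- segment_units(junk, u)
  expect_equal(length(none$units), 0)
  expect_equal(none$flank5, junk)
})

test_that("segmentation equals exhaustive tiling search on small instances", {
  set.seed(14)
  for (rep in 1:20) {
    cons <- rand_cds_codons(10) # 30-mer
    k <- sample(2:4, 1)
    lens <- sample(c(30L, 33L), k, replace = TRUE)
    units <- vapply(lens, function(l) {
      if (l == 30) cons else
        paste0(substr(cons, 1, 15), rand_cds_codons(1), substr(cons, 16, 30))
    }, character(1))
    # sprinkle a couple of substitutions
    units <- vapply(units, function(u) {
      i <- sample(nchar(u), 1)
      substr(u, i, i) <- sample(c("A", "C", "G", "T"), 1)
      u
    }, character(1), USE.NAMES = FALSE)
    cds <- paste0(rand_dna(sample(20:45, 1)), paste(units, collapse = ""),
      rand_dna(sample(20:45, 1)))
    if (nchar(cds) > 250) next
    got <- segment_units(cds, cons)
    want <- oracle_tiling(cds, cons)
    got_score <- (got$score_matched -
      2 * sum(got$unit_lengths != nchar(cons))) * 1000 +
      got$score_identity * 10 - 0.01 * length(got$units)
    expect_equal(got_score, want$score, tolerance = 1e-6)
    expect_equal(got$region_start, want$start)
    expect_equal(got$unit_lengths, want$lens)
  }
})

test_that("decomposition reconstructs its input and preserves frame", {
  cfg <- small_family_config(seed = 15)
  fam <- generate_family(cfg)
  dec <- decompose_repeats(tibble::tibble(id = fam$members$id,
    seq = fam$members$cds))
  for (i in seq_len(nrow(dec))) {
    a <- dec$array[[i]]
    expect_identical(paste0(a$flank5, paste(a$units, collapse = ""), a$flank3),
      fam$members$cds[i])
    expect_true(all(a$unit_lengths %% 3 == 0))
  }
})

test_that("published example arrays decompose to the printed unit counts", {
  # the 9-unit array with 279-nt region and the 8-unit 33-30x7 array
  cfg <- family_config(n_members = 2, motifs = c("YRSKDD", "CNDSGD"),
    fixed_patterns = list(c(33, 30, 30, 30, 30, 30, 33, 30, 33),
      c(33, rep(30, 7))),
    substitution_rate = 0, type_divergence = 0, seed = 16)
  fam <- generate_family(cfg)
  dec <- decompose_repeats(tibble::tibble(id = fam$members$id,
    seq = fam$members$cds))
  expect_equal(dec$pattern[1], "33-30-30-30-30-30-33-30-33")
  expect_equal(dec$region_len[1], 279L)
  expect_equal(dec$pattern[2], "33-30-30-30-30-30-30-30")
  expect_equal(dec$copy_number[2], 8L)
})

test_that("single-copy members are rescued with the family consensus", {
  cfg <- family_config(n_members = 4, motifs = "YRSKDD",
    fixed_patterns = list(c(30L), c(33L), c(30L, 30L, 30L, 30L, 30L),
      c(33L, 30L, 30L, 30L)),
    substitution_rate = 0.01, seed = 17)
  fam <- generate_family(cfg)
  dec <- decompose_repeats(tibble::tibble(id = fam$members$id,
    seq = fam$members$cds))
  expect_equal(dec$copy_number, fam$truth$members$copy_number)
  expect_equal(dec$pattern, fam$truth$members$pattern)
})

test_that("copy number is recovered under substitution noise", {
  cfg <- family_config(n_members = 60, substitution_rate = 0.03, seed = 18)
  fam <- generate_family(cfg)
  dec <- decompose_repeats(tibble::tibble(id = fam$members$id,
    seq = fam$members$cds))
  tr <- fam$truth$members
  rec <- mean(dec$copy_number == tr$copy_number[match(dec$id, tr$id)])
  expect_gte(rec, 0.95)
})
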