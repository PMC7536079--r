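make_units <- function(seed = 41) {
  set.seed(seed)
  u30 <- rand_cds_codons(10)
  u33 <- paste0(substr(u30, 1, 15), rand_cds_codons(1), substr(u30, 16, 30))
  list(u30 = u30, u33 = u33)
}

test_that("unit_match requires equal length and threshold identity", {
  u <- make_units()
  expect_true(unit_match(u$u30, u$u30))
  expect_false(unit_match(u$u30, u$u33))
  two_off <- u$u30
  substr(two_off, 3, 3) <- setdiff(c("A","C","G","T"), substr(u$u30, 3, 3))[1]
  substr(two_off, 9, 9) <- setdiff(c("A","C","G","T"), substr(u$u30, 9, 9))[1]
  expect_true(unit_match(u$u30, two_off))                     # 28/30
  expect_false(unit_match(u$u30, two_off, min_identity = 0.95))
})

test_that("infer_excision matches exhaustive search for planted deletions", {
  set.seed(42)
  # exhaustively check every contiguous internal deletion on arrays of
  # mutually distinguishable units
  for (n_units in c(5, 7, 9)) {
    longer_units <- replicate(n_units, rand_cds_codons(10))
    longer <- repeat_array(longer_units, flank5 = "AAA", flank3 = "TTT")
    for (from in 2:(n_units - 2)) for (len in 1:(n_units - from - 1)) {
      kept <- setdiff(seq_len(n_units), from:(from + len - 1))
      shorter <- repeat_array(longer_units[kept])
      ev <- infer_excision(longer, shorter)
      expect_false(is.null(ev))
      expect_equal(ev$excised$position, from:(from + len - 1))
      expect_true(ev$contiguous)
      expect_equal(ev$conserved_prefix, from - 1L)
      expect_equal(ev$conserved_suffix, n_units - (from + len - 1L))
      # soundness: applying the excision reproduces the shorter pattern
      expect_equal(apply_excision(longer, ev), shorter$unit_lengths)
    }
  }
})

test_that("infer_excision refuses equal arrays and unmatched units", {
  u <- make_units(43)
  a <- repeat_array(rep(u$u30, 3))
  expect_warning(res <- infer_excision(a, a))
  expect_null(res)
  foreign <- repeat_array(c(u$u30, paste(rev(strsplit(u$u30, "")[[1]]),
    collapse = "")))
  longer <- repeat_array(rep(u$u30, 4))
  expect_null(infer_excision(longer, foreign))
})

test_that("classification follows the five-class decision table", {
  u <- make_units(44)
  mk_event <- function(cl) {
    p <- plant_slippage_pair(u$u30, u$u33, cl)
    longer <- repeat_array(p$longer_units)
    shorter <- repeat_array(p$shorter_units)
    list(ev = infer_excision(longer, shorter), longer = longer,
      shorter = shorter, truth = p$truth)
  }
  for (cl in 1:5) {
    x <- mk_event(cl)
    expect_equal(classify_slippage(x$ev, x$longer, x$shorter), cl,
      label = paste("class", cl))
  }
  # the class-3 exemplar: first and last conserved, five 30-nt units excised
  x3 <- mk_event(3)
  expect_equal(nrow(x3$ev$excised), 5)
  expect_true(all(x3$ev$excised$unit_length == 30))
  expect_equal(length(x3$shorter$units), length(x3$longer$units) - 5L)
  # mixed excised lengths admit no class
  longer <- repeat_array(c(
    vntrfam:::apply_unit_mark(u$u30, 1, 4L), u$u30, u$u33,
    vntrfam:::apply_unit_mark(u$u30, 2, 4L),
    vntrfam:::apply_unit_mark(u$u30, 3, 4L)))
  shorter <- repeat_array(longer$units[c(1, 4, 5)])
  ev <- infer_excision(longer, shorter)
  expect_true(is.na(classify_slippage(ev, longer, shorter)))
})

test_that("a family with one exemplar pair per class yields the five classes", {
  cfg <- family_config(n_members = 0, n_slippage_pairs = 1L, seed = 45)
  res <- run_family_pipeline(generate = cfg, n_boot = 0)
  expect_equal(nrow(res$slippage), 5)
  expect_setequal(res$slippage$slip_class, 1:5)
  # events sorted by class; soundness of every event
  expect_equal(res$slippage$slip_class, sort(res$slippage$slip_class))
})

test_that("identical arrays give no events; cross-type scan is a superset", {
  cfg <- family_config(n_members = 4, motifs = "YRSKDD",
    fixed_patterns = list(c(30L, 30L, 30L)), substitution_rate = 0, seed = 46)
  fam <- generate_family(cfg)
  dec <- decompose_repeats(tibble::tibble(id = fam$members$id,
    seq = fam$members$cds))
  ty <- tibble::tibble(id = dec$id, motif = "YRSKDD", type = "YRSKDD")
  expect_equal(nrow(scan_slippage(dec, ty)), 0)
  # superset property on a family with types
  cfg2 <- family_config(n_members = 8, motifs = c("YRSKDD", "CNDSGD"),
    n_slippage_pairs = c(1L, 0L, 0L, 0L, 1L), seed = 47)
  res2 <- run_family_pipeline(generate = cfg2, n_boot = 0)
  fam2 <- generate_family(cfg2)
  dec2 <- decompose_repeats(tibble::tibble(id = fam2$members$id,
    seq = fam2$members$cds))
  ann2 <- annotate_transcripts(fam2$transcripts[, c("id", "seq")])
  ty2 <- assign_types(ann2[ann2$id %in% fam2$members$id, ])
  within <- scan_slippage(dec2, ty2, within_type_only = TRUE)
  across <- scan_slippage(dec2, ty2, within_type_only = FALSE)
  expect_gte(nrow(across), nrow(within))
  key <- function(df) paste(df$longer_id, df$shorter_id)
  expect_true(all(key(within) %in% key(across)))
})

test_that("class recovery survives light mutation noise", {
  hits <- 0; total <- 0
  for (seed in 48:52) {
    cfg <- family_config(n_members = 0, n_slippage_pairs = 1L,
      substitution_rate = 0.02, seed = seed)
    res <- run_family_pipeline(generate = cfg, n_boot = 0)
    fam <- generate_family(cfg)
    total <- total + nrow(fam$truth$slippage)
    hits <- hits + sum(res$recovery$recovered[res$recovery$stage == "slippage"])
  }
  expect_gte(hits / total, 0.9)
})
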