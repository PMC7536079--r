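test_that("mask_repeats removes repeat-encoded residues", {
  cfg <- family_config(n_members = 1, motifs = "YRSKDD",
    fixed_patterns = list(c(33, 30, 30, 30, 30, 30, 33, 30, 33)),
    substitution_rate = 0, type_divergence = 0, seed = 21)
  fam <- generate_family(cfg)
  ann <- annotate_transcripts(fam$transcripts[, c("id", "seq")])
  arr <- decompose(fam$members$cds[1])
  masked <- mask_repeats(ann$protein[1], arr)
  expect_equal(nchar(ann$protein[1]), 297L)
  expect_equal(sum(arr$unit_lengths) / 3, 93)
  expect_equal(nchar(masked), 204L)
  # zero units: unchanged
  expect_equal(mask_repeats("PROTEIN", vntrfam:::empty_array("AAA")), "PROTEIN")
  # out-of-frame region: error
  bad <- arr; bad$region_start <- arr$region_start + 1L
  expect_error(mask_repeats(ann$protein[1], bad), class = "vntrfam_mask_error")
})

test_that("motif extraction is anchored and tolerates one context mismatch", {
  anchor <- default_motif_anchor()
  prot <- paste0("AAAA", anchor$context, "YRSKDD", "TTTT")
  expect_equal(extract_motif(prot), "YRSKDD")
  prot2 <- paste0("AAAA", sub("Q", "A", anchor$context), "CNDSGD", "TTTT")
  expect_equal(extract_motif(prot2), "CNDSGD")
  expect_true(is.na(extract_motif("MKLVVVVLLLAAAA")))
})

test_that("p-distance matches a counting oracle and excludes invalid columns", {
  expect_equal(p_distance("KKKK", "KKKK"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  set.seed(22)
  aa <- c(LETTERS[1:20])
  a <- paste(sample(aa, 100, replace = TRUE), collapse = "")
  b <- paste(sample(aa, 100, replace = TRUE), collapse = "")
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  valid <- !(x %in% c("X", "-")) & !(y %in% c("X", "-"))
  expect_equal(p_distance(a, b), sum(x[valid] != y[valid]) / sum(valid))
  expect_equal(p_distance("A-XB", "AC-B"), 0) # only columns 1 and 4 valid
  expect_error(p_distance("XX", "AA"), class = "vntrfam_distance_error")
})

test_that("NJ solves the 3-taxon closed form exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ recovers generating trees from additive matrices", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    d <- cophenetic(tr)
    my <- nj_tree(d)
    expect_equal(phangorn::RF.dist(my, tr), 0)
    # additive matrices are reproduced exactly by the fitted tree
    expect_lt(max(abs(cophenetic(my)[rownames(d), colnames(d)] - d)), 1e-9)
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  skip_if_not_installed("phangorn")
  set.seed(24)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    m <- matrix(runif(n * n, 0.05, 1), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
    expect_equal(phangorn::RF.dist(nj_tree(m), ape::nj(m)), 0)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)))
  bad <- matrix(runif(9), 3, 3)
  expect_error(nj_tree(bad), class = "vntrfam_distance_error")
})

test_that("bootstrap support is deterministic and saturates on clean clades", {
  seqs <- c(a1 = "AAAAAAAAKKKK", a2 = "AAAAAAAAKKKR",
            b1 = "TTTTTTTTKKKK", b2 = "TTTTTTTTKKKR",
            c1 = "GGGGGGGGKKKK", c2 = "GGGGGGGGKKKR")
  b <- bootstrap_support(seqs, n_reps = 100, seed = 9)
  expect_true(all(b$support >= 0 & b$support <= 100))
  expect_true(all(b$support[b$bipartition %in% c("b1|b2", "c1|c2")] == 100))
  expect_identical(b, bootstrap_support(seqs, n_reps = 100, seed = 9))
  empty <- bootstrap_support(seqs, n_reps = 0, seed = 9)
  expect_equal(nrow(empty), 3) # bipartitions listed, zero support
  expect_true(all(empty$support == 0))
})

test_that("type assignment counts distinct motifs, order-invariantly", {
  cfg <- family_config(n_members = 30, seed = 25)
  fam <- generate_family(cfg)
  ann <- annotate_transcripts(fam$transcripts[, c("id", "seq")])
  ty <- assign_types(ann)
  expect_equal(sort(unique(ty$motif)), sort(unique(fam$truth$members$motif)))
  counts <- type_counts(ty)
  expect_equal(sum(counts$n_members), 30)
  # permuting the input changes nothing but row order
  perm <- ann[sample(nrow(ann)), ]
  expect_equal(type_counts(assign_types(perm)), counts)
})

test_that("types are monophyletic when between-type divergence dominates", {
  cfg <- family_config(n_members = 12, motifs = c("YRSKDD", "CNDSGD", "YHYQEH"),
    substitution_rate = 0.01, type_divergence = 0.05, seed = 26)
  res <- run_family_pipeline(generate = cfg, n_boot = 0)
  expect_false(is.null(res$tree))
  types <- res$types
  for (tp in unique(types$type)) {
    ids <- types$id[types$type == tp]
    expect_true(ape::is.monophyletic(res$tree$tree, ids))
  }
})

test_that("family_tree objects expose tidy, glance and newick output", {
  cfg <- family_config(n_members = 8, motifs = c("YRSKDD", "CNDSGD"), seed = 27)
  res <- run_family_pipeline(generate = cfg, n_boot = 10)
  td <- tidy(res$tree)
  expect_true(all(c("parent", "node", "branch_length", "label") %in% names(td)))
  expect_equal(sum(td$is_tip), 8)
  gl <- glance(res$tree)
  expect_equal(gl$n_taxa, 8)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(res$tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, res$types$id)
  expect_s3_class(autoplot(res$tree), "ggplot")
})
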