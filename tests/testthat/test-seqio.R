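test_that("FASTA round-trips through normalized records", {
  set.seed(1)
  df <- tibble::tibble(id = c("seqA", "seqB"),
    seq = c(rand_dna(130), rand_dna(61)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(df, f)
  back <- read_fasta(f)
  expect_equal(back, df)
  # rewrite is byte-stable
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("FASTA rejects bad alphabets and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "ACGTX"), f)
  expect_error(read_fasta(f), class = "vntrfam_alphabet_error")
  writeLines(character(0), f)
  expect_warning(res <- read_fasta(f), "no records")
  expect_equal(nrow(res), 0)
})

test_that("GFF3 coordinates convert exactly and round-trip", {
  set.seed(2)
  g <- rand_dna(4000)
  exl <- c(160L, 267L, 159L, 106L, 108L, 58L)
  inl <- c(201L, 910L, 420L, 563L, 532L)
  starts <- integer(6); pos <- 0L
  for (i in 1:6) {
    starts[i] <- pos
    pos <- pos + exl[i] + if (i < 6) inl[i] else 0L
  }
  m <- gene_model("g1", g, starts, starts + exl)
  # genomic span equals the sum of printed exon+intron lengths
  expect_equal(max(m$exon_ends) - min(m$exon_starts), sum(exl) + sum(inl))
  expect_equal(max(m$exon_ends) - min(m$exon_starts), 3484L)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(list(m), f)
  # the emitted 1-based inclusive exon lines
  lines <- grep("\texon\t", readLines(f), value = TRUE)
  first <- as.integer(strsplit(lines[1], "\t")[[1]][4:5])
  expect_equal(first, c(starts[1] + 1L, starts[1] + exl[1]))
  back <- read_gene_models(f, tibble::tibble(id = "g1", seq = g))
  expect_equal(back$model[[1]]$exon_starts, m$exon_starts)
  expect_equal(back$model[[1]]$exon_ends, m$exon_ends)
})

test_that("gene models reject overlapping or out-of-bounds exons", {
  g <- rand_dna(500)
  expect_error(gene_model("x", g, c(0, 50), c(100, 150)),
    class = "vntrfam_coordinate_error")
  expect_error(gene_model("x", g, c(0, 200), c(100, 600)),
    class = "vntrfam_coordinate_error")
  expect_error(gene_model("x", g, c(0, 101), c(100, 200)),
    class = "vntrfam_coordinate_error") # intron < 4 nt
})

test_that("find_orf returns the longest ATG-initiated frame, stop included", {
  set.seed(3)
  # assembled from the published component lengths: 47 + 894 + 467
  cfg <- family_config(n_members = 1, motifs = "YRSKDD",
    fixed_patterns = list(c(33, 30, 30, 30, 30, 30, 33, 30, 33)),
    substitution_rate = 0, type_divergence = 0, seed = 3)
  tr <- generate_family(cfg)$transcripts$seq[1]
  orf <- find_orf(tr)
  expect_equal(orf$start, 47L)
  expect_equal(orf$end, 941)
  expect_equal(orf$length, 894)
  expect_equal(find_orf("ATGTAA")[c("start", "end")], list(start = 0L, end = 6))
  expect_null(find_orf("CCCCCCCC"))
})

test_that("translation uses the standard code and excludes the stop", {
  # cross-checked against Biostrings on the whole codon table
  tab <- vntrfam:::CODON_TABLE
  bs <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(names(tab)), no.init.codon = TRUE))
  expect_equal(unname(tab), bs)
  expect_equal(translate_orf("ATGTAA", list(start = 0, end = 6)), "M")
  cds <- paste0("ATG", rand_cds_codons(8), "TAATTT", rand_cds_codons(2), "TAA")
  expect_error(translate_orf(cds, list(start = 0, end = nchar(cds))),
    class = "vntrfam_frame_error")
  # codons containing N become X
  expect_equal(translate_orf("ATGANTTAA", list(start = 0, end = 9)), "MX")
})

test_that("protein round-trips through codon encoding", {
  set.seed(4)
  aa <- paste(sample(setdiff(unique(vntrfam:::CODON_TABLE), "*"), 40,
    replace = TRUE), collapse = "")
  cds <- paste0(vntrfam:::encode_protein(paste0("M", aa)), "TAA")
  expect_equal(translate_orf(cds, list(start = 0, end = nchar(cds))),
    paste0("M", aa))
})

test_that("polyadenylation signal reports the 3'-most hit in the window", {
  set.seed(5)
  tail20 <- rand_dna(20)
  base <- gsub("AATAAA", "CCCCCC", paste0(rand_dna(300), "AATAAA", tail20))
  s <- paste0(rand_dna(300), "AATAAA", tail20)
  expect_equal(find_polya_signal(s), nchar(s) - 26L)
  expect_true(is.na(find_polya_signal(gsub("AATAAA", "CCCCCC", s))))
  two <- paste0(rand_dna(200), "AATAAA", "GG", "AATAAA", rand_dna(20))
  expect_equal(find_polya_signal(two), nchar(two) - 26L)
})

test_that("Ca-site motif scan finds EPN/QPD occurrences", {
  cfg <- family_config(n_members = 1, motifs = "YRSKDD",
    fixed_patterns = list(c(33, 30, 30, 30, 30, 30, 33, 30, 33)),
    substitution_rate = 0, type_divergence = 0, seed = 6)
  fam <- generate_family(cfg)
  prot <- annotate_transcripts(fam$transcripts[, c("id", "seq")])$protein
  hits <- scan_ca_site_motif(prot)
  expect_equal(nchar(prot), 297L)
  expect_true(any(hits$motif == "EPN" & hits$start == 248))
  expect_equal(scan_ca_site_motif("AAAQPDAAA"),
    tibble::tibble(motif = "QPD", start = 4L))
  expect_equal(nrow(scan_ca_site_motif("AAAAAA")), 0)
})

test_that("transcript component arithmetic is conserved", {
  cfg <- small_family_config(seed = 9)
  fam <- generate_family(cfg)
  ann <- annotate_transcripts(fam$transcripts[, c("id", "seq")])
  expect_true(all(ann$utr5_len + ann$orf_len + ann$utr3_len == ann$cdna_len))
  expect_true(all(ann$orf_len %% 3 == 0))
  expect_true(all(ann$protein_len == ann$orf_len / 3 - 1))
})
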