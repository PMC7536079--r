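## Synthetic gene-family generator. Emulates a duplicated 6-exon/5-intron
## lectin gene family whose second exon carries an in-frame tandem-repeat
## region of 30/33-nt units (copy number 1-9), with a diagnostic
## six-amino-acid motif in the exon-5-encoded block, optional planted
## unit-excision (slippage) pairs in five flank-conservation classes, and
## optional alternative-splicing variant transcripts. Every planted object
## is recorded as ground truth re-derivable from the emitted sequences.
##
## Backbone arithmetic (all defaults): coding exons 160, 267, 159, 106,
## 108, 58 nt; the repeat region sits inside exon 2 between a 14-nt 5'
## flank and a 10-nt 3' flank, so the region starts on a codon boundary
## (offset 174 of the CDS) and coding exon 2 is 24 + region nt (267 for the
## 8-unit backbone). CDS length is 615 + region nt: 894 for a 9-unit
## 33-30-30-30-30-30-33-30-33 array, encoding a 297-residue protein. With
## the default 47-nt 5'UTR and 467-nt 3'UTR the cDNA is 1408 nt.

AA2CODON <- local({
  inv <- split(names(CODON_TABLE), CODON_TABLE)
  vapply(inv, function(x) sort(x)[1], character(1))
})

encode_protein <- function(aa) {
  paste(AA2CODON[strsplit(aa, "")[[1]]], collapse = "")
}

MOTIF_LIST_DEFAULT <- c(
  "CNDSGD", "FHFKGG", "FHFKGD", "FHYKGD", "FQSKDG", "YHSKDD", "YHYQEH",
  "YKKKED", "YKKRED", "YNYFDD", "YRSKDD", "YTYKED", "YTYKKD", "YVVSDD",
  "YYYKED")

MOTIF_CONTEXT <- "WQNTGKPE"

#' Configuration for the synthetic family generator
#'
#' Defaults describe the family the analysis is modelled on: 76 members over
#' 15 motif types, 30/33-nt repeat units at copy numbers 1-9, a 6-exon
#' coding backbone of 160/267/159/106/108/58 nt with introns
#' 201/910/420/563/532 nt, a 47-nt 5'UTR and a 467-nt 3'UTR with AATAAA.
#'
#' @param n_members Number of ordinary family members.
#' @param motifs Character vector of diagnostic 6-residue motifs (one type
#'   each).
#' @param copy_range Integer range of repeat copy numbers (default 1:9).
#' @param unit_lengths Admissible unit lengths in nt (default c(30, 33);
#'   must be divisible by 3).
#' @param exon_lengths Six coding exon lengths; element 2 is the backbone
#'   (8-unit) value and scales with copy number.
#' @param intron_lengths Five intron lengths.
#' @param utr5_len,utr3_len Untranslated region lengths.
#' @param substitution_rate Per-base substitution rate between a member and
#'   its type founder (default 0.01; within-type members are highly
#'   conserved).
#' @param type_divergence Per-base substitution rate between a type founder
#'   and the family founder (default 0.05, i.e. 5x the within-type rate, so
#'   types form well-separated clades).
#' @param n_slippage_pairs Planted unit-excision exemplar pairs per class
#'   1-5 (scalar or length-5 vector; default 0).
#' @param n_splice_variants Named or length-3 vector: planted variant
#'   transcripts per mode (`alt_acceptor`, `alt_donor_acceptor`,
#'   `exon_skipping`; default 0).
#' @param canonical_context Force AG/GT dinucleotides at shifted splice
#'   junctions of planted variants (default `TRUE`).
#' @param hostile If `TRUE`, mutations may also hit the motif anchor
#'   context, start/stop codons and splice sites (default `FALSE`: those
#'   signals are protected, so they stay separate from what is being
#'   tested).
#' @param fixed_patterns Optional list of unit-length vectors; member i
#'   receives the i-th pattern (recycled) instead of a random arrangement.
#'   Used to pin worked examples (e.g. the 9-unit 33-30-30-30-30-30-33-30-33
#'   array) and engineered catalogues.
#' @param seed Integer seed; the whole family is a deterministic function of
#'   the config.
#' @return A `family_config` list.
#' @export
family_config <- function(n_members = 76,
                          motifs = MOTIF_LIST_DEFAULT,
                          copy_range = 1:9,
                          unit_lengths = c(30L, 33L),
                          exon_lengths = c(160L, 267L, 159L, 106L, 108L, 58L),
                          intron_lengths = c(201L, 910L, 420L, 563L, 532L),
                          utr5_len = 47L, utr3_len = 467L,
                          substitution_rate = 0.01,
                          type_divergence = 0.05,
                          n_slippage_pairs = 0L,
                          n_splice_variants = c(alt_acceptor = 0L,
                            alt_donor_acceptor = 0L, exon_skipping = 0L),
                          canonical_context = TRUE,
                          hostile = FALSE,
                          fixed_patterns = NULL,
                          seed = 1L) {
  stopifnot(length(exon_lengths) == 6, length(intron_lengths) == 5,
    all(unit_lengths %% 3 == 0),
    substitution_rate >= 0, substitution_rate <= 1,
    type_divergence >= 0, type_divergence <= 1,
    min(copy_range) >= 1, max(copy_range) <= 20)
  if (length(n_slippage_pairs) == 1) n_slippage_pairs <- rep(n_slippage_pairs, 5)
  stopifnot(length(n_slippage_pairs) == 5)
  nsv <- c(alt_acceptor = 0L, alt_donor_acceptor = 0L, exon_skipping = 0L)
  if (is.null(names(n_splice_variants))) {
    nsv[seq_along(n_splice_variants)] <- n_splice_variants
  } else {
    nsv[names(n_splice_variants)] <- n_splice_variants
  }
  # repeat region must fit exon 2: flanks are 24 nt
  max_region <- max(copy_range) * max(unit_lengths)
  backbone_region <- exon_lengths[2] - 24L
  if (backbone_region < min(unit_lengths)) {
    abort("exon 2 too short for any repeat region", class = "vntrfam_config_error")
  }
  structure(list(
    n_members = as.integer(n_members), motifs = motifs,
    copy_range = as.integer(copy_range),
    unit_lengths = as.integer(unit_lengths),
    exon_lengths = as.integer(exon_lengths),
    intron_lengths = as.integer(intron_lengths),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    substitution_rate = substitution_rate,
    type_divergence = type_divergence,
    n_slippage_pairs = as.integer(n_slippage_pairs),
    n_splice_variants = nsv,
    canonical_context = isTRUE(canonical_context),
    hostile = isTRUE(hostile),
    fixed_patterns = fixed_patterns,
    seed = as.integer(seed)
  ), class = "family_config")
}

BASES <- c("A", "C", "G", "T")

# sample() that never interprets a scalar as 1:n
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# codons that are not stops
SAFE_CODONS <- setdiff(names(CODON_TABLE), STOP_CODONS)
# codons safe for repeat units: third-position changes can never create a
# stop (i.e. first two bases not TA or TG)
UNIT_CODONS <- SAFE_CODONS[!substr(SAFE_CODONS, 1, 2) %in% c("TA", "TG")]

random_codons <- function(n, pool = SAFE_CODONS) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute bases at `rate`, never touching `protected` (0-based positions)
# and never creating an in-frame stop codon (frame anchored at position 0)
mutate_cds <- function(cds, rate, protected = integer(0)) {
  if (rate <= 0) return(cds)
  n <- nchar(cds)
  chars <- strsplit(cds, "")[[1]]
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protected + 1L)
  for (i in hit) {
    codon_start <- ((i - 1L) %/% 3L) * 3L + 1L
    for (b in sample(setdiff(BASES, chars[i]))) {
      old <- chars[i]; chars[i] <- b
      codon <- paste(chars[codon_start:min(codon_start + 2L, n)], collapse = "")
      if (nchar(codon) < 3 || !(codon %in% STOP_CODONS)) break
      chars[i] <- old
    }
  }
  paste(chars, collapse = "")
}

# substitute only third codon positions, at 3x the per-base rate, so the
# expected per-unit substitution count matches `rate` while the frame and
# the no-stop invariant of UNIT_CODONS are preserved
mutate_unit <- function(unit, rate) {
  if (rate <= 0) return(unit)
  n <- nchar(unit)
  chars <- strsplit(unit, "")[[1]]
  thirds <- seq(3L, n, by = 3L)
  hit <- thirds[stats::runif(length(thirds)) < min(1, 3 * rate)]
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  paste(chars, collapse = "")
}

mutate_plain <- function(seq, rate, protected = integer(0)) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- setdiff(which(stats::runif(n) < rate), protected + 1L)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  paste(chars, collapse = "")
}

random_utr5 <- function(len) {
  repeat {
    s <- random_dna(len)
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

random_utr3 <- function(len) {
  repeat {
    body <- random_dna(len - 26L)
    s <- paste0(body, "AATAAA", random_dna(20L))
    # the planted signal must be the 3'-most AATAAA in the scan window
    tail50 <- substr(s, len - 49L, len)
    if (max(gregexpr("AATAAA", tail50, fixed = TRUE)[[1]]) == 25L) return(s)
  }
}

# distinguishing marks for planted slippage arrays: single-nt
# third-position substitutions. 4-nt marks make any two marked units (and
# marked vs unmarked) differ by >= 4 nt, defeating the 0.9 unit-match
# threshold; 2-nt marks (disjoint codon pairs, >= 4 nt between marked
# units) are used where the unit's length differs from the array's
# consensus so the cross-length identity stays above the 0.8 segmentation
# threshold.
apply_unit_mark <- function(unit, mark, n_changes = 4L) {
  n_codons <- nchar(unit) %/% 3L
  codons <- if (n_changes == 2L) {
    ((mark - 1L) * 2L) %% n_codons + c(1L, 2L)
  } else {
    ((mark - 1L + 2L * (0:(n_changes - 1L))) %% n_codons) + 1L
  }
  step <- ((mark - 1L) %% 3L) + 1L
  chars <- strsplit(unit, "")[[1]]
  for (cd in codons) {
    p <- cd * 3L
    chars[p] <- BASES[(match(chars[p], BASES) - 1L + step) %% 4L + 1L]
  }
  paste(chars, collapse = "")
}

#' Plant a slippage exemplar pair of a given class
#'
#' Builds a (longer, shorter) pair of repeat arrays realizing one of the
#' five excision classes. Conserved flank units carry distinguishing marks
#' (4 third-position substitutions each) so the excision is unambiguously
#' inferable; excised units are plain consensus copies.
#'
#' Recipes (longer arrangement; excised 1-based positions):
#' class 1: 33-30-30-30-30-30-33-30-33, excise 2-6 (five 30s; 1 unit
#' conserved 5', 3 conserved 3'); class 2: 30-30-30-33-33-30-30, excise
#' 4-5 (33s; >= 2 conserved 5', >= 1 conserved 3'); class 3: 30 x 7,
#' excise 2-6 (five 30s; first and last conserved); class 4: 30 x 5,
#' excise 2-3 (30s; 1 conserved 5', 2 conserved 3'); class 5: 33 x 5,
#' excise 2-3 (all units 33).
#'
#' @param unit30,unit33 Base unit sequences (30 and 33 nt).
#' @param slip_class Integer 1-5.
#' @return List with `longer_units`, `shorter_units` (character vectors) and
#'   `truth` (list: `excised_positions`, `slip_class`, `conserved_prefix`,
#'   `conserved_suffix`).
#' @export
plant_slippage_pair <- function(unit30, unit33, slip_class) {
  recipe <- switch(as.character(slip_class),
    "1" = list(lens = c(33, 30, 30, 30, 30, 30, 33, 30, 33), excise = 2:6,
               marks = c(2L, 2L, 4L, 2L)),
    "2" = list(lens = c(30, 30, 30, 33, 33, 30, 30), excise = 4:5,
               marks = c(2L, 2L, 2L, 2L, 2L)),
    "3" = list(lens = rep(30, 7), excise = 2:6, marks = c(4L, 4L)),
    "4" = list(lens = rep(30, 5), excise = 2:3, marks = c(4L, 4L, 4L)),
    "5" = list(lens = rep(33, 5), excise = 2:3, marks = c(4L, 4L, 4L)),
    abort("slip_class must be 1-5", class = "vntrfam_plant_error"))
  lens <- recipe$lens; excise <- recipe$excise
  if (slip_class == 5 && !all(lens == 33)) {
    abort("class 5 requires an all-33 array", class = "vntrfam_plant_error")
  }
  kept <- setdiff(seq_along(lens), excise)
  units <- ifelse(lens == 30, unit30, unit33)
  for (k in seq_along(kept)) {
    units[kept[k]] <- apply_unit_mark(units[kept[k]], k, recipe$marks[k])
  }
  n <- length(lens)
  pre <- 0L; while (pre < n && (pre + 1L) %in% kept) pre <- pre + 1L
  suf <- 0L; while (suf < n && (n - suf) %in% kept) suf <- suf + 1L
  list(
    longer_units = units,
    shorter_units = units[kept],
    truth = list(excised_positions = excise, slip_class = as.integer(slip_class),
      conserved_prefix = pre, conserved_suffix = suf)
  )
}

#' Plant an alternative-splicing variant transcript
#'
#' Emits the transcript implied by a splice event on a gene model, together
#' with its ground truth.
#'
#' @param model A [gene_model()].
#' @param mode One of `"alt_acceptor"`, `"alt_donor_acceptor"`,
#'   `"exon_skipping"`.
#' @param params List: for `alt_acceptor`, `exon` and `acceptor_offset`; for
#'   `alt_donor_acceptor`, `exon` (donor side; acceptor side is `exon + 1`),
#'   `donor_offset`, `acceptor_offset`; for `exon_skipping`, `exon`.
#' @return List with `transcript` (DNA string) and `truth` (list: `mode`,
#'   `exon`, `exon2`, `donor_offset`, `acceptor_offset`).
#' @export
plant_splice_variant <- function(model, mode, params) {
  n_ex <- length(model$exon_starts)
  ex <- vapply(seq_len(n_ex), function(i) exon_seq(model, i), character(1))
  lens <- nchar(ex)
  e <- params$exon
  truth <- list(mode = mode, exon = as.integer(e), exon2 = NA_integer_,
    donor_offset = 0L, acceptor_offset = 0L)
  if (mode == "alt_acceptor") {
    off <- as.integer(params$acceptor_offset)
    if (off >= lens[e]) abort("acceptor offset >= exon length",
      class = "vntrfam_config_error")
    ex[e] <- substr(ex[e], off + 1L, lens[e])
    truth$acceptor_offset <- off
  } else if (mode == "alt_donor") {
    off <- as.integer(params$donor_offset)
    if (off >= lens[e]) abort("donor offset >= exon length",
      class = "vntrfam_config_error")
    ex[e] <- substr(ex[e], 1L, lens[e] - off)
    truth$donor_offset <- off
  } else if (mode == "alt_donor_acceptor") {
    doff <- as.integer(params$donor_offset)
    aoff <- as.integer(params$acceptor_offset)
    if (e + 1 > n_ex || doff >= lens[e] || aoff >= lens[e + 1]) {
      abort("donor/acceptor offsets incompatible with exon lengths",
        class = "vntrfam_config_error")
    }
    ex[e] <- substr(ex[e], 1L, lens[e] - doff)
    ex[e + 1] <- substr(ex[e + 1], aoff + 1L, lens[e + 1])
    truth$exon2 <- as.integer(e + 1)
    truth$donor_offset <- doff
    truth$acceptor_offset <- aoff
  } else if (mode == "exon_skipping") {
    ex <- ex[-e]
  } else {
    abort("unknown splice mode", class = "vntrfam_config_error")
  }
  list(transcript = paste(ex, collapse = ""), truth = truth)
}

# force a dinucleotide at 0-based CDS positions (pos, pos+1), then repair
# any in-frame stop this creates by editing a base outside the forced pair
force_dinucleotide <- function(cds, pos, dinuc) {
  chars <- strsplit(cds, "")[[1]]
  chars[pos + 1L] <- substr(dinuc, 1, 1)
  chars[pos + 2L] <- substr(dinuc, 2, 2)
  for (codon_start in unique(((c(pos, pos + 1L)) %/% 3L) * 3L)) {
    idx <- codon_start + 1:3
    if (max(idx) > length(chars)) next
    if (max(idx) == length(chars)) next # terminal stop codon is legitimate
    codon <- paste(chars[idx], collapse = "")
    if (codon %in% STOP_CODONS) {
      free <- setdiff(idx, c(pos + 1L, pos + 2L))
      for (i in free) {
        for (b in setdiff(BASES, chars[i])) {
          old <- chars[i]; chars[i] <- b
          if (!(paste(chars[idx], collapse = "") %in% STOP_CODONS)) break
          chars[i] <- old
        }
        if (!(paste(chars[idx], collapse = "") %in% STOP_CODONS)) break
      }
    }
  }
  paste(chars, collapse = "")
}

## --- the generator --------------------------------------------------------

#' Generate a synthetic gene family with ground truth
#'
#' Builds a founder gene, derives per-type founders by mutation plus motif
#' substitution, then derives members by further mutation, per-member repeat
#' arrays, optional planted slippage pairs and splice-variant transcripts.
#' The whole family is a deterministic function of the config (including its
#' seed).
#'
#' @param config A [family_config()].
#' @return A `synthetic_family` object: list with
#'   \describe{
#'     \item{members}{tibble: `id`, `type`, `copy_number`, `pattern`,
#'       `cdna`, `cds`, `region_start`, `units` (list), `model` (list of
#'       [gene_model()])}
#'     \item{transcripts}{tibble `id`, `gene_id`, `seq`: member cDNAs plus
#'       planted splice variants}
#'     \item{models}{tibble `id`, `model`}
#'     \item{genomic}{tibble `id`, `seq`}
#'     \item{truth}{list: `members` (id, motif, type, copy_number, pattern,
#'       region_start), `slippage` (tibble of planted pairs), `splice`
#'       (tibble of planted variants), `config`}
#'   }
#' @export
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  exl <- config$exon_lengths
  # CDS layout: prefix (exon1 + exon2 5' flank), repeat region, suffix
  prefix_len <- exl[1] + 14L
  suffix_len <- 10L + sum(exl[3:6])
  stopifnot(prefix_len %% 3 == 0, suffix_len %% 3 == 0)
  n_suffix_codons <- suffix_len %/% 3L
  # founder parts
  unit30 <- random_codons(10L, UNIT_CODONS)
  ins <- random_codons(1L, UNIT_CODONS)
  unit33 <- paste0(substr(unit30, 1, 15), ins, substr(unit30, 16, 30))
  prefix0 <- paste0("ATG", random_codons(prefix_len %/% 3L - 1L))
  # stop codon TAG: its AG doubles as the exonic acceptor context when a
  # planted donor/acceptor event removes the whole coding part of exon 6
  suffix_codons <- c(strsplit(random_codons(n_suffix_codons - 1L), "(?<=.{3})",
    perl = TRUE)[[1]], "TAG")
  # exon 5 occupies suffix nt [275, 383) (0-based); plant the Ca-site
  # tripeptide (EPN) at suffix codons 97-99 and the anchor context + motif
  # at codons 111-124 (1-based codon indices), all within exon 5's codons
  suffix_codons[97:99] <- strsplit(encode_protein("EPN"), "(?<=.{3})", perl = TRUE)[[1]]
  context_codons <- strsplit(encode_protein(MOTIF_CONTEXT), "(?<=.{3})", perl = TRUE)[[1]]
  suffix_codons[111:118] <- context_codons
  motif_codon_idx <- 119:124
  utr5_0 <- random_utr5(config$utr5_len)
  utr3_0 <- random_utr3(config$utr3_len)
  introns0 <- lapply(config$intron_lengths, function(l)
    paste0("GT", random_dna(l - 4L), "AG"))
  # protected 0-based CDS positions (relative to prefix/suffix starts)
  protect_prefix <- if (config$hostile) integer(0) else 0:2
  protect_suffix_codons <- if (config$hostile) integer(0) else
    c(97:99, 111:124, n_suffix_codons)
  protect_suffix <- sort(unique(as.vector(vapply(protect_suffix_codons,
    function(cd) (cd - 1L) * 3L + 0:2, integer(3)))))
  protect_utr3 <- if (config$hostile) integer(0) else
    (config$utr3_len - 26L):(config$utr3_len - 21L)

  mutate_suffix <- function(codons, rate, motif = NULL) {
    s <- mutate_cds(paste(codons, collapse = ""), rate, protected = protect_suffix)
    if (!is.null(motif)) {
      motif_seq <- encode_protein(motif)
      substr(s, (motif_codon_idx[1] - 1L) * 3L + 1L,
        motif_codon_idx[length(motif_codon_idx)] * 3L) <- motif_seq
    }
    s
  }
  mutate_utr5 <- function(u, rate) {
    for (try in 1:25) {
      cand <- mutate_plain(u, rate)
      if (!grepl("ATG", cand, fixed = TRUE)) return(cand)
    }
    u
  }
  mutate_intron <- function(intr, rate) {
    n <- nchar(intr)
    prot <- if (config$hostile) integer(0) else c(0L, 1L, n - 2L, n - 1L)
    mutate_plain(intr, rate, protected = prot)
  }

  # type founders
  types <- lapply(config$motifs, function(m) {
    u30 <- mutate_unit(unit30, config$type_divergence)
    # the 33-nt unit is the type's 30-nt unit with the founder insertion
    # codon, so mixed arrays stay alignable within a type
    u33 <- paste0(substr(u30, 1, 15), ins, substr(u30, 16, 30))
    list(
      motif = m,
      prefix = mutate_cds(prefix0, config$type_divergence, protected = protect_prefix),
      suffix = mutate_suffix(suffix_codons, config$type_divergence, motif = m),
      unit30 = u30,
      unit33 = u33,
      utr5 = mutate_utr5(utr5_0, config$type_divergence),
      utr3 = mutate_plain(utr3_0, config$type_divergence, protected = protect_utr3),
      introns = lapply(introns0, mutate_intron, rate = config$type_divergence)
    )
  })
  names(types) <- config$motifs


  build_member <- function(id, tf, units, force_dinucs = list()) {
    region <- paste(units, collapse = "")
    rate <- config$substitution_rate
    cds <- paste0(
      mutate_cds(tf$prefix, rate, protected = protect_prefix),
      region,
      {
        # suffix positions shift by the region; mutate in suffix-local frame
        s <- mutate_cds(tf$suffix, rate, protected = protect_suffix)
        s
      })
    for (fd in force_dinucs) cds <- force_dinucleotide(cds, fd$pos, fd$dinuc)
    utr5 <- mutate_utr5(tf$utr5, rate)
    utr3 <- mutate_plain(tf$utr3, rate, protected = protect_utr3)
    introns <- lapply(tf$introns, mutate_intron, rate = rate)
    cdna <- paste0(utr5, cds, utr3)
    # validate the planted ORF; redraw UTRs if a longer spurious ORF appears
    for (try in 1:25) {
      orf <- find_orf(cdna)
      if (!is.null(orf) && orf$start == nchar(utr5) && orf$length == nchar(cds)) break
      utr5 <- random_utr5(config$utr5_len)
      utr3 <- mutate_plain(tf$utr3, rate, protected = protect_utr3)
      cdna <- paste0(utr5, cds, utr3)
    }
    r <- nchar(region)
    # coding exon spans on the CDS (0-based half-open)
    bounds <- cumsum(c(0L, exl[1], 24L + r, exl[3], exl[4], exl[5], exl[6]))
    exon_cds <- vapply(1:6, function(i)
      substr(cds, bounds[i] + 1L, bounds[i + 1]), character(1))
    # genomic: UTRs live inside exons 1 and 6
    exon_full <- exon_cds
    exon_full[1] <- paste0(utr5, exon_cds[1])
    exon_full[6] <- paste0(exon_cds[6], utr3)
    pieces <- character(11)
    pieces[seq(1, 11, 2)] <- exon_full
    pieces[seq(2, 10, 2)] <- unlist(introns)
    genomic <- paste(pieces, collapse = "")
    exon_len_full <- nchar(exon_full)
    starts <- integer(6); ends <- integer(6)
    pos <- 0L
    for (i in 1:6) {
      starts[i] <- pos
      ends[i] <- pos + exon_len_full[i]
      pos <- ends[i] + if (i < 6) nchar(introns[[i]]) else 0L
    }
    model <- gene_model(id, genomic, starts, ends)
    list(id = id, cds = cds, cdna = cdna, units = units,
      region_start = prefix_len, model = model, motif = tf$motif)
  }

  member_rows <- list()
  add_member <- function(m, copy_number) {
    member_rows[[length(member_rows) + 1]] <<- tibble(
      id = m$id, type = m$motif, copy_number = copy_number,
      pattern = paste(nchar(m$units), collapse = "-"),
      cdna = m$cdna, cds = m$cds, region_start = m$region_start,
      units = list(m$units), model = list(m$model))
  }

  # ordinary members: types round-robin, copy numbers uniform over the range
  if (config$n_members > 0) {
    type_seq <- rep_len(config$motifs, config$n_members)
    for (i in seq_len(config$n_members)) {
      tf <- types[[type_seq[i]]]
      if (!is.null(config$fixed_patterns)) {
        lens <- config$fixed_patterns[[(i - 1L) %% length(config$fixed_patterns) + 1L]]
        cn <- length(lens)
      } else {
        cn <- resample(config$copy_range, 1)
        lens <- resample(config$unit_lengths, cn, replace = TRUE)
      }
      units <- vapply(lens, function(l)
        mutate_unit(if (l == 30) tf$unit30 else tf$unit33,
          config$substitution_rate), character(1))
      id <- sprintf("fam%03d_%s_%d", i, type_seq[i], cn)
      add_member(build_member(id, tf, units), cn)
    }
  }

  # planted slippage pairs: each pair gets its own type (cycling the motif
  # list) so pairs do not interfere with one another
  slip_truth <- list()
  pair_counter <- 0L
  for (cl in 1:5) {
    for (rep_i in seq_len(config$n_slippage_pairs[cl])) {
      pair_counter <- pair_counter + 1L
      tf <- types[[config$motifs[(pair_counter - 1L) %% length(config$motifs) + 1L]]]
      planted <- plant_slippage_pair(tf$unit30, tf$unit33, cl)
      mutate_units <- function(us) vapply(us, mutate_unit,
        character(1), rate = config$substitution_rate, USE.NAMES = FALSE)
      id_l <- sprintf("slip%d_%d_long", cl, rep_i)
      id_s <- sprintf("slip%d_%d_short", cl, rep_i)
      ml <- build_member(id_l, tf, mutate_units(planted$longer_units))
      ms <- build_member(id_s, tf, mutate_units(planted$shorter_units))
      add_member(ml, length(planted$longer_units))
      add_member(ms, length(planted$shorter_units))
      slip_truth[[length(slip_truth) + 1]] <- tibble(
        longer_id = id_l, shorter_id = id_s, type = tf$motif,
        slip_class = planted$truth$slip_class,
        conserved_prefix = planted$truth$conserved_prefix,
        conserved_suffix = planted$truth$conserved_suffix,
        excised_positions = paste(planted$truth$excised_positions, collapse = ","))
    }
  }

  members <- bind_rows(member_rows)

  # planted splice variants: hosted on dedicated members so the canonical
  # splice-context edits stay local
  splice_truth <- list()
  variant_rows <- list()
  sv_defaults <- list(
    alt_acceptor = list(exon = 5L, acceptor_offset = 11L),
    alt_donor_acceptor = list(exon = 5L, donor_offset = 79L, acceptor_offset = 58L),
    exon_skipping = list(exon = 5L))
  skip_exons <- c(5L, 3L) # alternate skipped exon for successive variants
  sv_counter <- 0L
  for (mode in names(config$n_splice_variants)) {
    for (rep_i in seq_len(config$n_splice_variants[[mode]])) {
      sv_counter <- sv_counter + 1L
      params <- sv_defaults[[mode]]
      if (mode == "exon_skipping") {
        params$exon <- skip_exons[(rep_i - 1L) %% length(skip_exons) + 1L]
      }
      tf <- types[[config$motifs[(sv_counter - 1L) %% length(config$motifs) + 1L]]]
      # host member with 7 repeats (the backbone the published events sit on)
      cn <- min(7L, max(config$copy_range))
      lens <- resample(config$unit_lengths, cn, replace = TRUE)
      units <- vapply(lens, function(l)
        mutate_unit(if (l == 30) tf$unit30 else tf$unit33,
          config$substitution_rate), character(1))
      host_id <- sprintf("sv%d_%s_host", sv_counter, mode)
      force_dinucs <- list()
      if (config$canonical_context && mode != "exon_skipping") {
        r <- sum(lens)
        # 0-based CDS offsets of coding exon 5 and 6 starts
        e5_start <- exl[1] + 24L + r + exl[3] + exl[4]
        e6_start <- e5_start + exl[5]
        if (mode == "alt_acceptor") {
          force_dinucs <- list(list(pos = e5_start + params$acceptor_offset - 2L,
            dinuc = "AG"))
        } else {
          force_dinucs <- list(
            list(pos = e5_start + exl[5] - params$donor_offset, dinuc = "GT"),
            list(pos = e6_start + params$acceptor_offset - 2L, dinuc = "AG"))
        }
      }
      host <- build_member(host_id, tf, units, force_dinucs = force_dinucs)
      add_member(host, cn)
      members <- bind_rows(member_rows)
      # exon indices on the full model equal coding exon indices (UTRs are
      # inside exons 1 and 6, which the planted events never touch)
      planted <- plant_splice_variant(host$model, mode, params)
      var_id <- sprintf("sv%d_%s_t", sv_counter, mode)
      variant_rows[[length(variant_rows) + 1]] <- tibble(
        id = var_id, gene_id = host_id, seq = planted$transcript)
      splice_truth[[length(splice_truth) + 1]] <- bind_cols(
        tibble(transcript_id = var_id, gene_id = host_id),
        as_tibble(planted$truth))
    }
  }
  members <- bind_rows(member_rows)

  transcripts <- bind_rows(
    tibble(id = members$id, gene_id = members$id, seq = members$cdna),
    bind_rows(variant_rows))
  empty_slip <- tibble(longer_id = character(), shorter_id = character(),
    type = character(), slip_class = integer(), conserved_prefix = integer(),
    conserved_suffix = integer(), excised_positions = character())
  empty_splice <- tibble(transcript_id = character(), gene_id = character(),
    mode = character(), exon = integer(), exon2 = integer(),
    donor_offset = integer(), acceptor_offset = integer())
  structure(list(
    members = members,
    transcripts = transcripts,
    models = tibble(id = members$id, model = members$model),
    genomic = tibble(id = members$id,
      seq = vapply(members$model, function(m) m$genomic, character(1))),
    truth = list(
      members = transmute(members, id = .data$id, motif = .data$type,
        type = .data$type, copy_number = .data$copy_number,
        pattern = .data$pattern, region_start = .data$region_start),
      slippage = if (length(slip_truth)) bind_rows(slip_truth) else empty_slip,
      splice = if (length(splice_truth)) bind_rows(splice_truth) else empty_splice,
      config = config)
  ), class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "<synthetic_family> %d members, %d types, %d transcripts (%d splice variants), %d planted slippage pairs\n",
    nrow(x$members), length(unique(x$members$type)), nrow(x$transcripts),
    nrow(x$truth$splice), nrow(x$truth$slippage)))
  invisible(x)
}

#' Write a synthetic family to disk
#'
#' Emits `transcripts.fasta`, `genomic.fasta`, `models.gff3` and
#' `truth.json` under `dir`.
#'
#' @param fam A `synthetic_family`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_family <- function(fam, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(select(fam$transcripts, "id", "seq"), file.path(dir, "transcripts.fasta"))
  write_fasta(fam$genomic, file.path(dir, "genomic.fasta"))
  write_gene_models(fam$models, file.path(dir, "models.gff3"))
  truth <- fam$truth
  truth$config <- unclass(truth$config)
  truth$transcript_gene_map <- fam$transcripts[, c("id", "gene_id")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare pipeline results against generator ground truth
#'
#' @param truth The `truth` element of a `synthetic_family`.
#' @param results Named list of pipeline outputs: `decomposed` (from
#'   [decompose_repeats()]), `types` (from [assign_types()]), `slippage`
#'   (from [scan_slippage()]), `splice` (from [classify_splicing()]); any
#'   subset may be present.
#' @return Tibble with columns `stage`, `metric`, `recovered`, `total`,
#'   `fraction`.
#' @export
truth_compare <- function(truth, results) {
  rows <- list()
  push <- function(stage, metric, recovered, total) {
    rows[[length(rows) + 1]] <<- tibble(stage = stage, metric = metric,
      recovered = recovered, total = total,
      fraction = if (total > 0) recovered / total else NA_real_)
  }
  tm <- truth$members
  if (!is.null(results$decomposed)) {
    d <- results$decomposed
    if (!all(tm$id %in% d$id)) {
      abort("decomposed results missing member ids", class = "vntrfam_compare_error")
    }
    d <- d[match(tm$id, d$id), ]
    push("repeat_decomposition", "copy_number",
      sum(d$copy_number == tm$copy_number), nrow(tm))
    push("repeat_decomposition", "pattern",
      sum(!is.na(d$pattern) & d$pattern == tm$pattern), nrow(tm))
  }
  if (!is.null(results$types)) {
    ty <- results$types[match(tm$id, results$types$id), ]
    push("typing", "motif", sum(!is.na(ty$motif) & ty$motif == tm$motif), nrow(tm))
  }
  if (!is.null(results$slippage) && nrow(truth$slippage) > 0) {
    ts <- truth$slippage
    found <- 0L
    for (k in seq_len(nrow(ts))) {
      hit <- results$slippage |>
        filter(.data$longer_id == ts$longer_id[k],
          .data$shorter_id == ts$shorter_id[k],
          .data$slip_class == ts$slip_class[k])
      if (nrow(hit) > 0) found <- found + 1L
    }
    push("slippage", "class", found, nrow(ts))
  }
  if (!is.null(results$splice) && nrow(truth$splice) > 0) {
    tsp <- truth$splice
    found <- 0L
    for (k in seq_len(nrow(tsp))) {
      hit <- results$splice |>
        filter(.data$transcript_id == tsp$transcript_id[k],
          .data$mode == tsp$mode[k],
          .data$exon == tsp$exon[k],
          .data$donor_offset == tsp$donor_offset[k],
          .data$acceptor_offset == tsp$acceptor_offset[k])
      if (nrow(hit) > 0) found <- found + 1L
    }
    push("splicing", "mode_and_offsets", found, nrow(tsp))
  }
  bind_rows(rows)
}
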