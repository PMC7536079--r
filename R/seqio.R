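#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

check_dna <- function(seq, id = "<sequence>") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), DNA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf(
      "sequence '%s' contains characters outside {A,C,G,T,N}: %s",
      id, paste(bad, collapse = ", ")
    ), class = "vntrfam_alphabet_error")
  }
  if (nchar(seq) < 1) {
    abort(sprintf("sequence '%s' is empty", id), class = "vntrfam_alphabet_error")
  }
  invisible(seq)
}

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' \{A,C,G,T,N\}; any other character is an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq` (uppercase DNA string). An empty file yields a
#'   zero-row tibble with a warning.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warn(sprintf("FASTA file '%s' contains no records", path))
    return(tibble(id = character(), seq = character()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) check_dna(seqs[[i]], ids[[i]])
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' Records are normalized: uppercase, wrapped at 60 columns, so
#' `read_fasta(write_fasta(x, f))` round-trips exactly.
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(toupper(seqs$seq))
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model is an exon chain on a plus-strand genomic sequence.
#' Coordinates are 0-based half-open internally; [read_gene_models()] and
#' [write_gene_models()] convert to/from the 1-based inclusive GFF3
#' convention.
#'
#' @param id Gene identifier.
#' @param genomic Genomic DNA string.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   intervals, strictly increasing and non-overlapping. Every intron (gap
#'   between consecutive exons) must be at least 4 nt long.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, genomic, exon_starts, exon_ends) {
  check_dna(genomic, id)
  n <- length(exon_starts)
  stopifnot(length(exon_ends) == n, n >= 1)
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_ends <= exon_starts)) {
    abort(sprintf("gene model '%s': empty or inverted exon", id),
      class = "vntrfam_coordinate_error")
  }
  if (any(exon_starts < 0) || any(exon_ends > nchar(genomic))) {
    abort(sprintf("gene model '%s': exon outside genomic bounds", id),
      class = "vntrfam_coordinate_error")
  }
  if (n > 1) {
    if (any(exon_starts[-1] < exon_ends[-n])) {
      abort(sprintf("gene model '%s': exons overlap or are unordered", id),
        class = "vntrfam_coordinate_error")
    }
    intron_len <- exon_starts[-1] - exon_ends[-n]
    if (any(intron_len < 4)) {
      abort(sprintf("gene model '%s': intron shorter than 4 nt", id),
        class = "vntrfam_coordinate_error")
    }
  }
  structure(
    list(id = id, genomic = genomic,
         exon_starts = exon_starts, exon_ends = exon_ends),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d nt genomic, %d exons (%s)\n",
    x$id, nchar(x$genomic), length(x$exon_starts),
    paste(x$exon_ends - x$exon_starts, collapse = ", ")))
  invisible(x)
}

exon_lengths <- function(model) model$exon_ends - model$exon_starts

intron_lengths <- function(model) {
  n <- length(model$exon_starts)
  if (n < 2) return(integer(0))
  model$exon_starts[-1] - model$exon_ends[-n]
}

exon_seq <- function(model, i) {
  substr(model$genomic, model$exon_starts[i] + 1L, model$exon_ends[i])
}

intron_seq <- function(model, i) {
  substr(model$genomic, model$exon_ends[i] + 1L, model$exon_starts[i + 1L])
}

#' Spliced transcript of a gene model
#'
#' Concatenates the exon sequences 5' to 3' (the canonical splice product).
#'
#' @param model A [gene_model()].
#' @return DNA string.
#' @export
spliced_transcript <- function(model) {
  paste(vapply(seq_along(model$exon_starts), function(i) exon_seq(model, i),
    character(1)), collapse = "")
}

#' Read gene models from GFF3
#'
#' Parses exon features (1-based inclusive, per the GFF3 standard) grouped by
#' their `Parent` (or `ID`/`gene_id`) attribute and attaches them to genomic
#' sequences. Only plus-strand models are supported; minus-strand features are
#' rejected.
#'
#' @param path GFF3 file path.
#' @param genomic Tibble with columns `id`, `seq` giving the genomic sequence
#'   for each seqid used in the GFF3.
#' @return A tibble with columns `id` and `model` (list-column of
#'   [gene_model()] objects).
#' @export
read_gene_models <- function(path, genomic) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) abort("no exon features in GFF3", class = "vntrfam_coordinate_error")
  if (any(as.character(BiocGenerics::strand(gr)) == "-")) {
    abort("minus-strand gene models are not supported; reverse-complement on ingest",
      class = "vntrfam_coordinate_error")
  }
  parent <- S4Vectors::mcols(gr)$Parent
  gene_ids <- if (!is.null(parent) && all(lengths(parent) > 0)) {
    vapply(parent, function(p) as.character(p)[1], character(1))
  } else {
    as.character(GenomicRanges::seqnames(gr))
  }
  seqid <- as.character(GenomicRanges::seqnames(gr))
  starts <- BiocGenerics::start(gr) # 1-based inclusive
  ends <- BiocGenerics::end(gr)
  out <- lapply(split(seq_along(gr), gene_ids), function(idx) {
    idx <- idx[order(starts[idx])]
    sid <- unique(seqid[idx])
    stopifnot(length(sid) == 1)
    gseq <- genomic$seq[match(sid, genomic$id)]
    if (is.na(gseq)) {
      abort(sprintf("GFF3 seqid '%s' not found among genomic sequences", sid),
        class = "vntrfam_coordinate_error")
    }
    if (any(ends[idx] > nchar(gseq))) {
      abort(sprintf("exon beyond end of sequence '%s'", sid),
        class = "vntrfam_coordinate_error")
    }
    gene_model(gene_ids[idx[1]], gseq,
      exon_starts = starts[idx] - 1L, exon_ends = ends[idx])
  })
  tibble(id = names(out), model = unname(out))
}

#' Write gene models to GFF3
#'
#' Emits one `gene` line and one `exon` line per exon, converting internal
#' 0-based half-open coordinates to 1-based inclusive.
#'
#' @param models Tibble with columns `id`, `model` (as from
#'   [read_gene_models()]), or a list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  if (is.data.frame(models)) models <- models$model
  grl <- lapply(models, function(m) {
    n <- length(m$exon_starts)
    gene <- GenomicRanges::GRanges(m$id,
      IRanges::IRanges(min(m$exon_starts) + 1L, max(m$exon_ends)),
      strand = "+", type = "gene", ID = m$id)
    ex <- GenomicRanges::GRanges(rep(m$id, n),
      IRanges::IRanges(m$exon_starts + 1L, m$exon_ends),
      strand = "+", type = "exon",
      ID = sprintf("%s.exon%d", m$id, seq_len(n)))
    S4Vectors::mcols(ex)$Parent <- as.character(rep(m$id, n))
    S4Vectors::mcols(gene)$Parent <- NA_character_
    suppressWarnings(c(gene, ex))
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## --- ORF arithmetic -------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame
#'
#' Scans all ATG-initiated frames and returns the longest one terminated by an
#' in-frame stop codon; the stop is included in the span. Ties are broken in
#' favour of the 5'-most start.
#'
#' @param cdna DNA string (length >= 6).
#' @return A list with `start` and `end` (0-based half-open span on `cdna`)
#'   and `length`, or `NULL` if no ORF exists.
#' @export
find_orf <- function(cdna) {
  cdna <- toupper(cdna)
  n <- nchar(cdna)
  if (n < 6) return(NULL)
  best <- NULL
  atg <- gregexpr("ATG", cdna, fixed = TRUE)[[1]]
  if (atg[1] == -1) return(NULL)
  for (s in as.integer(atg)) { # s is 1-based position of A
    # walk codons from s until a stop
    i <- s
    repeat {
      if (i + 2 > n) break
      codon <- substr(cdna, i, i + 2)
      if (codon %in% STOP_CODONS) {
        len <- i + 3 - s
        if (is.null(best) || len > best$length) {
          best <- list(start = s - 1L, end = s - 1L + len, length = len)
        }
        break
      }
      i <- i + 3
    }
  }
  best
}

CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  # Standard genetic code, TCAG order (third base fastest)
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

#' Translate an ORF span to protein
#'
#' Standard genetic code; the terminal stop codon is excluded from the output.
#' Any codon containing `N` translates to `X`. An internal in-frame stop
#' before the final codon is a frame error.
#'
#' @param cdna DNA string.
#' @param orf_span List with `start`,`end` (0-based half-open), e.g. from
#'   [find_orf()]. Span length must be divisible by 3.
#' @return Amino-acid string.
#' @export
translate_orf <- function(cdna, orf_span) {
  cdna <- toupper(cdna)
  s <- orf_span$start; e <- orf_span$end
  len <- e - s
  if (len %% 3 != 0) abort("ORF span not divisible by 3", class = "vntrfam_frame_error")
  codons <- substring(cdna, seq(s + 1, e - 2, by = 3), seq(s + 3, e, by = 3))
  aa <- ifelse(grepl("N", codons), "X", CODON_TABLE[codons])
  n_codons <- length(codons)
  if (any(aa[-n_codons] == "*", na.rm = TRUE)) {
    abort(sprintf("internal stop codon at codon %d of %d",
      which(aa == "*")[1], n_codons), class = "vntrfam_frame_error")
  }
  if (aa[n_codons] == "*") aa <- aa[-n_codons]
  paste(aa, collapse = "")
}

#' Locate the polyadenylation signal
#'
#' Reports the 0-based position of the 3'-most `AATAAA` hexamer within the
#' final `window` nucleotides of the transcript.
#'
#' @param cdna DNA string.
#' @param window Search window at the 3' end, in nt (default 50).
#' @return Integer position (0-based), or `NA_integer_` if absent.
#' @export
find_polya_signal <- function(cdna, window = 50) {
  cdna <- toupper(cdna)
  n <- nchar(cdna)
  from <- max(1L, n - as.integer(window) + 1L)
  tail_seq <- substr(cdna, from, n)
  hits <- gregexpr("(?=AATAAA)", tail_seq, perl = TRUE)[[1]]
  if (hits[1] == -1) return(NA_integer_)
  as.integer(from - 1L + hits[length(hits)] - 1L)
}

#' Scan a protein for the calcium-site sugar-specificity motif
#'
#' C-type lectin carbohydrate-recognition domains carry either an EPN
#' (mannose-type) or QPD (galactose-type) tripeptide at Ca2+ site 2. All
#' exact occurrences of either motif are reported.
#'
#' @param protein Amino-acid string.
#' @return Tibble with columns `motif` (`"EPN"` or `"QPD"`) and `start`
#'   (1-based residue position).
#' @export
scan_ca_site_motif <- function(protein) {
  protein <- toupper(protein)
  out <- lapply(c("EPN", "QPD"), function(m) {
    hits <- gregexpr(paste0("(?=", m, ")"), protein, perl = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    tibble(motif = m, start = as.integer(hits))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(tibble(motif = character(), start = integer()))
  arrange(out, .data$start)
}

#' Annotate a transcript: UTRs, ORF, protein, polyA signal
#'
#' Runs [find_orf()], [translate_orf()] and [find_polya_signal()] on each
#' cDNA and checks the component arithmetic
#' (`utr5_len + orf_len + utr3_len == cdna length`,
#' `protein length == orf_len/3 - 1`).
#'
#' @param seqs Tibble with columns `id`, `seq` (cDNA).
#' @return Input tibble with added columns `cdna_len`, `utr5_len`, `orf_start`,
#'   `orf_len`, `utr3_len`, `protein`, `protein_len`, `polya_pos`.
#' @export
annotate_transcripts <- function(seqs) {
  rows <- purrr::map2(seqs$id, seqs$seq, function(id, s) {
    orf <- find_orf(s)
    n <- nchar(s)
    if (is.null(orf)) {
      return(tibble(cdna_len = n, utr5_len = NA_integer_, orf_start = NA_integer_,
        orf_len = NA_integer_, utr3_len = NA_integer_,
        protein = NA_character_, protein_len = NA_integer_,
        polya_pos = find_polya_signal(s)))
    }
    prot <- translate_orf(s, orf)
    tibble(
      cdna_len = n,
      utr5_len = orf$start,
      orf_start = orf$start,
      orf_len = orf$length,
      utr3_len = n - orf$end,
      protein = prot,
      protein_len = nchar(prot),
      polya_pos = find_polya_signal(s)
    )
  })
  bind_cols(seqs, bind_rows(rows))
}
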