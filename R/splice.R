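## Alternative-splicing classification against a gene model. Observed
## transcripts are exact concatenations of exon substrings (the data these
## analyses come from are Sanger-sequenced clones, effectively
## mismatch-free); mapping is greedy exact matching, and per-exon usage
## differences are classified into three modes: alternative acceptor
## (5' truncation of an exon), combined alternative donor + acceptor
## (3' truncation of exon i with 5' truncation of exon i+1), and exon
## skipping.

#' Map a transcript onto a gene model's exon chain
#'
#' Exact left-to-right matching of the transcript against the exon
#' sequences: each exon contributes one contiguous substring (possibly
#' empty, i.e. the exon is skipped), in exon order, and the contributions
#' must concatenate to the transcript exactly. The mapper searches
#' depth-first with preference for the longest contribution at the 5'-most
#' exon offset (so the canonical full-exon mapping is found first),
#' backtracking over coincidental matches; failed (exon, position) states
#' are memoized.
#'
#' @param model A [gene_model()].
#' @param transcript DNA string.
#' @param min_anchor Minimum matched length for an exon to be considered
#'   used (default 8 nt), unless the match is capped by the exon or
#'   transcript end. Shorter coincidental matches would otherwise make a
#'   skipped exon look partially used.
#' @param max_backoff How far the mapper may shorten a maximal match while
#'   backtracking over junction ambiguity (default 15 nt).
#' @return An `exon_chain`: tibble with one row per used exon — `exon`
#'   (1-based index in the model), `start_offset` (nt of the exon's 5' end
#'   not used), `end_offset` (nt of its 3' end not used), `used_len` — plus
#'   attributes `skipped` (integer vector) and `n_exons`.
#' @export
map_transcript <- function(model, transcript, min_anchor = 8L,
                           max_backoff = 15L) {
  transcript <- toupper(transcript)
  n_ex <- length(model$exon_starts)
  exons <- vapply(seq_len(n_ex), function(i) exon_seq(model, i), character(1))
  nt <- nchar(transcript)
  tchars <- strsplit(transcript, "")[[1]]
  failed <- new.env(hash = TRUE)
  deepest_fail <- 0L
  # returns list of (exon, off, len) or NULL
  search <- function(e, t) {
    if (t > nt) return(list()) # transcript consumed; trailing exons skipped
    if (e > n_ex) { deepest_fail <<- max(deepest_fail, t); return(NULL) }
    key <- paste0(e, ":", t)
    if (!is.null(failed[[key]])) return(NULL)
    ex <- exons[e]; le <- nchar(ex)
    echars <- strsplit(ex, "")[[1]]
    # maximal run length at each offset; require min_anchor unless capped
    cand <- list()
    for (off in 0:(le - 1L)) {
      max_l <- min(le - off, nt - t + 1L)
      if (max_l < 1L) next
      cmp <- echars[(off + 1L):(off + max_l)] == tchars[t:(t + max_l - 1L)]
      run <- if (all(cmp)) max_l else which(!cmp)[1] - 1L
      # the anchor requirement is waived only when the match consumes the
      # remainder of the transcript (a final partial window), never when it
      # is merely capped by the exon end — short exon-terminal coincidences
      # would otherwise masquerade as used exons
      if (run >= min_anchor || run == nt - t + 1L) {
        cand[[length(cand) + 1]] <- c(off, run)
      }
    }
    if (length(cand) > 0) {
      cand_mat <- do.call(rbind, cand)
      cand_mat <- cand_mat[order(-cand_mat[, 2], cand_mat[, 1]), , drop = FALSE]
      for (k in seq_len(nrow(cand_mat))) {
        off <- cand_mat[k, 1]; run <- cand_mat[k, 2]
        for (l in seq(run, max(1L, run - max_backoff))) {
          rest <- search(e + 1L, t + l)
          if (!is.null(rest)) {
            return(c(list(c(e, off, l)), rest))
          }
        }
      }
    }
    rest <- search(e + 1L, t) # skip this exon
    if (!is.null(rest)) return(rest)
    failed[[key]] <- TRUE
    deepest_fail <<- max(deepest_fail, t)
    NULL
  }
  sol <- search(1L, 1L)
  if (is.null(sol)) {
    abort(sprintf(
      "transcript does not map onto model '%s'; first failing transcript position %d",
      model$id, deepest_fail), class = "vntrfam_mapping_error")
  }
  used <- vapply(sol, identity, numeric(3))
  if (length(sol) == 0) {
    chain <- tibble(exon = integer(), start_offset = integer(),
      end_offset = integer(), used_len = integer())
  } else {
    chain <- tibble(
      exon = as.integer(used[1, ]),
      start_offset = as.integer(used[2, ]),
      end_offset = as.integer(nchar(exons[used[1, ]]) - used[2, ] - used[3, ]),
      used_len = as.integer(used[3, ]))
  }
  skipped <- setdiff(seq_len(n_ex), chain$exon)
  structure(chain, skipped = skipped, n_exons = n_ex,
    class = c("exon_chain", class(chain)))
}

#' Classify splicing differences between two exon chains
#'
#' Per-exon comparison of an observed chain against the reference (canonical)
#' chain over the same model:
#' \itemize{
#'   \item extra 5' truncation of an exon's used region is an
#'     `alt_acceptor` event with `acceptor_offset` = truncated length;
#'   \item a 3' truncation of exon i combined with a 5' truncation of exon
#'     i+1 is reported as one `alt_donor_acceptor` event with
#'     `(donor_offset, acceptor_offset)`;
#'   \item an exon absent from the observed chain is `exon_skipping`.
#' }
#' Events are reported 5' to 3'.
#'
#' @param ref_chain,obs_chain `exon_chain`s from [map_transcript()] over the
#'   same model.
#' @param split_donor_acceptor If `TRUE`, report a combined donor+acceptor
#'   truncation as two separate events (default `FALSE`: one event).
#' @return Tibble with columns `mode`, `exon` (index; for combined events the
#'   donor-side exon), `exon2` (acceptor-side exon of combined events, else
#'   `NA`), `donor_offset`, `acceptor_offset`.
#' @export
classify_splice_events <- function(ref_chain, obs_chain,
                                   split_donor_acceptor = FALSE) {
  n_exons <- attr(ref_chain, "n_exons")
  if (!identical(n_exons, attr(obs_chain, "n_exons"))) {
    abort("chains are not over the same gene model", class = "vntrfam_chain_error")
  }
  ref <- as_tibble(ref_chain); obs <- as_tibble(obs_chain)
  events <- list()
  add <- function(...) events[[length(events) + 1]] <<- tibble(...)
  skipped_obs <- attr(obs_chain, "skipped")
  skipped_ref <- attr(ref_chain, "skipped")
  # per-exon truncation deltas (obs relative to ref)
  d5 <- d3 <- stats::setNames(rep(0L, n_exons), seq_len(n_exons))
  for (e in seq_len(n_exons)) {
    r <- ref[ref$exon == e, ]; o <- obs[obs$exon == e, ]
    if (nrow(o) == 0) {
      if (nrow(r) > 0 && !(e %in% skipped_ref)) {
        add(mode = "exon_skipping", exon = e, exon2 = NA_integer_,
          donor_offset = 0L, acceptor_offset = 0L)
      }
      next
    }
    if (nrow(r) == 0) {
      abort(sprintf("exon %d used by observed but not reference chain", e),
        class = "vntrfam_chain_error")
    }
    d5[e] <- o$start_offset - r$start_offset
    d3[e] <- o$end_offset - r$end_offset
    if (d5[e] < 0 || d3[e] < 0) {
      abort(sprintf("observed chain extends exon %d beyond the reference", e),
        class = "vntrfam_chain_error")
    }
  }
  # pair 3' truncations with the next used exon's 5' truncation
  used <- sort(intersect(ref$exon, obs$exon))
  paired5 <- integer(0)
  for (k in seq_along(used)) {
    e <- used[k]
    if (d3[e] > 0) {
      nxt <- if (k < length(used)) used[k + 1] else NA_integer_
      if (!is.na(nxt) && d5[nxt] > 0 && !split_donor_acceptor) {
        add(mode = "alt_donor_acceptor", exon = e, exon2 = nxt,
          donor_offset = unname(d3[e]), acceptor_offset = unname(d5[nxt]))
        paired5 <- c(paired5, nxt)
      } else {
        add(mode = "alt_donor", exon = e, exon2 = NA_integer_,
          donor_offset = unname(d3[e]), acceptor_offset = 0L)
      }
    }
  }
  for (e in used) {
    if (d5[e] > 0 && !(e %in% paired5)) {
      add(mode = "alt_acceptor", exon = e, exon2 = NA_integer_,
        donor_offset = 0L, acceptor_offset = unname(d5[e]))
    }
  }
  if (length(events) == 0) {
    return(tibble(mode = character(), exon = integer(), exon2 = integer(),
      donor_offset = integer(), acceptor_offset = integer()))
  }
  bind_rows(events) |> arrange(.data$exon, .data$mode)
}

#' Validate canonical GT..AG splice sites of a gene model
#'
#' @param model A [gene_model()].
#' @return Tibble with one row per intron: `intron`, `donor` (first 2 nt),
#'   `acceptor` (last 2 nt), `donor_ok` (`== "GT"`), `acceptor_ok`
#'   (`== "AG"`).
#' @export
validate_splice_sites <- function(model) {
  n_int <- length(model$exon_starts) - 1L
  if (n_int < 1) {
    return(tibble(intron = integer(), donor = character(),
      acceptor = character(), donor_ok = logical(), acceptor_ok = logical()))
  }
  rows <- lapply(seq_len(n_int), function(i) {
    intr <- intron_seq(model, i)
    donor <- substr(intr, 1, 2)
    acceptor <- substr(intr, nchar(intr) - 1, nchar(intr))
    tibble(intron = i, donor = donor, acceptor = acceptor,
      donor_ok = donor == "GT", acceptor_ok = acceptor == "AG")
  })
  bind_rows(rows)
}

#' Check GT/AG context at the shifted splice sites of an event
#'
#' For an alternative acceptor, the effective 3' splice junction moves
#' `acceptor_offset` nt into the exon; the 2 nt immediately upstream of the
#' junction on the genomic sequence should read `AG`. For an alternative
#' donor, the junction moves `donor_offset` nt back from the exon's 3' end;
#' the 2 nt immediately downstream should read `GT`.
#'
#' @param model A [gene_model()].
#' @param event One row of the [classify_splice_events()] tibble (as a list
#'   or one-row data frame), with mode `alt_acceptor` or
#'   `alt_donor_acceptor`.
#' @return Tibble with `donor_ok`, `acceptor_ok` (`NA` for a side the event
#'   does not shift).
#' @export
shifted_site_validation <- function(model, event) {
  if (is.data.frame(event)) event <- as.list(event[1, ])
  if (!event$mode %in% c("alt_acceptor", "alt_donor_acceptor", "alt_donor")) {
    abort("shifted-site validation applies to acceptor/donor shift events only",
      class = "vntrfam_event_error")
  }
  g <- model$genomic
  donor_ok <- NA
  acceptor_ok <- NA
  if (event$mode %in% c("alt_donor_acceptor", "alt_donor") &&
      event$donor_offset > 0) {
    e <- event$exon
    junction <- model$exon_ends[e] - event$donor_offset # 0-based, first excluded base
    donor_ok <- substr(g, junction + 1L, junction + 2L) == "GT"
  }
  if (event$mode %in% c("alt_acceptor", "alt_donor_acceptor") &&
      event$acceptor_offset > 0) {
    e <- if (event$mode == "alt_donor_acceptor") event$exon2 else event$exon
    junction <- model$exon_starts[e] + event$acceptor_offset # first included base
    acceptor_ok <- substr(g, junction - 1L, junction) == "AG"
  }
  tibble(donor_ok = donor_ok, acceptor_ok = acceptor_ok)
}

# A donor-side junction is ambiguous when the retained exon-i sequence ends
# with the same bases the exon-(i+1) acceptor side begins with: mappings
# (donor_offset + k, acceptor_offset - k) all reproduce the transcript.
# Realign to the offset pair whose shifted junctions carry GT/AG context,
# the same criterion used to validate real splice sites.
realign_donor_event <- function(model, ev, transcript, max_shift = 12L) {
  if (nrow(ev) != 1 || !ev$mode[1] %in% c("alt_donor_acceptor", "alt_donor")) {
    return(ev)
  }
  shifts <- order(abs(seq(-max_shift, max_shift)))
  ks <- seq(-max_shift, max_shift)[shifts] # 0, -1, 1, -2, 2, ...
  for (k in ks) {
    nd <- ev$donor_offset[1] + k
    na <- ev$acceptor_offset[1] - k
    if (nd < 1L || (ev$mode[1] == "alt_donor_acceptor" && na < 1L)) next
    cand <- ev
    cand$donor_offset[1] <- nd
    cand$acceptor_offset[1] <- if (ev$mode[1] == "alt_donor_acceptor") na else 0L
    params <- list(exon = cand$exon[1], donor_offset = nd, acceptor_offset = na)
    tt <- tryCatch(
      plant_splice_variant(model, cand$mode[1], params)$transcript,
      error = function(e) NULL)
    if (is.null(tt) || !identical(tt, toupper(transcript))) next
    flags <- shifted_site_validation(model, cand[1, ])
    if (isTRUE(flags$donor_ok) &&
        (cand$mode[1] == "alt_donor" || isTRUE(flags$acceptor_ok))) {
      return(cand)
    }
  }
  ev
}

#' Classify splicing of many transcripts against their gene models
#'
#' Tidy wrapper: maps each transcript onto its gene model, compares against
#' the canonical splice product, and classifies all events, with shifted-site
#' GT/AG flags.
#'
#' @param models Tibble with columns `id`, `model` (from
#'   [read_gene_models()]).
#' @param transcripts Tibble with columns `id`, `seq`, and `gene_id` linking
#'   each transcript to a model (defaults to `id` when absent).
#' @return Tibble: `transcript_id`, `gene_id`, `mode`, `exon`, `exon2`,
#'   `donor_offset`, `acceptor_offset`, `shifted_donor_ok`,
#'   `shifted_acceptor_ok`.
#' @export
classify_splicing <- function(models, transcripts) {
  if (!"gene_id" %in% names(transcripts)) transcripts$gene_id <- transcripts$id
  missing_ids <- setdiff(transcripts$gene_id, models$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("no gene model for transcript gene_id(s): %s",
      paste(missing_ids, collapse = ", ")), class = "vntrfam_id_error")
  }
  out <- list()
  for (k in seq_len(nrow(transcripts))) {
    m <- models$model[[match(transcripts$gene_id[k], models$id)]]
    ref <- map_transcript(m, spliced_transcript(m))
    obs <- map_transcript(m, transcripts$seq[k])
    ev <- classify_splice_events(ref, obs)
    if (nrow(ev) == 0) next
    ev <- realign_donor_event(m, ev, transcripts$seq[k])
    flags <- lapply(seq_len(nrow(ev)), function(r) {
      if (ev$mode[r] == "exon_skipping") {
        tibble(donor_ok = NA, acceptor_ok = NA)
      } else {
        shifted_site_validation(m, ev[r, ])
      }
    })
    flags <- bind_rows(flags)
    out[[length(out) + 1]] <- bind_cols(
      tibble(transcript_id = transcripts$id[k], gene_id = transcripts$gene_id[k]),
      ev,
      tibble(shifted_donor_ok = flags$donor_ok,
        shifted_acceptor_ok = flags$acceptor_ok))
  }
  if (length(out) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
      mode = character(), exon = integer(), exon2 = integer(),
      donor_offset = integer(), acceptor_offset = integer(),
      shifted_donor_ok = logical(), shifted_acceptor_ok = logical()))
  }
  bind_rows(out)
}
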