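## Slipped-strand mispairing (replication slippage) inference. Copy-number
## differences between family members are modelled as excisions of whole
## units from the longer array with conservation of flanking units. Events
## fall into five classes distinguished by how many 5'/3' flanking units are
## conserved and the length (30 vs 33 nt) of the excised units.

#' Do two repeat units match?
#'
#' Units match iff they have equal length and ungapped nucleotide identity
#' at least `min_identity`. `N` never matches.
#'
#' @param u,v Unit sequences.
#' @param min_identity Identity threshold (default 0.9).
#' @return Logical.
#' @export
unit_match <- function(u, v, min_identity = 0.9) {
  if (nchar(u) != nchar(v)) return(FALSE)
  a <- strsplit(toupper(u), "")[[1]]
  b <- strsplit(toupper(v), "")[[1]]
  mean(a == b & a != "N") >= min_identity
}

#' Infer a unit-excision event between two repeat arrays
#'
#' Finds the order-preserving matching of all shorter-array units into the
#' longer array (deletions allowed only in the longer) that maximizes the
#' number of matched units; among maxima, a single contiguous excised block
#' is preferred, then the 5'-most block. Returns `NULL` (with a warning
#' where noted) if the copy numbers do not differ or some shorter unit has
#' no match.
#'
#' @param longer,shorter `repeat_array` objects with
#'   `length(longer$units) > length(shorter$units)`.
#' @param min_identity Per-unit match threshold, see [unit_match()].
#' @return A `slippage_event`: list with `longer_id`, `shorter_id` (if the
#'   arrays carry `source_id`s, else `NA`), `conserved_prefix`,
#'   `conserved_suffix`, `excised` (tibble: `position` 1-based in longer,
#'   `unit_length`), `contiguous`, `matched_positions` (positions in longer
#'   aligned to shorter units), or `NULL`.
#' @export
infer_excision <- function(longer, shorter, min_identity = 0.9) {
  nl <- length(longer$units); ns <- length(shorter$units)
  if (nl <= ns) {
    warn("longer array does not exceed shorter array; no event inferred")
    return(NULL)
  }
  # DP over (i = longer index, j = shorter index): LCS-like, deletions only
  # in longer. match[i,j] = units identical per unit_match.
  M <- matrix(FALSE, nl, ns)
  for (i in seq_len(nl)) for (j in seq_len(ns)) {
    M[i, j] <- unit_match(longer$units[i], shorter$units[j], min_identity)
  }
  # all shorter units must be matched, in order; enumerate optimal matchings
  # via DP counting, then select preferred one. ns, nl <= ~9 so a direct
  # recursive enumeration with memo of feasibility is fine.
  # feasible[i, j]: can shorter[j..ns] be matched into longer[i..nl]?
  feasible <- matrix(FALSE, nl + 2, ns + 2)
  feasible[, ns + 1] <- TRUE
  for (i in seq(nl, 1)) for (j in seq(ns, 1)) {
    feasible[i, j] <- (M[i, j] && feasible[i + 1, j + 1]) || feasible[i + 1, j]
  }
  if (!feasible[1, 1]) return(NULL)
  # choose assignment minimizing (number of excised blocks, 3'-ness of
  # excision): walk greedily but explore both branches, scoring candidates.
  best <- NULL
  assignments <- list()
  walk <- function(i, j, used) {
    if (j > ns) {
      assignments[[length(assignments) + 1]] <<- used
      return(invisible(NULL))
    }
    if (i > nl || !feasible[i, j]) return(invisible(NULL))
    if (M[i, j] && feasible[i + 1, j + 1]) walk(i + 1, j + 1, c(used, i))
    if (feasible[i + 1, j]) walk(i + 1, j, used)
  }
  walk(1L, 1L, integer(0))
  score <- function(pos) {
    exc <- setdiff(seq_len(nl), pos)
    blocks <- sum(diff(exc) > 1) + 1
    c(blocks, exc[1]) # fewer blocks, then 5'-most excision
  }
  scores <- t(vapply(assignments, score, numeric(2)))
  ord <- order(scores[, 1], scores[, 2])
  pos <- assignments[[ord[1]]]
  excised <- setdiff(seq_len(nl), pos)
  # conserved prefix/suffix: leading/trailing runs of matched positions
  conserved_prefix <- 0L
  while (conserved_prefix < nl && (conserved_prefix + 1L) %in% pos) {
    conserved_prefix <- conserved_prefix + 1L
  }
  conserved_suffix <- 0L
  while (conserved_suffix < nl && (nl - conserved_suffix) %in% pos) {
    conserved_suffix <- conserved_suffix + 1L
  }
  structure(list(
    longer_id = longer$source_id %||% NA_character_,
    shorter_id = shorter$source_id %||% NA_character_,
    conserved_prefix = conserved_prefix,
    conserved_suffix = conserved_suffix,
    excised = tibble(position = excised,
      unit_length = longer$unit_lengths[excised]),
    contiguous = length(excised) <= 1 ||
      all(diff(sort(excised)) == 1),
    matched_positions = pos
  ), class = "slippage_event")
}

#' @export
print.slippage_event <- function(x, ...) {
  cat(sprintf(
    "<slippage_event> %s -> %s: %d unit(s) excised at [%s], prefix %d / suffix %d conserved%s\n",
    x$longer_id, x$shorter_id, nrow(x$excised),
    paste(x$excised$position, collapse = ","),
    x$conserved_prefix, x$conserved_suffix,
    if (x$contiguous) "" else " (non-contiguous)"))
  invisible(x)
}

#' Classify a slippage event into the five flank-conservation classes
#'
#' Decision table over (conserved flank counts, excised unit lengths, array
#' composition), evaluated in the order 5, 1, 2, 4, 3 (most specific
#' first):
#' \itemize{
#'   \item class 5: every unit of both arrays is 33 nt and all excised units
#'     are 33 nt;
#'   \item class 1: >= 1 unit conserved at the 5' end, >= 3 at the 3' end,
#'     all excised units 30 nt;
#'   \item class 2: >= 2 conserved 5', >= 1 conserved 3', all excised 33 nt;
#'   \item class 4: >= 1 conserved 5', >= 2 conserved 3', all excised 30 nt;
#'   \item class 3: >= 1 conserved 5', >= 1 conserved 3', all excised 30 nt.
#' }
#' Events admitting no class (e.g. mixed excised lengths) are `NA`
#' ("unclassified"). Thresholds are exposed for exploration but default to
#' the published exemplars.
#'
#' @param event A `slippage_event`.
#' @param longer,shorter The `repeat_array`s the event relates.
#' @param thresholds Named list of `c(prefix, suffix)` minima per class.
#' @return Integer class 1-5, or `NA_integer_`.
#' @export
classify_slippage <- function(event, longer, shorter,
    thresholds = list(`1` = c(1, 3), `2` = c(2, 1),
                      `3` = c(1, 1), `4` = c(1, 2))) {
  exc_len <- event$excised$unit_length
  pre <- event$conserved_prefix
  suf <- event$conserved_suffix
  all33 <- all(longer$unit_lengths == 33) && all(shorter$unit_lengths == 33)
  if (all33 && all(exc_len == 33)) return(5L)
  ok <- function(cl) pre >= thresholds[[cl]][1] && suf >= thresholds[[cl]][2]
  if (ok("1") && all(exc_len == 30)) return(1L)
  if (ok("2") && all(exc_len == 33)) return(2L)
  if (ok("4") && all(exc_len == 30)) return(4L)
  if (ok("3") && all(exc_len == 30)) return(3L)
  NA_integer_
}

#' Scan a family for slippage events
#'
#' Evaluates every ordered (longer, shorter) pair of decomposed members —
#' by default restricted to pairs of the same type — and reports the
#' classified events.
#'
#' @param decomposed Tibble from [decompose_repeats()] (`id`, `copy_number`,
#'   `array`).
#' @param type_table Optional tibble from [assign_types()]; required when
#'   `within_type_only = TRUE`.
#' @param within_type_only Only compare members of the same type (default).
#' @param min_identity Unit match threshold.
#' @param keep_unclassified Keep events that fit no class (default `FALSE`).
#' @return Tibble sorted by class then ids: `longer_id`, `shorter_id`,
#'   `type`, `slip_class`, `conserved_prefix`, `conserved_suffix`,
#'   `n_excised`, `excised_positions`, `excised_lengths`, `contiguous`,
#'   `event` (list-column).
#' @export
scan_slippage <- function(decomposed, type_table = NULL,
                          within_type_only = TRUE, min_identity = 0.9,
                          keep_unclassified = FALSE) {
  df <- decomposed
  if (!is.null(type_table)) {
    df <- inner_join(df, select(type_table, "id", "type"), by = "id")
  } else {
    if (within_type_only) {
      abort("within_type_only = TRUE requires a type_table")
    }
    df$type <- NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (i == j) next
    if (df$copy_number[j] < 1) next
    if (df$copy_number[i] <= df$copy_number[j]) next
    if (within_type_only &&
        (is.na(df$type[i]) || is.na(df$type[j]) || df$type[i] != df$type[j])) next
    longer <- df$array[[i]]
    longer$source_id <- df$id[i]
    # candidate shorter arrays: as decomposed, and re-segmented with the
    # longer's consensus (harmonizes unit phases when the two members were
    # decomposed with different consensus rotations); the first candidate
    # that yields a classified event wins
    shorter0 <- df$array[[j]]
    candidates <- list(shorter0)
    if (!is.na(longer$consensus) &&
        !identical(shorter0$consensus, longer$consensus)) {
      resegmented <- segment_units(reconstruct_cds(shorter0), longer$consensus)
      if (length(resegmented$units) > 0) candidates <- c(candidates,
        list(resegmented))
    }
    ev <- NULL; cl <- NA_integer_; shorter <- shorter0
    for (cand in candidates) {
      cand$source_id <- df$id[j]
      cand_ev <- withCallingHandlers(
        infer_excision(longer, cand, min_identity = min_identity),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(cand_ev)) next
      cand_cl <- classify_slippage(cand_ev, longer, cand)
      if (is.null(ev) || (!is.na(cand_cl) && is.na(cl))) {
        ev <- cand_ev; cl <- cand_cl; shorter <- cand
      }
      if (!is.na(cl)) break
    }
    if (is.null(ev)) next
    if (is.na(cl) && !keep_unclassified) next
    rows[[length(rows) + 1]] <- tibble(
      longer_id = df$id[i], shorter_id = df$id[j], type = df$type[i],
      slip_class = cl,
      conserved_prefix = ev$conserved_prefix,
      conserved_suffix = ev$conserved_suffix,
      n_excised = nrow(ev$excised),
      excised_positions = paste(ev$excised$position, collapse = ","),
      excised_lengths = paste(ev$excised$unit_length, collapse = ","),
      contiguous = ev$contiguous,
      event = list(ev)
    )
  }
  if (length(rows) == 0) {
    return(tibble(longer_id = character(), shorter_id = character(),
      type = character(), slip_class = integer(),
      conserved_prefix = integer(), conserved_suffix = integer(),
      n_excised = integer(), excised_positions = character(),
      excised_lengths = character(), contiguous = logical(),
      event = list()))
  }
  bind_rows(rows) |> arrange(.data$slip_class, .data$longer_id, .data$shorter_id)
}

#' Apply an inferred excision to an array's pattern
#'
#' Soundness helper: deleting the excised positions from the longer array
#' must reproduce the shorter array's unit-length pattern exactly.
#'
#' @param longer `repeat_array`.
#' @param event `slippage_event`.
#' @return Integer vector of remaining unit lengths.
#' @export
apply_excision <- function(longer, event) {
  longer$unit_lengths[-event$excised$position]
}
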