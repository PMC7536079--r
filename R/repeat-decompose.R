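## In-frame tandem-repeat decomposition of coding sequences.
##
## The repeat region of these lectin genes sits inside exon 2 and is built
## from 30- or 33-nt units (10 or 11 codons); copy number varies 1-9 among
## family members. Decomposition proceeds in three steps: period detection
## by windowed autocorrelation, consensus construction over period-phased
## windows, and dynamic-programming segmentation into codon-granular units.

#' Detect the tandem period of a sequence
#'
#' For each candidate period \eqn{p}, the match indicator
#' \eqn{m_i = [s_i = s_{i+p}]} is computed and the score is the best mean of
#' \eqn{m} over any window of length \eqn{2p} (so a tandem region embedded in
#' non-repetitive flanks still scores highly). Periods are ranked by score.
#'
#' @param seq DNA string, length >= 2 * `min_period`.
#' @param min_period,max_period Candidate period range in nt (defaults 24-39).
#' @return Tibble with one row per candidate period, ranked by descending
#'   `score`, with columns `period`, `score`, `region_start`, `region_end`
#'   (0-based half-open bounds of the maximal high-matching run around the
#'   best window). Zero rows if the sequence is too short.
#' @export
detect_period <- function(seq, min_period = 24, max_period = 39) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * min_period) {
    return(tibble(period = integer(), score = numeric(),
      region_start = integer(), region_end = integer()))
  }
  chars <- strsplit(seq, "")[[1]]
  rows <- lapply(seq(min_period, min(max_period, n %/% 2)), function(p) {
    m <- (chars[1:(n - p)] == chars[(p + 1):n]) &
      chars[1:(n - p)] != "N" # N never matches
    w <- 2L * p
    if (length(m) < w) {
      sc <- mean(m)
      best_start <- 1L
      w <- length(m)
    } else {
      cs <- c(0, cumsum(m))
      means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
      best_start <- which.max(means)
      sc <- means[best_start]
    }
    # extend the best window left/right while local match density stays high
    lo <- best_start; hi <- best_start + w - 1L
    while (lo > 1L && m[lo - 1L]) lo <- lo - 1L
    while (hi < length(m) && m[hi + 1L]) hi <- hi + 1L
    tibble(period = p, score = sc,
      region_start = lo - 1L, region_end = hi + p)
  })
  arrange(bind_rows(rows), desc(.data$score), .data$period)
}

#' Build a consensus repeat unit
#'
#' Splits the (region of the) sequence into consecutive period-length
#' windows and takes the per-column majority base; ties go to the
#' alphabetically first base. Incomplete trailing windows are ignored.
#'
#' @param seq DNA string.
#' @param period Unit length in nt.
#' @param region Optional 0-based half-open `c(start, end)` restricting the
#'   windows to a detected tandem region (default: whole sequence).
#' @return Consensus DNA string of length `period`.
#' @export
build_consensus <- function(seq, period, region = NULL) {
  seq <- toupper(seq)
  if (!is.null(region)) seq <- substr(seq, region[1] + 1L, region[2])
  n <- nchar(seq)
  k <- n %/% period
  stopifnot(k >= 1)
  chars <- strsplit(substr(seq, 1, k * period), "")[[1]]
  mat <- matrix(chars, nrow = period)
  cons <- apply(mat, 1, function(col) {
    col <- col[col != "N"]
    if (length(col) == 0) return("N")
    tab <- table(col)
    names(tab)[tab == max(tab)][1] # table() is alphabetical; ties -> first
  })
  paste(cons, collapse = "")
}

# Vectorized identity of every window of cds against the consensus, for
# each admissible unit length (equal to the consensus length, or one codon
# shorter/longer with the indel tried at every codon boundary). Returns a
# list keyed by unit length; element [i] is the identity of the window
# starting at 0-based position i-1, NA where the window does not fit.
precompute_identities <- function(cds, consensus, lens) {
  n <- nchar(cds)
  x <- strsplit(cds, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  lc <- length(cc)
  eq_at <- function(shift, k) {
    # indicator over window starts i: cds[i + shift + k - 1] == consensus[k]
    idx <- seq_len(n)
    v <- rep(FALSE, n)
    j <- idx + shift + k - 1L
    keep <- j <= n
    v[keep] <- x[j[keep]] == cc[k] & x[j[keep]] != "N"
    v
  }
  out <- list()
  for (l in lens) {
    if (l == lc) {
      s <- rep(0, n)
      for (k in seq_len(lc)) s <- s + eq_at(0L, k)
      ident <- s / lc
    } else if (l == lc + 3L) {
      # delete one codon from the window: snapshots of partial sums at
      # codon boundaries, aligned at shift 0 (before the deletion) and
      # shift 3 (after it)
      nd <- lc %/% 3L
      s0 <- rep(0, n); s3 <- rep(0, n)
      snap0 <- list(s0); snap3 <- list(s3)
      for (k in seq_len(lc)) {
        s0 <- s0 + eq_at(0L, k)
        s3 <- s3 + eq_at(3L, k)
        if (k %% 3L == 0L) {
          snap0[[k %/% 3L + 1L]] <- s0
          snap3[[k %/% 3L + 1L]] <- s3
        }
      }
      best <- rep(-Inf, n)
      for (d in 0:nd) {
        best <- pmax(best, snap0[[d + 1L]] + s3 - snap3[[d + 1L]])
      }
      ident <- best / l
    } else if (l == lc - 3L) {
      # delete one codon from the consensus
      nd <- l %/% 3L
      s0 <- rep(0, n); s3 <- rep(0, n)
      snap0 <- list(s0); snap3 <- list(s3)
      for (k in seq_len(l)) {
        s0 <- s0 + eq_at(0L, k)
        v <- rep(FALSE, n) # cds[i + k - 1] == consensus[k + 3]
        j <- seq_len(n) + k - 1L
        keep <- j <= n
        v[keep] <- x[j[keep]] == cc[k + 3L] & x[j[keep]] != "N"
        s3 <- s3 + v
        if (k %% 3L == 0L) {
          snap0[[k %/% 3L + 1L]] <- s0
          snap3[[k %/% 3L + 1L]] <- s3
        }
      }
      best <- rep(-Inf, n)
      for (d in 0:nd) {
        best <- pmax(best, snap0[[d + 1L]] + s3 - snap3[[d + 1L]])
      }
      ident <- best / lc
    } else {
      ident <- vapply(seq_len(n), function(i) {
        if (i + l - 1L > n) return(NA_real_)
        unit_identity(substr(cds, i, i + l - 1L), consensus)
      }, numeric(1))
    }
    ident[seq_len(n) + l - 1L > n] <- NA_real_
    out[[as.character(l)]] <- ident
  }
  out
}

# identity of a unit against the consensus allowing one codon-aligned
# 3-nt indel; returns matches / max(lengths)
unit_identity <- function(unit, consensus) {
  lu <- nchar(unit); lc <- nchar(consensus)
  u <- strsplit(unit, "")[[1]]
  v <- strsplit(consensus, "")[[1]]
  count_matches <- function(a, b) sum(a == b & a != "N" & b != "N")
  if (lu == lc) {
    return(count_matches(u, v) / lc)
  }
  if (abs(lu - lc) != 3) return(0)
  if (lu > lc) { longer <- u; shorter <- v } else { longer <- v; shorter <- u }
  ll <- length(longer)
  best <- 0L
  for (pos in seq(1, ll - 2, by = 3)) { # codon-aligned deletion from longer
    trimmed <- longer[-(pos:(pos + 2))]
    best <- max(best, count_matches(trimmed, shorter))
  }
  best / ll
}

#' Segment a CDS into tandem-repeat units
#'
#' Dynamic-programming tiling of a maximal contiguous region of `cds` into
#' units, where each unit aligns to the consensus with identity at least
#' `min_identity` and has a frame-preserving length (consensus length, or
#' one codon shorter/longer, intersected with `allowed_lengths`). Among
#' tilings the total number of matched bases is maximized; ties prefer fewer
#' units, then the 5'-most region. Untiled prefix/suffix become the flanks.
#'
#' @param cds DNA string (a coding sequence).
#' @param consensus Consensus unit from [build_consensus()].
#' @param min_identity Per-unit identity threshold (default 0.8).
#' @param allowed_lengths Admissible unit lengths in nt (default `c(30, 33)`).
#' @param indel_penalty Score penalty, in matched-base equivalents, for a
#'   unit whose length differs from the consensus (default 2): a codon
#'   indel is rarer than two substitutions, which stops edge units from
#'   absorbing flank bases through a spurious codon deletion.
#' @return A `repeat_array` object: list with `units` (character vector of
#'   unit sequences), `unit_lengths`, `flank5`, `flank3`, `consensus`,
#'   `identity` (per-unit identity to consensus), `region_start` (0-based
#'   offset of the repeat region in `cds`). Zero units means no repeat
#'   region passed the threshold.
#' @export
segment_units <- function(cds, consensus, min_identity = 0.8,
                          allowed_lengths = c(30L, 33L),
                          indel_penalty = 2) {
  cds <- toupper(cds)
  n <- nchar(cds)
  lc <- nchar(consensus)
  lens <- sort(intersect(as.integer(allowed_lengths), lc + c(-3L, 0L, 3L)))
  if (length(lens) == 0) lens <- lc
  ident_tab <- precompute_identities(cds, consensus, lens)
  # DP over tiling start positions. Per-unit contribution is a composite
  # score that encodes the lexicographic objective linearly: matched bases
  # (always an integer count, weight 1000) dominate, then total identity
  # (weight 10; breaks phase ties in favour of exact-length units over
  # units padded with flank bases, granularity >= 10/33), then fewer units
  # (-0.01 per unit). 5'-most region wins residual ties.
  valid <- sort(unique(unlist(lapply(lens, function(l) {
    which(!is.na(ident_tab[[as.character(l)]]) &
          ident_tab[[as.character(l)]] >= min_identity)
  }))))
  f <- numeric(n + 1)           # composite score of best tiling starting at i (index i+1)
  choice <- integer(n + 1)      # chosen unit length at i (0 = stop)
  for (i in rev(valid)) {       # 1-based window start == 0-based position i-1
    for (l in lens) {
      if (i + l - 1L > n) next
      ident <- ident_tab[[as.character(l)]][i]
      if (is.na(ident) || ident < min_identity) next
      pen <- if (l != lc) indel_penalty else 0
      s <- (ident * max(l, lc) - pen) * 1000 + ident * 10 - 0.01 + f[i + l]
      if (s > f[i] + 1e-6) {
        f[i] <- s; choice[i] <- l
      }
    }
  }
  best_i <- 0L; best_sc <- 0
  for (i in valid) {
    if (f[i] > best_sc + 1e-6) { best_sc <- f[i]; best_i <- i - 1L }
  }
  units <- character(0); idents <- numeric(0)
  i <- best_i
  while (choice[i + 1L] != 0L) {
    l <- choice[i + 1L]
    units <- c(units, substr(cds, i + 1L, i + l))
    idents <- c(idents, ident_tab[[as.character(l)]][i + 1L])
    i <- i + l
  }
  region_start <- if (length(units) > 0) best_i else nchar(cds)
  structure(list(
    units = units,
    unit_lengths = nchar(units),
    flank5 = substr(cds, 1, region_start),
    flank3 = if (length(units) > 0) substr(cds, i + 1L, n) else "",
    consensus = consensus,
    identity = idents,
    region_start = as.integer(region_start),
    score_matched = sum(idents * pmax(nchar(units), lc)),
    score_identity = sum(idents)
  ), class = "repeat_array")
}

rotate_seq <- function(s, r) {
  n <- nchar(s)
  r <- r %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1, n), substr(s, 1, r))
}

#' @export
print.repeat_array <- function(x, ...) {
  cat(sprintf("<repeat_array> %d units [%s], region %d nt, flanks %d/%d nt\n",
    length(x$units), paste(x$unit_lengths, collapse = "-"),
    sum(x$unit_lengths), nchar(x$flank5), nchar(x$flank3)))
  invisible(x)
}

#' Construct a repeat array directly from unit sequences
#'
#' @param units Character vector of unit sequences.
#' @param flank5,flank3 Flanking sequence (may be "").
#' @param consensus Optional consensus (defaults to the first unit).
#' @return A `repeat_array`.
#' @export
repeat_array <- function(units, flank5 = "", flank3 = "", consensus = NULL) {
  units <- toupper(units)
  structure(list(
    units = units,
    unit_lengths = nchar(units),
    flank5 = toupper(flank5),
    flank3 = toupper(flank3),
    consensus = consensus %||% units[1],
    identity = rep(NA_real_, length(units)),
    region_start = nchar(flank5)
  ), class = "repeat_array")
}

reconstruct_cds <- function(array) {
  paste0(array$flank5, paste(array$units, collapse = ""), array$flank3)
}

empty_array <- function(cds) {
  structure(list(
    units = character(0), unit_lengths = integer(0),
    flank5 = cds, flank3 = "", consensus = NA_character_,
    identity = numeric(0), region_start = nchar(cds),
    score_matched = 0, score_identity = 0
  ), class = "repeat_array")
}

array_better <- function(a, b) {
  if (a$score_matched > b$score_matched + 1e-9) return(TRUE)
  if (a$score_matched < b$score_matched - 1e-9) return(FALSE)
  a$score_identity > b$score_identity + 1e-9
}

#' Decompose one CDS into its repeat array
#'
#' Composition of [detect_period()], [build_consensus()] and
#' [segment_units()]. The autocorrelation region fixes the period but not
#' the unit boundary phase, so all rotations of the raw consensus are
#' scored by a windowed trial segmentation and the best phase wins; the
#' consensus is then refined once from the segmented units (column
#' majority) before the final full-length segmentation. If no period scores
#' at least `min_period_score` — a single repeat copy has no self-similarity
#' at all — an empty array (whole CDS as 5' flank) is returned, flagged for
#' review; supplying `consensus` (e.g. the family consensus, as
#' [decompose_repeats()] does) bypasses detection and segments directly.
#'
#' @inheritParams segment_units
#' @param min_period,max_period Passed to [detect_period()].
#' @param min_period_score Minimum autocorrelation score to accept a tandem
#'   signal (default 0.8).
#' @param consensus Optional known consensus unit; skips period detection.
#' @return A `repeat_array`.
#' @export
decompose <- function(cds, min_identity = 0.8, allowed_lengths = c(30L, 33L),
                      min_period = 24, max_period = 39,
                      min_period_score = 0.8, consensus = NULL) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (!is.null(consensus)) {
    return(segment_units(cds, consensus, min_identity = min_identity,
      allowed_lengths = allowed_lengths))
  }
  ranked <- detect_period(cds, min_period, max_period)
  if (nrow(ranked) == 0 || ranked$score[1] < min_period_score) {
    return(empty_array(cds))
  }
  # score all rotations of a consensus (the autocorrelation region fixes
  # the period but not the unit-boundary phase); ties across rotations
  # (homogeneous arrays are phase-ambiguous) prefer a frame-consistent
  # region (in-frame repeats start on codon boundaries of the CDS), then
  # the 5'-most region
  rotation_scan <- function(cons) {
    best <- NULL
    for (r in seq(0, nchar(cons) - 1)) {
      trial <- segment_units(cds, rotate_seq(cons, r),
        min_identity = min_identity, allowed_lengths = allowed_lengths)
      if (is.null(best) || array_better(trial, best)) {
        best <- trial
      } else if (!array_better(best, trial)) {
        t_frame <- trial$region_start %% 3L == 0L
        b_frame <- best$region_start %% 3L == 0L
        if ((t_frame && !b_frame) ||
            (t_frame == b_frame && trial$region_start < best$region_start)) {
          best <- trial
        }
      }
    }
    best
  }
  # mixed 30/33 arrays can score similarly at both periods, and the wrong
  # one yields a chimeric consensus: try every qualifying period (top 3)
  # and keep the best final array
  ranked <- ranked[ranked$score >= min_period_score, , drop = FALSE]
  ranked <- utils::head(ranked, 3)
  best <- NULL
  for (cand_row in seq_len(nrow(ranked))) {
    top <- ranked[cand_row, ]
    cons0 <- build_consensus(cds, top$period,
      region = c(top$region_start, top$region_end))
    this <- rotation_scan(cons0)
    # refinement: rebuild the consensus from the segmented full-length
    # units (column majority outvotes per-unit noise) and re-scan —
    # including rotations, since the first tiling may sit in a shifted
    # phase
    for (iter in 1:2) {
      full_units <- this$units[nchar(this$units) == nchar(this$consensus)]
      if (length(full_units) < 2) break
      refined <- build_consensus(paste(full_units, collapse = ""),
        nchar(this$consensus))
      if (identical(refined, this$consensus)) break
      cand <- rotation_scan(refined)
      if (array_better(cand, this)) this <- cand else break
    }
    if (is.null(best) || array_better(this, best)) best <- this
  }
  best
}

#' Decompose every coding sequence in a table
#'
#' Tidy wrapper over [decompose()]: one row in, one row out. Members whose
#' own tandem signal is too weak to detect — single-copy and two-copy
#' arrays have little or no self-similarity — are rescued with consensus
#' units borrowed from successfully decomposed family members (tried in
#' order of decreasing signal, strongest first), mirroring how such alleles
#' are genotyped against the family's known unit.
#'
#' @param seqs Tibble with columns `id` and `seq` (CDS), or `cds`.
#' @inheritParams decompose
#' @param max_rescue_consensi How many distinct family consensi to try for
#'   members without their own detectable period (default 10).
#' @return Tibble with columns `id`, `copy_number`, `pattern` (dash-joined
#'   unit lengths, 5' to 3'), `region_len`, `flank5_len`, `flank3_len`,
#'   `region_start`, `array` (list-column of `repeat_array`).
#' @export
decompose_repeats <- function(seqs, min_identity = 0.8,
                              allowed_lengths = c(30L, 33L),
                              min_period = 24, max_period = 39,
                              min_period_score = 0.8,
                              max_rescue_consensi = 10) {
  seq_col <- if ("cds" %in% names(seqs)) "cds" else "seq"
  arrays <- purrr::map(seqs[[seq_col]], decompose,
    min_identity = min_identity, allowed_lengths = allowed_lengths,
    min_period = min_period, max_period = max_period,
    min_period_score = min_period_score)
  # rescue members without their own signal using family consensi
  n_units <- vapply(arrays, function(a) length(a$units), integer(1))
  if (any(n_units == 0) && any(n_units > 0)) {
    ok <- order(-vapply(arrays, function(a) a$score_matched, numeric(1)))
    ok <- ok[n_units[ok] > 0]
    consensi <- unique(vapply(arrays[ok], function(a) a$consensus, character(1)))
    consensi <- utils::head(consensi, max_rescue_consensi)
    for (i in which(n_units == 0)) {
      best <- arrays[[i]]
      for (cons in consensi) {
        cand <- segment_units(seqs[[seq_col]][i], cons,
          min_identity = min_identity, allowed_lengths = allowed_lengths)
        if (array_better(cand, best)) best <- cand
      }
      arrays[[i]] <- best
    }
  }
  tibble(
    id = seqs$id,
    copy_number = vapply(arrays, function(a) length(a$units), integer(1)),
    pattern = vapply(arrays, function(a)
      if (length(a$units) == 0) NA_character_
      else paste(a$unit_lengths, collapse = "-"), character(1)),
    region_len = vapply(arrays, function(a) sum(a$unit_lengths), integer(1)),
    flank5_len = vapply(arrays, function(a) nchar(a$flank5), integer(1)),
    flank3_len = vapply(arrays, function(a) nchar(a$flank3), integer(1)),
    region_start = vapply(arrays, function(a) a$region_start, integer(1)),
    array = arrays
  )
}
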