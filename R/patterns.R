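## Arrangement-pattern cataloguing. The identity key of an array is its
## ordered unit-length sequence, written 5' to 3' as dash-joined lengths
## ("33-30-30-33"); no reversal or rotation, since orientation is
## biological.

#' Canonical arrangement pattern of a repeat array
#'
#' @param array A `repeat_array` (or an integer vector of unit lengths).
#' @return Pattern string, e.g. `"33-30-30-33"`. ASCII hyphens are emitted;
#'   [parse_pattern()] accepts en-dashes too.
#' @export
canonical_pattern <- function(array) {
  lens <- if (inherits(array, "repeat_array")) array$unit_lengths else as.integer(array)
  if (length(lens) == 0) abort("empty repeat array has no pattern")
  paste(lens, collapse = "-")
}

#' Parse a pattern string back to unit lengths
#'
#' @param pattern Dash-joined lengths; ASCII hyphen or en-dash.
#' @return Integer vector of unit lengths.
#' @export
parse_pattern <- function(pattern) {
  as.integer(strsplit(gsub("–", "-", pattern), "-", fixed = TRUE)[[1]])
}

#' Catalogue unique arrangement patterns
#'
#' Groups decomposed members by pattern and summarizes per copy number,
#' reproducing the family-wide arrangement catalogue. Members without a
#' detected repeat region (`NA` pattern) are excluded.
#'
#' @param decomposed Tibble from [decompose_repeats()] (needs `id`,
#'   `pattern`, `copy_number`).
#' @param by_sequence If `TRUE`, pattern identity additionally requires every
#'   aligned unit pair to share >= `seq_identity` nucleotide identity,
#'   splitting length-identical patterns with diverged units (needs the
#'   `array` column).
#' @param seq_identity Per-unit identity threshold for `by_sequence` mode.
#' @return A `pattern_catalog`: list with `patterns` (tibble: `pattern`,
#'   `copy_number`, `n_members`, `member_ids`), `by_copy_number` (tibble:
#'   `copy_number`, `n_patterns`, `n_members`), `n_patterns` (grand total).
#' @export
catalog_patterns <- function(decomposed, by_sequence = FALSE,
                             seq_identity = 0.95) {
  rows <- decomposed |> filter(!is.na(.data$pattern))
  key <- rows$pattern
  if (by_sequence) {
    # refine length-pattern groups by unit-sequence identity (single-linkage)
    key <- vapply(seq_len(nrow(rows)), function(i) rows$pattern[i], character(1))
    for (p in unique(rows$pattern)) {
      idx <- which(rows$pattern == p)
      if (length(idx) < 2) next
      rep_ids <- integer(0) # representative member per sub-pattern
      sub <- integer(length(idx))
      for (k in seq_along(idx)) {
        placed <- FALSE
        for (g in seq_along(rep_ids)) {
          a <- rows$array[[idx[k]]]; b <- rows$array[[rep_ids[g]]]
          ok <- all(vapply(seq_along(a$units), function(u)
            unit_identity(a$units[u], b$units[u]) >= seq_identity, logical(1)))
          if (ok) { sub[k] <- g; placed <- TRUE; break }
        }
        if (!placed) { rep_ids <- c(rep_ids, idx[k]); sub[k] <- length(rep_ids) }
      }
      key[idx] <- paste0(p, ".", sub)
    }
  }
  patterns <- tibble(pattern = key,
      copy_number = rows$copy_number, id = rows$id) |>
    group_by(.data$pattern, .data$copy_number) |>
    summarise(n_members = n(), member_ids = list(sort(.data$id)),
      .groups = "drop") |>
    arrange(.data$copy_number, .data$pattern)
  by_cn <- patterns |>
    group_by(.data$copy_number) |>
    summarise(n_patterns = n(), n_members = sum(.data$n_members),
      .groups = "drop")
  structure(list(patterns = patterns, by_copy_number = by_cn,
    n_patterns = nrow(patterns)), class = "pattern_catalog")
}

#' @export
print.pattern_catalog <- function(x, ...) {
  cat(sprintf("<pattern_catalog> %d unique patterns over %d members\n",
    x$n_patterns, sum(x$patterns$n_members)))
  print(x$by_copy_number, n = Inf)
  invisible(x)
}

#' @method tidy pattern_catalog
#' @export
tidy.pattern_catalog <- function(x, ...) x$patterns

#' @method glance pattern_catalog
#' @export
glance.pattern_catalog <- function(x, ...) {
  tibble(n_patterns = x$n_patterns,
    n_members = sum(x$patterns$n_members),
    copy_number_min = min(x$patterns$copy_number),
    copy_number_max = max(x$patterns$copy_number))
}

#' @method autoplot pattern_catalog
#' @export
autoplot.pattern_catalog <- function(object, ...) {
  df <- object$patterns |>
    mutate(row = dplyr::row_number()) |>
    mutate(units = purrr::map(.data$pattern,
      function(p) parse_pattern(sub("\\..*$", "", p)))) |>
    tidyr::unnest_longer(col = "units", indices_to = "unit_index")
  df <- df |>
    group_by(.data$row) |>
    mutate(xend = cumsum(.data$units), xstart = .data$xend - .data$units) |>
    ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xstart, xmax = .data$xend - 0.8,
      ymin = .data$row - 0.4, ymax = .data$row + 0.4,
      fill = factor(.data$units))) +
    ggplot2::scale_y_reverse(breaks = unique(df$row),
      labels = object$patterns$pattern[unique(df$row)]) +
    ggplot2::labs(x = "position in repeat region (nt)", y = NULL,
      fill = "unit length (nt)",
      title = "Repeat-unit arrangement patterns") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Per-type pattern catalogues
#'
#' @param decomposed Tibble from [decompose_repeats()].
#' @param type_table Tibble from [assign_types()] (columns `id`, `type`).
#' @inheritParams catalog_patterns
#' @return Tibble with columns `type`, `catalog` (list of `pattern_catalog`),
#'   `n_patterns`.
#' @export
per_type_patterns <- function(decomposed, type_table, by_sequence = FALSE,
                              seq_identity = 0.95) {
  joined <- inner_join(decomposed, type_table, by = "id") |>
    filter(!is.na(.data$type))
  out <- joined |>
    group_by(.data$type) |>
    summarise(catalog = list(catalog_patterns(pick(dplyr::everything()),
      by_sequence = by_sequence, seq_identity = seq_identity)),
      .groups = "drop")
  out$n_patterns <- vapply(out$catalog, function(cc) cc$n_patterns, integer(1))
  out
}
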