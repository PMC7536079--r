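## Motif-based typing and neighbour-joining phylogeny over repeat-masked
## protein alignments. Family members carry a diagnostic six-amino-acid
## motif in the exon-5-encoded block; the motif defines the type. Trees are
## built on proteins with the repeat-encoded residues removed, so copy
## number does not dominate the distances.

#' Remove repeat-encoded residues from a protein
#'
#' Deletes the residues encoded by the repeat region (not replaces them), so
#' members with different copy numbers become comparable. The repeat region
#' must start and end on codon boundaries of the ORF.
#'
#' @param protein Amino-acid string.
#' @param array A `repeat_array` whose `region_start` is an offset on the CDS
#'   (0-based, CDS starting at the ATG).
#' @return Masked protein string.
#' @export
mask_repeats <- function(protein, array) {
  if (length(array$units) == 0) return(protein)
  region_start <- array$region_start
  region_len <- sum(array$unit_lengths)
  if (region_start %% 3 != 0 || region_len %% 3 != 0) {
    abort("repeat region is not codon-resolvable against the ORF",
      class = "vntrfam_mask_error")
  }
  aa_start <- region_start %/% 3      # 0-based residue index
  aa_len <- region_len %/% 3
  if (aa_start + aa_len > nchar(protein)) {
    abort("repeat region maps outside the protein", class = "vntrfam_mask_error")
  }
  paste0(substr(protein, 1, aa_start),
         substr(protein, aa_start + aa_len + 1, nchar(protein)))
}

#' Default motif anchor
#'
#' The diagnostic motif is located relative to a conserved upstream context
#' rather than a fixed coordinate, because copy-number variation shifts
#' absolute positions. The anchor is a (context k-mer, offset) pair: the
#' motif is the 6 residues starting `offset` residues after the end of the
#' context. This default matches the synthetic family backbone, which plants
#' the conserved 8-residue context `WQNTGKPE` immediately before the motif.
#'
#' @return List with `context` and `offset`.
#' @export
default_motif_anchor <- function() list(context = "WQNTGKPE", offset = 0L)

# locate `context` in `protein` allowing at most 1 mismatch; first hit wins
find_anchor <- function(protein, context) {
  lp <- nchar(protein); lc <- nchar(context)
  if (lp < lc) return(NA_integer_)
  hit <- regexpr(context, protein, fixed = TRUE)[1]
  if (hit != -1) return(as.integer(hit))
  ctx <- strsplit(context, "")[[1]]
  chars <- strsplit(protein, "")[[1]]
  for (i in seq_len(lp - lc + 1)) {
    if (sum(chars[i:(i + lc - 1)] != ctx) <= 1) return(i)
  }
  NA_integer_
}

#' Extract the diagnostic six-residue motif
#'
#' @param protein (Masked) protein string.
#' @param anchor List with `context` (conserved upstream k-mer, located by
#'   exact then 1-mismatch search) and `offset` (residues between context end
#'   and motif start). Default [default_motif_anchor()].
#' @return The 6-residue motif, or `NA_character_` if the anchor is absent.
#' @export
extract_motif <- function(protein, anchor = default_motif_anchor()) {
  pos <- find_anchor(protein, anchor$context)
  if (is.na(pos)) return(NA_character_)
  start <- pos + nchar(anchor$context) + anchor$offset
  motif <- substr(protein, start, start + 5)
  if (nchar(motif) < 6) return(NA_character_)
  motif
}

#' Assign family types by diagnostic motif
#'
#' One type per unique motif; members with an unlocatable anchor are
#' reported as unassigned (`NA` type), not dropped.
#'
#' @param records Tibble with columns `id` and `protein` (or
#'   `masked_protein`, preferred if present).
#' @param anchor Motif anchor, see [extract_motif()].
#' @return Tibble with columns `id`, `motif`, `type` (the motif string
#'   itself, the field's naming convention for these families).
#' @export
assign_types <- function(records, anchor = default_motif_anchor()) {
  col <- if ("masked_protein" %in% names(records)) "masked_protein" else "protein"
  motifs <- vapply(records[[col]], extract_motif, character(1),
    anchor = anchor, USE.NAMES = FALSE)
  tibble(id = records$id, motif = motifs, type = motifs)
}

#' Summarize a type table
#'
#' @param type_table Output of [assign_types()].
#' @return Tibble with one row per type: `type`, `n_members`, `member_ids`.
#' @export
type_counts <- function(type_table) {
  type_table |>
    filter(!is.na(.data$type)) |>
    group_by(.data$type) |>
    summarise(n_members = n(),
      member_ids = list(sort(.data$id)), .groups = "drop") |>
    arrange(.data$type)
}

## --- distances and neighbour joining --------------------------------------

#' Pairwise p-distance between two aligned sequences
#'
#' Fraction of differing sites over valid columns; columns containing a gap
#' (`-`) or `X` in either sequence are excluded.
#'
#' @param a,b Aligned sequences of equal length.
#' @return Numeric in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  valid <- !(x %in% c("-", "X")) & !(y %in% c("-", "X"))
  if (!any(valid)) {
    abort("no valid columns between sequences", class = "vntrfam_distance_error")
  }
  sum(x[valid] != y[valid]) / sum(valid)
}

#' p-distance matrix over a set of aligned sequences
#'
#' @param seqs Named character vector, or tibble with `id` and a sequence
#'   column (`masked_protein`, `protein` or `seq`).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance_matrix <- function(seqs) {
  if (is.data.frame(seqs)) {
    col <- intersect(c("masked_protein", "protein", "seq"), names(seqs))[1]
    v <- stats::setNames(seqs[[col]], seqs$id)
  } else v <- seqs
  stopifnot(length(unique(nchar(v))) == 1)
  mat <- do.call(rbind, strsplit(toupper(unname(v)), ""))
  rownames(mat) <- names(v)
  p_dist_from_matrix(mat)
}

# vectorized p-distance over a character matrix (rows = sequences)
p_dist_from_matrix <- function(mat) {
  n <- nrow(mat)
  valid <- !(mat %in% c("-", "X"))
  dim(valid) <- dim(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2) return(d)
  for (i in 1:(n - 1)) {
    rows <- i:n
    neq <- sweep(mat[rows, , drop = FALSE], 2, mat[i, ], `!=`)
    vv <- sweep(valid[rows, , drop = FALSE], 2, valid[i, ], `&`)
    denom <- rowSums(vv)
    if (any(denom == 0)) {
      abort("no valid columns between sequences", class = "vntrfam_distance_error")
    }
    pd <- rowSums(neq & vv) / denom
    d[i, rows] <- d[rows, i] <- pd
  }
  diag(d) <- 0
  d
}

#' Neighbour-joining tree
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j} is joined (\eqn{R_i} = row sum,
#' \eqn{r} = current number of nodes), with the standard branch-length
#' formulas. Ties are broken by the lowest (i, j) index pair, making the
#' tree deterministic. Negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param d Symmetric distance matrix with dimnames (n >= 3).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("neighbour joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) || any(diag(d) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal",
      class = "vntrfam_distance_error")
  }
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # node bookkeeping in ape edge-matrix terms: tips 1..n, internals n+1, ...
  active <- seq_len(n)            # current cluster ids (tree node numbers)
  next_node <- 2L * n - 2L        # internal nodes numbered down from 2n-2
  edges <- matrix(0L, 0, 2); lens <- numeric(0)
  neg_clamped <- FALSE
  while (length(active) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    # lowest (i,j) among minima, scanning column-major upper triangle
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0 || lj < 0) neg_clamped <- TRUE
    li <- max(li, 0); lj <- max(lj, 0)
    new <- next_node; next_node <- next_node - 1L
    edges <- rbind(edges, c(new, active[i]), c(new, active[j]))
    lens <- c(lens, li, lj)
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d <- rbind(cbind(d[-c(i, j), -c(i, j), drop = FALSE], dn[-c(i, j)]),
               c(dn[-c(i, j)], 0))
    active <- c(active[-c(i, j)], new)
  }
  # final 3-star: closed-form branch lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) neg_clamped <- TRUE
  root <- n + 1L
  edges <- rbind(edges, c(root, active[1]), c(root, active[2]), c(root, active[3]))
  lens <- c(lens, max(la, 0), max(lb, 0), max(lc, 0))
  if (neg_clamped) warn("negative NJ branch length(s) clamped to 0")
  tree <- structure(list(
    edge = edges, edge.length = lens,
    Nnode = n - 2L, tip.label = labels
  ), class = "phylo", order = NULL)
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# canonical bipartition key for the edge above `node`: sorted tip labels of
# the side not containing the first tip
bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  out <- character(0)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  for (node in internal) {
    tips <- sort(tree$tip.label[tip_descendants(tree, node)])
    if (length(tips) <= 1 || length(tips) >= n - 1) next # trivial split
    if (tree$tip.label[1] %in% tips) {
      tips <- sort(setdiff(tree$tip.label, tips))
    }
    out <- c(out, paste(tips, collapse = "|"))
  }
  out
}

tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  stack <- node; tips <- integer(0)
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    tips <- c(tips, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  tips
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance NJ
#' tree per replicate, and reports the percentage of replicates containing
#' each internal bipartition of the original tree.
#'
#' @param seqs Named character vector (or tibble as in
#'   [p_distance_matrix()]) of equal-length aligned sequences.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; same seed gives identical supports.
#' @return Tibble with columns `bipartition` (pipe-joined tip labels of the
#'   smaller side) and `support` (percent, \[0, 100\]). Zero rows when
#'   `n_reps = 0`.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000, seed = 1) {
  if (is.data.frame(seqs)) {
    col <- intersect(c("masked_protein", "protein", "seq"), names(seqs))[1]
    seqs <- stats::setNames(seqs[[col]], seqs$id)
  }
  main <- nj_tree(p_distance_matrix(seqs))
  bp <- bipartitions(main)
  if (n_reps == 0 || length(bp) == 0) {
    return(tibble(bipartition = bp, support = numeric(length(bp))))
  }
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  ncol_aln <- ncol(mat)
  stopifnot(ncol_aln >= 2)
  counts <- stats::setNames(numeric(length(bp)), bp)
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    tree_b <- nj_tree(p_dist_from_matrix(mat[, cols, drop = FALSE]))
    hit <- intersect(bipartitions(tree_b), bp)
    counts[hit] <- counts[hit] + 1
  }
  tibble(bipartition = bp, support = 100 * unname(counts) / n_reps)
}

#' Build the family tree with bootstrap support
#'
#' Convenience wrapper: p-distance NJ tree over repeat-masked proteins plus
#' bootstrap supports, returned as a `family_tree` object with
#' [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()] methods.
#'
#' @param records Tibble with `id` and `masked_protein` (or `protein`)
#'   columns; sequences must be equal-length (the no-indel backbone
#'   alignment).
#' @param n_boot Bootstrap replicates (default 1000; 0 disables).
#' @param seed Seed for bootstrap resampling.
#' @return A `family_tree`: list with `tree` ([ape::phylo]), `support`
#'   (tibble), `n_taxa`.
#' @export
family_tree <- function(records, n_boot = 1000, seed = 1) {
  col <- intersect(c("masked_protein", "protein", "seq"), names(records))[1]
  seqs <- stats::setNames(records[[col]], records$id)
  tree <- nj_tree(p_distance_matrix(seqs))
  support <- bootstrap_support(seqs, n_reps = n_boot, seed = seed)
  structure(list(tree = tree, support = support, n_taxa = length(seqs)),
    class = "family_tree")
}

#' @export
print.family_tree <- function(x, ...) {
  cat(sprintf("<family_tree> %d taxa, %d internal bipartitions\n",
    x$n_taxa, nrow(x$support)))
  if (nrow(x$support) > 0) {
    cat(sprintf("  bootstrap support: median %.0f%%, range %.0f-%.0f%%\n",
      stats::median(x$support$support),
      min(x$support$support), max(x$support$support)))
  }
  invisible(x)
}

#' Write a family tree to Newick
#'
#' Bootstrap supports are attached as internal node labels.
#'
#' @param x A `family_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(x, path) {
  tree <- x$tree
  if (nrow(x$support) > 0) {
    n <- length(tree$tip.label)
    lab <- character(tree$Nnode)
    for (node in (n + 1):(n + tree$Nnode)) {
      tips <- sort(tree$tip.label[tip_descendants(tree, node)])
      if (tree$tip.label[1] %in% tips) tips <- sort(setdiff(tree$tip.label, tips))
      key <- paste(tips, collapse = "|")
      m <- match(key, x$support$bipartition)
      lab[node - n] <- if (!is.na(m)) sprintf("%.0f", x$support$support[m]) else ""
    }
    tree$node.label <- lab
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @method tidy family_tree
#' @export
tidy.family_tree <- function(x, ...) {
  tr <- x$tree
  n <- length(tr$tip.label)
  tibble(
    parent = tr$edge[, 1], node = tr$edge[, 2],
    branch_length = tr$edge.length,
    label = ifelse(tr$edge[, 2] <= n, tr$tip.label[tr$edge[, 2]], NA_character_),
    is_tip = tr$edge[, 2] <= n
  )
}

#' @method glance family_tree
#' @export
glance.family_tree <- function(x, ...) {
  tibble(
    n_taxa = x$n_taxa,
    n_internal_edges = nrow(x$support),
    total_branch_length = sum(x$tree$edge.length),
    median_support = if (nrow(x$support)) stats::median(x$support$support) else NA_real_
  )
}

#' @method autoplot family_tree
#' @export
autoplot.family_tree <- function(object, ...) {
  # simple unrooted-as-cladogram layout via ape coordinates
  tr <- object$tree
  n <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  ord <- ape::reorder.phylo(tr, "postorder")
  y <- numeric(n + tr$Nnode)
  y[seq_len(n)] <- seq_len(n)
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]
    kids <- ord$edge[ord$edge[, 1] == p, 2]
    y[p] <- mean(y[kids])
  }
  seg <- tibble(
    x = depth[tr$edge[, 1]], xend = depth[tr$edge[, 2]],
    y = y[tr$edge[, 2]], yend = y[tr$edge[, 2]]
  )
  ver <- tibble(
    x = depth[tr$edge[, 1]], xend = depth[tr$edge[, 1]],
    y = y[tr$edge[, 1]], yend = y[tr$edge[, 2]]
  )
  tips <- tibble(x = depth[seq_len(n)], y = y[seq_len(n)], label = tr$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = bind_rows(seg, ver),
      ggplot2::aes(x = .data$x, y = .data$y,
        xend = .data$xend, yend = .data$yend), linewidth = 0.3) +
    ggplot2::geom_text(data = tips,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = -0.05, size = 2.5) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.25))) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Neighbour-joining tree (p-distance, repeat-masked)")
}
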