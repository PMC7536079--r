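## End-to-end orchestration: generate (or read) a family, decompose repeat
## arrays, assign types, build the tree, catalogue patterns, infer slippage
## and splicing, compare against ground truth when available, and write all
## reports.

#' Run the full family analysis pipeline
#'
#' Stages: (optional) generate -> annotate -> decompose -> classify ->
#' catalog -> slippage -> splice -> truth comparison (when ground truth is
#' available). All randomness derives from `seed`; a rerun with the same
#' inputs is byte-identical.
#'
#' @param transcripts Tibble `id`, `seq` of cDNA/CDS sequences, or `NULL`
#'   when `generate` is given.
#' @param models Optional tibble `id`, `model` of gene models (enables the
#'   splice stage); transcripts may carry a `gene_id` column linking them to
#'   models.
#' @param generate Optional [family_config()]; when given, inputs are
#'   generated and ground truth is carried through to a recovery report.
#' @param out_dir Optional directory; when given, TSV/JSON/newick reports
#'   and a run manifest are written there.
#' @param n_boot Bootstrap replicates for the tree stage (default 100; 0
#'   disables support values).
#' @param min_identity Per-unit identity threshold for decomposition.
#' @param anchor Motif anchor, see [extract_motif()].
#' @param seed Seed for the bootstrap (and the generator, unless the config
#'   carries its own).
#' @return A `family_pipeline` list: `annotated`, `decomposed`, `types`,
#'   `type_summary`, `catalog`, `tree`, `slippage`, `splice`, `recovery`
#'   (NULL without truth), `manifest`.
#' @export
run_family_pipeline <- function(transcripts = NULL, models = NULL,
                                generate = NULL, out_dir = NULL,
                                n_boot = 100, min_identity = 0.8,
                                anchor = default_motif_anchor(),
                                seed = 1) {
  truth <- NULL
  fam <- NULL
  if (is.null(transcripts) && is.null(generate)) {
    abort("either transcripts or a generate config must be given",
      class = "vntrfam_config_error")
  }
  if (!is.null(generate)) {
    fam <- generate_family(generate)
    transcripts <- fam$transcripts
    models <- fam$models
    truth <- fam$truth
  }
  # annotate: ORF/UTR/protein arithmetic; splice variants may lack a clean
  # ORF and are excluded from the member-level stages
  annotated <- annotate_transcripts(transcripts)
  is_member <- if (!is.null(fam)) annotated$id %in% fam$members$id else
    !is.na(annotated$orf_len)
  members <- annotated[is_member & !is.na(annotated$orf_len), ]
  members$cds <- substr(members$seq, members$orf_start + 1,
    members$orf_start + members$orf_len)
  # decompose
  decomposed <- decompose_repeats(
    tibble(id = members$id, seq = members$cds), min_identity = min_identity)
  # mask + type; if a detected phase is off the codon frame (phase is
  # chosen by the tiling, not pinned to codons), round the repeat region to
  # the nearest codon boundary so the masked protein keeps its length
  masked <- vapply(seq_len(nrow(members)), function(i) {
    arr <- decomposed$array[[match(members$id[i], decomposed$id)]]
    tryCatch(mask_repeats(members$protein[i], arr), error = function(e) {
      aa_start <- round(arr$region_start / 3)
      aa_len <- sum(arr$unit_lengths) %/% 3
      prot <- members$protein[i]
      paste0(substr(prot, 1, aa_start),
             substr(prot, aa_start + aa_len + 1, nchar(prot)))
    })
  }, character(1))
  typed_input <- tibble(id = members$id, masked_protein = masked)
  types <- assign_types(typed_input, anchor = anchor)
  type_summary <- type_counts(types)
  # tree (needs equal-length masked proteins; skip otherwise with a warning)
  tree <- NULL
  if (nrow(members) >= 3 && length(unique(nchar(masked))) == 1) {
    tree <- family_tree(typed_input, n_boot = n_boot, seed = seed)
  } else if (nrow(members) >= 3) {
    warn("masked proteins are not equal-length; tree stage skipped (align first)")
  }
  # catalogue
  catalog <- catalog_patterns(decomposed)
  per_type <- per_type_patterns(decomposed, types)
  # slippage
  slippage <- scan_slippage(decomposed, types)
  # splice
  splice <- NULL
  if (!is.null(models)) {
    splice <- classify_splicing(models, transcripts)
  }
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- truth_compare(truth, list(decomposed = decomposed,
      types = types, slippage = slippage, splice = splice))
  }
  manifest <- tibble(
    stage = c("inputs", "decompose", "classify", "catalog", "slippage", "splice"),
    detail = c(
      sprintf("%d transcripts, %d members, seed %d", nrow(transcripts),
        nrow(members), as.integer(seed)),
      sprintf("%d arrays, copy numbers %s", nrow(decomposed),
        paste(range(decomposed$copy_number), collapse = "-")),
      sprintf("%d types, %d bootstrap reps", nrow(type_summary), n_boot),
      sprintf("%d unique patterns", catalog$n_patterns),
      sprintf("%d classified events", nrow(slippage)),
      if (is.null(splice)) "skipped (no gene models)" else
        sprintf("%d events", nrow(splice))))
  res <- structure(list(
    annotated = annotated, decomposed = decomposed, types = types,
    type_summary = type_summary, catalog = catalog, per_type = per_type,
    tree = tree, slippage = slippage, splice = splice,
    recovery = recovery, manifest = manifest
  ), class = "family_pipeline")
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir, fam = fam)
  res
}

#' @export
print.family_pipeline <- function(x, ...) {
  cat("<family_pipeline>\n")
  for (k in seq_len(nrow(x$manifest))) {
    cat(sprintf("  %-10s %s\n", x$manifest$stage[k], x$manifest$detail[k]))
  }
  if (!is.null(x$recovery)) {
    cat("  recovery:\n")
    for (k in seq_len(nrow(x$recovery))) {
      cat(sprintf("    %s/%s: %.3f\n", x$recovery$stage[k],
        x$recovery$metric[k], x$recovery$fraction[k]))
    }
  }
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits `decomposition.tsv`, `types.tsv`, `patterns.tsv`,
#' `patterns_by_type.tsv`, `slippage.tsv`, `splice.tsv`, `tree.nwk`,
#' `recovery.tsv` (when truth was available), `arrays.json` and
#' `manifest.tsv`; logs never mix with data.
#'
#' @param res A `family_pipeline` result.
#' @param dir Output directory.
#' @param fam Optional `synthetic_family` to also write (under `dir/input/`).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(res, dir, fam = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) readr::write_tsv(df, file.path(dir, name))
  tsv(select(res$decomposed, -"array"), "decomposition.tsv")
  tsv(res$types, "types.tsv")
  tsv(res$catalog$patterns |>
        mutate(member_ids = vapply(.data$member_ids, paste,
          character(1), collapse = ",")), "patterns.tsv")
  by_type <- res$per_type |>
    mutate(patterns = purrr::map(.data$catalog, function(cc)
      cc$patterns |> mutate(member_ids = vapply(.data$member_ids, paste,
        character(1), collapse = ",")))) |>
    select("type", "patterns") |>
    tidyr::unnest("patterns")
  tsv(by_type, "patterns_by_type.tsv")
  tsv(select(res$slippage, -"event"), "slippage.tsv")
  if (!is.null(res$splice)) tsv(res$splice, "splice.tsv")
  if (!is.null(res$tree)) write_tree_newick(res$tree, file.path(dir, "tree.nwk"))
  if (!is.null(res$recovery)) tsv(res$recovery, "recovery.tsv")
  arrays <- lapply(seq_len(nrow(res$decomposed)), function(i) {
    a <- res$decomposed$array[[i]]
    list(id = res$decomposed$id[i], units = a$units,
      flank5 = a$flank5, flank3 = a$flank3, consensus = a$consensus)
  })
  jsonlite::write_json(arrays, file.path(dir, "arrays.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv(res$manifest, "manifest.tsv")
  if (!is.null(fam)) write_family(fam, file.path(dir, "input"))
  invisible(dir)
}
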