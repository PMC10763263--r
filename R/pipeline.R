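# End-to-end selection: enumerate -> score -> rank -> consensus ->
# expression -> clonality -> tier, with a run manifest recording every
# effective parameter and the survivor count at each stage.

.default_config <- function() {
  list(k = 9, long_len = 25,
       min_reads = 5, min_vaf = 0.2,
       consensus_policy = "any", consensus_cutoff = 2,
       keep_unmatched = FALSE,
       delta_big = 1, delta_small = 0.5,
       exposure_threshold = 4, anchors = NULL,
       seed = NULL)
}

#' Assemble a run configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected so typos cannot silently revert a threshold to its default.
#'
#' @param config Named list (or path to a YAML file) of settings; see
#'   [select_neoantigens()] for the meaning of each key.
#' @return Named list with every effective parameter.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

#' Collapse scored windows to one candidate per variant
#'
#' All enumerated windows of a variant compete; the top-ranked window (best
#' NOAH score, deterministic tie-breaks) becomes the variant's candidate
#' row. For a frameshift the reported candidate is its long peptide, which
#' inherits the score, allele, external ranks and offset of the variant's
#' best 9-mer tile (kept in `tile_peptide`).
#'
#' @param records Ranked score records (after [rank_candidates()]).
#' @return One row per variant, re-ranked among candidates.
#' @export
candidate_table <- function(records) {
  if (nrow(records) == 0) {
    records$tile_peptide <- character(0)
    return(records)
  }
  out <- lapply(split(records, records$variant_id), function(g) {
    g <- g[order(g$noah_rank), , drop = FALSE]
    if (any(g$origin == "fs_long")) {
      long <- g[g$origin == "fs_long", , drop = FALSE][1, ]
      tiles <- g[g$origin == "fs_9mer", , drop = FALSE]
      if (nrow(tiles) > 0) {
        best <- tiles[1, ]
        long$allele <- best$allele
        long$noah_score <- best$noah_score
        long$mut_offset <- best$mut_offset
        long$tile_peptide <- best$mut_peptide
        for (col in .rank_columns(records)) long[[col]] <- best[[col]]
      } else {
        long$tile_peptide <- NA_character_
      }
      long
    } else {
      best <- g[1, , drop = FALSE]
      best$tile_peptide <- NA_character_
      best
    }
  })
  out <- do.call(rbind, out)
  rank_candidates(out)
}

#' Run the full neoantigen selection pipeline
#'
#' Enumerates candidate peptides from the variant table, scores every
#' window against the model, collapses to one candidate per variant,
#' attaches external percentile ranks, applies the consensus, expression
#' (`rna_reads > min_reads`) and clonality (`vaf > min_vaf`) filters, and
#' classifies survivors into tiers 1-4. Candidates failing every tier rule
#' are kept, flagged unassigned.
#'
#' @param variants data.frame from [parse_variant_table()].
#' @param proteins Named character vector from [read_proteins()].
#' @param model A fitted `noah` model (or path to a model JSON).
#' @param contact_map The `contact_map` used for tier anchors/exposure;
#'   default [default_contact_map()]. Must cover the model's alleles.
#' @param external Optional external rank table (data.frame or TSV path).
#' @param config Named list or YAML path of settings (see [run_config()]):
#'   `k`, `long_len`, `min_reads`, `min_vaf`, `consensus_policy`,
#'   `consensus_cutoff`, `keep_unmatched`, `delta_big`, `delta_small`,
#'   `exposure_threshold`, `anchors`, `seed`.
#' @return An object of class `neoantigen_selection`: list with
#'   `candidates` (final table sorted by tier then rank, unassigned last)
#'   and `manifest` (effective parameters plus survivor counts per stage).
#' @export
select_neoantigens <- function(variants, proteins, model,
                               contact_map = default_contact_map(),
                               external = NULL, config = list()) {
  cfg <- run_config(config)
  if (is.character(model)) model <- read_noah(model)
  stopifnot(inherits(model, "noah"), inherits(contact_map, "contact_map"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  counts <- list(variants = nrow(variants))
  pairs <- enumerate_peptides(variants, proteins, k = cfg$k,
                              long_len = cfg$long_len)
  counts$enumerated <- nrow(pairs)

  rec <- score_candidates(model, pairs, variants)
  counts$scored <- sum(!is.na(rec$noah_score))
  if (!is.null(external)) rec <- attach_external_ranks(rec, external)
  rec <- rank_candidates(rec)

  cand <- candidate_table(rec)
  counts$candidates <- nrow(cand)

  cand <- filter_consensus(cand, policy = cfg$consensus_policy,
                           rank_cutoff = cfg$consensus_cutoff,
                           keep_unmatched = cfg$keep_unmatched)
  counts$post_consensus <- nrow(cand)
  cand <- filter_expression(cand, min_reads = cfg$min_reads)
  counts$post_expression <- nrow(cand)
  cand <- filter_clonality(cand, min_vaf = cfg$min_vaf)
  counts$post_clonality <- nrow(cand)

  cand <- if (nrow(cand) > 0) rank_candidates(cand) else cand
  cand <- classify_tiers(cand, contact_map, anchors = cfg$anchors,
                         exposure_threshold = cfg$exposure_threshold,
                         delta_big = cfg$delta_big,
                         delta_small = cfg$delta_small,
                         consensus_cutoff = cfg$consensus_cutoff)
  counts$tiered <- sum(!is.na(cand$tier))
  if (nrow(cand) > 0) {
    o <- order(is.na(cand$tier), cand$tier, cand$noah_rank)
    cand <- cand[o, , drop = FALSE]
    rownames(cand) <- NULL
  }
  structure(list(candidates = cand,
                 manifest = list(params = cfg[setdiff(names(cfg), "anchors")],
                                 anchors = cfg$anchors,
                                 counts = counts,
                                 alleles = model$alleles,
                                 created = format(Sys.time(), tz = "UTC"))),
            class = "neoantigen_selection")
}

#' @export
print.neoantigen_selection <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("Neoantigen selection:", cnt$variants, "variants ->",
      cnt$candidates, "candidates ->", cnt$post_clonality,
      "after filters\n")
  cat("  stage counts:",
      paste(sprintf("%s=%d", names(cnt), unlist(cnt)), collapse = ", "),
      "\n")
  if (nrow(x$candidates) > 0) {
    tt <- table(factor(x$candidates$tier, levels = 1:4), useNA = "ifany")
    cat("  tiers:", paste(sprintf("T%s=%d", names(tt), as.integer(tt)),
                          collapse = ", "),
        " unassigned =", sum(is.na(x$candidates$tier)), "\n")
  }
  invisible(x)
}

#' Write the selection table and its run manifest
#'
#' @param x A `neoantigen_selection`.
#' @param path Output TSV path; the JSON manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "neoantigen_selection"))
  utils::write.table(x$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  jsonlite::write_json(x$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
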