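# Candidate scoring, external-predictor consensus, expression and clonality
# filters, and the four-tier classification.

#' Score enumerated peptide pairs against a fitted model
#'
#' Every short peptide (length k) is scored against each requested allele;
#' the best-scoring allele is retained per record, together with the
#' wild-type counterpart's score under that same allele and their
#' difference. Frameshift long peptides are not scored directly (the model
#' is fixed-length); they inherit a score when candidates are collapsed per
#' variant (see [candidate_table()]).
#'
#' @param fit A fitted `noah` model.
#' @param pairs data.frame from [enumerate_peptides()].
#' @param variants data.frame from [parse_variant_table()]; supplies `gene`,
#'   `wt_aa`, `mut_aa`, `rna_reads` and `vaf` per record.
#' @param alleles Alleles to score against; default all alleles of the model.
#' @return data.frame of score records: the pair columns plus `gene`,
#'   `wt_aa`, `mut_aa`, `allele`, `noah_score`, `wt_score`, `score_delta`,
#'   `rna_reads`, `vaf`, and empty external rank columns `netmhcpan4`,
#'   `mhcflurry`.
#' @export
score_candidates <- function(fit, pairs, variants,
                             alleles = names(fit$allele_weights)) {
  stopifnot(inherits(fit, "noah"))
  vcols <- variants[match(pairs$variant_id, variants$variant_id),
                    c("gene", "wt_aa", "mut_aa", "rna_reads", "vaf"),
                    drop = FALSE]
  rec <- cbind(pairs, vcols)
  rec$allele <- rep(NA_character_, nrow(rec))
  rec$noah_score <- rep(NA_real_, nrow(rec))
  rec$wt_score <- rep(NA_real_, nrow(rec))
  short <- which(rec$length == fit$k)
  if (length(short)) {
    sc <- sapply(alleles, function(a)
      unname(predict(fit, rec$mut_peptide[short], allele = a)))
    sc <- matrix(sc, nrow = length(short), dimnames = list(NULL, alleles))
    best <- max.col(sc, ties.method = "first")
    rec$allele[short] <- alleles[best]
    rec$noah_score[short] <- sc[cbind(seq_along(short), best)]
    has_wt <- short[!is.na(rec$wt_peptide[short])]
    if (length(has_wt)) {
      rec$wt_score[has_wt] <- vapply(has_wt, function(i)
        unname(predict(fit, rec$wt_peptide[i], allele = rec$allele[i])),
        numeric(1))
    }
  }
  rec$score_delta <- rec$noah_score - rec$wt_score
  rec$netmhcpan4 <- rep(NA_real_, nrow(rec))
  rec$mhcflurry <- rep(NA_real_, nrow(rec))
  rownames(rec) <- NULL
  rec
}

#' Attach external predictor percentile ranks
#'
#' Joins NetMHCpan-4/MHCflurry style percentile ranks onto score records by
#' (peptide, allele). Lower rank means stronger predicted binding. Unmatched
#' records keep `NA` ranks and are retained; the number matched per
#' predictor is reported in attribute `"matched"`.
#'
#' @param records data.frame from [score_candidates()].
#' @param table data.frame with columns `peptide`, `allele`, `predictor`,
#'   `percentile_rank` (or a path to such a TSV). Duplicate
#'   (peptide, allele, predictor) rows with conflicting ranks are an error.
#' @return The records with the predictor columns filled where matched.
#' @export
attach_external_ranks <- function(records, table) {
  if (is.character(table)) table <- read_external_table(table)
  need <- c("peptide", "allele", "predictor", "percentile_rank")
  if (!all(need %in% names(table)))
    stop("external table must have columns ", paste(need, collapse = ", "))
  if (any(table$percentile_rank < 0 | table$percentile_rank > 100,
          na.rm = TRUE))
    stop("percentile ranks must lie in [0, 100]")
  key <- paste(table$peptide, table$allele, table$predictor, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    if (any(table$percentile_rank[dup] != table$percentile_rank[first]))
      stop("duplicate (peptide, allele) rows with conflicting ranks")
    table <- table[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  matched <- c()
  for (pred in unique(table$predictor)) {
    sub <- table[table$predictor == pred, , drop = FALSE]
    idx <- match(paste(records$mut_peptide, records$allele, sep = "\r"),
                 paste(sub$peptide, sub$allele, sep = "\r"))
    if (!pred %in% names(records)) records[[pred]] <- NA_real_
    records[[pred]] <- ifelse(is.na(idx), records[[pred]],
                              sub$percentile_rank[idx])
    matched[pred] <- sum(!is.na(idx))
  }
  attr(records, "matched") <- matched
  records
}

#' Read an external predictor rank table
#'
#' @param path TSV with columns `peptide`, `allele`, `predictor`,
#'   `percentile_rank`.
#' @return data.frame.
#' @export
read_external_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  tab$percentile_rank <- as.numeric(tab$percentile_rank)
  tab
}

.rank_columns <- function(records) {
  known <- c("netmhcpan4", "mhcflurry")
  extra <- setdiff(names(records), c(
    "variant_id", "mut_peptide", "wt_peptide", "mut_offset", "length",
    "origin", "gene", "wt_aa", "mut_aa", "allele", "noah_score", "wt_score",
    "score_delta", "rna_reads", "vaf", "noah_rank", "tier", "anchor_hit",
    "exposed_hit", "physchem_class", "reasons", "tile_peptide"))
  unique(c(intersect(known, names(records)), extra))
}

#' Consensus filter over external predictor ranks
#'
#' Keeps records whose available external percentile ranks pass
#' `rank <= rank_cutoff` under the chosen policy: `"any"` requires at least
#' one passing predictor, `"all"` requires every available one to pass.
#' Records with no external rank at all are dropped unless
#' `keep_unmatched = TRUE` under the `"any"` policy.
#'
#' @param records Score records with external rank columns attached.
#' @param policy `"any"` (default) or `"all"`.
#' @param rank_cutoff Percentile-rank cutoff; default 2.
#' @param keep_unmatched Keep records with no external ranks (policy
#'   `"any"` only); default `FALSE`.
#' @return The surviving records.
#' @export
filter_consensus <- function(records, policy = c("any", "all"),
                             rank_cutoff = 2, keep_unmatched = FALSE) {
  policy <- match.arg(policy)
  if (nrow(records) == 0) return(records)
  cols <- .rank_columns(records)
  ranks <- as.matrix(records[, cols, drop = FALSE])
  n_avail <- rowSums(!is.na(ranks))
  n_pass <- rowSums(ranks <= rank_cutoff, na.rm = TRUE)
  keep <- if (policy == "any") {
    ifelse(n_avail == 0, keep_unmatched, n_pass >= 1)
  } else {
    n_avail > 0 & n_pass == n_avail
  }
  out <- records[as.logical(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression filter
#'
#' Keeps records supported by strictly more than `min_reads` RNA reads
#' (default 5, i.e. the "more than 5 reads" rule: 6 passes, 5 does not).
#'
#' @param records Score records with an `rna_reads` column.
#' @param min_reads Strict lower bound; default 5.
#' @return The surviving records.
#' @export
filter_expression <- function(records, min_reads = 5) {
  out <- records[records$rna_reads > min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clonality filter
#'
#' Keeps records whose variant allele frequency is strictly greater than
#' `min_vaf` (default 0.2; for a heterozygous variant this corresponds to
#' roughly 0.4 of the tumor cells carrying it).
#'
#' @param records Score records with a `vaf` column.
#' @param min_vaf Strict lower bound; default 0.2.
#' @return The surviving records.
#' @export
filter_clonality <- function(records, min_vaf = 0.2) {
  out <- records[records$vaf > min_vaf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-allele anchor positions
#'
#' Anchor positions are the peptide positions buried in the MHC groove whose
#' identity dominates binding. Defaults are derived from the contact map as
#' the two positions with the highest contact counts (ties to the lower
#' position); entries of `override` replace the derived set per allele
#' (e.g. the canonical H2-Db P5/P9 and H2-Kb P5/P8).
#'
#' @param map A `contact_map`.
#' @param override Named list of integer vectors.
#' @return Named list of anchor position vectors per allele.
#' @export
anchor_positions <- function(map, override = NULL) {
  out <- lapply(map$alleles, function(pockets) {
    cc <- nchar(pockets)
    sort(order(-cc, seq_along(cc))[1:2])
  })
  for (a in names(override)) out[[a]] <- as.integer(override[[a]])
  out
}

#' Per-allele solvent-exposed positions
#'
#' Positions with fewer MHC contacts than `exposure_threshold` are classed
#' solvent-exposed (available to the TCR).
#'
#' @param map A `contact_map`.
#' @param exposure_threshold Minimum contact count for a buried position;
#'   default 4.
#' @return Named list of exposed position vectors per allele.
#' @export
exposed_positions <- function(map, exposure_threshold = 4) {
  lapply(map$alleles, function(pockets)
    which(nchar(pockets) < exposure_threshold))
}

#' Classify surviving candidates into tiers 1-4
#'
#' First-match-wins precedence 4 -> 1 -> 2 -> 3:
#' \describe{
#'   \item{Tier 4}{frameshift-derived candidates (entirely novel sequence).}
#'   \item{Tier 1}{mutation at an MHC anchor position with
#'     `score_delta >= delta_big` -- predicted to increase binding relative
#'     to the wild type.}
#'   \item{Tier 2}{external consensus passes (`best rank <= consensus_cutoff`),
#'     mutation at a solvent-exposed (TCR-facing) position, and a drastic
#'     physicochemical change (e.g. charge reversal, polar to aliphatic).}
#'   \item{Tier 3}{binding similar to wild type (`|score_delta| <=
#'     delta_small`) with a moderate or conservative change at an exposed
#'     position.}
#' }
#' Records matching no rule are flagged `NA` (unassigned) but retained.
#'
#' @param records Filtered score records (missense records must carry
#'   `wt_score`).
#' @param map The `contact_map` used to derive anchors and exposure.
#' @param anchors Named list of anchor positions; default
#'   [anchor_positions()] of `map` with no override.
#' @param exposure_threshold Contact count below which a position is
#'   exposed; default 4.
#' @param delta_big Minimum score gain for Tier 1; default 1 (log2 units).
#' @param delta_small Maximum |score change| for Tier 3; default 0.5.
#' @param consensus_cutoff Best external rank required by Tier 2; default 2.
#' @param physchem A [physchem_table()].
#' @return The records with columns `tier` (integer, `NA` = unassigned),
#'   `anchor_hit`, `exposed_hit`, `physchem_class` and `reasons` (the rules
#'   evaluated, in order, with their outcomes).
#' @export
classify_tiers <- function(records, map, anchors = NULL,
                           exposure_threshold = 4, delta_big = 1,
                           delta_small = 0.5, consensus_cutoff = 2,
                           physchem = physchem_table()) {
  if (is.null(anchors)) anchors <- anchor_positions(map)
  exposed <- exposed_positions(map, exposure_threshold)
  n <- nrow(records)
  records$tier <- rep(NA_integer_, n)
  records$anchor_hit <- rep(FALSE, n)
  records$exposed_hit <- rep(FALSE, n)
  records$physchem_class <- rep(NA_character_, n)
  records$reasons <- rep("", n)
  if (n == 0) return(records)
  rank_cols <- .rank_columns(records)
  for (i in seq_len(n)) {
    r <- records[i, ]
    reasons <- character(0)
    if (r$origin %in% c("fs_9mer", "fs_long")) {
      records$tier[i] <- 4L
      records$reasons[i] <- "tier4:frameshift"
      next
    }
    reasons <- c(reasons, "tier4:not-frameshift")
    if (is.na(r$wt_score))
      stop("missense record ", r$variant_id, " lacks a wild-type score")
    a_hit <- r$mut_offset %in% anchors[[r$allele]]
    e_hit <- r$mut_offset %in% exposed[[r$allele]]
    pclass <- classify_physchem(r$wt_aa, r$mut_aa, physchem)
    records$anchor_hit[i] <- a_hit
    records$exposed_hit[i] <- e_hit
    records$physchem_class[i] <- pclass
    ranks <- unlist(r[rank_cols])
    best_rank <- if (all(is.na(ranks))) Inf else min(ranks, na.rm = TRUE)
    if (a_hit && r$score_delta >= delta_big) {
      records$tier[i] <- 1L
      records$reasons[i] <- paste(c(reasons, "tier1:anchor+delta_big"),
                                  collapse = ";")
      next
    }
    reasons <- c(reasons, sprintf("tier1:%s", if (!a_hit) "not-anchor"
                                  else "delta-below-big"))
    if (best_rank <= consensus_cutoff && e_hit && pclass == "drastic") {
      records$tier[i] <- 2L
      records$reasons[i] <- paste(
        c(reasons, "tier2:exposed+drastic+consensus"), collapse = ";")
      next
    }
    reasons <- c(reasons, "tier2:no")
    if (abs(r$score_delta) <= delta_small && e_hit &&
        pclass %in% c("moderate", "conservative")) {
      records$tier[i] <- 3L
      records$reasons[i] <- paste(c(reasons, "tier3:exposed+similar-binding"),
                                  collapse = ";")
      next
    }
    records$reasons[i] <- paste(c(reasons, "tier3:no", "unassigned"),
                                collapse = ";")
  }
  records
}
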