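# Synthetic-data generators. Every input the pipeline consumes can be
# produced here from a seed: a planted ground-truth weight matrix with its
# contact map, qualitative binding records drawn from it, somatic variant
# cohorts with a designed fate at each filter, and external percentile-rank
# tables correlated with the model's scores at a chosen level. All
# generators are pure functions of (seed, parameters).

#' Generate a planted ground-truth position weight matrix
#'
#' Builds a pool of mutually dissimilar pocket environments (pairwise
#' similarity kept below `separation`), assigns one to each
#' (allele, position), and draws a zero-mean weight vector per environment.
#' The second allele duplicates the first allele's pocket assignment so
#' that environment clustering has a planted merge to recover.
#'
#' @param seed Integer seed.
#' @param alleles Allele names; at least 2. Default three synthetic mouse
#'   class I alleles; the first two share identical pockets.
#' @param k Peptide length; default 9.
#' @param weight_scale Standard deviation of the planted weights; 0 gives
#'   an all-zero model under which every peptide scores 0.
#' @param n_envs Pocket pool size; default 8.
#' @return Object of class `planted_model`: list with `k`, `alleles`,
#'   `env_pockets` (pool), `env_of` (allele x position index into the
#'   pool), `weights` (per pool entry, named 20-vector), `seed`,
#'   `weight_scale`.
#' @export
simulate_planted_model <- function(seed, alleles = c("H2-Kb", "H2-Dd",
                                                     "H2-Db"),
                                   k = 9, weight_scale = 1, n_envs = 8) {
  stopifnot(length(alleles) >= 2, weight_scale >= 0, n_envs >= 2)
  set.seed(seed)
  S <- residue_similarity_matrix()
  pool <- character(0)
  sizes <- c(0, rep(c(2, 5, 6, 7), length.out = n_envs - 1))
  for (s in sizes) {
    for (attempt in 1:200) {
      cand <- paste(sample(AA_STANDARD, s, replace = TRUE), collapse = "")
      seps <- vapply(pool, function(p) pocket_similarity(cand, p, S),
                     numeric(1))
      if (length(seps) == 0 || max(seps) < 0.55) break
      cand <- NA_character_
    }
    if (is.na(cand))
      stop("could not build a separated pocket pool; lower n_envs")
    pool <- c(pool, cand)
  }
  env_of <- matrix(sample.int(n_envs, length(alleles) * k, replace = TRUE),
                   nrow = length(alleles), dimnames = list(alleles, NULL))
  env_of[2, ] <- env_of[1, ]  # the designated duplicate-pocket pair
  weights <- lapply(seq_len(n_envs), function(e)
    stats::setNames(stats::rnorm(20, 0, weight_scale), AA_STANDARD))
  structure(list(k = k, alleles = alleles, env_pockets = pool,
                 env_of = env_of, weights = weights, seed = seed,
                 weight_scale = weight_scale),
            class = "planted_model")
}

#' Contact map of a planted model
#'
#' @param model A `planted_model`.
#' @return The `contact_map` implied by the planted pocket assignment.
#' @export
planted_contact_map <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  contact_map(model$k, stats::setNames(lapply(model$alleles, function(a)
    model$env_pockets[model$env_of[a, ]]), model$alleles))
}

#' True scores under a planted model
#'
#' @param model A `planted_model`.
#' @param peptides Character vector of length-k peptides.
#' @param allele One of the model's alleles.
#' @return Numeric vector of planted (ground-truth) scores.
#' @export
planted_scores <- function(model, peptides, allele) {
  stopifnot(inherits(model, "planted_model"),
            allele %in% model$alleles)
  res <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                ncol = model$k, byrow = TRUE)
  envs <- model$env_of[allele, ]
  contrib <- matrix(0, nrow = nrow(res), ncol = model$k)
  for (p in seq_len(model$k))
    contrib[, p] <- model$weights[[envs[p]]][res[, p]]
  rowSums(contrib)
}

#' Sample qualitative binding records from a planted model
#'
#' Peptides are drawn uniformly, assigned a uniform random allele, and
#' labelled binder when their planted score exceeds the sample median (so
#' classes stay balanced); labels are then flipped independently with
#' probability `noise_rate`. The planted score and flip indicator are
#' returned in a sidecar, never in the records themselves.
#'
#' @param model A `planted_model`.
#' @param n Number of records.
#' @param noise_rate Label flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List with `records` (data.frame `peptide`, `allele`, `label`)
#'   and `truth` (sidecar data.frame adding `true_score`, `clean_label`,
#'   `flipped`).
#' @export
sample_binding_records <- function(model, n, noise_rate = 0.1, seed = 1) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5)
  set.seed(seed)
  pep <- random_peptides(n, model$k)
  al <- sample(model$alleles, n, replace = TRUE)
  sc <- vapply(seq_len(n), function(i)
    planted_scores(model, pep[i], al[i]), numeric(1))
  clean <- ifelse(sc > stats::median(sc), "binder", "nonbinder")
  flip <- stats::runif(n) < noise_rate
  lab <- ifelse(flip, ifelse(clean == "binder", "nonbinder", "binder"),
                clean)
  list(records = data.frame(peptide = pep, allele = al, label = lab,
                            stringsAsFactors = FALSE),
       truth = data.frame(peptide = pep, allele = al, true_score = sc,
                          clean_label = clean, flipped = flip,
                          stringsAsFactors = FALSE))
}

#' Sample structural (crystal-structure) positives from a planted model
#'
#' Emulates peptides observed bound in structures: the best-scoring decile
#' of a random draw, each tagged with a synthetic structure id.
#'
#' @param model A `planted_model`.
#' @param n Number of structural records.
#' @param seed Integer seed.
#' @return data.frame with `peptide`, `allele`, `source_id`.
#' @export
simulate_structural_records <- function(model, n, seed = 1) {
  set.seed(seed)
  m <- 10 * n
  pep <- random_peptides(m, model$k)
  al <- sample(model$alleles, m, replace = TRUE)
  sc <- vapply(seq_len(m), function(i)
    planted_scores(model, pep[i], al[i]), numeric(1))
  top <- order(-sc)[seq_len(n)]
  data.frame(peptide = pep[top], allele = al[top],
             source_id = sprintf("SYNTH-PDB-%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Generate a designed somatic variant cohort
#'
#' Emulates a tumor mutanome feed: one random wild-type protein per
#' variant, missense or frameshift changes, and RNA read counts / allele
#' frequencies realizing a per-variant design of which filters the variant
#' passes. Each designed failure is single-cause (a variant failing
#' expression passes clonality and consensus, and so on), so per-stage
#' survivor counts follow exactly from the design.
#'
#' The default design (60 SNVs + 3 frameshifts; 4 SNVs failing consensus,
#' 4 failing expression, 4 failing clonality) yields a 51-candidate list
#' with 3 frameshift-derived long peptides.
#'
#' @param seed Integer seed.
#' @param n_snv,n_fs Number of missense and frameshift variants.
#' @param pass_design Optional data.frame with logical columns
#'   `consensus_pass`, `expr_pass`, `vaf_pass` (one row per variant, SNVs
#'   first); default as above.
#' @return List with `variants` (validated variant table), `proteins`
#'   (named character vector), `design` (the realized design with
#'   `variant_id`), and `expected_counts` (survivors after each stage,
#'   assuming the pipeline's consensus -> expression -> clonality order).
#' @export
simulate_variant_cohort <- function(seed, n_snv = 60, n_fs = 3,
                                    pass_design = NULL) {
  set.seed(seed)
  n <- n_snv + n_fs
  if (is.null(pass_design)) {
    pass_design <- data.frame(consensus_pass = rep(TRUE, n),
                              expr_pass = TRUE, vaf_pass = TRUE)
    if (n_snv >= 12) {
      pass_design$consensus_pass[1:4] <- FALSE
      pass_design$expr_pass[5:8] <- FALSE
      pass_design$vaf_pass[9:12] <- FALSE
    }
  }
  stopifnot(nrow(pass_design) == n,
            all(c("consensus_pass", "expr_pass", "vaf_pass") %in%
                  names(pass_design)))
  multi_fail <- rowSums(!pass_design[, c("consensus_pass", "expr_pass",
                                         "vaf_pass")]) > 1
  if (any(multi_fail))
    stop("contradictory design: variants must fail at most one filter")

  proteins <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- if (i <= n_snv) "missense" else "frameshift"
    L <- sample(30:60, 1)
    prot <- paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
    proteins[i] <- prot
    reads <- if (pass_design$expr_pass[i]) sample(6:200, 1) else
      sample(0:5, 1)
    vaf <- if (pass_design$vaf_pass[i])
      round(stats::runif(1, 0.25, 0.9), 3) else
      round(stats::runif(1, 0.01, 0.2), 3)
    if (kind == "missense") {
      pos <- sample(2:(L - 1), 1)
      wt <- substr(prot, pos, pos)
      mut <- sample(setdiff(AA_STANDARD, wt), 1)
      rows[[i]] <- data.frame(
        variant_id = sprintf("v%03d", i), gene = sprintf("GENE%03d", i),
        protein_id = sprintf("P%03d", i), kind = "missense",
        protein_pos = pos, wt_aa = wt, mut_aa = mut, novel_seq = "",
        rna_reads = reads, vaf = vaf, stringsAsFactors = FALSE)
    } else {
      pos <- sample(12:(L - 10), 1)
      novel <- paste(sample(AA_STANDARD, sample(12:20, 1), replace = TRUE),
                     collapse = "")
      rows[[i]] <- data.frame(
        variant_id = sprintf("v%03d", i), gene = sprintf("GENE%03d", i),
        protein_id = sprintf("P%03d", i), kind = "frameshift",
        protein_pos = pos, wt_aa = "", mut_aa = "", novel_seq = novel,
        rna_reads = reads, vaf = vaf, stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  names(proteins) <- variants$protein_id
  design <- cbind(variant_id = variants$variant_id, pass_design)

  alive <- rep(TRUE, n)
  counts <- list(candidates = n)
  alive <- alive & pass_design$consensus_pass
  counts$post_consensus <- sum(alive)
  alive <- alive & pass_design$expr_pass
  counts$post_expression <- sum(alive)
  alive <- alive & pass_design$vaf_pass
  counts$post_clonality <- sum(alive)
  counts$frameshift_survivors <- sum(alive[variants$kind == "frameshift"])

  list(variants = variants, proteins = proteins, design = design,
       expected_counts = counts)
}

#' External rank table realizing a cohort design
#'
#' Assigns percentile ranks so that every peptide of a consensus-passing
#' variant passes `rank <= cutoff` under both predictors and every peptide
#' of a failing variant fails both -- whichever window later becomes the
#' variant's candidate, its consensus fate matches the design.
#'
#' @param records Scored records (from [score_candidates()]).
#' @param design Design data.frame from [simulate_variant_cohort()].
#' @param seed Integer seed.
#' @param cutoff The consensus cutoff the design targets; default 2.
#' @param predictors Predictor names; default NetMHCpan-4 and MHCflurry
#'   style columns.
#' @return Long-format data.frame `peptide`, `allele`, `predictor`,
#'   `percentile_rank`.
#' @export
simulate_design_external <- function(records, design, seed = 1, cutoff = 2,
                                     predictors = c("netmhcpan4",
                                                    "mhcflurry")) {
  set.seed(seed)
  short <- records[!is.na(records$allele), , drop = FALSE]
  key <- !duplicated(paste(short$mut_peptide, short$allele, sep = "\r"))
  short <- short[key, , drop = FALSE]
  pass <- design$consensus_pass[match(short$variant_id, design$variant_id)]
  out <- lapply(predictors, function(pred) {
    rank <- ifelse(pass,
                   round(stats::runif(nrow(short), 0.05, cutoff - 0.1), 3),
                   round(stats::runif(nrow(short), cutoff + 0.5, 60), 3))
    data.frame(peptide = short$mut_peptide, allele = short$allele,
               predictor = pred, percentile_rank = rank,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' External rank table correlated with the model's scores
#'
#' Emulates an independent predictor whose ranking agrees with the NOAH
#' scores at a chosen level: `agreement = 1` reproduces the NOAH order
#' exactly, `agreement = 0` is independent of it.
#'
#' @param records Scored records with `mut_peptide`, `allele`,
#'   `noah_score`.
#' @param agreement Correlation knob in `[0, 1]`.
#' @param seed Integer seed.
#' @param predictor Predictor name for the output column.
#' @return Long-format data.frame `peptide`, `allele`, `predictor`,
#'   `percentile_rank` (ties broken deterministically).
#' @export
simulate_external_ranks <- function(records, agreement, seed = 1,
                                    predictor = "netmhcpan4") {
  stopifnot(agreement >= 0, agreement <= 1)
  set.seed(seed)
  short <- records[!is.na(records$noah_score), , drop = FALSE]
  short <- short[!duplicated(paste(short$mut_peptide, short$allele,
                                   sep = "\r")), , drop = FALSE]
  n <- nrow(short)
  z <- as.numeric(scale(short$noah_score))
  if (any(!is.finite(z))) z <- rep(0, n)
  latent <- agreement * z + (1 - agreement) * stats::rnorm(n)
  pr <- 100 * rank(-latent, ties.method = "first") / n
  data.frame(peptide = short$mut_peptide, allele = short$allele,
             predictor = predictor, percentile_rank = pr,
             stringsAsFactors = FALSE)
}

#' Write a contact map to YAML
#'
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  doc <- list(k = map$k, alleles = lapply(map$alleles, function(p)
    stats::setNames(as.list(p), as.character(seq_along(p)))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write every pipeline input for a simulated study
#'
#' Generates a planted model, binding/structural training records, a
#' designed variant cohort and a matching external rank table, and writes
#' them as plain-text files: `contact_map.yaml`, `binding.tsv`,
#' `structural.tsv`, `variants.tsv`, `proteins.fasta`, `external.tsv`, and
#' `truth.json` (the design ledger and expected per-stage counts --
#' ground truth for tests, never a pipeline input).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every generator.
#' @param n_binding Training records; default 2000.
#' @param noise_rate Label noise; default 0.1.
#' @param n_snv,n_fs Cohort composition; defaults 60 and 3.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_inputs <- function(dir, seed, n_binding = 2000, noise_rate = 0.1,
                            n_snv = 60, n_fs = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  model <- simulate_planted_model(seed)
  map <- planted_contact_map(model)
  write_contact_map(map, p("contact_map.yaml"))

  bind <- sample_binding_records(model, n_binding, noise_rate, seed + 1)
  utils::write.table(bind$records, p("binding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  struct <- simulate_structural_records(model, 50, seed + 2)
  utils::write.table(struct, p("structural.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cohort <- simulate_variant_cohort(seed + 3, n_snv = n_snv, n_fs = n_fs)
  utils::write.table(cohort$variants, p("variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(cohort$proteins), p("proteins.fasta"))

  fit <- noah(bind$records, struct, contact_map = map)
  pairs <- enumerate_peptides(cohort$variants, cohort$proteins)
  rec <- score_candidates(fit, pairs, cohort$variants)
  ext <- simulate_design_external(rec, cohort$design, seed + 4)
  utils::write.table(ext, p("external.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  jsonlite::write_json(
    list(seed = seed, design = cohort$design,
         expected_counts = cohort$expected_counts,
         planted = list(alleles = model$alleles, k = model$k,
                        weight_scale = model$weight_scale)),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(contact_map = p("contact_map.yaml"),
                 binding = p("binding.tsv"),
                 structural = p("structural.tsv"),
                 variants = p("variants.tsv"),
                 proteins = p("proteins.fasta"),
                 external = p("external.tsv"),
                 truth = p("truth.json")))
}
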