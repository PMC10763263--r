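# Pan-allele position-specific weight matrix (PSWM) for peptide/MHC-I fit.
#
# The model factorizes a k-mer peptide into independent positions. Each
# (allele, position) pair carries a pocket environment; environments with
# similar pocket composition are clustered and share one 20-entry weight
# vector, so qualitative binding data from different alleles is pooled
# wherever the local structural context agrees. A peptide's score is the sum
# of its per-position weights: not an affinity, but a log-odds measure of how
# well the peptide fits the groove. Training mixes binder/nonbinder labels
# with structural positives (peptides seen bound in crystal structures) via
# a weighted pseudocount scheme.

#' Fit a pan-allele peptide/MHC-I position weight matrix
#'
#' For each environment cluster `c` and amino acid `a`, the fitted weight is
#' a background-normalised log-odds with pseudocounts,
#'
#' \deqn{w(c,a) = \log_2\frac{n_b(c,a) + \lambda n_s(c,a) + \kappa q_a}
#'                           {N_b(c) + \lambda N_s(c) + \kappa} - \log_2 q_a
#'  - \eta\left[\log_2\frac{n_n(c,a) + \kappa q_a}{N_n(c) + \kappa}
#'              - \log_2 q_a\right]}
#'
#' where \eqn{n_b, n_s, n_n} count binder, structural and nonbinder
#' observations of residue `a` pooled over every (allele, position) assigned
#' to cluster `c`, capital letters are the corresponding totals, and
#' \eqn{q_a} is the background frequency. With no data every weight is
#' exactly 0 under a uniform background; a cluster with no positive
#' (binder or structural) observations falls back to the background
#' (all-zero weights) with a warning.
#'
#' @param binding data.frame with columns `peptide`, `allele`, `label`
#'   (`"binder"` or `"nonbinder"`). Labels are qualitative by design; the
#'   model is never trained on affinities.
#' @param structural Optional data.frame with columns `peptide`, `allele`,
#'   `source_id`; each row is treated as a positive observation with prior
#'   weight `lambda`.
#' @param contact_map A [contact_map()] covering every allele present in the
#'   training records; defines `k` and the pocket environments.
#' @param kappa Pseudocount mass (default 1).
#' @param lambda Weight of one structural record relative to one binder
#'   record (default 1).
#' @param eta Weight of the nonbinder (discriminative) correction; 0 turns
#'   nonbinder records off (default 1).
#' @param background Named numeric vector of background amino-acid
#'   frequencies over [AA_STANDARD]; default uniform (1/20). Must sum to 1.
#' @param similarity_threshold Pocket-environment clustering threshold passed
#'   to [cluster_environments()] (default 0.7).
#' @return An object of class `noah`: list with elements `k`, `alleles`,
#'   `clusters` (the environment table with `env_id`), `matrices` (named
#'   list, per-cluster 20-vector of weights), `global` (all-data pooled
#'   20-vector used as the pan-allele fallback), `allele_weights` (per
#'   allele, a k x 20 matrix), `support` (observations pooled per cluster),
#'   `params`, `n_binding`, `n_structural`.
#' @examples
#' map <- contact_map(3, list(X1 = c("YY", "FW", "")))
#' rec <- data.frame(peptide = c("ALA", "AVA"), allele = "X1",
#'                   label = c("binder", "binder"))
#' fit <- noah(rec, contact_map = map)
#' predict(fit, "ALA", allele = "X1")
#' @seealso [predict.noah()], [project_allele()], [write_noah()]
#' @export
noah <- function(binding, structural = NULL, contact_map,
                 kappa = 1, lambda = 1, eta = 1,
                 background = NULL, similarity_threshold = 0.7) {
  stopifnot(inherits(contact_map, "contact_map"))
  k <- contact_map$k
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  } else {
    if (!all(AA_STANDARD %in% names(background)))
      stop("background must name all 20 standard amino acids")
    background <- background[AA_STANDARD]
    if (abs(sum(background) - 1) > 1e-8)
      stop("background frequencies must sum to 1")
  }
  if (kappa < 0 || lambda < 0)
    stop("kappa and lambda must be non-negative")

  binding <- .check_records(binding, c("peptide", "allele", "label"), k,
                            contact_map, what = "binding")
  if (!all(binding$label %in% c("binder", "nonbinder")))
    stop("binding labels must be 'binder' or 'nonbinder'")
  if (!is.null(structural) && nrow(structural) > 0) {
    structural <- .check_records(structural, c("peptide", "allele"), k,
                                 contact_map, what = "structural")
  } else {
    structural <- data.frame(peptide = character(), allele = character(),
                             stringsAsFactors = FALSE)
  }

  clusters <- cluster_environments(contact_environments(contact_map),
                                   similarity_threshold)
  n_env <- max(clusters$env_id)
  assignment <- .assignment_matrix(clusters, k)

  n_b <- .pooled_counts(binding[binding$label == "binder", ], assignment, k)
  n_n <- .pooled_counts(binding[binding$label == "nonbinder", ], assignment, k)
  n_s <- .pooled_counts(structural, assignment, k)

  matrices <- vector("list", n_env)
  empty <- integer(0)
  for (c_id in seq_len(n_env)) {
    if (sum(n_b[c_id, ]) + lambda * sum(n_s[c_id, ]) == 0) {
      matrices[[c_id]] <- stats::setNames(rep(0, 20), AA_STANDARD)
      empty <- c(empty, c_id)
    } else {
      matrices[[c_id]] <- .pswm_weights(n_b[c_id, ], n_s[c_id, ], n_n[c_id, ],
                                        kappa, lambda, eta, background)
    }
  }
  names(matrices) <- paste0("env", seq_len(n_env))
  if (length(empty) && (nrow(binding) > 0 || nrow(structural) > 0))
    warning("no positive training data for cluster(s) ",
            paste(empty, collapse = ", "),
            "; falling back to background (all-zero weights)")

  global <- if (sum(n_b) + lambda * sum(n_s) == 0) {
    stats::setNames(rep(0, 20), AA_STANDARD)
  } else {
    .pswm_weights(colSums(n_b), colSums(n_s), colSums(n_n),
                  kappa, lambda, eta, background)
  }

  fit <- structure(list(
    k = k,
    alleles = sort(names(contact_map$alleles)),
    clusters = clusters,
    matrices = matrices,
    global = global,
    support = rowSums(n_b) + rowSums(n_s) + rowSums(n_n),
    params = list(kappa = kappa, lambda = lambda, eta = eta,
                  background = background,
                  similarity_threshold = similarity_threshold),
    n_binding = nrow(binding),
    n_structural = nrow(structural),
    projected = character(0)
  ), class = "noah")
  fit$allele_weights <- .allele_weight_matrices(fit)
  fit
}

.check_records <- function(x, cols, k, map, what) {
  if (!is.data.frame(x) || !all(cols %in% names(x)))
    stop(what, " records must be a data.frame with columns ",
         paste(cols, collapse = ", "))
  x$peptide <- toupper(as.character(x$peptide))
  bad_len <- nchar(x$peptide) != k
  if (any(bad_len))
    stop(sum(bad_len), " ", what, " peptide(s) are not length ", k)
  bad_aa <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"),
                  x$peptide)
  if (any(bad_aa))
    stop(sum(bad_aa), " ", what, " peptide(s) contain non-standard residues")
  unk <- setdiff(unique(x$allele), names(map$alleles))
  if (length(unk))
    stop(what, " records reference allele(s) absent from the contact map: ",
         paste(unk, collapse = ", "))
  x
}

# cluster assignment as an allele x position integer matrix
.assignment_matrix <- function(clusters, k) {
  alleles <- sort(unique(clusters$allele))
  m <- matrix(NA_integer_, nrow = length(alleles), ncol = k,
              dimnames = list(alleles, NULL))
  m[cbind(match(clusters$allele, alleles), clusters$position)] <-
    clusters$env_id
  m
}

# env x residue count matrix pooling every (record, position) observation
.pooled_counts <- function(records, assignment, k) {
  n_env <- max(assignment)
  counts <- matrix(0, nrow = n_env, ncol = 20,
                   dimnames = list(NULL, AA_STANDARD))
  if (nrow(records) == 0) return(counts)
  res <- matrix(unlist(strsplit(records$peptide, ""), use.names = FALSE),
                ncol = k, byrow = TRUE)
  env <- assignment[records$allele, , drop = FALSE]
  tab <- table(factor(as.vector(env), levels = seq_len(n_env)),
               factor(as.vector(res), levels = AA_STANDARD))
  counts + unclass(tab)
}

.pswm_weights <- function(nb, ns, nn, kappa, lambda, eta, q) {
  pos <- log2((nb + lambda * ns + kappa * q) /
                (sum(nb) + lambda * sum(ns) + kappa)) - log2(q)
  neg <- if (eta == 0) 0 else
    log2((nn + kappa * q) / (sum(nn) + kappa)) - log2(q)
  w <- pos - eta * neg
  stats::setNames(as.numeric(w), AA_STANDARD)
}

# per-allele k x 20 weight matrices resolved through the cluster assignment
.allele_weight_matrices <- function(fit) {
  assignment <- .assignment_matrix(fit$clusters, fit$k)
  out <- lapply(rownames(assignment), function(a) {
    W <- do.call(rbind, lapply(seq_len(fit$k), function(p) {
      e <- assignment[a, p]
      fit$matrices[[e]]
    }))
    rownames(W) <- NULL
    W
  })
  names(out) <- rownames(assignment)
  out
}

#' Score peptides with a fitted model
#'
#' The score of a peptide is the sum of one local contribution per position:
#' `contributions[p] = W[p, peptide[p]]` where `W` is the allele's k x 20
#' weight matrix. Higher means a better predicted fit in the groove; the
#' value is unitless and is not an affinity.
#'
#' @param object A fitted `noah` model.
#' @param peptides Character vector of peptides of length `k`.
#' @param allele A single allele name known to the model (fitted or added by
#'   [project_allele()]), or `NULL` to score against every allele.
#' @param contributions If `TRUE` (single allele only), also return the
#'   per-position contribution matrix.
#' @param ... Unused.
#' @return For a single allele, a numeric vector of scores (named by
#'   peptide), or if `contributions = TRUE` a list with elements `score` and
#'   `contributions` (an n x k matrix). With `allele = NULL`, an n x
#'   n_alleles score matrix. Residues outside the 20-letter alphabet (for
#'   example `X`) contribute 0, with a warning.
#' @export
predict.noah <- function(object, peptides, allele = NULL,
                         contributions = FALSE, ...) {
  peptides <- toupper(as.character(peptides))
  if (any(nchar(peptides) != object$k))
    stop("all peptides must have length k = ", object$k)
  if (is.null(allele)) {
    if (contributions)
      stop("contributions are only returned for a single allele")
    out <- vapply(names(object$allele_weights), function(a)
      .score_matrix(object$allele_weights[[a]], peptides, object$k)$score,
      numeric(length(peptides)))
    out <- matrix(out, nrow = length(peptides),
                  dimnames = list(peptides, names(object$allele_weights)))
    return(out)
  }
  if (!allele %in% names(object$allele_weights))
    stop("allele '", allele, "' is not in the model; use project_allele() ",
         "to add an unseen allele from its contact environments")
  res <- .score_matrix(object$allele_weights[[allele]], peptides, object$k)
  if (contributions) res else stats::setNames(res$score, peptides)
}

.score_matrix <- function(W, peptides, k) {
  if (length(peptides) == 0)
    return(list(score = numeric(0),
                contributions = matrix(numeric(0), ncol = k)))
  res <- matrix(unlist(strsplit(peptides, ""), use.names = FALSE),
                ncol = k, byrow = TRUE)
  idx <- match(res, AA_STANDARD)
  if (anyNA(idx))
    warning("non-standard residue(s) scored as 0: ",
            paste(unique(res[is.na(idx)]), collapse = ", "))
  contrib <- matrix(0, nrow = length(peptides), ncol = k)
  ok <- !is.na(idx)
  pos <- matrix(rep(seq_len(k), each = length(peptides)), ncol = k)
  contrib[ok] <- W[cbind(pos[ok], idx[ok])]
  list(score = rowSums(contrib), contributions = contrib)
}

#' Project an unseen allele into a fitted model
#'
#' Pan-allele prediction: each position of the new allele is assigned the
#' trained environment cluster with the most similar pocket composition
#' (single linkage: maximal similarity over the cluster's member
#' environments; ties broken by lowest cluster id). A position whose best
#' similarity falls below the model's clustering threshold gets the global
#' all-data matrix instead.
#'
#' @param object A fitted `noah` model.
#' @param contact_map A `contact_map` containing the new allele(s).
#' @param alleles Allele names to add; default all alleles of `contact_map`
#'   not already in the model.
#' @return The model with the new alleles' weight matrices added; the
#'   projection assignment is recorded in `$projection` (cluster id or
#'   `"global"` per position).
#' @export
project_allele <- function(object, contact_map, alleles = NULL) {
  stopifnot(inherits(object, "noah"), inherits(contact_map, "contact_map"))
  if (contact_map$k != object$k)
    stop("contact map k does not match the model")
  if (is.null(alleles))
    alleles <- setdiff(names(contact_map$alleles),
                       names(object$allele_weights))
  S <- residue_similarity_matrix()
  thr <- object$params$similarity_threshold
  for (a in alleles) {
    pockets <- contact_map$alleles[[a]]
    if (is.null(pockets)) stop("allele '", a, "' not in the contact map")
    assign_row <- character(object$k)
    W <- matrix(0, nrow = object$k, ncol = 20,
                dimnames = list(NULL, AA_STANDARD))
    for (p in seq_len(object$k)) {
      sims <- vapply(seq_len(nrow(object$clusters)), function(i)
        pocket_similarity(pockets[p], object$clusters$pocket[i], S),
        numeric(1))
      best <- max(sims)
      if (best >= thr) {
        e <- min(object$clusters$env_id[sims == best])
        assign_row[p] <- as.character(e)
        W[p, ] <- object$matrices[[e]]
      } else {
        assign_row[p] <- "global"
        W[p, ] <- object$global
      }
    }
    object$allele_weights[[a]] <- W
    object$projection[[a]] <- assign_row
    object$projected <- union(object$projected, a)
  }
  object
}

#' Rank scored candidates
#'
#' Orders records by NOAH score, descending; ties are broken by peptide then
#' variant id (lexicographic) so the ranking is deterministic under
#' permutation of the input. A 1-based `noah_rank` column is attached.
#'
#' @param records data.frame with columns `noah_score`, `mut_peptide` and
#'   (optionally) `variant_id`.
#' @return The records sorted with `noah_rank` attached.
#' @export
rank_candidates <- function(records) {
  stopifnot(is.data.frame(records), "noah_score" %in% names(records))
  vid <- if ("variant_id" %in% names(records)) records$variant_id else ""
  o <- order(-records$noah_score, records$mut_peptide, vid)
  records <- records[o, , drop = FALSE]
  records$noah_rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  records
}

#' @export
print.noah <- function(x, ...) {
  cat("Pan-allele peptide/MHC-I position weight matrix (k =", x$k, ")\n")
  cat("  alleles:", paste(x$alleles, collapse = ", "), "\n")
  if (length(x$projected))
    cat("  projected:", paste(x$projected, collapse = ", "), "\n")
  cat("  environment clusters:", length(x$matrices),
      " (similarity threshold", x$params$similarity_threshold, ")\n")
  cat("  training records:", x$n_binding, "binding,",
      x$n_structural, "structural\n")
  invisible(x)
}

#' @method summary noah
#' @export
summary.noah <- function(object, ...) {
  rng <- t(vapply(object$matrices, range, numeric(2)))
  colnames(rng) <- c("min_weight", "max_weight")
  s <- list(k = object$k, alleles = object$alleles,
            n_clusters = length(object$matrices),
            support = object$support, weight_range = rng,
            params = object$params[c("kappa", "lambda", "eta",
                                     "similarity_threshold")],
            n_binding = object$n_binding,
            n_structural = object$n_structural)
  class(s) <- "summary.noah"
  s
}

#' @export
print.summary.noah <- function(x, ...) {
  cat("Pan-allele PSWM, k =", x$k, ",", x$n_clusters,
      "environment clusters\n")
  cat("alleles:", paste(x$alleles, collapse = ", "), "\n")
  cat("params: kappa =", x$params$kappa, ", lambda =", x$params$lambda,
      ", eta =", x$params$eta, ", similarity threshold =",
      x$params$similarity_threshold, "\n")
  cat("training:", x$n_binding, "binding records,", x$n_structural,
      "structural records\n")
  df <- data.frame(cluster = seq_along(x$support),
                   support = as.integer(x$support),
                   round(x$weight_range, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract fitted weights
#'
#' @param object A fitted `noah` model.
#' @param allele If given, return that allele's k x 20 position weight
#'   matrix; otherwise the per-cluster weight matrix (clusters x 20).
#' @param ... Unused.
#' @return A numeric matrix of log2 odds weights.
#' @method coef noah
#' @export
coef.noah <- function(object, allele = NULL, ...) {
  if (is.null(allele)) {
    W <- do.call(rbind, object$matrices)
    rownames(W) <- names(object$matrices)
    return(W)
  }
  if (!allele %in% names(object$allele_weights))
    stop("allele '", allele, "' is not in the model")
  object$allele_weights[[allele]]
}

#' Plot an allele's position weight matrix
#'
#' Heatmap of the k x 20 weight matrix (positions on the x axis, residues on
#' the y axis), blue for disfavoured and red for favoured residues.
#'
#' @param x A fitted `noah` model.
#' @param allele Allele to plot; default the model's first allele.
#' @param ... Passed to [graphics::image()].
#' @method plot noah
#' @export
plot.noah <- function(x, allele = x$alleles[1], ...) {
  W <- coef(x, allele = allele)
  lim <- max(abs(W), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  graphics::image(seq_len(x$k), seq_len(20), W, zlim = c(-lim, lim),
                  col = pal, xlab = "peptide position", ylab = "",
                  axes = FALSE, main = paste0(allele, " position weights"),
                  ...)
  graphics::axis(1, at = seq_len(x$k))
  graphics::axis(2, at = seq_len(20), labels = AA_STANDARD, las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Simulate qualitative binding records from a fitted model
#'
#' Draws peptides uniformly at random, scores them against a random fitted
#' allele and labels the upper half of the score distribution "binder" --
#' the same labelling convention the synthetic-data generator uses.
#'
#' @param object A fitted `noah` model.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param n Records per replicate.
#' @param ... Unused.
#' @return data.frame with columns `sim`, `peptide`, `allele`, `label`.
#' @export
simulate.noah <- function(object, nsim = 1, seed = NULL, n = 100, ...) {
  if (!is.null(seed)) set.seed(seed)
  alleles <- names(object$allele_weights)
  out <- lapply(seq_len(nsim), function(s) {
    pep <- random_peptides(n, object$k)
    al <- sample(alleles, n, replace = TRUE)
    sc <- vapply(seq_len(n), function(i)
      unname(predict(object, pep[i], allele = al[i])), numeric(1))
    data.frame(sim = s, peptide = pep, allele = al,
               label = ifelse(sc > stats::median(sc), "binder", "nonbinder"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Uniform random peptides
#'
#' @param n Number of peptides.
#' @param k Length.
#' @return Character vector of n random k-mers over the standard alphabet.
#' @export
random_peptides <- function(n, k = 9) {
  if (n == 0) return(character(0))
  m <- matrix(sample(AA_STANDARD, n * k, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}
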