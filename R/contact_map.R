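# MHC binding-pocket contact maps: which MHC residues touch each peptide
# position. This is the structural prior behind pan-allele pooling: peptide
# positions whose pocket environments look alike (by substitution-matrix
# similarity of the pocket residues) share one weight matrix.

#' Read a peptide--MHC contact map
#'
#' The contact map records, per allele and per peptide position 1..k, the
#' one-letter identities of the MHC residues contacting that position
#' (distilled offline from crystal structures). YAML layout:
#'
#' ```yaml
#' k: 9
#' alleles:
#'   H2-Kb:
#'     1: "YYRE"
#'     2: "EKYY"
#'     ...
#' ```
#'
#' An empty string means no contacts (a solvent-exposed, TCR-facing
#' position). Every allele must define all k positions.
#'
#' @param path Path to a YAML file.
#' @return An object of class `contact_map`: list with `k` (peptide length)
#'   and `alleles`, a named list of length-k character vectors of pocket
#'   residue strings.
#' @seealso [default_contact_map()], [contact_environments()]
#' @export
read_contact_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$k) || is.null(cfg$alleles))
    stop("contact map must declare top-level 'k' and 'alleles'")
  k <- as.integer(cfg$k)
  alleles <- lapply(cfg$alleles, function(pos) {
    pos <- pos[order(as.integer(names(pos)))]
    got <- as.integer(names(pos))
    if (!identical(got, seq_len(k)))
      stop("contact map allele is missing positions: expected 1..", k,
           ", got {", paste(got, collapse = ","), "}")
    pockets <- vapply(pos, function(p) if (is.null(p)) "" else as.character(p),
                      character(1))
    bad <- setdiff(unique(unlist(strsplit(pockets, ""))), AA_STANDARD)
    if (length(bad))
      stop("contact map contains unknown residue letter(s): ",
           paste(bad, collapse = ", "))
    unname(pockets)
  })
  structure(list(k = k, alleles = alleles), class = "contact_map")
}

#' Build a contact map in code
#'
#' @param k Peptide length.
#' @param alleles Named list of length-k character vectors of pocket strings.
#' @return A `contact_map`.
#' @export
contact_map <- function(k, alleles) {
  stopifnot(is.list(alleles), length(names(alleles)) == length(alleles))
  for (a in names(alleles)) {
    if (length(alleles[[a]]) != k)
      stop("allele ", a, " does not define all ", k, " positions")
    bad <- setdiff(unique(unlist(strsplit(alleles[[a]], ""))), AA_STANDARD)
    if (length(bad))
      stop("allele ", a, " has unknown residue letter(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(k = as.integer(k), alleles = alleles), class = "contact_map")
}

#' Default contact map shipped with the package
#'
#' A curated stand-in covering the mouse class I alleles H2-Kb and H2-Db plus
#' two common human alleles (HLA-A0201, HLA-B0702), with pocket compositions
#' consistent with the canonical anchor architecture of each allele (H2-Db
#' anchors P5/P9, H2-Kb P5/P8, HLA-A*02:01 P2/P9).
#'
#' @return A `contact_map`.
#' @export
default_contact_map <- function() {
  read_contact_map(system.file("extdata", "contact_map.yaml",
                               package = "neoforge", mustWork = TRUE))
}

#' @export
print.contact_map <- function(x, ...) {
  cat("MHC contact map: k =", x$k, "\n")
  for (a in names(x$alleles)) {
    cc <- nchar(x$alleles[[a]])
    cat(sprintf("  %-12s contacts/position: %s\n", a,
                paste(cc, collapse = " ")))
  }
  invisible(x)
}

#' Flatten a contact map into per-position environments
#'
#' @param map A `contact_map`.
#' @return data.frame with columns `allele`, `position`, `pocket`
#'   (residue string), `contact_count`, one row per (allele, position),
#'   sorted by (allele, position).
#' @export
contact_environments <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  alleles <- sort(names(map$alleles))
  out <- do.call(rbind, lapply(alleles, function(a) {
    data.frame(allele = a, position = seq_len(map$k),
               pocket = map$alleles[[a]],
               stringsAsFactors = FALSE)
  }))
  out$contact_count <- nchar(out$pocket)
  rownames(out) <- NULL
  out
}

# BLOSUM62-derived residue similarity, normalised so self-similarity is 1:
# s(a,b) = B(a,b) / sqrt(B(a,a) B(b,b)). Cached after first use.
.similarity_cache <- new.env(parent = emptyenv())

residue_similarity_matrix <- function() {
  if (!is.null(.similarity_cache$S)) return(.similarity_cache$S)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[AA_STANDARD, AA_STANDARD]
  d <- sqrt(diag(B))
  S <- B / outer(d, d)
  .similarity_cache$S <- S
  S
}

# Similarity of two pocket residue strings: sort both, pad the shorter with a
# gap (similarity 0 per padded slot), average the per-slot residue
# similarities. Two empty pockets are maximally similar (both fully exposed).
pocket_similarity <- function(p1, p2, S = residue_similarity_matrix()) {
  a <- sort(strsplit(p1, "")[[1]])
  b <- sort(strsplit(p2, "")[[1]])
  n <- max(length(a), length(b))
  if (n == 0) return(1)
  sims <- numeric(n)
  m <- min(length(a), length(b))
  if (m > 0) sims[seq_len(m)] <- S[cbind(a[seq_len(m)], b[seq_len(m)])]
  mean(sims)
}

#' Cluster pocket environments across alleles and positions
#'
#' Environments whose pocket compositions are similar (average residue-level
#' BLOSUM62 similarity at or above `similarity_threshold`, on a scale where
#' self-similarity is 1) are joined by single linkage: clusters are the
#' connected components of the thresholded similarity graph. Cluster ids are
#' assigned in (allele, position) order, so the result is deterministic.
#'
#' @param environments data.frame from [contact_environments()].
#' @param similarity_threshold Join threshold in `[0, 1]`; default 0.7.
#' @return The input data.frame with an integer `env_id` column appended.
#' @export
cluster_environments <- function(environments, similarity_threshold = 0.7) {
  env <- environments[order(environments$allele, environments$position), ,
                      drop = FALSE]
  n <- nrow(env)
  sim <- environment_similarity_matrix(env$pocket)
  adj <- sim >= similarity_threshold
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  env$env_id <- comp
  rownames(env) <- NULL
  env
}

# Pairwise pocket similarity matrix; identical pocket strings share one
# computation.
environment_similarity_matrix <- function(pockets) {
  S <- residue_similarity_matrix()
  uniq <- unique(pockets)
  iu <- match(pockets, uniq)
  m <- length(uniq)
  US <- diag(1, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        US[i, j] <- US[j, i] <- pocket_similarity(uniq[i], uniq[j], S)
      }
    }
  }
  US[iu, iu, drop = FALSE]
}
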