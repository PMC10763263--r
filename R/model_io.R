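# Trained-model serialization: one JSON document holding the clusters,
# matrices, parameters and per-allele assignments, with a format version.
# Doubles are written at full precision so a round trip reproduces scores
# bit for bit.

.model_format_version <- "1.0"

#' Write a fitted model to JSON
#'
#' @param fit A fitted `noah` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_noah()]
#' @export
write_noah <- function(fit, path) {
  stopifnot(inherits(fit, "noah"))
  doc <- list(
    format_version = .model_format_version,
    k = fit$k,
    alleles = fit$alleles,
    projected = fit$projected,
    params = fit$params,
    clusters = fit$clusters,
    matrices = lapply(fit$matrices, function(m) as.list(m)),
    global = as.list(fit$global),
    support = as.numeric(fit$support),
    allele_weights = lapply(fit$allele_weights, function(W) {
      lapply(seq_len(nrow(W)), function(p) as.list(W[p, ]))
    }),
    projection = fit$projection,
    n_binding = fit$n_binding,
    n_structural = fit$n_structural
  )
  # digits = I(17): significant-digit mode, enough for doubles to
  # round-trip bit for bit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path written by [write_noah()].
#' @return A `noah` model producing bit-identical scores to the one
#'   serialized.
#' @export
read_noah <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format_version) ||
      doc$format_version != .model_format_version)
    stop("unsupported model format version: ",
         if (is.null(doc$format_version)) "<missing>" else doc$format_version)
  unvec <- function(x) stats::setNames(vapply(x, as.numeric, numeric(1))[
    AA_STANDARD], AA_STANDARD)
  clusters <- do.call(rbind, lapply(doc$clusters, function(r)
    data.frame(allele = r$allele, position = as.integer(r$position),
               pocket = as.character(r$pocket),
               contact_count = as.integer(r$contact_count),
               env_id = as.integer(r$env_id), stringsAsFactors = FALSE)))
  params <- doc$params
  params$background <- unvec(params$background)
  fit <- structure(list(
    k = as.integer(doc$k),
    alleles = as.character(unlist(doc$alleles)),
    clusters = clusters,
    matrices = lapply(doc$matrices, unvec),
    global = unvec(doc$global),
    support = as.numeric(unlist(doc$support)),
    params = params,
    n_binding = as.integer(doc$n_binding),
    n_structural = as.integer(doc$n_structural),
    projected = as.character(unlist(doc$projected))
  ), class = "noah")
  fit$allele_weights <- lapply(doc$allele_weights, function(rows) {
    W <- do.call(rbind, lapply(rows, unvec))
    rownames(W) <- NULL
    W
  })
  fit$projection <- lapply(doc$projection, function(p)
    as.character(unlist(p)))
  fit
}
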