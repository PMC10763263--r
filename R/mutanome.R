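# Somatic variant parsing and mutant/wild-type peptide enumeration.
#
# Variants are consumed at protein level: a missense carries a single
# substitution (wt_aa -> mut_aa at protein_pos); a frameshift carries the
# novel amino-acid sequence read after the junction up to the new stop.
# Coordinates are 1-based inclusive throughout, matching conventional
# protein mutation notation (L10P).

#' Read wild-type protein sequences from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each record id.
#' @export
read_proteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

.variant_columns <- c("variant_id", "gene", "protein_id", "kind",
                      "protein_pos", "wt_aa", "mut_aa", "novel_seq",
                      "rna_reads", "vaf")

.variant_kinds <- c("missense", "frameshift", "inframe")

#' Parse a somatic variant table
#'
#' Reads a tab-delimited table (columns `variant_id`, `gene`, `protein_id`,
#' `kind`, `protein_pos`, `wt_aa`, `mut_aa`, `novel_seq`, `rna_reads`,
#' `vaf`; `#` comment lines ignored; empty string for inapplicable fields)
#' and validates every row against the supplied protein sequences.
#' `rna_reads` is the RNA read count supporting the variant and `vaf` its
#' variant allele frequency; both feed the downstream expression and
#' clonality filters. Row order is preserved.
#'
#' @param path Path to the TSV file, or a character vector of lines.
#' @param proteins Named character vector from [read_proteins()] (or an
#'   `AAStringSet`).
#' @return data.frame of validated variants, one row per input row, with
#'   `protein_pos` integer, `rna_reads` integer and `vaf` numeric. In-frame
#'   indels (`kind = "inframe"`) are accepted and later enumerated through
#'   the frameshift-style chimeric path.
#' @export
parse_variant_table <- function(path, proteins) {
  proteins <- .as_protein_set(proteins)
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("variant table is empty")
  tab <- utils::read.delim(text = lines, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.variant_columns, names(tab))
  if (length(missing))
    stop("variant table is missing column(s): ",
         paste(missing, collapse = ", "))
  tab <- tab[, .variant_columns]
  n <- nrow(tab)
  tab$protein_pos <- suppressWarnings(as.integer(tab$protein_pos))
  tab$rna_reads <- suppressWarnings(as.integer(tab$rna_reads))
  tab$vaf <- suppressWarnings(as.numeric(tab$vaf))
  tab$wt_aa <- toupper(tab$wt_aa)
  tab$mut_aa <- toupper(tab$mut_aa)
  tab$novel_seq <- toupper(tab$novel_seq)

  errs <- character(0)
  err <- function(row, msg) sprintf("row %d: %s", row, msg)
  for (i in seq_len(n)) {
    v <- tab[i, ]
    if (!v$kind %in% .variant_kinds) {
      errs <- c(errs, err(i, paste0("unknown kind '", v$kind, "'")))
      next
    }
    prot <- proteins[[v$protein_id]]
    if (is.null(prot) || is.na(prot)) {
      errs <- c(errs, err(i, paste0("protein '", v$protein_id,
                                    "' not in the FASTA")))
      next
    }
    if (is.na(v$protein_pos) || v$protein_pos < 1 ||
        v$protein_pos > nchar(prot)) {
      errs <- c(errs, err(i, "protein_pos out of range"))
      next
    }
    if (is.na(v$vaf) || v$vaf < 0 || v$vaf > 1)
      errs <- c(errs, err(i, "vaf outside [0, 1]"))
    if (is.na(v$rna_reads) || v$rna_reads < 0)
      errs <- c(errs, err(i, "rna_reads must be a non-negative integer"))
    if (v$kind == "missense") {
      if (!nzchar(v$wt_aa) || !nzchar(v$mut_aa) ||
          !(v$wt_aa %in% AA_STANDARD) || !(v$mut_aa %in% AA_STANDARD))
        errs <- c(errs, err(i, "missense requires one-letter wt_aa, mut_aa"))
      else if (v$wt_aa == v$mut_aa)
        errs <- c(errs, err(i, "missense with wt_aa == mut_aa"))
      else if (substr(prot, v$protein_pos, v$protein_pos) != v$wt_aa)
        errs <- c(errs, err(i, sprintf(
          "wt_aa '%s' does not match the FASTA residue '%s' at position %d",
          v$wt_aa, substr(prot, v$protein_pos, v$protein_pos),
          v$protein_pos)))
      if (nzchar(v$novel_seq))
        errs <- c(errs, err(i, "missense must not carry novel_seq"))
    } else {
      if (!nzchar(v$novel_seq) ||
          grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"),
                v$novel_seq))
        errs <- c(errs, err(i, paste0(v$kind, " requires a non-empty ",
                                      "novel_seq over the 20-letter alphabet")))
    }
  }
  if (anyDuplicated(tab$variant_id))
    errs <- c(errs, paste0("duplicate variant_id: ",
                           paste(unique(tab$variant_id[
                             duplicated(tab$variant_id)]), collapse = ", ")))
  if (length(errs))
    stop("invalid variant table:\n  ", paste(errs, collapse = "\n  "))
  rownames(tab) <- NULL
  tab
}

.as_protein_set <- function(proteins) {
  if (inherits(proteins, "XStringSet")) {
    out <- toupper(as.character(proteins))
    names(out) <- sub("\\s.*$", "", names(proteins))
    return(as.list(out))
  }
  as.list(proteins)
}

#' Enumerate mutant/wild-type 9-mer pairs for a missense variant
#'
#' Every length-`k` window of the mutant protein containing the mutated
#' residue is emitted, paired with the same window of the wild-type protein.
#' Mutations within `k` residues of a terminus yield fewer than `k` windows
#' and are kept.
#'
#' @param variant A single-row data.frame (one row of
#'   [parse_variant_table()]) with `kind == "missense"`.
#' @param protein Wild-type sequence of the mutated protein.
#' @param k Window length; default 9, the class I short-peptide length.
#' @return data.frame of peptide pairs: `variant_id`, `mut_peptide`,
#'   `wt_peptide`, `mut_offset` (1-based position of the altered residue
#'   within the peptide), `length`, `origin = "snv_9mer"`.
#' @export
enumerate_snv_peptides <- function(variant, protein, k = 9) {
  stopifnot(nrow(variant) == 1, variant$kind == "missense")
  L <- nchar(protein)
  if (k < 1 || k > L) stop("k must be in [1, protein length]")
  pos <- variant$protein_pos
  mut_protein <- paste0(substr(protein, 1, pos - 1), variant$mut_aa,
                        substr(protein, pos + 1, L))
  starts <- seq(max(1, pos - k + 1), min(pos, L - k + 1))
  data.frame(
    variant_id = variant$variant_id,
    mut_peptide = substring(mut_protein, starts, starts + k - 1),
    wt_peptide = substring(protein, starts, starts + k - 1),
    mut_offset = pos - starts + 1,
    length = k,
    origin = "snv_9mer",
    stringsAsFactors = FALSE
  )
}

#' Enumerate peptides for a frameshift (or in-frame indel) variant
#'
#' The chimeric mutant sequence is the wild-type prefix up to
#' `protein_pos - 1` followed by `novel_seq`. Two kinds of peptides are
#' emitted: (a) `fs_9mer` tiles -- every length-`k` window of the chimera
#' containing at least one novel residue, with no wild-type counterpart;
#' and (b) one `fs_long` peptide of length at most `long_len` centred on the
#' junction, intended for downstream vaccine-cassette use.
#'
#' @param variant A single-row data.frame with `kind` `"frameshift"` or
#'   `"inframe"` and a non-empty `novel_seq`.
#' @param protein Wild-type sequence of the affected protein.
#' @param k Tile length; default 9.
#' @param long_len Maximum long-peptide length; default 25.
#' @return data.frame of peptide pairs with `wt_peptide = NA`; `mut_offset`
#'   is the 1-based position of the first novel residue within the peptide
#'   (1 for tiles lying entirely in the novel sequence).
#' @export
enumerate_frameshift_peptides <- function(variant, protein, k = 9,
                                          long_len = 25) {
  stopifnot(nrow(variant) == 1, variant$kind %in% c("frameshift", "inframe"))
  novel <- variant$novel_seq
  if (is.na(novel) || !nzchar(novel)) stop("empty novel_seq")
  pos <- variant$protein_pos
  chimera <- paste0(substr(protein, 1, pos - 1), novel)
  M <- nchar(chimera)
  tiles <- if (M >= k) {
    starts <- seq(max(1, pos - k + 1), M - k + 1)
    starts <- starts[starts + k - 1 >= pos]  # >= 1 novel residue
    data.frame(
      variant_id = variant$variant_id,
      mut_peptide = substring(chimera, starts, starts + k - 1),
      wt_peptide = NA_character_,
      mut_offset = pmax(1L, as.integer(pos - starts + 1)),
      length = k,
      origin = "fs_9mer",
      stringsAsFactors = FALSE
    )
  } else {
    data.frame()
  }
  ll <- min(long_len, M)
  start <- max(1, pos - (ll %/% 2))
  start <- max(1, min(start, M - ll + 1))
  long <- data.frame(
    variant_id = variant$variant_id,
    mut_peptide = substr(chimera, start, start + ll - 1),
    wt_peptide = NA_character_,
    mut_offset = max(1L, as.integer(pos - start + 1)),
    length = ll,
    origin = "fs_long",
    stringsAsFactors = FALSE
  )
  rbind(tiles, long)
}

#' Enumerate candidate peptides for a whole variant table
#'
#' @param variants data.frame from [parse_variant_table()].
#' @param proteins Named character vector from [read_proteins()].
#' @param k Short-peptide window length (default 9).
#' @param long_len Frameshift long-peptide length (default 25).
#' @return data.frame of peptide pairs across all variants (row-bound in
#'   variant order); zero rows (with the full set of columns) for an empty
#'   variant table.
#' @export
enumerate_peptides <- function(variants, proteins, k = 9, long_len = 25) {
  proteins <- .as_protein_set(proteins)
  empty <- data.frame(variant_id = character(), mut_peptide = character(),
                      wt_peptide = character(), mut_offset = integer(),
                      length = integer(), origin = character(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0) return(empty)
  out <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    prot <- proteins[[v$protein_id]]
    if (v$kind == "missense") enumerate_snv_peptides(v, prot, k)
    else enumerate_frameshift_peptides(v, prot, k, long_len)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read protein-level variants from a VCF with ANN annotations
#'
#' A minimal reader for VCF 4.x files whose INFO field carries SnpEff/VEP
#' style `ANN=` annotations. Only missense records with an HGVS protein
#' term (`p.Leu10Pro`) are converted to variants; frameshift annotations
#' carry no novel peptide sequence at protein level and are rejected with a
#' warning (supply frameshifts through the variant TSV instead). RNA read
#' support is taken from the INFO `DP` field and the allele frequency from
#' `AF` (0 when absent).
#'
#' @param path Path to an (uncompressed) VCF file.
#' @param proteins Named character vector of wild-type proteins; the ANN
#'   feature id must match a FASTA record id.
#' @return data.frame in the same shape as [parse_variant_table()] output.
#' @export
read_vcf_variants <- function(path, proteins) {
  proteins <- .as_protein_set(proteins)
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) stop("VCF contains no records")
  rows <- list()
  skipped <- 0L
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t")[[1]]
    if (length(f) < 8) stop("VCF record ", i, " has fewer than 8 fields")
    info <- f[8]
    ann <- sub("^.*?ANN=([^;]*).*$", "\\1", info)
    if (identical(ann, info)) { skipped <- skipped + 1L; next }
    dp <- if (grepl("(^|;)DP=", info))
      as.integer(sub("^.*?DP=([^;]*).*$", "\\1", info)) else 0L
    af <- if (grepl("(^|;)AF=", info))
      as.numeric(sub("^.*?AF=([^;]*).*$", "\\1", info)) else 0
    parsed <- FALSE
    for (a in strsplit(ann, ",")[[1]]) {
      sub_f <- strsplit(a, "\\|")[[1]]
      if (length(sub_f) < 11) next
      effect <- sub_f[2]
      feature <- sub_f[7]
      hgvs_p <- sub_f[11]
      if (!nzchar(hgvs_p) || !feature %in% names(proteins)) next
      if (grepl("missense", effect)) {
        m <- regmatches(hgvs_p, regexec(
          "^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", hgvs_p))[[1]]
        if (length(m) == 4) {
          rows[[length(rows) + 1]] <- data.frame(
            variant_id = if (nzchar(f[3]) && f[3] != ".") f[3]
                         else paste0("vcf", i),
            gene = sub_f[4], protein_id = feature, kind = "missense",
            protein_pos = as.integer(m[3]),
            wt_aa = .aa3to1(m[2]), mut_aa = .aa3to1(m[4]),
            novel_seq = "", rna_reads = dp, vaf = af,
            stringsAsFactors = FALSE)
          parsed <- TRUE
          break
        }
      } else if (grepl("frameshift", effect)) {
        skipped <- skipped + 1L
        parsed <- TRUE
        break
      }
    }
    if (!parsed) skipped <- skipped + 1L
  }
  if (skipped > 0)
    warning(skipped, " VCF record(s) without a usable protein-level ",
            "missense annotation were skipped")
  if (length(rows) == 0) stop("no usable protein-level annotations in VCF")
  out <- do.call(rbind, rows)
  # reuse the TSV validator for coordinate/FASTA consistency
  tsv <- c(paste(.variant_columns, collapse = "\t"),
           apply(out, 1, function(r) paste(r, collapse = "\t")))
  parse_variant_table(tsv, proteins)
}

.aa3to1 <- function(x) {
  map <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
           Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
           Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
           Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  out <- map[x]
  if (anyNA(out)) stop("unknown three-letter amino acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}
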