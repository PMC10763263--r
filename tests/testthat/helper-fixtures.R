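# Shared fixtures and independent brute-force oracles. The oracles slide
# every window and filter, independently of the enumeration code they check.

random_protein <- function(L) {
  paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
}

# Brute force: all k-windows of the mutant protein, keep those overlapping
# the mutated residue.
oracle_snv_windows <- function(protein, pos, mut_aa, k) {
  L <- nchar(protein)
  mut_protein <- paste0(substr(protein, 1, pos - 1), mut_aa,
                        substr(protein, pos + 1, L))
  out <- list()
  for (s in seq_len(L - k + 1)) {
    if (pos >= s && pos <= s + k - 1) {
      out[[length(out) + 1]] <- list(
        mut = substr(mut_protein, s, s + k - 1),
        wt = substr(protein, s, s + k - 1),
        offset = pos - s + 1)
    }
  }
  out
}

# Brute force: all k-windows of the chimeric sequence, keep those containing
# at least one novel residue (chimera position >= pos).
oracle_fs_windows <- function(protein, pos, novel, k) {
  chimera <- paste0(substr(protein, 1, pos - 1), novel)
  M <- nchar(chimera)
  out <- list()
  if (M < k) return(out)
  for (s in seq_len(M - k + 1)) {
    if (s + k - 1 >= pos) {
      out[[length(out) + 1]] <- list(mut = substr(chimera, s, s + k - 1),
                                     offset = max(1, pos - s + 1))
    }
  }
  out
}

# A tiny two-allele contact map with known structure: positions 1 and 2 of
# each allele share pockets across alleles, position 3 is exposed.
tiny_map <- function() {
  contact_map(3, list(
    AL1 = c("YYFW", "DEKR", ""),
    AL2 = c("YYFW", "DEKR", "H")
  ))
}

# A deterministic small fit for scoring tests.
tiny_fit <- function(seed = 5, n = 200) {
  model <- simulate_planted_model(seed, k = 9)
  bind <- sample_binding_records(model, n, noise_rate = 0, seed = seed + 1)
  noah(bind$records, contact_map = planted_contact_map(model))
}

# Minimal single-variant score records for filter/tier tests.
make_record <- function(variant_id = "v1", mut_peptide = "AAAAAAAAA",
                        wt_peptide = "AAAAAAAAL", mut_offset = 9,
                        origin = "snv_9mer", wt_aa = "L", mut_aa = "A",
                        allele = "H2-Kb", noah_score = 1, wt_score = 0,
                        rna_reads = 10, vaf = 0.5,
                        netmhcpan4 = NA_real_, mhcflurry = NA_real_) {
  data.frame(variant_id = variant_id, mut_peptide = mut_peptide,
             wt_peptide = wt_peptide, mut_offset = mut_offset,
             length = nchar(mut_peptide), origin = origin,
             gene = "G", wt_aa = wt_aa, mut_aa = mut_aa, allele = allele,
             noah_score = noah_score, wt_score = wt_score,
             score_delta = noah_score - wt_score,
             rna_reads = rna_reads, vaf = vaf,
             netmhcpan4 = netmhcpan4, mhcflurry = mhcflurry,
             stringsAsFactors = FALSE)
}

write_variant_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
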