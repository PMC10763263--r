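# External-rank attachment, filters and tier classification.

test_that("external ranks attach by (peptide, allele) and count matches", {
  set.seed(17)
  rec <- do.call(rbind, lapply(1:100, function(i)
    make_record(variant_id = sprintf("v%03d", i),
                mut_peptide = random_peptides(1, 9))))
  # 80 matched in netmhcpan4, 50 in mhcflurry, rest absent
  tab <- rbind(
    data.frame(peptide = rec$mut_peptide[1:80], allele = rec$allele[1:80],
               predictor = "netmhcpan4", percentile_rank = 1.0),
    data.frame(peptide = rec$mut_peptide[1:50], allele = rec$allele[1:50],
               predictor = "mhcflurry", percentile_rank = 3.0))
  out <- attach_external_ranks(rec, tab)
  expect_equal(sum(!is.na(out$netmhcpan4)), 80)
  expect_equal(sum(!is.na(out$mhcflurry)), 50)
  expect_equal(unname(attr(out, "matched")["netmhcpan4"]), 80L)
  expect_equal(nrow(out), 100)  # unmatched records retained
  # conflicting duplicates are an error; consistent duplicates are not
  dup_bad <- rbind(tab, data.frame(peptide = rec$mut_peptide[1],
                                   allele = rec$allele[1],
                                   predictor = "netmhcpan4",
                                   percentile_rank = 9))
  expect_error(attach_external_ranks(rec, dup_bad), "conflicting")
  dup_ok <- rbind(tab, tab[1, ])
  expect_silent(attach_external_ranks(rec, dup_ok))
})

test_that("consensus policy any/all behaves on mixed ranks", {
  r <- rbind(make_record("v1", netmhcpan4 = 1.5, mhcflurry = 3.0),
             make_record("v2", netmhcpan4 = 1.5, mhcflurry = 1.0),
             make_record("v3"))  # no external ranks at all
  expect_equal(filter_consensus(r, "any", 2)$variant_id, c("v1", "v2"))
  expect_equal(filter_consensus(r, "all", 2)$variant_id, "v2")
  expect_equal(filter_consensus(r, "any", 2, keep_unmatched = TRUE)$variant_id,
               c("v1", "v2", "v3"))
})

test_that("consensus 'all' survivors are a subset of 'any' survivors", {
  model <- simulate_planted_model(19)
  bind <- sample_binding_records(model, 200, 0, 20)
  fit <- noah(bind$records, contact_map = planted_contact_map(model))
  set.seed(21)
  rec <- do.call(rbind, lapply(1:200, function(i)
    make_record(variant_id = sprintf("v%03d", i),
                mut_peptide = random_peptides(1, 9),
                allele = model$alleles[1])))
  rec$noah_score <- unname(predict(fit, rec$mut_peptide,
                                   allele = model$alleles[1]))
  ext <- rbind(simulate_external_ranks(rec, 0.7, seed = 1, "netmhcpan4"),
               simulate_external_ranks(rec, 0.7, seed = 2, "mhcflurry"))
  rec <- attach_external_ranks(rec, ext)
  for (cutoff in c(1, 2, 5, 20)) {
    any_set <- filter_consensus(rec, "any", cutoff)$variant_id
    all_set <- filter_consensus(rec, "all", cutoff)$variant_id
    expect_true(all(all_set %in% any_set))
  }
})

test_that("expression and clonality filters are strict inequalities", {
  r <- rbind(make_record("v5", rna_reads = 5), make_record("v6", rna_reads = 6))
  expect_equal(filter_expression(r)$variant_id, "v6")
  expect_equal(nrow(filter_expression(r, min_reads = 0)), 2)
  expect_equal(nrow(filter_expression(rbind(r, make_record("v0", rna_reads = 0)),
                                      min_reads = 0)), 2)
  r2 <- rbind(make_record("va", vaf = 0.20), make_record("vb", vaf = 0.21))
  expect_equal(filter_clonality(r2)$variant_id, "vb")
  expect_equal(nrow(filter_clonality(r2, min_vaf = 0)), 2)
})

test_that("filters commute, are idempotent, and tightening shrinks output", {
  cohort <- simulate_variant_cohort(23, n_snv = 480, n_fs = 20)
  v <- cohort$variants
  rec <- do.call(rbind, lapply(seq_len(nrow(v)), function(i)
    make_record(v$variant_id[i], rna_reads = v$rna_reads[i],
                vaf = v$vaf[i])))
  a <- filter_clonality(filter_expression(rec))
  b <- filter_expression(filter_clonality(rec))
  expect_equal(a[order(a$variant_id), ], b[order(b$variant_id), ],
               ignore_attr = TRUE)
  expect_identical(filter_expression(filter_expression(rec)),
                   filter_expression(rec))
  # brute-force recount of the survivors
  expect_equal(nrow(filter_expression(rec)), sum(v$rna_reads > 5))
  expect_equal(nrow(filter_clonality(rec)), sum(v$vaf > 0.2))
  # monotonicity in the threshold
  sizes_e <- vapply(c(0, 5, 20, 100), function(t)
    nrow(filter_expression(rec, t)), numeric(1))
  expect_true(all(diff(sizes_e) <= 0))
  sizes_v <- vapply(c(0, 0.2, 0.5, 0.9), function(t)
    nrow(filter_clonality(rec, t)), numeric(1))
  expect_true(all(diff(sizes_v) <= 0))
})

test_that("physicochemical severity follows the class pairs", {
  tab <- physchem_table()
  expect_equal(classify_physchem("D", "K", tab), "drastic")   # - to +
  expect_equal(classify_physchem("N", "L", tab), "drastic")   # polar to aliphatic
  expect_equal(classify_physchem("L", "I", tab), "conservative")
  expect_equal(classify_physchem("F", "W", tab), "conservative")
  expect_equal(classify_physchem("F", "L", tab), "moderate")  # aromatic-aliphatic
  expect_equal(classify_physchem("K", "A", tab), "drastic")   # charge to uncharged
  expect_error(classify_physchem("B", "K", tab), "unknown residue")
  # the table itself must partition all 20 residues
  expect_setequal(names(tab$class_of), AA_STANDARD)
})

test_that("the tier truth table classifies constructed cases as designed", {
  map <- default_contact_map()
  # H2-Kb: anchors 5 and 8; exposed (contact < 4): 4, 6, 7
  cases <- rbind(
    # anchor position, big score gain -> Tier 1
    make_record("t1", mut_offset = 5, noah_score = 2, wt_score = 0,
                wt_aa = "L", mut_aa = "I", netmhcpan4 = 1),
    # exposed position, charge reversal, consensus pass -> Tier 2
    make_record("t2", mut_offset = 4, noah_score = 1, wt_score = 0.8,
                wt_aa = "D", mut_aa = "K", netmhcpan4 = 1),
    # exposed position, conservative change, similar binding -> Tier 3
    make_record("t3", mut_offset = 6, noah_score = 1, wt_score = 0.9,
                wt_aa = "L", mut_aa = "I", netmhcpan4 = 1),
    # frameshift -> Tier 4 regardless of the rest
    make_record("t4", origin = "fs_9mer", mut_offset = 5, noah_score = 2,
                wt_peptide = NA, wt_score = NA),
    # anchor mutation with too small a gain, drastic but buried -> unassigned
    make_record("t5", mut_offset = 5, noah_score = 0.2, wt_score = 0,
                wt_aa = "D", mut_aa = "K", netmhcpan4 = 1)
  )
  out <- classify_tiers(cases, map)
  expect_equal(out$tier, c(1L, 2L, 3L, 4L, NA_integer_))
  expect_true(out$anchor_hit[1])
  expect_true(out$exposed_hit[2])
  expect_equal(out$physchem_class[2], "drastic")
  expect_match(out$reasons[4], "tier4:frameshift")
  expect_match(out$reasons[5], "unassigned")
})

test_that("tiers partition survivors; frameshifts are exactly tier 4", {
  dir <- tempfile("cohort")
  files <- simulate_inputs(dir, 29, n_binding = 400, n_snv = 30, n_fs = 4)
  prot <- read_proteins(files$proteins)
  vars <- parse_variant_table(files$variants, prot)
  map <- read_contact_map(files$contact_map)
  fit <- noah(utils::read.delim(files$binding), contact_map = map)
  sel <- select_neoantigens(vars, prot, fit, contact_map = map,
                            external = files$external)
  cand <- sel$candidates
  expect_equal(anyDuplicated(cand$variant_id), 0L)
  fs <- cand$origin %in% c("fs_9mer", "fs_long")
  expect_true(all(cand$tier[fs] == 4))
  expect_true(all(is.na(cand$tier[!fs]) | cand$tier[!fs] %in% 1:3))
})
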