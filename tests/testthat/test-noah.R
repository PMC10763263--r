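# PSWM training, scoring, ranking, projection and serialization.

test_that("no training data under a uniform background gives the zero model", {
  map <- tiny_map()
  fit <- suppressWarnings(noah(
    data.frame(peptide = character(), allele = character(),
               label = character()), contact_map = map))
  for (m in fit$matrices) expect_equal(unname(m), rep(0, 20))
  expect_equal(unname(predict(fit, "AWH", allele = "AL1")), 0)
})

test_that("the closed form is recovered in the single-cluster limit", {
  # both positions share one pocket -> one cluster pooling both; binders all
  # carry A; eta = 0, lambda = 0, kappa -> 0 gives weight(A) -> log2(20)
  map <- contact_map(2, list(A1 = c("YYFW", "YYFW")))
  bind <- data.frame(peptide = rep("AA", 10), allele = "A1",
                     label = "binder", stringsAsFactors = FALSE)
  fit <- noah(bind, contact_map = map, kappa = 1e-9, lambda = 0, eta = 0)
  expect_equal(length(fit$matrices), 1)
  expect_equal(unname(fit$matrices[[1]]["A"]), log2(20), tolerance = 1e-6)
})

test_that("a cluster with no positive data falls back to zero with a warning", {
  # allele A2's pockets are dissimilar from A1's, so its clusters receive no
  # observations when all training records concern A1
  map <- contact_map(3, list(A1 = c("YYFW", "YYFW", "DDEE"),
                             A2 = c("GGGG", "GGGG", "PPPP")))
  bind <- data.frame(peptide = c("AAA", "AAC"), allele = "A1",
                     label = c("binder", "nonbinder"),
                     stringsAsFactors = FALSE)
  expect_warning(fit <- noah(bind, contact_map = map),
                 "falling back to background")
  a2_envs <- unique(fit$clusters$env_id[fit$clusters$allele == "A2"])
  for (e in a2_envs)
    expect_equal(unname(fit$matrices[[e]]), rep(0, 20))
})

test_that("scores are additive per-position table lookups", {
  fit <- tiny_fit()
  al <- fit$alleles[1]
  set.seed(21)
  peptides <- random_peptides(50, 9)
  W <- coef(fit, allele = al)
  got <- predict(fit, peptides, allele = al, contributions = TRUE)
  for (i in seq_along(peptides)) {
    res <- strsplit(peptides[i], "")[[1]]
    manual <- vapply(1:9, function(p) W[p, res[p]], numeric(1))
    expect_identical(unname(got$contributions[i, ]), unname(manual))
    expect_equal(got$score[i], sum(manual))
  }
})

test_that("Hamming-1 score differences equal the single weight difference", {
  fit <- tiny_fit()
  al <- fit$alleles[1]
  W <- coef(fit, allele = al)
  set.seed(33)
  for (i in 1:200) {
    pep <- random_peptides(1, 9)
    p <- sample(9, 1)
    res <- strsplit(pep, "")[[1]]
    alt <- sample(setdiff(AA_STANDARD, res[p]), 1)
    res2 <- res
    res2[p] <- alt
    pep2 <- paste(res2, collapse = "")
    d_score <- unname(predict(fit, pep, allele = al) -
                        predict(fit, pep2, allele = al))
    d_weight <- W[p, res[p]] - W[p, alt]
    expect_lt(abs(d_score - unname(d_weight)), 1e-12)
  }
})

test_that("appending binders carrying a residue never lowers its weight", {
  map <- contact_map(2, list(A1 = c("YYFW", "DDEE")))
  set.seed(4)
  base <- data.frame(peptide = random_peptides(60, 2), allele = "A1",
                     label = sample(c("binder", "nonbinder"), 60, TRUE),
                     stringsAsFactors = FALSE)
  fit0 <- noah(base, contact_map = map)
  cl <- fit0$clusters
  for (a in c("W", "K", "G")) {
    # records carrying residue a at every position of the first cluster
    e1_pos <- cl$position[cl$env_id == 1]
    pep <- rep("", 2)
    pep[e1_pos] <- a
    pep[-e1_pos] <- "A"
    extra <- data.frame(peptide = rep(paste(pep, collapse = ""), 10),
                        allele = "A1", label = "binder",
                        stringsAsFactors = FALSE)
    fit1 <- noah(rbind(base, extra), contact_map = map)
    expect_gte(fit1$matrices[[1]][a], fit0$matrices[[1]][a])
  }
})

test_that("scoring rejects wrong lengths and zeroes unknown residues", {
  fit <- tiny_fit()
  al <- fit$alleles[1]
  expect_error(predict(fit, "SHORT", allele = al), "length k")
  expect_warning(sx <- predict(fit, "AXAAAAAAA", allele = al),
                 "non-standard residue")
  s0 <- suppressWarnings(predict(fit, "AXAAAAAAA", allele = al,
                                 contributions = TRUE))
  expect_equal(unname(s0$contributions[1, 2]), 0)
})

test_that("ranking is descending with deterministic tie-breaks", {
  rec <- data.frame(variant_id = c("v2", "v1", "v3"),
                    mut_peptide = c("CCCCCCCCC", "BBBBBBBBB", "AAAAAAAAA"),
                    noah_score = c(3, 1, 2), stringsAsFactors = FALSE)
  ranked <- rank_candidates(rec)
  expect_equal(ranked$noah_score, c(3, 2, 1))
  expect_equal(ranked$noah_rank, 1:3)
  # equal scores: lexicographic peptide then variant id
  tie <- data.frame(variant_id = c("vb", "va"),
                    mut_peptide = c("AAAAAAAAA", "AAAAAAAAA"),
                    noah_score = c(1, 1), stringsAsFactors = FALSE)
  expect_equal(rank_candidates(tie)$variant_id, c("va", "vb"))
})

test_that("ranking is invariant under input permutation", {
  set.seed(9)
  rec <- data.frame(variant_id = sprintf("v%02d", 1:51),
                    mut_peptide = random_peptides(51, 9),
                    noah_score = round(rnorm(51), 3),
                    stringsAsFactors = FALSE)
  r1 <- rank_candidates(rec)
  r2 <- rank_candidates(rec[sample(51), ])
  expect_identical(r1, r2)
})

test_that("projecting a training allele reproduces it exactly", {
  model <- simulate_planted_model(6)
  map <- planted_contact_map(model)
  bind <- sample_binding_records(model, 300, 0, 10)
  fit <- noah(bind$records, contact_map = map)
  al <- model$alleles[1]
  refit <- project_allele(fit, map, alleles = al)
  expect_identical(refit$allele_weights[[al]], fit$allele_weights[[al]])
  set.seed(2)
  pep <- random_peptides(20, 9)
  expect_identical(predict(refit, pep, allele = al),
                   predict(fit, pep, allele = al))
})

test_that("an alien pocket falls back to the global matrix at that position", {
  model <- simulate_planted_model(6)
  map <- planted_contact_map(model)
  bind <- sample_binding_records(model, 300, 0, 10)
  fit <- noah(bind$records, contact_map = map)
  # new allele: copies allele 1 except position 5 gets an unmatched pocket
  pockets <- map$alleles[[model$alleles[1]]]
  pockets[5] <- "CCCCCCCC"
  stopifnot(max(vapply(fit$clusters$pocket, function(p)
    neoforge:::pocket_similarity("CCCCCCCC", p), numeric(1))) < 0.7)
  map2 <- contact_map(9, c(map$alleles, list(NEW = pockets)))
  fit2 <- project_allele(fit, map2, alleles = "NEW")
  expect_equal(fit2$projection$NEW[5], "global")
  W <- fit2$allele_weights$NEW
  expect_equal(unname(W[5, ]), unname(fit$global))
  # all other positions reuse allele 1's matrices verbatim
  W1 <- fit$allele_weights[[model$alleles[1]]]
  expect_identical(W[-5, ], W1[-5, ])
})

test_that("training is deterministic and models round-trip through JSON", {
  model <- simulate_planted_model(12)
  map <- planted_contact_map(model)
  bind <- sample_binding_records(model, 400, 0.1, 13)
  struct <- simulate_structural_records(model, 20, 14)
  f1 <- noah(bind$records, struct, contact_map = map)
  f2 <- noah(bind$records, struct, contact_map = map)
  expect_identical(f1$matrices, f2$matrices)
  path <- tempfile(fileext = ".json")
  write_noah(f1, path)
  f3 <- read_noah(path)
  set.seed(5)
  pep <- random_peptides(100, 9)
  for (al in f1$alleles)
    expect_identical(predict(f1, pep, allele = al),
                     predict(f3, pep, allele = al))
})

test_that("print, summary, coef, plot and simulate methods work", {
  fit <- tiny_fit()
  expect_output(print(fit), "position weight matrix")
  expect_output(print(summary(fit)), "clusters")
  expect_equal(dim(coef(fit)), c(length(fit$matrices), 20))
  expect_equal(dim(coef(fit, allele = fit$alleles[1])), c(9, 20))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  sim <- simulate(fit, nsim = 2, seed = 3, n = 30)
  expect_equal(nrow(sim), 60)
  expect_true(all(sim$label %in% c("binder", "nonbinder")))
  sim2 <- simulate(fit, nsim = 2, seed = 3, n = 30)
  expect_identical(sim, sim2)
})
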