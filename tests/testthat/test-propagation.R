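test_that("propagateSites applies the site AND +1 rule with S/T substitutions", {
  reg <- tinyRegistry()
  msa <- makeMsa(c(REF = "ASPK",
                   "pri1|a" = "ATPK",    # T aligned to S, +1 P conserved
                   "pri2|b" = "ASAK",    # +1 lost
                   "mam1|c" = "A-PK"))   # site column gap
  sites <- tinySites("P1", 2L, "S")
  res <- propagateSites(msa, sites, reg)
  expect_equal(nrow(res$predictions), 1)
  expect_equal(res$predictions$species_id, "pri1")
  expect_equal(res$predictions$residue, "T")
  expect_equal(res$predictions$position, 2L)
  expect_equal(res$predictions$accession, "a")
  expect_equal(res$predictions$source_position, 2L)
})

test_that("C-terminal sites are skipped and reported", {
  reg <- tinyRegistry()
  msa <- makeMsa(c(REF = "AKS", "pri1|a" = "AKS"))
  res <- propagateSites(msa, tinySites("P1", 3L, "S"), reg)
  expect_equal(nrow(res$predictions), 0)
  expect_equal(nrow(res$skipped), 1)
  expect_match(res$skipped$reason, "C-terminal")
})

test_that("predicted positions index the stated residue in the ungapped target", {
  reg <- tinyRegistry()
  set.seed(17)
  aa <- c("A", "C", "D", "E", "S", "T", "Y", "K", "L", "P")
  nChecked <- 0L
  for (rep in 1:20) {
    # subjects are mutated, gap-bearing copies of the reference so that some
    # sites do propagate
    len <- sample(10:30, 1)
    refSeq <- paste(sample(aa, len, replace = TRUE), collapse = "")
    width <- len + 3
    rows <- c(REF = paste0(refSeq, "---"))
    for (i in 1:4) {
      chars <- strsplit(refSeq, "")[[1]]
      mut <- runif(len) < 0.2
      chars[mut] <- sample(aa, sum(mut), replace = TRUE)
      gapAt <- sample(len, 2)
      chars[gapAt] <- "-"
      ins <- paste(sample(aa, 3, replace = TRUE), collapse = "")
      rows[paste0(speciesIds(reg)[i], "|t", i)] <-
        paste0(paste(chars, collapse = ""), ins)
    }
    msa <- makeMsa(rows)
    sty <- which(strsplit(refSeq, "")[[1]] %in% c("S", "T", "Y"))
    if (length(sty) == 0) next
    sites <- tinySites("P", sty,
                       substring(refSeq, sty, sty))
    res <- propagateSites(msa, sites, reg)
    for (i in seq_len(nrow(res$predictions))) {
      p <- res$predictions[i, ]
      rowId <- paste0(p$species_id, "|", p$accession)
      target <- gsub("-", "", as.character(msa@alignment[[rowId]]), fixed = TRUE)
      expect_identical(substr(target, p$position, p$position), p$residue)
      nChecked <- nChecked + 1L
    }
  }
  expect_gt(nChecked, 20)   # the fixture must actually exercise the check
})

test_that("self-propagation predicts exactly the sites that have a +1 residue", {
  set.seed(23)
  reg <- tinyRegistry()
  aa <- c("A", "S", "T", "Y", "K", "L", "P")
  for (rep in 1:10) {
    n <- sample(20:40, 1)
    seqv <- paste(sample(aa, n, replace = TRUE), collapse = "")
    sty <- which(strsplit(seqv, "")[[1]] %in% c("S", "T", "Y"))
    if (length(sty) == 0) next
    msa <- makeMsa(c(REF = seqv, "pri1|self" = seqv))
    sites <- tinySites("P", sty, substring(seqv, sty, sty))
    res <- propagateSites(msa, sites, reg)
    expect_setequal(res$predictions$position, sty[sty < n])
    expect_equal(sort(res$skipped$position), sty[sty >= n])
  }
})

test_that("prediction counts equal the conjunction of site and +1 flags", {
  cfg <- simulationConfig(seed = 404, archetypes = standardArchetypes(3))
  b <- simulateStudy(cfg)
  sc <- profileSites(b$msas, b$sites, b$registry)
  cons <- SummarizedExperiment::assay(sc, "conserved")
  plus1 <- SummarizedExperiment::assay(sc, "plus1")
  allPred <- do.call(rbind, lapply(unique(b$sites$accession), function(acc) {
    propagateSites(b$msas[[acc]],
                   b$sites[b$sites$accession == acc, , drop = FALSE],
                   b$registry)$predictions
  }))
  for (s in sample(speciesIds(b$registry), 10)) {
    expected <- sum(cons[, s] & plus1[, s], na.rm = TRUE)
    expect_equal(sum(allPred$species_id == s), expected, info = s)
  }
})

test_that("making a residue non-conserved never increases predictions", {
  reg <- tinyRegistry()
  msa <- makeMsa(c(REF = "ASPKSA", "pri1|a" = "ASPKSA"))
  sites <- tinySites("P", c(2L, 5L), c("S", "S"))
  n0 <- nrow(propagateSites(msa, sites, reg)$predictions)
  msa2 <- makeMsa(c(REF = "ASPKSA", "pri1|a" = "AAPKSA"))
  n1 <- nrow(propagateSites(msa2, sites, reg)$predictions)
  expect_lte(n1, n0)
})

test_that("validatePredictions reports exact planted evidence fractions", {
  pred <- data.frame(species_id = "pri1",
                     accession = "t", position = 1:10,
                     residue = c(rep("S", 8), "Y", "Y"),
                     plus1_residue = "P", source_accession = "P",
                     source_position = 1:10, source_residue = "S")
  # 40% of the 8 ST predictions evidenced; 2 strong of those 3 (wait: 3.2) ->
  # use positions 1:3 evidenced, 2 strong
  ev <- data.frame(accession = "t", position = c(1, 2, 3, 9),
                   evidence_count = c(10, 7, 2, 1))
  v <- validatePredictions(pred, ev, minStrong = 5)
  st <- v[v$residue_class == "ST", ]
  expect_equal(st$n_predictions, 8)
  expect_equal(st$percent_any_evidence, 100 * 3 / 8)
  expect_equal(st$percent_strong_of_evidenced, 100 * 2 / 3)
  y <- v[v$residue_class == "Y", ]
  expect_equal(y$percent_any_evidence, 50)
  expect_equal(y$n_strong, 0)

  # empty evidence -> 0%
  v0 <- validatePredictions(pred,
                            data.frame(accession = character(0),
                                       position = integer(0),
                                       evidence_count = integer(0)))
  expect_equal(v0$percent_any_evidence[v0$residue_class == "ST"], 0)
  expect_error(validatePredictions(pred[0, ], ev), "empty")
})

test_that("summarizeByGroup counts reconcile across species and groups", {
  reg <- tinyRegistry()
  pred <- data.frame(species_id = c("pri1", "pri2", "mam1", "fish1", "fish1"),
                     accession = "t", position = 1:5,
                     residue = c("S", "T", "Y", "S", "S"),
                     plus1_residue = "P", source_accession = "P",
                     source_position = 1:5, source_residue = "S")
  summ <- summarizeByGroup(pred, reg)
  expect_equal(sum(summ$per_species$n_total), nrow(pred))
  fishRow <- summ$per_group[summ$per_group$group == "fish", ]
  expect_equal(fishRow$n_ser, 2)
  mamRow <- summ$per_group[summ$per_group$group == "mammals", ]
  expect_equal(mamRow$n_total, 3)   # pri1 + pri2 + mam1
  # empty predictions -> all zeros
  z <- summarizeByGroup(pred[0, ], reg)
  expect_true(all(z$per_group$n_total == 0))
})
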