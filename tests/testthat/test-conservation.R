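test_that("siteConserved applies the Ser/Thr substitution and gap rules", {
  msa <- makeMsa(c(H = "ASYK", m1 = "ATYK", m2 = "AS-K", m3 = "ASFK"))
  expect_true(siteConserved(msa, 2, "m1"))          # S aligned with T
  expect_false(siteConserved(msa, 2, "m1", stEquivalent = FALSE))
  expect_true(siteConserved(msa, 3, "m1"))          # Y identity
  expect_false(siteConserved(msa, 3, "m3"))         # Y vs F
  expect_false(siteConserved(msa, 3, "m2"))         # gap
  expect_error(siteConserved(msa, 9, "m1"), "beyond")
})

test_that("Ser/Thr symmetry: swapping S and T in both rows never changes the outcome", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  swapST <- function(x) chartr("ST", "TS", x)
  for (ref in aa) {
    for (subj in c(aa, "X", "-")) {
      msa1 <- makeMsa(c(H = paste0("A", ref), m = paste0("A", subj)))
      msa2 <- makeMsa(c(H = paste0("A", swapST(ref)),
                        m = paste0("A", swapST(subj))))
      expect_identical(siteConserved(msa1, 2, "m"), siteConserved(msa2, 2, "m"),
                       info = sprintf("ref=%s subj=%s", ref, subj))
    }
  }
})

test_that("profileSites computes flags, +1 flags and group percentages", {
  reg <- tinyRegistry()
  # reference ASPK: site S2 with +1 P
  msa <- makeMsa(c(REF = "ASPK",
                   "pri1|a" = "ATPK",    # S->T conserved, +1 conserved
                   "pri2|b" = "AAPK",    # site lost
                   "mam1|c" = "ASAK",    # site ok, +1 lost
                   "fish1|d" = "AS-K"))  # site ok, +1 gap
  sites <- tinySites("P1", 2L, "S")
  sc <- profileSites(list(P1 = msa), sites, reg)
  fl <- SummarizedExperiment::assay(sc, "conserved")[1, ]
  expect_true(fl[["pri1"]]); expect_false(fl[["pri2"]])
  expect_true(fl[["mam1"]]); expect_true(fl[["fish1"]])
  expect_false(fl[["fun1"]])                 # absent from MSA
  p1 <- SummarizedExperiment::assay(sc, "plus1")[1, ]
  expect_true(p1[["pri1"]]); expect_false(p1[["mam1"]]); expect_false(p1[["fish1"]])
  gp <- groupPercent(sc)
  expect_equal(unname(gp[1, "primates"]), 50)        # 1 of 2
  expect_equal(unname(gp[1, "fungi"]), 0)            # absent species count in denominator
  expect_equal(unname(gp[1, "mammals"]), 50)         # 2 of 4
})

test_that("C-terminal sites have undefined +1 flags", {
  reg <- tinyRegistry()
  msa <- makeMsa(c(REF = "AKS", "pri1|a" = "AKS"))
  sc <- profileSites(list(P1 = msa), tinySites("P1", 3L, "S"), reg)
  expect_true(all(is.na(SummarizedExperiment::assay(sc, "plus1")[1, ])))
})

test_that("group percentage invariants: range, monotonicity, weighted broader means", {
  reg <- tinyRegistry()
  set.seed(41)
  for (rep in 1:10) {
    nsub <- sample(2:8, 1)
    ids <- sample(speciesIds(reg), nsub)
    rows <- c(REF = "ASTKY")
    for (id in ids) {
      rows[paste0(id, "|x")] <- paste(sample(c("A", "S", "T", "K", "Y"), 5,
                                             replace = TRUE), collapse = "")
    }
    msa <- makeMsa(rows)
    sc <- profileSites(list(P = msa), tinySites("P", 2L, "S"), reg)
    gp <- groupPercent(sc)
    expect_true(all(gp >= 0 & gp <= 100))
    # broader group = species-count-weighted mean of its base groups
    expect_equal(unname(gp[1, "mammals"]),
                 unname((2 * gp[1, "primates"] + 2 * gp[1, "other_mammals"]) / 4))
  }
  # adding one conserved species never decreases a group percentage
  msa1 <- makeMsa(c(REF = "AS", "pri1|a" = "AS"))
  msa2 <- makeMsa(c(REF = "AS", "pri1|a" = "AS", "pri2|b" = "AS"))
  s <- tinySites("P", 2L, "S")
  expect_gte(unname(groupPercent(profileSites(list(P = msa2), s, reg))[1, "primates"]),
             unname(groupPercent(profileSites(list(P = msa1), s, reg))[1, "primates"]))
})

test_that("profileSites agrees exactly with a brute-force column scanner on random MSAs", {
  set.seed(123)
  aa <- c("S", "T", "Y", "A", "K")
  for (rep in 1:40) {
    msa <- randomMsa(nspecies = sample(2:6, 1), len = sample(8:25, 1))
    refSeq <- referenceSequence(msa)
    pos <- sample(nchar(refSeq), 1)
    oracle <- oracleScan(msa, pos)
    for (id in names(oracle)) {
      expect_identical(siteConserved(msa, pos, id), oracle[[id]],
                       info = sprintf("rep %d row %s pos %d", rep, id, pos))
    }
  }
})

test_that("proteinProfiles averages per residue class", {
  reg <- tinyRegistry()
  msaA <- makeMsa(c(REF = "ASAKSAY",
                    "pri1|a" = "ASAKAAY",   # S2 yes, S5 no, Y7 yes
                    "pri2|b" = "ATAKSAF"))  # S2 yes(T), S5 yes, Y7 no
  sites <- tinySites("P1", c(2L, 5L, 7L), c("S", "S", "Y"))
  sc <- profileSites(list(P1 = msaA), sites, reg)
  pp <- proteinProfiles(sc, "ST")
  # site S2: primates 100; site S5: primates 50 -> mean 75
  expect_equal(pp["P1", "primates"], 75)
  ppy <- proteinProfiles(sc, "Y")
  expect_equal(ppy["P1", "primates"], 50)
  # single-site class: protein profile equals the site profile
  sc1 <- profileSites(list(P1 = msaA), sites[3, , drop = FALSE], reg)
  expect_equal(proteinProfiles(sc1, "Y")["P1", ],
               groupPercent(sc1)[1, ])
  # mean invariant under site reordering
  sc2 <- profileSites(list(P1 = msaA), sites[c(2, 3, 1), ], reg)
  expect_equal(proteinProfiles(sc2, "ST")["P1", ], pp["P1", ])
})

test_that("classifyDisorder uses a strict 0.5 threshold", {
  expect_equal(classifyDisorder(c(0.7, 0.5, 0)),
               c("disordered", "ordered", "ordered"))
  expect_error(classifyDisorder(1.2), "\\[0,1\\]")
})

test_that("Tukey box statistics and Welch comparison", {
  x <- c(1, 2, 3, 4, 100)
  bs <- boxStats(x)
  expect_equal(bs$whisker_high, 4)
  expect_equal(bs$whisker_low, 1)
  expect_equal(bs$outliers, 100)

  same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # planted +30-point shift is detected
  set.seed(202)
  a <- pmin(100, pmax(0, rnorm(50, 50, 12)))
  b <- pmin(100, pmax(0, rnorm(50, 80, 12)))
  res <- compareGroups(a, b)
  expect_lt(res$p_value, 0.05)
})
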