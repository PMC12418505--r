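# exhaustive hypergeometric tail by enumerating all draws of size n from N
enumTail <- function(k, K, N, n) {
  universe <- seq_len(N)
  annotated <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

test_that("hypergeometric p equals exhaustive enumeration (all universes N <= 12)", {
  for (N in 2:12) {
    for (K in 1:N) {
      for (n in 1:N) {
        bg <- sprintf("p%02d", seq_len(N))
        ann <- list(T1 = bg[seq_len(K)])
        cl <- bg[seq_len(n)]
        k <- length(intersect(cl, ann$T1))
        res <- hypergeomEnrich(cl, bg, ann, minTermSize = 1)
        expect_equal(res$p, enumTail(k, K, N, n), tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("hypergeomEnrich worked example and degenerate cases", {
  bg <- sprintf("p%02d", 1:10)
  ann <- list(T1 = bg[1:5])
  res <- hypergeomEnrich(bg[1:4], bg, ann)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)   # N=10,K=5,n=4,k=4

  # k = 0 -> p = 1
  res0 <- hypergeomEnrich(bg[6:9], bg, ann)
  expect_equal(res0$p, 1)

  # cluster = background -> saturation, p = 1
  resAll <- hypergeomEnrich(bg, bg, ann)
  expect_equal(resAll$p, 1)
  expect_equal(resAll$k, resAll$K)

  expect_error(hypergeomEnrich(c(bg, "zz"), bg, ann), "subset")
})

test_that("bhAdjust matches a hand-rolled step-up on random p-vectors", {
  stepUp <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, stepUp(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("mapSitesToDomains applies the first-match rule with inclusive bounds", {
  spans <- data.frame(accession = "P1",
                      start = c(100L, 140L), stop = c(200L, 160L),
                      interpro_id = c("IPR_A", "IPR_B"), file_rank = 1:2)
  sites <- data.frame(accession = "P1", position = c(150L, 99L, 100L, 200L))
  got <- mapSitesToDomains(sites, spans)
  expect_equal(got, c("IPR_A", NA, "IPR_A", "IPR_A"))

  # rank order, not coordinate order, decides overlaps
  spans2 <- spans[2:1, ]; spans2$file_rank <- 1:2
  expect_equal(mapSitesToDomains(sites[1, , drop = FALSE], spans2), "IPR_B")
})

test_that("domainFoldEnrichment computes (a/b)/(A/B) and filters A < 2", {
  keys <- sprintf("P1:%d", 1:20)
  dm <- stats::setNames(c(rep("D1", 5), rep("D2", 14), "D3"), keys)
  res <- domainFoldEnrichment(keys[1:4][c(1, 2)], keys, dm)
  # a=2 (both in D1), b=2, A=5, B=20 -> fold for D1 = (2/2)/(5/20) = 4
  d1 <- res[res$interpro_id == "D1", ]
  expect_equal(d1$fold, 4)
  expect_equal(d1$log2_fold, 2)
  expect_equal(d1$percent_mapped, 100)
  expect_false("D3" %in% res$interpro_id)       # A = 1 excluded

  # pattern = background -> fold 1 everywhere
  resAll <- domainFoldEnrichment(keys, keys, dm)
  expect_true(all(resAll$fold == 1))
  # and the A-weighted mean fold is 1
  expect_equal(sum(resAll$fold * resAll$A) / sum(resAll$A), 1)

  expect_error(domainFoldEnrichment(c(keys, "x:1"), keys, dm), "subset")
})

test_that("worked fold-enrichment example a=2 b=4 A=5 B=20", {
  keys <- sprintf("P:%d", 1:20)
  dm <- stats::setNames(c(rep("D", 5), rep(NA, 15)), keys)
  pat <- keys[c(1, 2, 6, 7)]     # 2 in domain, 2 unmapped -> b counts mapped only
  # to realize b = 4 mapped pattern sites with a = 2 in D, map the others elsewhere
  dm[c("P:6", "P:7")] <- "E"
  res <- domainFoldEnrichment(pat, keys, dm)
  d <- res[res$interpro_id == "D", ]
  expect_equal(d$a, 2); expect_equal(d$b, 4)
  expect_equal(d$A, 5); expect_equal(d$B, 7)
  expect_equal(d$fold, (2 / 4) / (5 / 7))
})

test_that("enrichmentFactor arithmetic, saturation and duplication invariance", {
  prot <- Biostrings::AAStringSet(c(p1 = "SSSSSTTTTTYYYYYAAAAA"))
  # evidence covers 10% of the 15 S/T/Y residues is impossible with integers;
  # use 3 of 15 = 20%
  ev <- data.frame(accession = "p1", position = c(1, 2, 3))
  pred <- data.frame(accession = "p1", position = c(1, 2))
  res <- enrichmentFactor(pred, ev, prot)
  expect_equal(res$observed_rate, 1)
  expect_equal(res$background_rate, 3 / 15)
  expect_equal(res$factor, 5)

  # evidence = all S/T/Y residues -> factor exactly 1
  evAll <- data.frame(accession = "p1", position = 1:15)
  expect_equal(enrichmentFactor(pred, evAll, prot)$factor, 1)

  # duplicating every protein leaves the factor unchanged
  prot2 <- Biostrings::AAStringSet(c(p1 = "SSSSSTTTTTYYYYYAAAAA",
                                     p1 = "SSSSSTTTTTYYYYYAAAAA"))
  expect_equal(enrichmentFactor(pred, ev, prot2)$factor, res$factor)

  expect_error(enrichmentFactor(pred[0, ], ev, prot), "empty")
})

test_that("uniformly random predictions give factor near 1", {
  set.seed(31)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("S", "T", "Y", "A", "K", "L"), 200, replace = TRUE),
          collapse = "")
  }, "")
  names(seqs) <- sprintf("p%02d", 1:30)
  prot <- Biostrings::AAStringSet(seqs)
  sty <- do.call(rbind, lapply(names(seqs), function(a) {
    pos <- which(strsplit(seqs[[a]], "")[[1]] %in% c("S", "T", "Y"))
    data.frame(accession = a, position = pos)
  }))
  ev <- sty[runif(nrow(sty)) < 0.3, ]
  factors <- replicate(50, {
    pred <- sty[sample(nrow(sty), 500), ]
    enrichmentFactor(pred, ev, prot)$factor
  })
  # mean over draws is ~1 with binomial-scale error
  expect_lt(abs(mean(factors) - 1), 0.05)
})
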