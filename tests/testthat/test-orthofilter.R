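test_that("component representative is the longest ORF with deterministic ties", {
  comp <- data.frame(contig_id = c("c1", "c2", "c3"),
                     component_id = "comp1",
                     sequence_length = c(1000, 1500, 900),
                     orf_start = 0L, orf_end = c(300L, 900L, 450L))
  expect_identical(select_component_representative(comp), "c2")
  expect_identical(select_component_representative(comp[1, ]), "c1")

  # equal ORF lengths: longer contig wins; then smaller id
  tie <- data.frame(contig_id = c("cB", "cA"), component_id = "comp2",
                    sequence_length = c(800, 1200),
                    orf_start = 0L, orf_end = 600L)
  expect_identical(select_component_representative(tie), "cA")
  tie$sequence_length <- c(1200, 1200)
  expect_identical(select_component_representative(tie), "cA")

  expect_error(select_component_representative(comp[0, ]), "empty")
  comp$component_id <- c("x", "y", "z")
  expect_error(select_component_representative(comp), "component")
})

test_that("pair classification separates isoforms, paralogs and sub-gene paralogs", {
  set.seed(42)
  base <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)

  ident <- classify_pair(base, base)
  expect_identical(ident$verdict, "compatible")
  expect_equal(ident$mean_identity, 1.0)

  # 30 uniformly spread mismatches: identity 0.970 < 0.98, no local tract
  mm <- base
  idx <- round(seq(10, 990, length.out = 30))
  mm[idx] <- vapply(mm[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  res <- classify_pair(base, mm)
  expect_identical(res$verdict, "paralog")
  expect_equal(res$mean_identity, 0.970)

  # internal 90-column tract at 60% identity: sub-gene paralogy wins even
  # though the mean identity (0.964) alone would only say "paralog"
  tract <- base
  tr_idx <- sample(450:539, 36)
  tract[tr_idx] <- vapply(tract[tr_idx],
                          function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  res <- classify_pair(base, tract)
  expect_identical(res$verdict, "paralog_subgene")
  expect_equal(res$mean_identity, 0.964)
  expect_gte(nrow(res$flagged_internal_tracts), 1)
  # the detector must cover the planted window
  expect_lte(res$flagged_internal_tracts[1, 1], 450)
  expect_gte(res$flagged_internal_tracts[1, 2], 539)

  # a low-identity tract at the terminus is excluded from the mean
  term <- base
  term[1:80] <- vapply(term[1:80],
                       function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  res <- classify_pair(base, term)
  expect_identical(res$verdict, "compatible")
  expect_gt(res$excluded_terminal_columns, 0)

  expect_error(classify_pair("---", "AC-"), "comparable")
})

test_that("pair classification is symmetric and monotone in the threshold", {
  set.seed(7)
  for (rep in 1:5) {
    a <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
    b <- a
    n_mut <- sample(c(5, 15, 30), 1)
    idx <- sample(600, n_mut)
    b[idx] <- vapply(b[idx], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    r1 <- classify_pair(a, b)
    r2 <- classify_pair(b, a)
    expect_identical(r1$verdict, r2$verdict)
    expect_equal(r1$mean_identity, r2$mean_identity)
    # raising the threshold can only make the call stricter
    lo <- classify_pair(a, b, identity_threshold = 0.90)
    hi <- classify_pair(a, b, identity_threshold = 0.999)
    if (lo$verdict == "paralog") expect_false(hi$verdict == "compatible")
  }
})

test_that("cluster filtering annotates every violated criterion", {
  mk <- function(id, taxa, contigs) {
    df <- data.frame(taxon = taxa, contig_id = contigs)
    df
  }
  clusters <- list(inflation = 1.5, clusters = list(
    ok1 = mk("ok1", c("t1", "t2", "t3", "t4", "St", "St"),
             c("a1", "b1", "c1", "d1", "s1", "s2")),
    ok2 = mk("ok2", c("t1", "t2", "t3", "t4"), c("a2", "b2", "c2", "d2")),
    par = mk("par", c("t1", "t1", "t2", "t3", "t4"),
             c("a3", "a3p", "b3", "c3", "d3")),
    miss = mk("miss", c("t1", "t2", "t3"), c("a4", "b4", "c4")),
    backb = mk("backb", c("t1", "t2", "t3", "t4", "St", "St", "St", "St"),
               c("a5", "b5", "c5", "d5", "s5", "s6", "s7", "s8")),
    multi = mk("multi", c("t1", "t1", "t2", "St", "St", "St", "St"),
               c("a6", "a6p", "b6", "s9", "s10", "s11", "s12"))))
  pp <- data.frame(taxon = "t1", contig_a = c("a3", "a6"),
                   contig_b = c("a3p", "a6p"))
  dec <- filter_clusters(clusters, pp, required_taxa = paste0("t", 1:4),
                         backbone_taxon = "St", backbone_limit = 3)
  expect_identical(dec$cluster_id[dec$retained], c("ok1", "ok2"))
  # the multiply-violating cluster carries all of its reasons
  multi <- dec[dec$cluster_id == "multi", ]
  expect_true(multi$has_paralog_pair && multi$missing_taxon && multi$excess_backbone)
  # per-reason counts can sum to more than the number excluded
  expect_identical(sum(!dec$retained), 4L)
  expect_gte(sum(dec$has_paralog_pair) + sum(dec$missing_taxon) +
               sum(dec$excess_backbone), 4L)
  # empty input
  empty <- filter_clusters(list(inflation = 1.5, clusters = list()), pp,
                           "t1", "St")
  expect_identical(nrow(empty), 0L)
})

test_that("robustness requires exact non-backbone membership at every inflation", {
  mk_set <- function(..., inflation = 1) {
    cl <- list(...)
    list(inflation = inflation, clusters = cl)
  }
  c1 <- data.frame(taxon = c("t1", "t2", "St"), contig_id = c("a", "b", "s"))
  c2 <- data.frame(taxon = c("t1", "t2"), contig_id = c("x", "y"))
  primary <- mk_set(g1 = c1, g2 = c2)

  # identical clusterings (different backbone attachment is tolerated)
  c1_alt <- data.frame(taxon = c("t1", "t2", "St", "St"),
                       contig_id = c("a", "b", "s", "s2"))
  same <- mk_set(A1 = c1_alt, A2 = c2)
  expect_setequal(robust_orthogroups(c("g1", "g2"), primary, list(same), "St"),
                  c("g1", "g2"))

  # an alternate that splits g2 removes it
  split_alt <- mk_set(A1 = c1,
                      A2a = data.frame(taxon = "t1", contig_id = "x"),
                      A2b = data.frame(taxon = "t2", contig_id = "y"))
  expect_identical(robust_orthogroups(c("g1", "g2"), primary,
                                      list(same, split_alt), "St"), "g1")

  # anti-monotone: adding alternates never enlarges the robust set
  r1 <- robust_orthogroups(c("g1", "g2"), primary, list(same), "St")
  r2 <- robust_orthogroups(c("g1", "g2"), primary, list(same, split_alt), "St")
  expect_true(all(r2 %in% r1))

  # 10 clusters, 3 perturbed at the highest inflation -> 7 robust
  big <- list(inflation = 1.5, clusters = lapply(1:10, function(i)
    data.frame(taxon = c("t1", "t2"), contig_id = paste0(c("a", "b"), i))))
  names(big$clusters) <- paste0("G", 1:10)
  pert <- big
  for (i in 1:3)
    pert$clusters[[paste0("G", i)]] <-
      data.frame(taxon = "t1", contig_id = paste0("a", i))
  expect_length(robust_orthogroups(paste0("G", 1:10), big, list(pert), "St"), 7L)
})

test_that("groups files round-trip through the OrthoMCL dialect", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1: t1|a t2|b St|s1", "G2: t1|x t2|y"), tmp)
  cs <- read_groups_file(tmp, inflation = 1.5)
  expect_identical(names(cs$clusters), c("G1", "G2"))
  expect_identical(cs$clusters$G1$contig_id, c("a", "b", "s1"))
  writeLines(c("G1: t1|a", "G2: t1|a"), tmp)
  expect_error(read_groups_file(tmp), "more than one cluster")
})
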