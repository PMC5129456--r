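test_that("alternate haplotypes apply het SNPs and drop indels and alt-homozygotes", {
  ref <- "ATGGCTGGCCATGGA"
  none <- apply_vcf_haplotype(ref, NULL)
  expect_identical(none$alt_seq, ref)
  expect_identical(none$n_het_applied, 0L)

  one <- apply_vcf_haplotype(ref, data.frame(pos = 10L, ref = "C", alt = "T",
                                             gt = "0/1", filter = "PASS"))
  expect_identical(substr(one$alt_seq, 10, 10), "T")
  expect_identical(which(strsplit(one$alt_seq, "")[[1]] !=
                           strsplit(ref, "")[[1]]), 10L) # differs only there
  expect_identical(one$n_het_applied, 1L)

  mixed <- apply_vcf_haplotype(ref, data.frame(
    pos = c(4L, 7L, 13L),
    ref = c("G", "G", "G"),
    alt = c("A", "GAT", "T"),
    gt = c("0/1", "0/1", "1/1"),
    filter = "PASS"))
  expect_identical(mixed$n_het_applied, 1L)
  expect_identical(mixed$n_indels_dropped, 1L)
  expect_identical(mixed$n_alt_homozygotes_dropped, 1L)
  expect_identical(substr(mixed$alt_seq, 4, 4), "A")
  expect_identical(substr(mixed$alt_seq, 13, 13), "G") # 1/1 not applied

  expect_error(
    apply_vcf_haplotype(ref, data.frame(pos = 99L, ref = "A", alt = "T",
                                        gt = "0/1", filter = "PASS"),
                        contig_id = "ctg7"),
    "ctg7")
})

test_that("codon alignments back-translate peptide gaps in frame", {
  hp <- function(ref, alt = ref)
    structure(list(ref_seq = ref, alt_seq = alt), class = "haplotype_pair")

  # identical ungapped peptides
  cds <- "ATGGGAGCT" # M G A
  aln <- build_codon_alignment("MGA", "MGA", hp(cds), hp(cds))
  expect_identical(ncol(aln), 9L)
  expect_identical(paste(aln["a_ref", ], collapse = ""), cds)

  # one-residue gap in taxon B becomes a 3-column gap in both B rows
  cds_b <- "ATGGCT" # M A
  aln <- build_codon_alignment("MGA", "M-A", hp(cds), hp(cds_b))
  expect_identical(paste(aln["b_ref", 4:6], collapse = ""), "---")
  expect_identical(paste(aln["b_alt", 4:6], collapse = ""), "---")
  expect_identical(paste(aln["b_ref", ], collapse = ""), "ATG---GCT")

  # planted SNPs land at predicted columns around two gaps
  cds_a2 <- "ATGGGAGCTAAAGAA"  # M G A K E
  alt_a2 <- "ATGGGCGCTAAAGAA"  #   SNP at cds pos 6
  cds_b2 <- "ATGGCTGAA"        # M A E
  alt_b2 <- "ATGGCTGAG"        #     SNP at cds pos 9
  aln <- build_codon_alignment("MGAKE", "M-A-E", hp(cds_a2, alt_a2),
                               hp(cds_b2, alt_b2))
  expect_identical(unname(aln["a_alt", 6]), "C")
  expect_identical(unname(aln["a_ref", 6]), "A")
  expect_identical(unname(aln["b_alt", 15]), "G")
  expect_identical(unname(aln["b_ref", 15]), "A")

  expect_error(build_codon_alignment("MW", "MW", hp("ATGGGA"), hp("ATGTGG"),
                                     orthogroup_id = "OG9"),
               "OG9")
})

test_that("fourfold sites require a shared fourfold codon prefix", {
  rn <- c("a_ref", "a_alt", "b_ref", "b_alt")

  aln <- do.call(rbind, strsplit(c("GGT", "GGT", "GGC", "GGC"), ""))
  rownames(aln) <- rn
  expect_identical(fourfold_sites(aln), 3L) # glycine: fourfold

  aln <- do.call(rbind, strsplit(rep("TGG", 4), ""))
  rownames(aln) <- rn
  expect_length(fourfold_sites(aln), 0L) # tryptophan: single codon

  aln <- do.call(rbind, strsplit(c("GGA", "GGA", "CGA", "CGA"), ""))
  rownames(aln) <- rn
  expect_length(fourfold_sites(aln), 0L) # first position differs across rows

  aln <- do.call(rbind, strsplit(c("GGAGGT", "GGAGG-", "GGAGGT", "GGAGGT"), ""))
  rownames(aln) <- rn
  expect_identical(fourfold_sites(aln), 3L) # gapped codon disqualified
})

test_that("site classification folds alleles and rejects multiallelic columns", {
  expect_identical(classify_site(c("C", "C", "C", "C")), "invariant")
  expect_identical(classify_site(c("C", "T", "C", "C")), "kA")
  expect_identical(classify_site(c("C", "C", "C", "T")), "kB")
  expect_identical(classify_site(c("C", "T", "C", "T")), "kAB")
  expect_identical(classify_site(c("C", "C", "T", "T")), "kAABB")
  expect_identical(classify_site(c("C", "T", "C", "G")), "excluded_multiallelic")
  expect_identical(classify_site(c("C", "N", "C", "C")), "excluded_ambiguous")

  # folding: swapping within-taxon haplotypes or relabeling alleles is
  # irrelevant
  set.seed(3)
  for (i in 1:20) {
    b <- sample(c("A", "G"), 4, replace = TRUE)
    cls <- classify_site(b)
    expect_identical(classify_site(b[c(2, 1, 3, 4)]), cls)
    expect_identical(classify_site(b[c(1, 2, 4, 3)]), cls)
    swapped <- chartr("AG", "GA", b)
    expect_identical(classify_site(swapped), cls)
  }
})

test_that("blocks are cut from consecutive qualifying sites", {
  few <- rep("invariant", 149)
  expect_identical(nrow(make_blocks(few, "og1")), 0L)

  cls <- rep("invariant", 150)
  cls[c(2, 30, 77)] <- "kA"
  cls[c(10, 140)] <- "kAABB"
  tab <- make_blocks(cls, "og1")
  expect_identical(tab$kA, 3L)
  expect_identical(tab$kAABB, 2L)
  expect_identical(tab$kB + tab$kAB, 0L)
  expect_true(tab$four_gamete_pass)

  # 320 sites: all_blocks yields 2 full blocks, the default policy 1
  long <- rep("invariant", 320)
  long[c(5, 200)] <- "kAB"
  expect_identical(nrow(make_blocks(long, "og1", policy = "all_blocks")), 2L)
  expect_identical(nrow(make_blocks(long, "og1")), 1L)

  # excluded sites occupy block positions but count to no class
  cls[1] <- "excluded_multiallelic"
  tab2 <- make_blocks(cls, "og1")
  expect_identical(tab2$kA + tab2$kB + tab2$kAB + tab2$kAABB, 5L)
})

test_that("four-gamete rule fails only on joint kAB and kAABB", {
  expect_true(four_gamete_pass(list(kAB = 0, kAABB = 10)))
  expect_true(four_gamete_pass(list(kAB = 2, kAABB = 0)))
  expect_false(four_gamete_pass(list(kAB = 1, kAABB = 1)))
})

test_that("SFS summaries count sites and draws correctly", {
  blocks <- data.frame(orthogroup = c("a", "b"), n_sites = 150,
                       kA = c(3, 0), kB = c(0, 3), kAB = 0, kAABB = c(0, 4),
                       four_gamete_pass = TRUE)
  s <- summarize_sfs(blocks, "all_sites")
  expect_equal(unname(s$frequencies), c(0.01, 0.01, 0, 2 / 150))

  zero <- blocks
  zero[, c("kA", "kB", "kAB", "kAABB")] <- 0
  expect_true(all(summarize_sfs(zero, "all_sites")$frequencies == 0))

  d1 <- summarize_sfs(blocks, "one_variable_site_per_block", seed = 5)
  d2 <- summarize_sfs(blocks, "one_variable_site_per_block", seed = 5)
  expect_identical(d1$drawn_counts, d2$drawn_counts)
  expect_identical(sum(d1$drawn_counts), 2L) # one site per variable block
})

test_that("block tables round-trip through TSV", {
  tab <- toy_blocks()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_block_table(tab, tmp)
  back <- read_block_table(tmp)
  expect_equal(back$kAABB, tab$kAABB)
  expect_equal(back$four_gamete_pass, tab$four_gamete_pass)
})
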