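# Synthetic data with the statistical structure the analysis assumes:
# block tables drawn from the coalescent simulator, and full sequence
# fixtures (CDS/peptide FASTA, VCF, cluster files) with planted paralogs,
# isoforms and variants plus truth tables, so the whole pipeline can be
# exercised end to end without external data.

.NONFOURFOLD_CODONS <- c("TTT", "TTC", "ATG", "ATC", "ATT", "AAA", "AAG",
                         "GAA", "GAG", "CAT", "CAC", "TGG", "GAT", "GAC")

#' Describe a synthetic scenario
#'
#' Bundles a demographic model with the dimensions of the synthetic data
#' to generate.  The defaults emulate the study conditions this package
#' was built around: about 1,500 blocks of 150 fourfold degenerate sites
#' from coding sequences averaging ~1,500 bp, per-site theta of order
#' 0.001-0.0075, split times of a few to ~20 (in units of 2 Nanc
#' generations) and weak unidirectional migration.
#'
#' @param model A \code{\link{demographic_model}} (default: an IM2 model
#'   typical of a pair of hybridizing taxa, theta 0.00154, T 19.8,
#'   M 0.015 into A, size factor 1.36 on A).
#' @param n_blocks Number of blocks for block-table simulation.
#' @param n_sites Sites per block.
#' @param n_orthogroups Orthogroups in a sequence fixture.
#' @param n_codons Codons per synthetic CDS.
#' @param fourfold_density Fraction of codons drawn from
#'   fourfold-degenerate families.
#' @param taxa Names of the two focal taxa (A first).
#' @param backbone Name of the outgroup backbone taxon.
#' @param backbone_limit Maximum backbone contigs per retained cluster.
#' @param inflation_grid Inflation values of the emitted clusterings.
#' @param n_planted_indels,n_planted_althom Spurious VCF records planted
#'   in taxon A's VCF (indels / alternate homozygotes).
#' @param seed Master seed; every derived draw is reproducible from it.
#' @return List of class \code{"synthetic_scenario"}.
#' @export
synthetic_scenario <- function(model = NULL, n_blocks = 1479, n_sites = 150,
                               n_orthogroups = 8, n_codons = 520,
                               fourfold_density = 0.35,
                               taxa = c("taxA", "taxB"), backbone = "outg",
                               backbone_limit = 3,
                               inflation_grid = c(0.5, 1, 1.5, 2, 3, 5),
                               n_planted_indels = 2, n_planted_althom = 2,
                               seed = 1) {
  if (is.null(model))
    model <- demographic_model("IM2", theta = 0.00154, T = 19.8, M = 0.015,
                               direction = "B->A", size_factor = 1.36,
                               factor_target = "A")
  stopifnot(inherits(model, "demographic_model"), n_blocks >= 1,
            n_sites >= 1, fourfold_density > 0, fourfold_density <= 1,
            length(taxa) == 2L)
  if (floor(n_codons * fourfold_density) < n_sites)
    stop("n_codons x fourfold_density must provide at least n_sites ",
         "fourfold sites")
  structure(list(model = model, n_blocks = n_blocks, n_sites = n_sites,
                 n_orthogroups = n_orthogroups, n_codons = n_codons,
                 fourfold_density = fourfold_density, taxa = taxa,
                 backbone = backbone, backbone_limit = backbone_limit,
                 inflation_grid = inflation_grid,
                 n_planted_indels = as.integer(n_planted_indels),
                 n_planted_althom = as.integer(n_planted_althom),
                 seed = seed),
            class = "synthetic_scenario")
}

#' Simulate a block table under a scenario
#'
#' Draws \code{n_blocks} independent blockwise mutation configurations
#' from the scenario's demographic model and formats them as a block
#' table with four-gamete flags.
#'
#' @param scenario A \code{\link{synthetic_scenario}}.
#' @return Block table data frame.
#' @export
simulate_block_table <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  k <- simulate_blocks(scenario$model, scenario$n_blocks, scenario$n_sites)
  data.frame(orthogroup = sprintf("og%05d", seq_len(scenario$n_blocks)),
             n_sites = scenario$n_sites, k,
             four_gamete_pass = !(k[, "kAB"] > 0 & k[, "kAABB"] > 0),
             stringsAsFactors = FALSE)
}

#' Generate a full sequence fixture
#'
#' Writes CDS and peptide FASTA files, per-taxon VCFs, cluster files at
#' each inflation value and truth tables into \code{dir}.  Planted
#' objects: per-orthogroup site classes realised from a simulated
#' genealogy (mutations restricted to the first \code{n_sites} fourfold
#' sites, so the first block equals the simulated configuration); one
#' cluster contaminated with a global paralog pair; one with an excess of
#' backbone contigs; one whose membership is split at the highest
#' inflation value (not robust); an isoform component (compatible pair);
#' a sub-gene paralog pair (internal low-identity tract); and spurious
#' indel / alternate-homozygote VCF records.
#'
#' @param scenario A \code{\link{synthetic_scenario}} with
#'   \code{n_orthogroups >= 4}.
#' @param dir Output directory (created if needed).
#' @return Manifest list: file paths, truth block table
#'   (\code{truth_blocks}), planted paralog pairs
#'   (\code{paralog_pairs}), planted VCF drop counts
#'   (\code{planted_drops}), expected retained orthogroups
#'   (\code{expected_retained}), contig metadata and the orthogroup ->
#'   contig map.
#' @export
simulate_fixture <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            scenario$n_orthogroups >= 4)
  set.seed(scenario$seed + 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- scenario
  tA <- sc$taxa[1]
  tB <- sc$taxa[2]
  n_og <- sc$n_orthogroups
  og_ids <- sprintf("OG%03d", seq_len(n_og))

  cds <- list()
  pep <- list()
  meta <- list()
  vcf <- list()
  vcf[[tA]] <- list()
  vcf[[tB]] <- list()
  truth <- list()

  for (i in seq_len(n_og)) {
    g <- .synth_orthogroup(sc)
    idA <- sprintf("%s_og%03d", tA, i)
    idB <- sprintf("%s_og%03d", tB, i)
    cds[[tA]][[idA]] <- g$a_ref
    cds[[tB]][[idB]] <- g$b_ref
    pep[[tA]][[idA]] <- .translate_cds(g$a_ref)
    pep[[tB]][[idB]] <- .translate_cds(g$b_ref)
    meta[[length(meta) + 1L]] <- data.frame(
      contig_id = c(idA, idB), taxon = c(tA, tB),
      component_id = sprintf("comp_%s_%03d", c(tA, tB), i),
      sequence_length = nchar(c(g$a_ref, g$b_ref)),
      orf_start = 0L, orf_end = nchar(c(g$a_ref, g$b_ref)))
    vcf[[tA]][[idA]] <- g$vcf_a
    vcf[[tB]][[idB]] <- g$vcf_b
    truth[[i]] <- data.frame(orthogroup = og_ids[i], n_sites = sc$n_sites,
                             kA = g$k[1], kB = g$k[2], kAB = g$k[3],
                             kAABB = g$k[4],
                             four_gamete_pass = !(g$k[3] > 0 && g$k[4] > 0))
  }
  truth_blocks <- do.call(rbind, truth)

  # ---- planted paralogs and isoform -----------------------------------
  rep1 <- sprintf("%s_og%03d", tA, 1L)
  par1 <- paste0(rep1, "_par") # global paralog: ~4% divergence
  cds[[tA]][[par1]] <- .mutate_fraction(cds[[tA]][[rep1]], 0.04)
  rep4 <- sprintf("%s_og%03d", tA, 4L)
  par4 <- paste0(rep4, "_par") # sub-gene paralog: internal 300-nt tract
  cds[[tA]][[par4]] <- .mutate_tract(cds[[tA]][[rep4]], 601L, 900L, 0.4)
  iso2 <- sprintf("%s_og%03d_iso", tA, 2L) # isoform: 3'-truncated copy
  full2 <- sprintf("%s_og%03d", tA, 2L)
  cds[[tA]][[iso2]] <- substr(cds[[tA]][[full2]], 1L,
                              nchar(cds[[tA]][[full2]]) - 60L)
  for (extra in c(par1, par4, iso2)) {
    comp_i <- sub(".*og(\\d+).*", "\\1", extra)
    meta[[length(meta) + 1L]] <- data.frame(
      contig_id = extra, taxon = tA,
      component_id = sprintf("comp_%s_%s", tA, comp_i),
      sequence_length = nchar(cds[[tA]][[extra]]),
      orf_start = 0L, orf_end = nchar(cds[[tA]][[extra]]))
    pep[[tA]][[extra]] <- .translate_cds(cds[[tA]][[extra]])
  }
  paralog_pairs <- data.frame(
    taxon = tA,
    contig_a = c(rep1, rep4, full2),
    contig_b = c(par1, par4, iso2),
    verdict = c("paralog", "paralog_subgene", "compatible"))

  # ---- planted spurious VCF records in taxon A, orthogroup n_og -------
  target <- sprintf("%s_og%03d", tA, n_og)
  seqt <- .split_chars(cds[[tA]][[target]])
  taken <- vcf[[tA]][[target]]$pos
  free <- setdiff(seq_along(seqt), taken)
  pick <- sample(free, sc$n_planted_indels + sc$n_planted_althom)
  extra_rec <- list()
  for (j in seq_len(sc$n_planted_indels)) {
    p <- pick[j]
    extra_rec[[j]] <- data.frame(pos = p, ref = seqt[p],
                                 alt = paste0(seqt[p], "A"), gt = "0/1",
                                 filter = "PASS")
  }
  for (j in seq_len(sc$n_planted_althom)) {
    p <- pick[sc$n_planted_indels + j]
    other <- setdiff(c("A", "C", "G", "T"), seqt[p])[1]
    extra_rec[[sc$n_planted_indels + j]] <-
      data.frame(pos = p, ref = seqt[p], alt = other, gt = "1/1",
                 filter = "PASS")
  }
  vcf[[tA]][[target]] <- rbind(vcf[[tA]][[target]], do.call(rbind, extra_rec))
  vcf[[tA]][[target]] <- vcf[[tA]][[target]][order(vcf[[tA]][[target]]$pos), ]
  planted_drops <- list(contig = target, n_indels = sc$n_planted_indels,
                        n_alt_homozygotes = sc$n_planted_althom)

  # ---- cluster files ---------------------------------------------------
  # og1: contaminated with the paralog pair; og2: backbone excess;
  # og3: split at the highest inflation (not robust); the rest clean.
  make_cluster_line <- function(id, members)
    paste0(id, ": ", paste(members, collapse = " "))
  base_members <- function(i, n_backbone = 2L) {
    m <- c(sprintf("%s|%s_og%03d", tA, tA, i), sprintf("%s|%s_og%03d", tB, tB, i),
           sprintf("%s|st%03d_%d", sc$backbone, i, seq_len(n_backbone)))
    m
  }
  primary_lines <- character(n_og)
  for (i in seq_len(n_og)) {
    members <- base_members(i)
    if (i == 1L) members <- c(members, paste0(tA, "|", par1))
    if (i == 2L) members <- base_members(i, sc$backbone_limit + 1L)
    primary_lines[i] <- make_cluster_line(og_ids[i], members)
  }
  files <- list()
  for (inf in sc$inflation_grid) {
    lines <- primary_lines
    if (inf == max(sc$inflation_grid)) {
      # split og3 between two clusters
      m3 <- strsplit(sub("^OG\\d+: ", "", primary_lines[3]), " ")[[1]]
      keep <- grepl(paste0("^", tA, "\\|"), m3)
      lines[3] <- make_cluster_line(og_ids[3], m3[keep])
      lines <- c(lines, make_cluster_line("OG900", m3[!keep]))
    }
    f <- file.path(dir, sprintf("groups_inflation%s.txt", inf))
    writeLines(lines, f)
    files[[sprintf("groups_%s", inf)]] <- f
  }

  # ---- FASTA / VCF / tables -------------------------------------------
  for (tx in c(tA, tB)) {
    f1 <- file.path(dir, paste0(tx, "_cds.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(cds[[tx]])), f1)
    f2 <- file.path(dir, paste0(tx, "_pep.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(unlist(pep[[tx]])), f2)
    f3 <- file.path(dir, paste0(tx, ".vcf"))
    .write_vcf(f3, vcf[[tx]], tx)
    files[[paste0("cds_", tx)]] <- f1
    files[[paste0("pep_", tx)]] <- f2
    files[[paste0("vcf_", tx)]] <- f3
  }
  meta <- do.call(rbind, meta)
  f <- file.path(dir, "contigs.tsv")
  utils::write.table(meta, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files$contigs <- f
  f <- file.path(dir, "paralog_pairs.tsv")
  utils::write.table(paralog_pairs, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$paralog_pairs <- f
  f <- file.path(dir, "truth_blocks.tsv")
  write_block_table(truth_blocks, f)
  files$truth_blocks <- f

  expected_retained <- og_ids[-(1:3)]
  og_map <- stats::setNames(
    lapply(seq_len(n_og), function(i)
      list(contig_a = sprintf("%s_og%03d", tA, i),
           contig_b = sprintf("%s_og%03d", tB, i))),
    og_ids)
  list(dir = dir, files = files, truth_blocks = truth_blocks,
       paralog_pairs = paralog_pairs, planted_drops = planted_drops,
       expected_retained = expected_retained, contigs = meta,
       orthogroup_map = og_map, scenario = sc)
}

# one orthogroup: ancestral CDS, four descendant haplotypes realised from
# a simulated genealogy, VCF records for the heterozygous sites
.synth_orthogroup <- function(sc) {
  n_codons <- sc$n_codons
  n_ff <- floor(n_codons * sc$fourfold_density)
  ff_idx <- sort(sample(seq_len(n_codons - 1L), n_ff)) # keep last codon plain
  codons <- character(n_codons)
  codons[ff_idx] <- paste0(sample(.FOURFOLD_PREFIXES, n_ff, replace = TRUE),
                           sample(c("A", "C", "G", "T"), n_ff, replace = TRUE))
  codons[-ff_idx] <- sample(.NONFOURFOLD_CODONS, n_codons - n_ff,
                            replace = TRUE)
  anc <- .split_chars(paste(codons, collapse = ""))
  a_ref <- a_alt <- b_ref <- b_alt <- anc

  k <- as.integer(simulate_blocks(sc$model, 1L, sc$n_sites)[1, ])
  # mutations land on distinct sites among the first n_sites fourfold sites
  ff_third <- ff_idx * 3L
  usable <- ff_third[seq_len(min(sc$n_sites, length(ff_third)))]
  total <- sum(k)
  if (total > length(usable))
    stop("more mutations than available fourfold sites; increase n_codons")
  pos <- sample(usable, total)
  classes <- rep(c("kA", "kB", "kAB", "kAABB"), times = k)
  for (j in seq_along(pos)) {
    p <- pos[j]
    derived <- sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1L)
    switch(classes[j],
           kA = { a_alt[p] <- derived },
           kB = { b_alt[p] <- derived },
           kAB = { a_alt[p] <- derived; b_alt[p] <- derived },
           kAABB = { b_ref[p] <- derived; b_alt[p] <- derived })
  }
  vcf_a <- .het_records(a_ref, a_alt)
  vcf_b <- .het_records(b_ref, b_alt)
  list(a_ref = paste(a_ref, collapse = ""),
       b_ref = paste(b_ref, collapse = ""),
       k = k, vcf_a = vcf_a, vcf_b = vcf_b)
}

.het_records <- function(ref, alt) {
  d <- which(ref != alt)
  if (!length(d))
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), gt = character(0),
                      filter = character(0)))
  data.frame(pos = d, ref = ref[d], alt = alt[d], gt = "0/1",
             filter = "PASS")
}

.mutate_fraction <- function(seq, frac) {
  s <- .split_chars(seq)
  n <- max(1L, round(length(s) * frac))
  idx <- sample(seq_along(s), n)
  s[idx] <- vapply(s[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(s, collapse = "")
}

.mutate_tract <- function(seq, start, end, frac) {
  s <- .split_chars(seq)
  end <- min(end, length(s))
  idx <- sample(start:end, round((end - start + 1L) * frac))
  s[idx] <- vapply(s[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(s, collapse = "")
}

.write_vcf <- function(path, per_contig, sample_name) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_name)), con)
  for (ctg in names(per_contig)) {
    df <- per_contig[[ctg]]
    if (is.null(df) || nrow(df) == 0L) next
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t99\t%s\t.\tGT\t%s",
                       ctg, df$pos, df$ref, df$alt, df$filter, df$gt), con)
  }
  invisible(path)
}
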