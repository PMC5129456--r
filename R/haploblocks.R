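# From reference CDS + VCF genotypes to blocks of classified fourfold
# degenerate sites for a pair of taxa (one unphased diploid each).

# fourfold-degenerate codon families: the first two bases determine the
# amino acid irrespective of the third position
.FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

#' Apply heterozygous VCF calls to a reference CDS
#'
#' Builds the alternate haplotype of a contig from its variant calls.
#' Only biallelic SNP records with a heterozygous genotype containing the
#' reference allele (0/1) are applied; indels are dropped and counted, as
#' are genotypes lacking the reference allele (alternate homozygotes,
#' which in a self-mapped single-individual assembly indicate assembly
#' errors).  Records with a non-PASS filter status are skipped.
#'
#' @param ref_seq Reference coding sequence (character string or
#'   \code{DNAString}).
#' @param variants Data frame with columns \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{gt}, and optionally \code{filter}.
#'   May be empty or \code{NULL}.
#' @param contig_id Used in error messages.
#' @return List of class \code{"haplotype_pair"}: \code{ref_seq},
#'   \code{alt_seq} (equal-length character strings), and the counts
#'   \code{n_het_applied}, \code{n_indels_dropped},
#'   \code{n_alt_homozygotes_dropped}, \code{n_skipped}.
#' @export
apply_vcf_haplotype <- function(ref_seq, variants, contig_id = "<contig>") {
  ref_seq <- toupper(as.character(ref_seq))
  ref <- .split_chars(ref_seq)
  alt <- ref
  n_het <- n_indel <- n_althom <- n_skip <- 0L
  if (!is.null(variants) && nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (!is.null(v$filter) && !is.na(v$filter) &&
          !(v$filter %in% c("PASS", ".", ""))) {
        n_skip <- n_skip + 1L
        next
      }
      if (v$pos > length(ref))
        stop("VCF position ", v$pos, " beyond end of contig ", contig_id)
      alleles <- c(v$ref, strsplit(v$alt, ",", fixed = TRUE)[[1]])
      if (any(nchar(alleles) != 1L)) {
        n_indel <- n_indel + 1L
        next
      }
      gt <- gsub("|", "/", v$gt, fixed = TRUE)
      gti <- suppressWarnings(as.integer(strsplit(gt, "/", fixed = TRUE)[[1]]))
      if (length(gti) != 2L || anyNA(gti)) {
        n_skip <- n_skip + 1L
        next
      }
      if (!any(gti == 0L)) {
        n_althom <- n_althom + 1L
        next
      }
      if (all(gti == 0L)) {
        n_skip <- n_skip + 1L
        next
      }
      if (!ref[v$pos] %in% c("A", "C", "G", "T")) {
        n_skip <- n_skip + 1L
        next
      }
      alt_allele <- alleles[max(gti) + 1L]
      if (!alt_allele %in% c("A", "C", "G", "T")) {
        n_skip <- n_skip + 1L
        next
      }
      alt[v$pos] <- alt_allele
      n_het <- n_het + 1L
    }
  }
  structure(list(ref_seq = paste(ref, collapse = ""),
                 alt_seq = paste(alt, collapse = ""),
                 n_het_applied = n_het, n_indels_dropped = n_indel,
                 n_alt_homozygotes_dropped = n_althom, n_skipped = n_skip),
            class = "haplotype_pair")
}

#' Read genotype records from a VCF file
#'
#' Thin wrapper around \code{vcfR} returning, per contig, the fields
#' needed by \code{\link{apply_vcf_haplotype}}.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Named list (by contig) of data frames with columns \code{pos},
#'   \code{ref}, \code{alt}, \code{gt}, \code{filter}.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(list())
  gt <- vcfR::extract.gt(v, element = "GT")
  df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   gt = as.character(gt[, 1]),
                   filter = fix$FILTER, stringsAsFactors = FALSE)
  split(df[, -1], df$chrom)
}

#' Back-translate a peptide alignment into a four-row codon alignment
#'
#' Converts an aligned peptide pair into a nucleotide alignment of the two
#' reference CDS plus the two alternate haplotypes: each peptide residue
#' becomes its source codon and each peptide gap a 3-column gap, so the
#' reading frame is preserved and the reference and alternate rows of a
#' taxon share that taxon's gap structure.
#'
#' @param pep_a,pep_b Aligned peptide sequences (equal length, gaps
#'   \code{"-"}).
#' @param hap_a,hap_b \code{"haplotype_pair"} objects (see
#'   \code{\link{apply_vcf_haplotype}}) whose \code{ref_seq} translate to
#'   the ungapped peptides.
#' @param orthogroup_id Used in error messages.
#' @return A 4 x L character matrix with rows \code{a_ref}, \code{a_alt},
#'   \code{b_ref}, \code{b_alt}.
#' @export
build_codon_alignment <- function(pep_a, pep_b, hap_a, hap_b,
                                  orthogroup_id = "<orthogroup>") {
  pa <- .split_chars(pep_a)
  pb <- .split_chars(pep_b)
  if (length(pa) != length(pb))
    stop("aligned peptides differ in length in ", orthogroup_id)
  .check_translation(hap_a$ref_seq, pa[pa != "-"], orthogroup_id, "first")
  .check_translation(hap_b$ref_seq, pb[pb != "-"], orthogroup_id, "second")
  ncol <- 3L * length(pa)
  out <- matrix("-", 4L, ncol,
                dimnames = list(c("a_ref", "a_alt", "b_ref", "b_alt"), NULL))
  .fill <- function(row_ref, row_alt, pep, hap) {
    ref <- .split_chars(hap$ref_seq)
    alt <- .split_chars(hap$alt_seq)
    cdspos <- 0L
    for (j in seq_along(pep)) {
      if (pep[j] == "-") next
      cols <- (3L * (j - 1L) + 1L):(3L * j)
      out[row_ref, cols] <<- ref[cdspos + 1:3]
      out[row_alt, cols] <<- alt[cdspos + 1:3]
      cdspos <- cdspos + 3L
    }
  }
  .fill("a_ref", "a_alt", pa, hap_a)
  .fill("b_ref", "b_alt", pb, hap_b)
  out
}

.check_translation <- function(cds, pep_residues, orthogroup_id, which_row) {
  n_codon <- nchar(cds) %/% 3L
  if (n_codon != length(pep_residues))
    stop("CDS/peptide length mismatch (", which_row, " row) in ",
         orthogroup_id)
  aa <- .split_chars(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X")))
  pep <- toupper(pep_residues)
  diff <- which(aa != pep & aa != "X" & pep != "X")
  # a trailing stop in the CDS is tolerated
  diff <- diff[!(diff == n_codon & aa[diff] == "*")]
  if (length(diff))
    stop("translation mismatch in ", orthogroup_id, " at codon ", diff[1],
         " (", which_row, " row): ", aa[diff[1]], " vs ", pep[diff[1]])
}

#' Locate fourfold degenerate sites in a codon alignment
#'
#' A column qualifies when it is a third codon position, no row has a gap
#' anywhere in that codon, the first two codon positions are identical
#' across all four rows, and the shared codon prefix belongs to a
#' fourfold-degenerate family (so any third-position base is synonymous
#' in every row).
#'
#' @param aln 4 x L character matrix from
#'   \code{\link{build_codon_alignment}}.
#' @return Integer vector of qualifying column indices.
#' @export
fourfold_sites <- function(aln) {
  stopifnot(is.matrix(aln), nrow(aln) == 4L, ncol(aln) %% 3L == 0L)
  n_codon <- ncol(aln) %/% 3L
  out <- integer(0)
  for (j in seq_len(n_codon)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    codon <- toupper(aln[, cols, drop = FALSE])
    if (any(codon == "-")) next
    p12 <- paste0(codon[, 1], codon[, 2])
    if (length(unique(p12)) != 1L) next
    if (!p12[1] %in% .FOURFOLD_PREFIXES) next
    out <- c(out, cols[3])
  }
  out
}

#' Classify one fourfold site from the four haplotype bases
#'
#' Folding: only the genotypes matter, not which haplotype carries which
#' allele, so the classification is invariant to swapping ref/alt within
#' a taxon and to relabeling the two alleles.
#'
#' @param bases Character vector \code{c(a_ref, a_alt, b_ref, b_alt)}.
#' @return One of \code{"invariant"}, \code{"kA"}, \code{"kB"},
#'   \code{"kAB"}, \code{"kAABB"}, \code{"excluded_multiallelic"},
#'   \code{"excluded_ambiguous"}.
#' @export
classify_site <- function(bases) {
  stopifnot(length(bases) == 4L)
  bases <- toupper(bases)
  if (!all(bases %in% c("A", "C", "G", "T"))) return("excluded_ambiguous")
  n_allele <- length(unique(bases))
  if (n_allele == 1L) return("invariant")
  if (n_allele > 2L) return("excluded_multiallelic")
  het_a <- bases[1] != bases[2]
  het_b <- bases[3] != bases[4]
  if (het_a && het_b) return("kAB")
  if (het_a) return("kA")
  if (het_b) return("kB")
  "kAABB"
}

#' Cut classified fourfold sites into blocks
#'
#' Blocks are runs of \code{block_size} *consecutive qualifying* fourfold
#' sites (intervening non-qualifying alignment columns are permitted).
#' Sites excluded from classification (multiallelic or ambiguous) still
#' occupy a position in the block but contribute to no mutation class.
#' Orthogroups with fewer than \code{block_size} qualifying sites yield
#' no block.  The default policy keeps only the first complete block per
#' orthogroup, so each retained orthogroup contributes one independent
#' replicate of the coalescent.
#'
#' @param site_classes Character vector of per-site classes in alignment
#'   order (output of \code{\link{classify_site}} over the columns from
#'   \code{\link{fourfold_sites}}).
#' @param orthogroup_id Orthogroup label for the output rows.
#' @param block_size Sites per block (default 150).
#' @param policy \code{"first_block_per_orthogroup"} (default) or
#'   \code{"all_blocks"}.
#' @return Block table: data frame with columns \code{orthogroup},
#'   \code{n_sites}, \code{kA}, \code{kB}, \code{kAB}, \code{kAABB},
#'   \code{four_gamete_pass}.
#' @export
make_blocks <- function(site_classes, orthogroup_id = "orthogroup",
                        block_size = 150,
                        policy = c("first_block_per_orthogroup",
                                   "all_blocks")) {
  policy <- match.arg(policy)
  n <- length(site_classes)
  n_full <- n %/% block_size
  if (n_full == 0L) return(.empty_block_table())
  if (policy == "first_block_per_orthogroup") n_full <- 1L
  rows <- lapply(seq_len(n_full), function(b) {
    cls <- site_classes[((b - 1L) * block_size + 1L):(b * block_size)]
    k <- c(kA = sum(cls == "kA"), kB = sum(cls == "kB"),
           kAB = sum(cls == "kAB"), kAABB = sum(cls == "kAABB"))
    data.frame(orthogroup = if (n_full == 1L) orthogroup_id else
                 paste0(orthogroup_id, ".", b),
               n_sites = block_size, kA = k[["kA"]], kB = k[["kB"]],
               kAB = k[["kAB"]], kAABB = k[["kAABB"]],
               four_gamete_pass = !(k[["kAB"]] > 0 && k[["kAABB"]] > 0))
  })
  do.call(rbind, rows)
}

.empty_block_table <- function() {
  data.frame(orthogroup = character(0), n_sites = integer(0),
             kA = integer(0), kB = integer(0), kAB = integer(0),
             kAABB = integer(0), four_gamete_pass = logical(0))
}

#' Four-gamete compatibility of a block
#'
#' With unphased diploids the only detectable two-site incompatibility is
#' the joint presence of shared-heterozygous sites and fixed differences:
#' no single unrooted genealogy of the four haplotypes contains both a
#' branch ancestral to one lineage from each taxon and a branch ancestral
#' to both lineages of one taxon.
#'
#' @param block One block-table row, or a vector/list with \code{kAB} and
#'   \code{kAABB}.
#' @return \code{TRUE} if the block passes (no incompatibility).
#' @export
four_gamete_pass <- function(block) {
  block[["kAB"]] <= 0 || block[["kAABB"]] <= 0
}

#' Summarise a block table into site-class frequencies
#'
#' @param blocks Block table.
#' @param mode \code{"all_sites"}: per-site frequency of each class over
#'   all blocks and sites.  \code{"one_variable_site_per_block"}: one
#'   variable site is drawn uniformly per block that has any, and class
#'   counts of the drawn sites are reported.
#' @param seed Optional seed for the site draw.
#' @return List with \code{n_blocks}, \code{n_sites} and either
#'   \code{frequencies} (per-site, all classes) or \code{drawn_counts}
#'   plus \code{n_invariant_blocks}.
#' @export
summarize_sfs <- function(blocks, mode = c("all_sites",
                                           "one_variable_site_per_block"),
                          seed = NULL) {
  mode <- match.arg(mode)
  blocks <- .check_blocks(blocks)
  if (nrow(blocks) == 0L) stop("no blocks")
  n_sites <- if ("n_sites" %in% names(blocks)) blocks$n_sites[1] else 150
  kmat <- as.matrix(blocks[, c("kA", "kB", "kAB", "kAABB")])
  if (mode == "all_sites") {
    freq <- colSums(kmat) / (nrow(kmat) * n_sites)
    return(list(mode = mode, n_blocks = nrow(kmat), n_sites = n_sites,
                frequencies = freq))
  }
  if (!is.null(seed)) set.seed(seed)
  n_var <- rowSums(kmat)
  has <- which(n_var > 0)
  drawn <- integer(4)
  if (length(has)) {
    cls <- vapply(has, function(i) sample.int(4L, 1L, prob = kmat[i, ]), 0L)
    drawn <- tabulate(cls, nbins = 4L)
  }
  names(drawn) <- c("kA", "kB", "kAB", "kAABB")
  list(mode = mode, n_blocks = nrow(kmat), n_sites = n_sites,
       drawn_counts = drawn, n_invariant_blocks = sum(n_var == 0))
}

#' Write / read a block table
#'
#' Tab-separated with the canonical column order.
#'
#' @param blocks Block table.
#' @param path File path.
#' @return \code{read_block_table} returns the block table.
#' @export
write_block_table <- function(blocks, path) {
  utils::write.table(
    blocks[, c("orthogroup", "n_sites", "kA", "kB", "kAB", "kAABB",
               "four_gamete_pass")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_table
#' @export
read_block_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .check_blocks(df)
}

#' Build the block table for a taxon pair from sequence data
#'
#' Runs the per-orthogroup chain: peptide alignment (computed with a
#' global pairwise alignment when not supplied), alternate-haplotype
#' construction from the VCF genotypes, codon back-translation, fourfold
#' site extraction, site classification, and blocking.
#'
#' @param orthogroups Named list; each element is a list with elements
#'   \code{contig_a}, \code{contig_b} (contig ids of the two taxa).
#' @param cds_a,cds_b Named character vectors (or \code{DNAStringSet}) of
#'   reference CDS per contig.
#' @param variants_a,variants_b Named lists of per-contig variant data
#'   frames (see \code{\link{read_vcf_genotypes}}).
#' @param block_size,policy Passed to \code{\link{make_blocks}}.
#' @return List with the combined block table (\code{blocks}) and
#'   per-orthogroup bookkeeping (\code{log}: applied and dropped variant
#'   counts, classified-site tallies).
#' @export
make_block_table <- function(orthogroups, cds_a, cds_b, variants_a,
                             variants_b, block_size = 150,
                             policy = "first_block_per_orthogroup") {
  cds_a <- .as_seq_vector(cds_a)
  cds_b <- .as_seq_vector(cds_b)
  tabs <- list()
  logs <- list()
  for (og in names(orthogroups)) {
    ca <- orthogroups[[og]]$contig_a
    cb <- orthogroups[[og]]$contig_b
    hap_a <- apply_vcf_haplotype(cds_a[[ca]], variants_a[[ca]], ca)
    hap_b <- apply_vcf_haplotype(cds_b[[cb]], variants_b[[cb]], cb)
    pep_a <- .translate_cds(hap_a$ref_seq)
    pep_b <- .translate_cds(hap_b$ref_seq)
    if (identical(pep_a, pep_b)) {
      aln_a <- pep_a
      aln_b <- pep_b
    } else {
      pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(pep_a),
                                          Biostrings::AAString(pep_b),
                                          type = "global")
      aln_a <- as.character(Biostrings::alignedPattern(pa))
      aln_b <- as.character(Biostrings::alignedSubject(pa))
    }
    aln <- build_codon_alignment(aln_a, aln_b, hap_a, hap_b, og)
    sites <- fourfold_sites(aln)
    cls <- vapply(sites, function(cidx) classify_site(aln[, cidx]), "")
    tabs[[og]] <- make_blocks(cls, og, block_size, policy)
    logs[[og]] <- list(
      n_fourfold = length(sites),
      site_classes = table(factor(cls, levels = c(
        "invariant", "kA", "kB", "kAB", "kAABB", "excluded_multiallelic",
        "excluded_ambiguous"))),
      a = hap_a[c("n_het_applied", "n_indels_dropped",
                  "n_alt_homozygotes_dropped")],
      b = hap_b[c("n_het_applied", "n_indels_dropped",
                  "n_alt_homozygotes_dropped")])
  }
  blocks <- if (length(tabs)) do.call(rbind, tabs) else .empty_block_table()
  rownames(blocks) <- NULL
  list(blocks = blocks, log = logs)
}

.as_seq_vector <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  as.list(x)
}

.translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
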