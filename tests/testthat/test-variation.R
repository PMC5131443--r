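test_that("codon site counts match hand-derived cases", {
  tt <- codonSiteCounts("TTT")   # only TTT->TTC synonymous
  expect_equal(tt$syn_sites, 1 / 3)
  expect_equal(tt$nonsyn_sites, 8 / 3)
  atg <- codonSiteCounts("ATG")  # Met: every change is non-synonymous
  expect_equal(atg$syn_sites, 0)
  expect_equal(atg$nonsyn_sites, 3)
  ctg <- codonSiteCounts("CTG")  # Leu: 3rd position 4-fold + CTG->TTG
  expect_equal(ctg$syn_sites, 4 / 3)
  expect_equal(ctg$nonsyn_sites, 5 / 3)

  expect_error(codonSiteCounts("TAA"), "stop")
  expect_error(codonSiteCounts("TXT"), "A,C,G,T")
})

test_that("site counts equal the exhaustive 9-mutation oracle for all 61 sense codons", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  sense <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  expect_length(sense, 61)
  for (cod in sense) {
    got <- codonSiteCounts(cod)
    want <- oracleCodonSites(cod)
    expect_equal(got$syn_sites, unname(want["syn_sites"]), info = cod)
    expect_equal(got$syn_sites + got$nonsyn_sites, 3, info = cod)
  }
})

test_that("CDS site counts aggregate to 3 x n_codons exactly", {
  models <- generateGeneModels(sprintf("G%02d", 1:10), c(20, 60), seed = 3)
  for (cds in models) {
    sc <- cdsSiteCounts(cds)
    expect_equal(sc$syn_sites + sc$nonsyn_sites, nchar(cds))
  }
  expect_error(cdsSiteCounts("ATGTA"), "multiple of 3")
  expect_error(cdsSiteCounts("ATGTAA"), "stop")
})

test_that("variant annotation classifies consequences and CpG context", {
  models <- c(G1 = "ATGTTT")
  syn <- annotateVariants(models, data.frame(
    protein = "G1", cds_pos = 6, ref = "T", alt = "C"))
  expect_equal(syn$kind, "synonymous")       # TTT -> TTC
  ns <- annotateVariants(models, data.frame(
    protein = "G1", cds_pos = 4, ref = "T", alt = "A"))
  expect_equal(ns$kind, "nonsynonymous")     # TTT -> ATT, Phe -> Ile
  expect_equal(ns$aa_pos, 2L)

  # CpG context: C followed by G, or G preceded by C (reference strand)
  expect_true(cpgContext("ACGT", 2))
  expect_true(cpgContext("ACGT", 3))
  expect_false(cpgContext("ACGT", 1))
  expect_false(cpgContext("ACGT", 4))
  expect_true(cpgContext("CG", 1))   # one-sided context at the ends
  expect_true(cpgContext("CG", 2))

  expect_error(
    annotateVariants(models, data.frame(protein = "G1", cds_pos = 4,
                                        ref = "G", alt = "A")),
    "reference mismatch.*G1.*position 4")
})

test_that("dN is SNP count per non-synonymous site with CpG exclusion", {
  models <- c(G1 = "TTT")
  v1 <- data.frame(protein = "G1", cds_pos = 1, ref = "T", alt = "A")  # nonsyn
  dn <- computeDn(models, v1, excludeCpg = FALSE)
  expect_equal(dn$dn, 1 / (8 / 3))   # 0.375

  dn0 <- computeDn(models, v1[0, ], excludeCpg = FALSE)
  expect_equal(dn0$dn, 0)
  expect_equal(dn0$n_nonsyn, 0L)

  vsyn <- data.frame(protein = "G1", cds_pos = 3, ref = "T", alt = "C")
  expect_equal(computeDn(models, vsyn, excludeCpg = FALSE)$dn, 0)

  # CpG exclusion removes the CpG-context non-synonymous SNP
  m2 <- c(G2 = "ACGTTT")
  vcpg <- data.frame(protein = "G2", cds_pos = c(2, 4), ref = c("C", "T"),
                     alt = c("T", "A"))
  keep <- computeDn(m2, vcpg, excludeCpg = FALSE)
  drop <- computeDn(m2, vcpg, excludeCpg = TRUE)
  expect_equal(keep$n_nonsyn, 2L)
  expect_equal(drop$n_nonsyn, 1L)
  expect_equal(drop$n_excluded_cpg, 1L)
  expect_lte(drop$n_nonsyn, keep$n_nonsyn)
})

test_that("dN is invariant to variant order and duplicate records count once", {
  models <- generateGeneModels("G1", c(30, 30), seed = 5)
  v <- generateVariants(models, c(G1 = "NHB"),
                        c(HB = 0, HNB = 0, NHB = 0.05, NHNB = 0),
                        synDensity = 0.05, cpgFraction = 0, seed = 6)
  shuffled <- v[rev(seq_len(nrow(v))), ]
  expect_equal(computeDn(models, v)$dn, computeDn(models, shuffled)$dn)
  dup <- rbind(v, v[1, ])
  expect_equal(computeDn(models, dup)$dn, computeDn(models, v)$dn)
})

test_that("mean dN across proteins converges to the generating density", {
  prot <- sprintf("G%03d", 1:400)
  classes <- setNames(rep("NHNB", 400), prot)
  p <- 0.01
  models <- generateGeneModels(prot, c(100, 100), seed = 9)
  v <- generateVariants(models, classes,
                        c(HB = p, HNB = p, NHB = p, NHNB = p),
                        synDensity = 0, cpgFraction = 0.1, seed = 10)
  dn <- computeDn(models, annotateVariants(models, v), excludeCpg = TRUE)
  # each protein has ~231 nonsyn sites; mean of 400 binomial proportions
  se <- sqrt(p * (1 - p) / mean(dn$nonsyn_sites) / 400)
  expect_lt(abs(mean(dn$dn) - p), 3 * se)
})

test_that("FASTA and variant-file readers round-trip generator output", {
  prot <- sprintf("G%02d", 1:5)
  models <- generateGeneModels(prot, c(20, 40), seed = 2)
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(models), "\n", unname(models)), fa)
  expect_equal(readCdsFasta(fa), models)

  v <- generateVariants(models, setNames(rep("NHB", 5), prot),
                        c(HB = 0, HNB = 0, NHB = 0.05, NHNB = 0), seed = 3)
  tsv <- tempfile(fileext = ".tsv")
  write.table(v, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rv <- readVariants(tsv)
  expect_equal(rv$cds_pos, v$cds_pos)
  expect_equal(rv$alt, v$alt)
})

test_that("VCF variant input keeps biallelic SNPs and skips the rest", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "G1\t4\t.\tT\tA\t.\tPASS\t.",
    "G1\t6\t.\tT\tTA\t.\tPASS\t.",
    "G1\t2\t.\tT\tC,G\t.\tPASS\t."), vcf)
  expect_warning(v <- readVariants(vcf), "non-SNP")
  expect_equal(nrow(v), 1)
  expect_equal(v$cds_pos, 4L)
})
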