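#' Synonymous and non-synonymous site counts of a codon
#'
#' Each of the nine single-base changes of a sense codon is classified as
#' synonymous or non-synonymous under the standard genetic code (changes to
#' stop codons count as non-synonymous). The synonymous fraction at each of
#' the three positions is (synonymous changes)/3; syn_sites is the sum of
#' the three fractions and nonsyn_sites its complement to 3. This is the
#' site-counting denominator of dN.
#'
#' @param codon a 3-base string over A,C,G,T encoding an amino acid.
#' @return list with \code{syn_sites}, \code{nonsyn_sites}
#'   (\code{syn_sites + nonsyn_sites == 3} exactly).
#' @examples
#' codonSiteCounts("TTT")  # 1/3 synonymous site
#' @export
codonSiteCounts <- function(codon) {
    ct <- .codonTables()
    if (!is.character(codon) || length(codon) != 1 || nchar(codon) != 3 ||
        !codon %in% ct$codons)
        stop("codon must be a 3-base string over A,C,G,T")
    if (ct$is_stop[codonIndex(codon)])
        stop("stop codon has no site counts: ", codon)
    s <- sum(ct$syn_frac[codonIndex(codon), ])
    list(syn_sites = s, nonsyn_sites = 3 - s)
}

# Split a CDS into its codon strings (validates length).
.cdsCodons <- function(cds) {
    L <- nchar(cds)
    if (L == 0 || L %% 3 != 0)
        stop("CDS length must be a positive multiple of 3")
    substring(cds, seq(1, L, by = 3), seq(3, L, by = 3))
}

#' Site counts aggregated over a CDS
#'
#' @param cds nucleotide string, length divisible by 3, no internal stops.
#' @return list with \code{syn_sites}, \code{nonsyn_sites}; their sum is
#'   exactly 3 times the number of codons.
#' @export
cdsSiteCounts <- function(cds) {
    ct <- .codonTables()
    idx <- codonIndex(.cdsCodons(cds))
    if (any(ct$is_stop[idx]))
        stop("CDS contains internal stop codon(s)")
    s <- sum(ct$syn_frac[idx, ])
    list(syn_sites = s, nonsyn_sites = 3 * length(idx) - s)
}

#' Is a CDS position in CpG dinucleotide context?
#'
#' TRUE iff the reference base at \code{pos} is the C of a CG dinucleotide
#' or the G of a CG dinucleotide on the reference CDS strand. Positions 1
#' and L have one-sided context.
#'
#' @param cds reference nucleotide string.
#' @param pos 1-based position(s).
#' @return logical vector.
#' @export
cpgContext <- function(cds, pos) {
    L <- nchar(cds)
    stopifnot(all(pos >= 1 & pos <= L))
    b <- substring(cds, pos, pos)
    nxt <- ifelse(pos < L, substring(cds, pos + 1, pos + 1), "")
    prv <- ifelse(pos > 1, substring(cds, pos - 1, pos - 1), "")
    (b == "C" & nxt == "G") | (b == "G" & prv == "C")
}

#' Annotate coding SNPs against CDS models
#'
#' Classifies each variant as synonymous or non-synonymous from the codon
#' change alone and flags CpG context on the reference strand. The variant's
#' stated reference base must match the CDS.
#'
#' @param models named character vector of CDS sequences (names = protein
#'   IDs), or a \code{Biostrings::DNAStringSet}.
#' @param variants data.frame with columns \code{protein}, \code{cds_pos},
#'   \code{ref}, \code{alt}. Duplicate (protein, pos, alt) rows are counted
#'   once.
#' @return the variants data.frame with added columns \code{kind}
#'   ("synonymous"/"nonsynonymous"), \code{cpg_related}, \code{aa_pos}.
#' @export
annotateVariants <- function(models, variants) {
    models <- .asCdsVector(models)
    v <- variants
    v$cds_pos <- as.integer(v$cds_pos)
    key <- paste(v$protein, v$cds_pos, v$alt, sep = "\r")
    v <- v[!duplicated(key), , drop = FALSE]
    rownames(v) <- NULL
    cds <- models[v$protein]
    if (anyNA(names(cds)) || any(is.na(cds)))
        stop("variant protein(s) without a CDS model: ",
             paste(unique(v$protein[is.na(cds)]), collapse = ", "))
    L <- nchar(cds)
    if (any(v$cds_pos < 1 | v$cds_pos > L))
        stop("variant position outside CDS")
    refBase <- substr(cds, v$cds_pos, v$cds_pos)
    bad <- refBase != v$ref
    if (any(bad)) {
        i <- which(bad)[1]
        stop(sprintf(
            "reference mismatch for %s at CDS position %d: CDS has %s, variant says %s",
            v$protein[i], v$cds_pos[i], refBase[i], v$ref[i]))
    }
    codonIdx <- (v$cds_pos - 1L) %/% 3L
    start <- codonIdx * 3L + 1L
    refCodon <- substr(cds, start, start + 2L)
    posInCodon <- v$cds_pos - start + 1L
    altCodon <- refCodon
    substr(altCodon, posInCodon, posInCodon) <- v$alt
    syn <- translateCodon(refCodon) == translateCodon(altCodon)
    v$kind <- ifelse(syn, "synonymous", "nonsynonymous")
    v$cpg_related <- vapply(seq_len(nrow(v)), function(i)
        cpgContext(cds[i], v$cds_pos[i]), logical(1))
    v$aa_pos <- as.integer(ceiling(v$cds_pos / 3))
    v
}

.asCdsVector <- function(models) {
    if (methods::is(models, "DNAStringSet")) {
        out <- as.character(models)
    } else {
        out <- models
    }
    if (is.null(names(out)) || anyDuplicated(names(out)))
        stop("CDS models must be uniquely named by protein ID")
    out
}

#' Non-synonymous SNP density (dN) per protein
#'
#' dN is the number of non-synonymous SNPs divided by the number of
#' non-synonymous sites of the protein's CDS (codon-site enumeration). With
#' \code{excludeCpg = TRUE}, CpG-context SNPs are removed before counting,
#' controlling for the elevated CpG mutation rate. Every protein with a
#' model appears in the output; zero variants gives dN = 0. Synonymous
#' density (dS) is reported alongside for completeness but is not used by
#' the pipeline.
#'
#' @param models named character vector (or DNAStringSet) of CDS sequences.
#' @param variants data.frame with columns \code{protein}, \code{cds_pos},
#'   \code{ref}, \code{alt} (annotated or not).
#' @param excludeCpg drop CpG-context SNPs before counting (default TRUE).
#' @return data.frame: \code{protein}, \code{n_nonsyn}, \code{nonsyn_sites},
#'   \code{dn}, \code{n_excluded_cpg}, \code{n_syn}, \code{syn_sites},
#'   \code{ds}.
#' @export
computeDn <- function(models, variants, excludeCpg = TRUE) {
    models <- .asCdsVector(models)
    if (any(nchar(models) == 0)) stop("empty CDS in models")
    prot <- names(models)
    if (NROW(variants) > 0 && !all(c("kind", "cpg_related") %in% names(variants)))
        variants <- annotateVariants(models, variants)
    sites <- vapply(models, function(s) {
        sc <- cdsSiteCounts(s)
        c(sc$syn_sites, sc$nonsyn_sites)
    }, numeric(2))
    if (NROW(variants) > 0) {
        cpg <- variants$cpg_related
        kept <- variants[!(excludeCpg & cpg), , drop = FALSE]
        nEx <- tabulate(factor(variants$protein[excludeCpg & cpg],
                               levels = prot), nbins = length(prot))
        nN <- tabulate(factor(kept$protein[kept$kind == "nonsynonymous"],
                              levels = prot), nbins = length(prot))
        nS <- tabulate(factor(kept$protein[kept$kind == "synonymous"],
                              levels = prot), nbins = length(prot))
    } else {
        nEx <- nN <- nS <- integer(length(prot))
    }
    data.frame(protein = prot,
               n_nonsyn = nN,
               nonsyn_sites = sites[2, ],
               dn = nN / sites[2, ],
               n_excluded_cpg = nEx,
               n_syn = nS,
               syn_sites = sites[1, ],
               ds = nS / sites[1, ],
               row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Read CDS sequences from FASTA
#'
#' @param path FASTA file; record IDs are protein IDs.
#' @return named character vector of CDS strings.
#' @export
readCdsFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(out))
    out
}

#' Read coding variants from TSV or a CDS-relative VCF
#'
#' TSV: columns \code{protein}, \code{pos} (or \code{cds_pos}), \code{ref},
#' \code{alt}. VCF: CHROM is the protein ID and POS the 1-based CDS
#' position; only biallelic SNP records are used, others are skipped with a
#' warning (requires the vcfR package).
#'
#' @param path input file.
#' @param format "tsv" or "vcf"; guessed from the file extension by default.
#' @return data.frame with columns \code{protein}, \code{cds_pos},
#'   \code{ref}, \code{alt}.
#' @export
readVariants <- function(path, format = c("auto", "tsv", "vcf")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (format == "tsv") {
        df <- readTsv(path, header = TRUE)
        posCol <- if ("cds_pos" %in% names(df)) "cds_pos" else "pos"
        out <- data.frame(protein = df$protein,
                          cds_pos = as.integer(df[[posCol]]),
                          ref = df$ref, alt = df$alt,
                          stringsAsFactors = FALSE)
    } else {
        if (!requireNamespace("vcfR", quietly = TRUE))
            stop("VCF input requires the vcfR package")
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
        snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
            !grepl(",", fix$ALT, fixed = TRUE) &
            fix$REF %in% .BASES & fix$ALT %in% .BASES
        if (any(!snp))
            warning(sum(!snp), " non-SNP VCF record(s) skipped")
        out <- data.frame(protein = fix$CHROM[snp],
                          cds_pos = as.integer(fix$POS[snp]),
                          ref = fix$REF[snp], alt = fix$ALT[snp],
                          stringsAsFactors = FALSE)
    }
    out
}
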