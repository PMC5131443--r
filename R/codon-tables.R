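# Codon lookup tables built once at load from the standard genetic code.
#
# For every codon and codon position we enumerate the three single-base
# changes and record (i) the fraction that are synonymous and (ii) the
# alternative bases grouped by consequence. Changes to stop codons count as
# non-synonymous. These tables back both the site-counting denominator of dN
# and the synthetic variant generator.

.BASES <- c("A", "C", "G", "T")

.buildCodonTables <- function() {
    gc_tab <- Biostrings::GENETIC_CODE
    grid <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                        stringsAsFactors = FALSE)
    codons <- paste0(grid$p1, grid$p2, grid$p3)
    aa <- unname(gc_tab[codons])
    is_stop <- aa == "*"

    syn_frac <- matrix(NA_real_, nrow = 64, ncol = 3,
                       dimnames = list(codons, NULL))
    syn_alts <- vector("list", 64 * 3)
    nonsyn_alts <- vector("list", 64 * 3)
    dim(syn_alts) <- dim(nonsyn_alts) <- c(64, 3)
    dimnames(syn_alts) <- dimnames(nonsyn_alts) <- list(codons, NULL)

    for (ci in seq_along(codons)) {
        if (is_stop[ci]) next
        cod <- strsplit(codons[ci], "")[[1]]
        for (pos in 1:3) {
            alts <- setdiff(.BASES, cod[pos])
            mut <- vapply(alts, function(b) {
                m <- cod; m[pos] <- b
                paste0(m, collapse = "")
            }, character(1))
            syn <- unname(gc_tab[mut]) == aa[ci]  # stop => "*" != aa => FALSE
            syn_frac[ci, pos] <- sum(syn) / 3
            syn_alts[[ci, pos]] <- alts[syn]
            nonsyn_alts[[ci, pos]] <- alts[!syn]
        }
    }
    list(codons = codons, aa = aa, is_stop = is_stop, syn_frac = syn_frac,
         syn_alts = syn_alts, nonsyn_alts = nonsyn_alts,
         sense_codons = codons[!is_stop])
}

.ct <- NULL

.codonTables <- function() {
    if (is.null(.ct)) {
        # built lazily so Biostrings is touched only on first use
        utils::assignInMyNamespace(".ct", .buildCodonTables())
    }
    .ct
}

codonIndex <- function(codon) {
    ct <- .codonTables()
    idx <- match(codon, ct$codons)
    if (anyNA(idx)) stop("not a valid codon: ",
                         paste(unique(codon[is.na(idx)]), collapse = ", "))
    idx
}

translateCodon <- function(codon) {
    ct <- .codonTables()
    ct$aa[codonIndex(codon)]
}
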