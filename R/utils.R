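#' @useDynLib ppivar, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats cor.test fisher.test kmeans median rbinom rlnorm runif
#'   wilcox.test lm coef
#' @importFrom utils read.delim write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Derive the i-th substream seed from a master seed by counter. Keeps every
# derived seed in [1, 2^31 - 2] and is stable when the number of streams
# grows: stream i always receives the same seed.
substreamSeed <- function(master, i) {
    as.integer((as.numeric(master) + as.numeric(i) * 1000003) %% 2147483646 + 1)
}

# Locale-independent ordering (radix = C collation) used everywhere IDs are
# sorted so that written outputs are byte-stable across machines.
idOrder <- function(...) order(..., method = "radix")

readTsv <- function(path, header = TRUE, ...) {
    read.delim(path, header = header, sep = "\t", quote = "",
               comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character", check.names = FALSE, ...)
}

writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
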