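.DIALECTS <- c("biogrid", "dip", "hprd", "intact")

#' Parse an interaction table in one of the supported source dialects
#'
#' Applies the dialect-specific row filters used when assembling the merged
#' human network:
#' \itemize{
#'   \item \code{biogrid}: both organism taxids "9606" and experimental
#'     system type "physical";
#'   \item \code{dip}: both taxid fields contain "9606" and the interaction
#'     type is "physical interaction" or "direct interaction";
#'   \item \code{hprd}: self-interactions dropped;
#'   \item \code{intact}: both interactor types "protein" and interaction
#'     type "direct interaction".
#' }
#' Comment lines start with \code{#}. biogrid and intact files carry a
#' header and are addressed by column name; dip and hprd are positional.
#' Malformed rows (missing required fields) are skipped with a warning and
#' counted in the \code{"counts"} attribute, never fatal.
#'
#' @param path path to the TSV file.
#' @param dialect one of "biogrid", "dip", "hprd", "intact".
#' @return data.frame with columns \code{interactor_a}, \code{interactor_b},
#'   \code{source}; attribute \code{counts} holds named integers
#'   (\code{n_rows}, \code{n_kept}, \code{n_filtered}, \code{n_malformed}).
#' @export
parseInteractions <- function(path, dialect = .DIALECTS) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("interaction file not found: ", path)
    has_header <- dialect %in% c("biogrid", "intact")
    df <- tryCatch(
        readTsv(path, header = has_header, fill = TRUE),
        error = function(e) stop("cannot read ", path, ": ",
                                 conditionMessage(e)))
    n_rows <- nrow(df)
    get <- function(col, pos) {
        if (has_header) {
            if (!col %in% names(df))
                stop("missing column '", col, "' in ", dialect, " file")
            df[[col]]
        } else {
            if (pos <= ncol(df)) df[[pos]] else rep(NA_character_, n_rows)
        }
    }
    if (dialect == "biogrid") {
        a <- get("Interactor A"); b <- get("Interactor B")
        ta <- get("Organism Interactor A"); tb <- get("Organism Interactor B")
        ty <- get("Experimental System Type")
        malformed <- is.na(a) | is.na(b) | a == "" | b == "" |
            is.na(ta) | is.na(tb) | is.na(ty)
        keep <- !malformed & ta == "9606" & tb == "9606" & ty == "physical"
    } else if (dialect == "dip") {
        a <- get(pos = 1); b <- get(pos = 2)
        ta <- get(pos = 10); tb <- get(pos = 11); ty <- get(pos = 12)
        malformed <- is.na(a) | is.na(b) | a == "" | b == "" |
            is.na(ta) | is.na(tb) | is.na(ty)
        keep <- !malformed & grepl("9606", ta, fixed = TRUE) &
            grepl("9606", tb, fixed = TRUE) &
            ty %in% c("physical interaction", "direct interaction")
    } else if (dialect == "hprd") {
        a <- get(pos = 1); b <- get(pos = 2)
        malformed <- is.na(a) | is.na(b) | a == "" | b == ""
        keep <- !malformed & a != b   # self-interactions filtered
    } else { # intact
        a <- get("ID A"); b <- get("ID B")
        tya <- get("Type A"); tyb <- get("Type B")
        ty <- get("Interaction type")
        malformed <- is.na(a) | is.na(b) | a == "" | b == "" |
            is.na(tya) | is.na(tyb) | is.na(ty)
        keep <- !malformed & tya == "protein" & tyb == "protein" &
            ty == "direct interaction"
    }
    if (any(malformed))
        warning(sum(malformed), " malformed row(s) skipped in ", path)
    out <- data.frame(interactor_a = a[keep], interactor_b = b[keep],
                      source = dialect, stringsAsFactors = FALSE)
    attr(out, "counts") <- c(n_rows = n_rows, n_kept = sum(keep),
                             n_filtered = sum(!keep & !malformed),
                             n_malformed = sum(malformed))
    out
}

#' Read a source-ID to transcript-ID mapping table
#'
#' Two-column TSV, one (source ID, transcript ID) pair per line; a source ID
#' repeated on several lines is a multi-mapping. Absent keys are "unmapped"
#' on lookup, not an error.
#'
#' @param path path to the mapping TSV (no header).
#' @return named list of character vectors (class \code{"IDMap"}).
#' @export
readIdMap <- function(path) {
    df <- readTsv(path, header = FALSE)
    if (ncol(df) < 2) stop("idmapping file needs two columns: ", path)
    asIdMap(data.frame(src = df[[1]], tgt = df[[2]],
                       stringsAsFactors = FALSE))
}

#' @rdname readIdMap
#' @param pairs data.frame with columns \code{src}, \code{tgt}.
#' @export
asIdMap <- function(pairs) {
    pairs <- unique(pairs[pairs$src != "" & pairs$tgt != "", , drop = FALSE])
    m <- split(pairs$tgt, pairs$src)
    class(m) <- "IDMap"
    m
}

#' Replace source interactor IDs by mapped transcript IDs
#'
#' Records with any unmapped interactor are dropped; records where a source
#' ID maps to more than one transcript are dropped as ambiguous (no edge is
#' fabricated by expansion). Drop counts are reported, never raised.
#'
#' @param records data.frame from \code{\link{parseInteractions}}.
#' @param idmap an \code{IDMap} from \code{\link{readIdMap}}.
#' @return list with \code{records} (mapped data.frame) and \code{dropped}
#'   (named integer vector: \code{unmapped}, \code{ambiguous}).
#' @export
mapIdentifiers <- function(records, idmap) {
    stopifnot(inherits(idmap, "IDMap"))
    keys <- names(idmap)
    sizes <- lengths(idmap)
    single <- vapply(idmap, function(v) if (length(v) == 1L) v else NA_character_,
                     character(1))
    lookup <- function(ids) {
        i <- match(ids, keys)
        status <- ifelse(is.na(i), "unmapped",
                         ifelse(sizes[i] > 1L, "ambiguous", "ok"))
        list(tgt = ifelse(status == "ok", single[i], NA_character_),
             status = status)
    }
    la <- lookup(records$interactor_a)
    lb <- lookup(records$interactor_b)
    amb <- la$status == "ambiguous" | lb$status == "ambiguous"
    unm <- !amb & (la$status == "unmapped" | lb$status == "unmapped")
    ok <- !amb & !unm
    out <- records[ok, , drop = FALSE]
    out$interactor_a <- unname(la$tgt[ok])
    out$interactor_b <- unname(lb$tgt[ok])
    rownames(out) <- NULL
    list(records = out,
         dropped = c(unmapped = sum(unm), ambiguous = sum(amb)))
}

#' Write / read a canonical two-column edge list
#'
#' Endpoints within a row and rows themselves are lexicographically ordered,
#' so the file is byte-stable for identical networks.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
    e <- networkEdges(net)
    writeTsv(data.frame(a = e[, 1], b = e[, 2], stringsAsFactors = FALSE),
             path)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    df <- readTsv(path, header = TRUE)
    PPINetwork(as.matrix(df[, 1:2]))
}
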