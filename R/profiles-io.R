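#' Construct a TaxonProfile
#'
#' @param abundance non-negative numeric matrix, taxa in rows (rownames =
#'   taxon ids), samples in columns (colnames = sample ids).
#' @param individual,day per-sample individual ids and integer collection
#'   days (recycled names must match `colnames(abundance)` order).
#' @param group optional per-sample group label (e.g. "control",
#'   "seroconverter", "T1D-case"); NA where unknown.
#' @param lineage optional per-taxon lineage string in Greengenes style
#'   ("k__...;p__...;...;s__...") or plain ";"-separated ranks.
#' @return a validated [TaxonProfile-class]; columns are reordered by
#'   (individual, day).
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
#' tp <- TaxonProfile(m, individual = rep(c("A", "B"), each = 2),
#'                    day = c(1, 30, 1, 30))
#' @export
TaxonProfile <- function(abundance, individual, day, group = NA, lineage = NULL) {
    abundance <- as.matrix(abundance)
    if (is.null(colnames(abundance)))
        colnames(abundance) <- paste0("sample", seq_len(ncol(abundance)))
    if (is.null(rownames(abundance)))
        rownames(abundance) <- paste0("taxon", seq_len(nrow(abundance)))
    n <- ncol(abundance)
    individual <- rep_len(as.character(individual), n)
    day <- rep_len(as.numeric(day), n)
    group <- rep_len(as.character(group), n)
    ord <- order(individual, day)
    abundance <- abundance[, ord, drop = FALSE]
    cd <- DataFrame(individual = individual[ord], day = day[ord],
                    group = group[ord], row.names = colnames(abundance))
    rd <- DataFrame(lineage = if (is.null(lineage)) NA_character_
                    else as.character(lineage),
                    zeroSum = rowSums(abundance) == 0,
                    row.names = rownames(abundance))
    new("TaxonProfile",
        SummarizedExperiment(assays = list(abundance = abundance),
                             rowData = rd, colData = cd))
}

#' Read a taxon-abundance table plus sample metadata
#'
#' The table must have a header row of sample ids and a taxon-id first
#' column; the metadata file maps sample id to individual, collection day
#' and (optionally) group.  Tab- and comma-delimited files are detected
#' from the header line.  All-zero taxon rows are retained and flagged in
#' `rowData(x)$zeroSum`.
#'
#' @param path path to the abundance table.
#' @param metadataPath path to the metadata table with columns
#'   `sample_id`, `individual_id`, `day` and optionally `group`.
#' @return a [TaxonProfile-class].
#' @seealso [writeTaxonProfile()] for the inverse.
#' @export
readTaxonProfile <- function(path, metadataPath) {
    sep <- detectSep(path)
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    sampleIds <- header[-1L]
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id in ", path, ": ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                             row.names = 1L, comment.char = "", quote = "\"")
    lineage <- NULL
    if ("lineage" %in% colnames(tab)) {
        lineage <- as.character(tab[["lineage"]])
        tab[["lineage"]] <- NULL
    }
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    if (any(is.na(m))) stop("missing abundance values in ", path)
    if (any(m < 0)) stop("negative abundance value in ", path)
    md <- utils::read.table(metadataPath, header = TRUE, sep = detectSep(metadataPath),
                            check.names = FALSE, comment.char = "", quote = "\"",
                            colClasses = "character")
    need <- c("sample_id", "individual_id", "day")
    if (!all(need %in% colnames(md)))
        stop("metadata must have columns ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(m), md$sample_id)
    if (length(missing))
        stop("sample(s) in table missing from metadata: ",
             paste(missing, collapse = ", "))
    md <- md[match(colnames(m), md$sample_id), , drop = FALSE]
    TaxonProfile(m,
                 individual = md$individual_id,
                 day = as.numeric(md$day),
                 group = if ("group" %in% colnames(md)) md$group else NA,
                 lineage = lineage)
}

#' Write a TaxonProfile (and its metadata) as delimited text
#'
#' @param x a [TaxonProfile-class].
#' @param path,metadataPath output file paths.
#' @param sep field separator (default tab).
#' @return invisibly, `path`.
#' @export
writeTaxonProfile <- function(x, path, metadataPath = NULL, sep = "\t") {
    m <- abundances(x)
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
    lin <- taxonLineages(x)
    if (!all(is.na(lin))) df$lineage <- lin
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    if (!is.null(metadataPath)) {
        md <- data.frame(sample_id = colnames(m),
                         individual_id = sampleIndividuals(x),
                         day = sampleDays(x),
                         group = sampleGroups(x))
        utils::write.table(md, metadataPath, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

detectSep <- function(path) {
    line <- readLines(path, n = 1L)
    if (grepl("\t", line)) "\t" else ","
}

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
.RANK_PREFIX <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
                  family = "f__", genus = "g__", species = "s__")

#' Parse lineage strings to a given taxonomic rank
#'
#' Greengenes-style prefixes ("k__", "p__", ..., "s__") are used when
#' present; otherwise the ";"-separated position of the rank is taken.
#' Missing or empty rank values yield NA.
#'
#' @param lineage character vector of lineage strings.
#' @param level one of kingdom, phylum, class, order, family, genus, species.
#' @return character vector of rank values (NA where unresolvable).
#' @export
parseLineage <- function(lineage, level) {
    level <- match.arg(level, .RANKS)
    idx <- match(level, .RANKS)
    pre <- .RANK_PREFIX[[level]]
    vapply(lineage, function(s) {
        if (is.na(s)) return(NA_character_)
        parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
        hit <- parts[startsWith(parts, pre)]
        val <- if (length(hit)) sub(pre, "", hit[1L], fixed = TRUE)
               else if (length(parts) >= idx && !any(grepl("__", parts)))
                   parts[idx]
               else NA_character_
        if (is.na(val) || !nzchar(val)) NA_character_ else val
    }, character(1), USE.NAMES = FALSE)
}

#' Aggregate a profile to a taxonomic rank
#'
#' Rows are summed within each rank value.  Taxa whose lineage lacks the
#' requested rank are pooled into an "unclassified <parent>" bin keyed by
#' the deepest resolvable parent rank, so column sums are preserved
#' exactly.
#'
#' @param x a [TaxonProfile-class] with lineages.
#' @param level target rank (kingdom ... species).
#' @return an aggregated [TaxonProfile-class].
#' @export
aggregateToLevel <- function(x, level) {
    level <- match.arg(level, .RANKS)
    lin <- taxonLineages(x)
    if (all(is.na(lin))) stop("profile has no lineage annotation")
    key <- parseLineage(lin, level)
    idx <- match(level, .RANKS)
    for (i in which(is.na(key))) {
        parent <- NA_character_
        for (up in rev(seq_len(idx - 1L))) {
            v <- parseLineage(lin[i], .RANKS[up])
            if (!is.na(v)) { parent <- v; break }
        }
        key[i] <- paste0("unclassified_",
                         if (is.na(parent)) rownames(x)[i] else parent)
    }
    m <- rowsum(abundances(x), group = key, reorder = TRUE)
    agg <- TaxonProfile(m, individual = sampleIndividuals(x),
                        day = sampleDays(x), group = sampleGroups(x))
    metadata(agg)$aggregatedTo <- level
    agg
}

#' Pseudocount and close to relative abundances
#'
#' Adds `pseudocount` to every entry (the default 0.5 is the standard
#' compositional zero replacement; downstream log-ratio steps require
#' strictly positive values) and divides each column by its sum, so every
#' column sums to 1.
#'
#' @param x a [TaxonProfile-class].
#' @param pseudocount non-negative value added to every entry before
#'   closure.  With `pseudocount = 0` an all-zero column is an error.
#' @return a [TaxonProfile-class] of relative abundances.
#' @export
normalizeRelative <- function(x, pseudocount = 0.5) {
    stopifnot(pseudocount >= 0)
    m <- abundances(x) + pseudocount
    cs <- colSums(m)
    if (any(cs == 0))
        stop("all-zero sample column(s): ",
             paste(colnames(m)[cs == 0], collapse = ", "))
    m <- sweep(m, 2L, cs, "/")
    out <- replaceAbundance(x, m)
    metadata(out)$normalized <- TRUE
    metadata(out)$pseudocount <- pseudocount
    out
}

# replace the abundance assay, keeping all annotation
replaceAbundance <- function(x, m) {
    assay(x, "abundance", withDimnames = FALSE) <- m
    validObject(x)
    x
}

#' Split samples into reference and case sets
#'
#' The reference set follows the usual convention for single-sample
#' perturbation scoring: the samples from each individual's first
#' `nRefTimePoints` collection days (all individuals are pre-symptomatic
#' then), pooled across the cohort.  Case samples are the remaining samples
#' of `individual`, ordered by day.
#'
#' @param x a [TaxonProfile-class].
#' @param individual the individual whose later samples are to be scored.
#' @param nRefTimePoints number of leading time points per individual that
#'   form the reference pool (default 2).
#' @param referenceScope `"cohort"` (default) pools the leading time points
#'   of every individual; `"individual"` restricts the reference to
#'   `individual`'s own leading samples.
#' @return list with character vectors `reference` and `case` (sample ids,
#'   case ordered by day), and `caseDays`.
#' @export
referenceSplit <- function(x, individual, nRefTimePoints = 2L,
                           referenceScope = c("cohort", "individual")) {
    referenceScope <- match.arg(referenceScope)
    ind <- sampleIndividuals(x)
    day <- sampleDays(x)
    ids <- colnames(x)
    if (!individual %in% ind) stop("unknown individual: ", individual)
    refIdx <- unlist(lapply(split(seq_along(ids), ind), function(i)
        i[order(day[i])][seq_len(min(nRefTimePoints, length(i)))]),
        use.names = FALSE)
    if (referenceScope == "individual")
        refIdx <- refIdx[ind[refIdx] == individual]
    caseIdx <- setdiff(which(ind == individual), refIdx)
    caseIdx <- caseIdx[order(day[caseIdx])]
    if (!length(refIdx)) stop("empty reference set")
    list(reference = ids[refIdx], case = ids[caseIdx], caseDays = day[caseIdx])
}
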