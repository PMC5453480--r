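#' @importFrom utils read.table write.table
NULL

# Shared identifier normalization: lower-case and strip surrounding
# whitespace, nothing else — prediction-table dialects vary and silent
# rewriting hides bugs.
normalizeId <- function(x) tolower(trimws(as.character(x)))

pairKey <- function(mirna, gene) paste(mirna, gene, sep = "\r")

#' Load miRNA-target prediction tables
#'
#' Reads one two-column TSV (`mirna<TAB>gene`) per prediction source.
#' `#`-prefixed comment lines are ignored; an optional header row is
#' detected and dropped when its first field looks like a column label
#' (`mirna`/`mir`/`microrna`). Identifiers are lower-cased and stripped;
#' duplicate pairs within a file are collapsed. Rows with fewer than two
#' fields are skipped with a warning.
#'
#' @param paths character vector of file paths, one per source.
#' @param sourceNames character vector of source names, parallel to `paths`.
#' @return list of [PredictionTable-class], in input order.
#' @export
loadPredictionTables <- function(paths, sourceNames) {
  if (length(paths) != length(sourceNames))
    stop("need exactly one path per source name")
  tables <- Map(function(path, src) {
    if (!file.exists(path))
      stop("cannot read prediction table: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
    if (length(lines) &&
        grepl("^(mirna|mir|microrna)\\b", tolower(lines[1L])))
      lines <- lines[-1L]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(fields) < 2L
    if (any(short))
      warning(sum(short), " row(s) with fewer than 2 columns skipped in ",
              path, call. = FALSE)
    fields <- fields[!short]
    if (!length(fields))
      return(PredictionTable(src, character(), character()))
    PredictionTable(src,
                    normalizeId(vapply(fields, `[[`, "", 1L)),
                    normalizeId(vapply(fields, `[[`, "", 2L)))
  }, paths, sourceNames)
  stats::setNames(tables, sourceNames)
}

#' Load a pre-miRNA to mature-miRNA mapping table
#'
#' TSV with columns `pre_id<TAB>mature_id`, one row per mapping (a precursor
#' with two arms appears on two rows).
#'
#' @param path path to the mapping TSV.
#' @return data.frame with character columns `pre_id` and `mature_id`.
#' @export
loadMatureMap <- function(path) {
  if (!file.exists(path)) stop("cannot read mature map: ", path)
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("pre_id", "mature_id"),
                  colClasses = "character", comment.char = "#")
  data.frame(pre_id = normalizeId(d$pre_id),
             mature_id = normalizeId(d$mature_id),
             stringsAsFactors = FALSE)
}

#' Convert precursor miRNA ids to mature ids in a prediction table
#'
#' Each pair whose miRNA id is a precursor id in the map is expanded to one
#' pair per mapped mature arm. Ids already in the mature namespace pass
#' through unchanged. Ids that look like unconverted precursors (no
#' `-3p`/`-5p` arm suffix) but are absent from the map pass through with a
#' warning, so partial maps remain usable.
#'
#' @param table a [PredictionTable-class].
#' @param map data.frame as returned by [loadMatureMap()]; may have 0 rows.
#' @return a new [PredictionTable-class] in the mature namespace.
#' @export
mapToMature <- function(table, map) {
  stopifnot(is(table, "PredictionTable"))
  p <- table@pairs
  if (!nrow(p) || !nrow(map))
    return(warnUnmappedPre(table, map))
  bypre <- split(map$mature_id, map$pre_id)
  hit <- p$mirna %in% names(bypre)
  expanded <- p[!hit, , drop = FALSE]
  if (any(hit)) {
    mm <- bypre[p$mirna[hit]]
    expanded <- rbind(expanded,
                      data.frame(mirna = unlist(mm, use.names = FALSE),
                                 gene = rep(p$gene[hit], lengths(mm)),
                                 stringsAsFactors = FALSE))
  }
  out <- PredictionTable(table@sourceName, expanded$mirna, expanded$gene)
  warnUnmappedPre(out, map)
}

# warn for pre-style ids (hsa-mir-NNN without an arm suffix) that the map
# does not cover and that are not themselves in the map's mature namespace
warnUnmappedPre <- function(table, map) {
  ids <- unique(table@pairs$mirna)
  prelike <- grepl("mir", ids, fixed = TRUE) & !grepl("-[35]p$", ids)
  known <- if (nrow(map)) prelike & ids %in% map$mature_id else FALSE
  unmapped <- ids[prelike & !known &
                    !(if (nrow(map)) ids %in% map$pre_id else FALSE)]
  if (length(unmapped))
    warning("unmapped precursor-style id(s) passed through in source '",
            table@sourceName, "': ",
            paste(utils::head(unmapped, 5L), collapse = ", "),
            if (length(unmapped) > 5L) ", ...", call. = FALSE)
  table
}

#' Build the consensus interaction catalog
#'
#' A (miRNA, gene) pair is retained when it appears in at least `minSources`
#' distinct prediction sources; a pair listed twice inside one source counts
#' that source once. Raising `minSources` can only shrink the catalog.
#'
#' @param tables list of [PredictionTable-class] sharing one normalized
#'   identifier namespace.
#' @param minSources consensus threshold (default 2 sources).
#' @return an [InteractionCatalog-class].
#' @export
buildCatalog <- function(tables, minSources = 2L) {
  minSources <- as.integer(minSources)
  if (minSources < 1L) stop("minSources must be >= 1")
  if (minSources > length(tables))
    stop("minSources (", minSources, ") exceeds the number of prediction ",
         "sources (", length(tables), ")")
  per <- lapply(tables, function(t) {
    stopifnot(is(t, "PredictionTable"))
    cbind(t@pairs, source = rep(t@sourceName, nrow(t@pairs)))
  })
  all <- do.call(rbind, per)
  if (is.null(all) || !nrow(all))
    return(new("InteractionCatalog",
               records = data.frame(mirna = character(), gene = character(),
                                    source_count = integer(),
                                    sources = character()),
               minSources = minSources))
  key <- pairKey(all$mirna, all$gene)
  srcs <- lapply(split(all$source, key), unique)
  keep <- names(srcs)[lengths(srcs) >= minSources]
  keep <- sort(keep)
  parts <- strsplit(keep, "\r", fixed = TRUE)
  rec <- data.frame(
    mirna = vapply(parts, `[[`, "", 1L),
    gene = vapply(parts, `[[`, "", 2L),
    source_count = lengths(srcs[keep]),
    sources = vapply(srcs[keep], function(s) paste(sort(s), collapse = ","),
                     ""),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  new("InteractionCatalog", records = rec, minSources = minSources)
}

#' Write an interaction catalog as TSV
#'
#' Columns: mirna, gene, source_count, comma-joined sources.
#' @param catalog an [InteractionCatalog-class].
#' @param path output path.
#' @export
writeCatalog <- function(catalog, path) {
  write.table(catalog@records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
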