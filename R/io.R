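#' @include AllClasses.R AllGenerics.R
NULL

#' Read a delimited count table
#'
#' Expects sample identifiers in the first column and taxon identifiers in
#' the header row; use \code{transpose = TRUE} for taxa-in-rows dialects.
#' Duplicate identifiers, non-numeric cells and ragged rows are rejected
#' with errors naming the offending row or column — no silent coercion.
#'
#' @param path file path.
#' @param dialect "tsv" (default) or "csv".
#' @param transpose logical; the file stores taxa in rows.
#' @return a \linkS4class{CompositionTable}.
#' @export
readCounts <- function(path, dialect = c("tsv", "csv"), transpose = FALSE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (dialect == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "", quote = "\"", fill = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate identifiers in first column: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    df <- df[, -1, drop = FALSE]
    bad <- !vapply(df, is.numeric, TRUE)
    if (any(bad))
        stop("non-numeric values in column(s): ",
             paste(names(df)[bad], collapse = ", "))
    if (anyDuplicated(names(df)))
        stop("duplicate identifiers in header: ",
             paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
    m <- as.matrix(df)
    rownames(m) <- ids
    CompositionTable(m, transpose = transpose)
}

#' Read taxon-set definitions
#'
#' GMT format (one set per line: name, description, then tab-separated taxon
#' ids) or long-format TSV with header columns \code{taxon_id} and
#' \code{set_name}. Membership is aligned to the supplied taxon universe;
#' members absent from it are dropped with a message, sets left empty are
#' dropped with a warning.
#'
#' @param path file path.
#' @param format "gmt" (default) or "long_tsv".
#' @param universe character vector of taxon ids (typically
#'   \code{taxonIds(table)}).
#' @return a \linkS4class{SetCollection}.
#' @export
readSets <- function(path, format = c("gmt", "long_tsv"), universe) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "gmt") {
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        fields <- strsplit(lines, "\t", fixed = TRUE)
        short <- which(vapply(fields, length, 0L) < 3L)
        if (length(short))
            stop("malformed GMT line ", short[1],
                 ": need name, description and at least one member")
        sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                                vapply(fields, `[[`, "", 1L))
    } else {
        df <- utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE, quote = "\"")
        if (!all(c("taxon_id", "set_name") %in% names(df)))
            stop("long-format set file needs header columns ",
                 "'taxon_id' and 'set_name'")
        sets <- split(as.character(df$taxon_id), df$set_name)
    }
    SetCollection(sets, universe = universe)
}

## 17 significant digits: enough for an exact double round trip
.fmtFull <- function(x) formatC(x, digits = 17, format = "g")

#' Write an enrichment result as TSV (plus a JSON manifest)
#'
#' Writes the score matrix with a \code{sample_id} first column and one
#' column per set, at full floating-point precision (round-trip safe), and —
#' unless \code{manifest = NULL} — a \code{<path>.manifest.json} sidecar
#' recording the tool version, the output scale, input digests and any
#' run parameters passed in \code{manifest}, sufficient to reproduce the run.
#'
#' @param result an \linkS4class{EnrichmentResult}.
#' @param path output TSV path.
#' @param manifest optional named list of run metadata (seeds, resolved
#'   config, input paths — paths are digested with md5); use NULL to skip
#'   the sidecar.
#' @return invisibly, the manifest list (or NULL).
#' @export
writeResult <- function(result, path, manifest = list()) {
    stopifnot(methods::is(result, "EnrichmentResult"))
    sc <- scores(result)
    body <- cbind(sample_id = rownames(sc),
                  as.data.frame(apply(sc, 2, .fmtFull, simplify = FALSE),
                                check.names = FALSE))
    utils::write.table(body, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (is.null(manifest)) return(invisible(NULL))
    man <- runManifest(outputType = outputType(result), extra = manifest)
    man$output <- list(path = path,
                       md5 = unname(tools::md5sum(path)))
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(man)
}

#' Build a run manifest
#'
#' @param ... ignored.
#' @param outputType the score scale written.
#' @param extra named list of run metadata; character elements that are
#'   existing file paths are replaced by \code{list(path, md5)}.
#' @return a manifest list (tool, version, outputType, then \code{extra}).
#' @export
runManifest <- function(..., outputType = NULL, extra = list()) {
    extra <- lapply(extra, function(x) {
        if (is.character(x) && length(x) == 1L && file.exists(x))
            list(path = x, md5 = unname(tools::md5sum(x)))
        else x
    })
    c(list(tool = "cbea",
           version = as.character(utils::packageVersion("cbea")),
           outputType = outputType),
      extra)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes \code{<prefix>_counts.tsv}, \code{<prefix>_sets.gmt},
#' \code{<prefix>_truth.tsv} and \code{<prefix>_meta.json} (the full
#' generating configuration and seed).
#'
#' @param dataset a \linkS4class{SimulatedDataset}.
#' @param prefix output path prefix.
#' @param seed the seed used to generate the dataset (recorded in the
#'   metadata).
#' @return invisibly, the vector of written paths.
#' @export
writeSimulation <- function(dataset, prefix, seed = NULL) {
    stopifnot(methods::is(dataset, "SimulatedDataset"))
    cts <- abundances(simCounts(dataset))
    countsPath <- paste0(prefix, "_counts.tsv")
    utils::write.table(cbind(sample_id = rownames(cts),
                             as.data.frame(cts, check.names = FALSE)),
                       countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gmtPath <- paste0(prefix, "_sets.gmt")
    members <- setMembers(simSets(dataset))
    writeLines(vapply(names(members), function(s)
        paste(c(s, "simulated", members[[s]]), collapse = "\t"), ""),
        gmtPath)
    truthPath <- paste0(prefix, "_truth.tsv")
    utils::write.table(data.frame(set_name = names(truthLabels(dataset)),
                                  enriched = truthLabels(dataset)),
                       truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cfg <- dataset@config
    meta <- list(seed = seed,
                 config = list(nSamples = cfg@nSamples, nTaxa = cfg@nTaxa,
                               setSize = cfg@setSize, nSets = cfg@nSets,
                               nbMean = cfg@nbMean,
                               nbDispersion = cfg@nbDispersion,
                               zeroProb = cfg@zeroProb, rho = cfg@rho,
                               foldChange = cfg@foldChange,
                               enrichedSets = cfg@enrichedSets),
                 groups = as.list(table(groupLabels(dataset))))
    metaPath <- paste0(prefix, "_meta.json")
    jsonlite::write_json(runManifest(extra = meta), metaPath,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(countsPath, gmtPath, truthPath, metaPath))
}
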