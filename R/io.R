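## Plain-text readers/writers: TSV matrices with node-label headers, 3-column
## parcellation TSV, 2-column volume TSV, cohort CSV, YAML/JSON run configs.

#' Write / read a labeled symmetric matrix as TSV
#'
#' First column `label`, remaining columns named by node label.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `readMatrixTSV` returns the matrix with dimnames.
#' @export
writeMatrixTSV <- function(m, path) {
    df <- data.frame(label = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    if (names(df)[1] != "label")
        stop("malformed matrix file '", path, "': first column must be 'label'")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(m) != ncol(m))
        stop("malformed matrix file '", path, "': not square (",
             nrow(m), " x ", ncol(m), ")")
    rownames(m) <- df$label
    if (!identical(rownames(m), colnames(m)))
        stop("malformed matrix file '", path,
             "': row labels disagree with column header")
    m
}

#' Write / read a parcellation as a 3-column TSV
#' @param parc a [Parcellation-class].
#' @param path file path.
#' @export
writeParcellationTSV <- function(parc, path) {
    utils::write.table(parc@nodes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeParcellationTSV
#' @export
readParcellationTSV <- function(path) {
    df <- read.delim(path)
    parcellation(df$label, df$hemisphere)
}

#' Write / read per-node volumes as a 2-column TSV (label, volume_mm3)
#' @param volumes named numeric vector (mm^3).
#' @param path file path.
#' @export
writeVolumesTSV <- function(volumes, path) {
    utils::write.table(
        data.frame(label = names(volumes), volume_mm3 = as.numeric(volumes)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeVolumesTSV
#' @export
readVolumesTSV <- function(path) {
    df <- read.delim(path)
    setNames(df$volume_mm3, df$label)
}

#' Write one subject's raw inputs into a directory
#'
#' Files are `<id>_counts.tsv`, `<id>_fa.tsv`, `<id>_volumes.tsv`.
#' @param raw a [SubjectRaw-class].
#' @param dir output directory.
#' @export
writeSubjectRaw <- function(raw, dir) {
    writeMatrixTSV(raw@counts, file.path(dir, paste0(raw@id, "_counts.tsv")))
    writeMatrixTSV(raw@meanFA, file.path(dir, paste0(raw@id, "_fa.tsv")))
    writeVolumesTSV(raw@volumes, file.path(dir, paste0(raw@id, "_volumes.tsv")))
    invisible(raw@id)
}

#' Read one subject's raw inputs from a directory
#' @param id subject identifier (file prefix).
#' @param dir directory holding `<id>_counts.tsv` etc.
#' @param icv intracranial volume (mm^3), usually from the cohort table.
#' @return a [SubjectRaw-class].
#' @export
readSubjectRaw <- function(id, dir, icv) {
    counts <- readMatrixTSV(file.path(dir, paste0(id, "_counts.tsv")))
    fa <- readMatrixTSV(file.path(dir, paste0(id, "_fa.tsv")))
    volumes <- readVolumesTSV(file.path(dir, paste0(id, "_volumes.tsv")))
    subjectRaw(id, counts, fa, volumes, icv, labels = rownames(counts))
}

#' Write / read a weighted network
#' @param net a [WeightedNetwork-class].
#' @param path file path; `writeNetworkGraphML` writes GraphML for external
#'   viewers.
#' @export
writeNetworkTSV <- function(net, path) writeMatrixTSV(net@weights, path)

#' @rdname writeNetworkTSV
#' @export
readNetworkTSV <- function(path) weightedNetwork(readMatrixTSV(path))

#' @rdname writeNetworkTSV
#' @export
writeNetworkGraphML <- function(net, path) {
    igraph::write_graph(.asIgraph(net@weights), path, format = "graphml")
    invisible(path)
}

#' Read a run configuration (YAML or JSON by extension)
#' @param path config file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Validate a bundle of raw input files
#'
#' Checks each subject's counts matrix (square, symmetric to 1e-8,
#' non-negative integers, zero diagonal), FA matrix (range `[0, 1]`, zero
#' where counts are zero), label agreement with the parcellation, volume
#' positivity, and cohort-column completeness (disease flags, six
#' covariates, 14 cognition scores).
#'
#' @param dir directory of per-subject files (see [writeSubjectRaw()]).
#' @param cohortFile cohort CSV path.
#' @param parc a [Parcellation-class].
#' @return data.frame of violations (`file`, `violation`); zero rows means
#'   the bundle is valid.
#' @export
validateInputs <- function(dir, cohortFile, parc = aalParcellation()) {
    bad <- list()
    note <- function(file, msg) bad[[length(bad) + 1L]] <<-
        data.frame(file = file, violation = msg)
    if (!file.exists(cohortFile)) stop("cannot read cohort file: ", cohortFile)
    cohort <- read.csv(cohortFile)
    need <- c("subject_id", "group", "adci", "lbci", .COVARIATES,
              cognitionScores())
    miss <- setdiff(need, names(cohort))
    if (length(miss))
        note(cohortFile, paste("missing column(s):",
                               paste(miss, collapse = ", ")))
    labels <- nodeLabels(parc)
    for (id in cohort$subject_id) {
        countsM <- NULL
        for (kind in c("counts", "fa")) {
            f <- file.path(dir, paste0(id, "_", kind, ".tsv"))
            if (!file.exists(f)) { note(f, "file missing"); next }
            m <- tryCatch(readMatrixTSV(f), error = function(e) {
                note(f, conditionMessage(e)); NULL })
            if (is.null(m)) next
            if (!identical(rownames(m), labels))
                note(f, "labels disagree with parcellation")
            asym <- which(abs(m - t(m)) > 1e-8, arr.ind = TRUE)
            if (nrow(asym))
                note(f, sprintf("asymmetric at [%d, %d] (and %d more)",
                                asym[1, 1], asym[1, 2], nrow(asym) - 1L))
            if (any(m < 0)) note(f, "negative entries")
            if (kind == "fa" && any(m > 1))
                note(f, sprintf("FA out of range: max %.3g", max(m)))
            if (kind == "counts") countsM <- m
            else if (!is.null(countsM) && any(m[countsM == 0] != 0))
                note(f, "FA nonzero where count is zero")
        }
        f <- file.path(dir, paste0(id, "_volumes.tsv"))
        if (!file.exists(f)) note(f, "file missing")
        else {
            v <- readVolumesTSV(f)
            if (!identical(names(v), labels))
                note(f, "labels disagree with parcellation")
            if (any(v <= 0)) note(f, "non-positive volume(s)")
        }
    }
    out <- if (length(bad)) do.call(rbind, bad)
           else data.frame(file = character(), violation = character())
    rownames(out) <- NULL
    out
}
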