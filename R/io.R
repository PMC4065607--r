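## Plain-text I/O: TSV tables with documented columns, FASTA target lists,
## JSON sidecars for seeds and manifests.

#' Write a target list as TSV
#'
#' Columns: the full 22-mer plus the derived region columns (r2N4, r5N3,
#' r7N2, r11N4). Region columns are derived, never authoritative.
#'
#' @param targets character vector of 22-mers.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTargetsTSV <- function(targets, path) {
  df <- extractRegions(targets)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target list from TSV or FASTA
#'
#' TSV input must have a `full` column of 22-mers (extra columns ignored);
#' FASTA input has one 22-mer record per target. Sequences are uppercased and
#' validated against the strict ACGT alphabet.
#'
#' @param path input path; format inferred from extension (`.fa`/`.fasta`
#'   vs everything else = TSV) unless `format` is given.
#' @param format `"auto"`, `"tsv"` or `"fasta"`.
#' @return character vector of validated 22-mers.
#' @export
readTargets <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  seqs <- if (format == "fasta") {
    as.character(Biostrings::readDNAStringSet(path))
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (is.null(df$full))
      stop(validationError("target TSV needs a 'full' column"))
    df$full
  }
  out <- toupper(unname(seqs))
  assertDna(out, len = 22L)
  out
}

#' Write screening records as TSV (with a JSON seed sidecar)
#'
#' @param x ScreeningSet or records data.frame.
#' @param path output TSV path; when `x` is a ScreeningSet a `<path>.json`
#'   sidecar records the generation seeds and parameters.
#' @return the path, invisibly.
#' @export
writeScreeningTSV <- function(x, path) {
  rec <- recordsFrom(x)
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is(x, "ScreeningSet"))
    jsonlite::write_json(x@meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read screening records from TSV
#'
#' @param path TSV written by [writeScreeningTSV()].
#' @return A [ScreeningSet-class] (meta restored from the sidecar if
#'   present).
#' @export
readScreeningTSV <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(target = "character"))
  missing <- setdiff(SCREENING_COLUMNS, names(rec))
  if (length(missing))
    stop(validationError(paste("screening TSV lacks columns:",
                               paste(missing, collapse = ", "))))
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("ScreeningSet", records = rec, targets = sort(unique(rec$target)),
      meta = as.list(meta))
}

#' Write a module library as long-format TSV
#'
#' Columns: module_id, region, the residue columns, region_target, activity,
#' label (activity >= tau), measured_flag.
#'
#' @param lib a ModuleLibrary.
#' @param path output path.
#' @param tau activity threshold for the label column.
#' @return the path, invisibly.
#' @export
writeModuleLibraryTSV <- function(lib, path, tau = 0.25) {
  stopifnot(is(lib, "ModuleLibrary"))
  act <- moduleActivities(lib)
  mods <- moduleResidues(lib)
  long <- data.frame(
    module_id = rep(rownames(act), times = ncol(act)),
    region = moduleRegion(lib),
    mods[rep(seq_len(nrow(mods)), times = ncol(act)),
         setdiff(names(mods), "module_id"), drop = FALSE],
    region_target = rep(colnames(act), each = nrow(act)),
    activity = as.vector(act),
    label = as.integer(as.vector(act) >= tau),
    measured_flag = TRUE,
    stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module library from long-format TSV
#'
#' Reconstructs a [ModuleLibrary-class] from the table written by
#' [writeModuleLibraryTSV()]. The latent compatibility matrix is not part of
#' the interchange format (measured activities only).
#'
#' @param path TSV path.
#' @return A [ModuleLibrary-class].
#' @export
readModuleLibraryTSV <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("module_id", "region", "region_target", "activity")
  if (!all(need %in% names(long)))
    stop(validationError("module library TSV lacks required columns"))
  region <- unique(long$region)
  if (length(region) != 1L)
    stop(validationError("module library TSV must hold a single region"))
  space <- enumerateRegionSpace(sub("^p", "", region))
  pos <- if (region == "p5N3") P5N3_POSITIONS else P11N4_POSITIONS
  resCols <- paste0("p", pos)
  mods <- unique(long[c("module_id", resCols)])
  mods <- mods[order(match(mods$module_id, unique(long$module_id))), ]
  rownames(mods) <- NULL
  act <- matrix(NA_real_, nrow(mods), length(space),
                dimnames = list(mods$module_id, space))
  act[cbind(match(long$module_id, mods$module_id),
            match(long$region_target, space))] <- long$activity
  if (anyNA(act))
    stop(validationError("module library TSV misses region targets"))
  new("ModuleLibrary", region = region, modules = mods, activities = act,
      latent = NULL)
}

#' Export a feature matrix as TSV plus a JSON column-metadata sidecar
#'
#' Dense TSV of the design matrix; the sidecar carries the full column
#' metadata (name grammar: `P44=R`, `T5N3.2=G`, `P44=R*T5N3.2=G`).
#'
#' @param fm a FeatureMatrix.
#' @param path output TSV path (sidecar at `<path>.json`).
#' @return the path, invisibly.
#' @export
writeFeatureMatrixTSV <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  x <- fm@x
  df <- if (is.data.frame(x)) x else as.data.frame(as.matrix(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fm@columnData, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a CVSummary as per-target TSV plus JSON aggregates
#'
#' @param cv a CVSummary.
#' @param path output TSV path (aggregates at `<path>.json`).
#' @return the path, invisibly.
#' @export
writeCVSummaryTSV <- function(cv, path) {
  stopifnot(is(cv, "CVSummary"))
  write.table(cvPerTarget(cv), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(c(cvAggregates(cv), cv@settings),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
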