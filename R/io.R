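#' Write a cohort to disk
#'
#' The clinical table goes to `clinical.csv`; each scan is stored as a
#' pair of plain-text matrices (`<id>_bmd.tsv`, `<id>_mask.tsv`) with a
#' JSON sidecar carrying the pixel spacing. Plain-text containers keep
#' the cohort portable and diff-able.
#'
#' @param cohort a [generate_cohort()] result
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  for (id in names(cohort$scans)) {
    sc <- cohort$scans[[id]]
    utils::write.table(sc$bmd, file.path(dir, paste0(id, "_bmd.tsv")),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    utils::write.table(sc$mask * 1L, file.path(dir, paste0(id, "_mask.tsv")),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    jsonlite::write_json(list(dx = sc$dx, dy = sc$dy),
                         file.path(dir, paste0(id, "_meta.json")),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

read_scan_pair <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  bmd <- as.matrix(utils::read.table(file.path(dir, paste0(id, "_bmd.tsv")),
                                     sep = "\t"))
  mask <- as.matrix(utils::read.table(file.path(dir, paste0(id, "_mask.tsv")),
                                      sep = "\t")) > 0.5
  dimnames(bmd) <- NULL; dimnames(mask) <- NULL
  scan_raster(bmd, mask, meta$dx, meta$dy)
}

#' Ingest an external cohort
#'
#' Reads a clinical CSV (columns subject_id, group, age, height, weight,
#' bmi, bmd_total, gender; unknown extra columns are ignored with a
#' warning) and one scan pair per row from `dir`, validating each scan.
#' The result is interchangeable with [generate_cohort()] output.
#'
#' @param clinical_csv path to the clinical table
#' @param dir directory holding `<id>_bmd.tsv` / `<id>_mask.tsv` /
#'   `<id>_meta.json` triples
#' @return a `cohort` object
#' @export
ingest_cohort <- function(clinical_csv, dir = dirname(clinical_csv)) {
  clin <- utils::read.csv(clinical_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "height", "weight", "bmi",
            "bmd_total", "gender")
  missing <- setdiff(need, names(clin))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(clin), need)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  clin <- clin[, need]
  bad_bmi <- abs(clin$bmi - clin$weight / (clin$height / 100)^2) >
    0.005 * clin$bmi
  if (any(bad_bmi))
    stop("BMI inconsistent with height and weight for: ",
         paste(clin$subject_id[bad_bmi], collapse = ", "))
  scans <- list()
  for (id in clin$subject_id) {
    if (!file.exists(file.path(dir, paste0(id, "_bmd.tsv"))))
      stop("no scan files for subject ", id)
    scans[[id]] <- read_scan_pair(dir, id)
  }
  structure(list(clinical = clin, scans = scans, spec = NULL),
            class = "cohort")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the nested stage configurations can be overridden
#' from a YAML file; unknown keys are rejected.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  known_top <- c("seed", "out_dir", "cohort", "sim", "split", "smote")
  unknown <- setdiff(names(y), known_top)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$out_dir)) cfg$out_dir <- y$out_dir
  for (section in c("cohort", "sim", "split", "smote")) {
    if (is.null(y[[section]])) next
    tgt <- cfg[[section]]
    bad <- setdiff(names(y[[section]]), names(tgt))
    if (length(bad))
      stop("unknown keys in '", section, "': ", paste(bad, collapse = ", "))
    for (k in names(y[[section]])) tgt[[k]] <- y[[section]][[k]]
    cfg[[section]] <- tgt
  }
  cfg$cohort$seed <- cfg$seed
  cfg$split$base_seed <- cfg$seed
  cfg
}
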