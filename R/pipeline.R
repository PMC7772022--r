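#' Simulation options for the per-subject pipeline
#'
#' @param target_elements mesh density (desk default 6000; the
#'   reference-scale 60000 is available by configuration)
#' @param law a [material_law()]
#' @param yield a [yield_model()]
#' @param impact an [impact_params()]
#' @param b_frac,t_frac,pad_depth pad geometry settings (see
#'   [place_pads()])
#' @param neck_band neck ROI band width, mm
#' @param lsr_area critical-region area for the LSR, mm^2
#' @return object of class `sim_options`
#' @export
sim_options <- function(target_elements = 6000, law = material_law(),
                        yield = yield_model(), impact = impact_params(),
                        b_frac = 0.8, t_frac = 0.40, pad_depth = 10,
                        neck_band = 15, lsr_area = 9) {
  structure(list(target_elements = target_elements, law = law,
                 yield = yield, impact = impact, b_frac = b_frac,
                 t_frac = t_frac, pad_depth = pad_depth,
                 neck_band = neck_band, lsr_area = lsr_area),
            class = "sim_options")
}

#' Simulate one subject end to end
#'
#' Pose standardisation, morphometry, pad placement, fall-impact chain,
#' finite-element solve and attribute extraction for a single subject.
#'
#' @param record one-row clinical record
#' @param scan the subject's [scan_raster()]
#' @param opts a [sim_options()]
#' @param keep_solution retain the full `fe_solution` in the result
#' @return list with `attributes` (named 39-vector), `morph`, `pads`,
#'   `fall`, and optionally `solution`
#' @export
simulate_subject <- function(record, scan, opts = sim_options(),
                             keep_solution = FALSE) {
  posed <- standardise_pose(scan, canonical_orientation = TRUE)
  morph <- measure_morphometry(posed)
  pads <- place_pads(posed, morph, b_frac = opts$b_frac,
                     t_frac = opts$t_frac, depth = opts$pad_depth)
  fall <- fall_attributes(record, pads, opts$impact)
  mesh <- mesh_domain(posed, pads, opts$target_elements)
  materials <- assign_materials(mesh, posed, opts$law)
  constraints <- apply_constraints(mesh)
  load <- apply_load(mesh, fall$HP, pads)
  sol <- fe_solve(mesh, materials, constraints, load)

  rois <- partition_rois(posed, morph, opts$neck_band)
  cen <- element_centroids(mesh)
  fem <- which(mesh$tag == "femur")
  in_neck <- rois$predicates$neck(cen[fem, 1], cen[fem, 2])
  in_troch <- rois$predicates$troch(cen[fem, 1], cen[fem, 2]) & !in_neck
  neck <- fem[in_neck]; troch <- fem[in_troch]
  if (!length(neck) || !length(troch)) stop("empty element region of interest")

  tissue <- tissue_attributes(materials)
  lsr <- load_to_strength_ratio(sol, opts$yield, opts$lsr_area)
  mech <- list(LSR = lsr$lsr, FS = femoral_strength(fall$FP, lsr$lsr))
  for (rg in list(list(n = "N", el = neck), list(n = "T", el = troch))) {
    for (q in c("S1", "S3", "E1", "E3", "MPStress", "MPStrain", "SED"))
      mech[[paste0(q, "_", rg$n)]] <- regional_average(sol, rg$el, q)
  }
  mech$FRI_N <- fracture_risk_index(sol, neck, opts$yield, materials)
  mech$FRI_T <- fracture_risk_index(sol, troch, opts$yield, materials)

  out <- list(
    attributes = assemble_attributes(record, morph, fall, tissue, mech),
    morph = morph, pads = pads, fall = fall
  )
  if (keep_solution) out$solution <- sol
  out
}

#' Attribute table for a whole cohort
#'
#' Runs [simulate_subject()] for every subject and assembles the
#' canonical attribute table (subject_id, group, then the 39 canonical
#' columns in fixed order).
#'
#' @param cohort a [generate_cohort()] result (or compatible list)
#' @param opts a [sim_options()]
#' @param progress print one line per subject
#' @return data frame
#' @export
compute_attribute_table <- function(cohort, opts = sim_options(),
                                    progress = FALSE) {
  rows <- vector("list", nrow(cohort$clinical))
  for (i in seq_len(nrow(cohort$clinical))) {
    rec <- cohort$clinical[i, ]
    if (progress) message("subject ", rec$subject_id)
    sim <- simulate_subject(rec, cohort$scans[[rec$subject_id]], opts)
    rows[[i]] <- data.frame(subject_id = rec$subject_id, group = rec$group,
                            t(sim$attributes), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Bundles all stage configurations with a global seed. Unknown fields
#' are rejected. A configuration can be round-tripped through YAML (see
#' [read_pipeline_config()]).
#'
#' @param cohort a [cohort_spec()]
#' @param sim a [sim_options()]
#' @param split a [split_spec()]
#' @param smote a [smote_spec()]
#' @param feature_sets named list of feature sets; `NULL` selects
#'   features from the data (see [select_features()])
#' @param models model battery (see [default_model_battery()])
#' @param out_dir output directory
#' @param seed global seed propagated to every stage
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(cohort = cohort_spec(), sim = sim_options(),
                            split = split_spec(n_runs = 25),
                            smote = smote_spec(),
                            feature_sets = NULL,
                            models = default_model_battery(),
                            out_dir = tempfile("sidefall_run_"),
                            seed = 1) {
  cohort$seed <- seed
  split$base_seed <- seed
  structure(list(cohort = cohort, sim = sim, split = split, smote = smote,
                 feature_sets = feature_sets, models = models,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  config$out_dir <- NULL     # the hash identifies the computation, not
                             # where its outputs land
  s <- utils::capture.output(utils::str(config, digits.d = 12,
                                        list.len = 10000))
  sum(utf8ToInt(paste(s, collapse = "\n")) *
        (seq_along(utf8ToInt(paste(s, collapse = "\n"))) %% 97 + 1)) %%
    2147483647
}

#' Run the full pipeline
#'
#' Cohort generation, per-subject simulation, attribute table, feature
#' selection and classifier benchmarking; writes the attribute CSV, the
#' selection audit JSON and the evaluation report CSV to the output
#' directory and returns a manifest.
#'
#' @param config a [pipeline_config()]
#' @return list: `table` (attribute data frame), `selection`,
#'   `report` (an `eval_report`), `manifest`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  timings <- c()
  tick <- function(label, expr) {
    t <- Sys.time()
    val <- force(expr)
    timings[[label]] <<- as.numeric(Sys.time() - t, units = "secs")
    val
  }
  cohort <- tick("generate", generate_cohort(config$cohort))
  table <- tick("simulate", compute_attribute_table(cohort, config$sim))
  sel <- tick("select", select_features(table[, attribute_names()]))
  feature_sets <- config$feature_sets
  if (is.null(feature_sets)) {
    feature_sets <- list(selected = sel$final,
                         extended = c(sel$final, sel$extension_features))
  }
  report <- tick("benchmark",
                 benchmark(table, feature_sets, config$models,
                           config$split, config$smote))

  paths <- list(
    attributes = file.path(config$out_dir, "attributes.csv"),
    selection = file.path(config$out_dir, "selection_audit.json"),
    report = file.path(config$out_dir, "evaluation_report.csv")
  )
  utils::write.csv(table, paths$attributes, row.names = FALSE)
  jsonlite::write_json(
    list(pca_selected = sel$pca_selected, augmented = sel$augmented,
         removed_by_interdependence = sel$removed_by_interdependence,
         final = sel$final, extension_features = sel$extension_features,
         explained_variance_pct = unname(sel$pca$variance_pct)),
    paths$selection, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  utils::write.csv(report$summary, paths$report, row.names = FALSE)

  manifest <- list(
    config_hash = config_hash(config),
    version = tryCatch(as.character(utils::packageVersion("sidefall")),
                       error = function(e) "dev"),
    seed = config$seed,
    timings = timings,
    outputs = unlist(paths),
    finished = format(Sys.time()),
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(table = table, selection = sel, report = report, manifest = manifest)
}
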