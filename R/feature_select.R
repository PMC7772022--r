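#' Canonical attribute names
#'
#' The 39 attributes in canonical order: clinical (Age, Height, Weight,
#' BMI, BMD), geometric (NW, HAL, NSA, SAL, ITW, STW, FA), fall-related
#' (STH, FPK, FAT, FP, HP), bone-tissue (TB, TBE, CT, CTE) and
#' finite-element (LSR, FS, regional stresses/strains/energies and
#' fracture risk indices for neck `_N` and trochanter `_T`).
#'
#' @return character vector of length 39
#' @export
attribute_names <- function() {
  c("Age", "Height", "Weight", "BMI", "BMD",
    "NW", "HAL", "NSA", "SAL", "ITW", "STW", "FA",
    "STH", "FPK", "FAT", "FP", "HP",
    "TB", "TBE", "CT", "CTE",
    "LSR", "FS",
    "S1_N", "S3_N", "E1_N", "E3_N", "MPStress_N", "MPStrain_N", "SED_N",
    "S1_T", "S3_T", "E1_T", "E3_T", "MPStress_T", "MPStrain_T", "SED_T",
    "FRI_N", "FRI_T")
}

#' Z-score normalisation of an attribute table
#'
#' Per-column standardisation to mean 0 and SD 1, required before PCA on
#' attributes with heterogeneous units. Zero-variance columns are passed
#' through as zeros and flagged in the `"constant"` attribute.
#'
#' @param table numeric matrix or data frame (rows = subjects)
#' @return normalised numeric matrix with attributes `center`, `scale`,
#'   `constant`
#' @export
normalise_attributes <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stop("need at least two rows to normalise")
  if (any(!is.finite(x))) stop("missing or non-finite values in attribute table")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- sdv == 0
  sc <- ifelse(const, 1, sdv)
  z <- sweep(sweep(x, 2, mu), 2, sc, "/")
  z[, const] <- 0
  structure(z, center = mu, scale = sc, constant = const)
}

#' Principal component analysis of a normalised attribute matrix
#'
#' SVD-based PCA. Explained-variance percentages sum to 100; loadings are
#' orthonormal columns.
#'
#' @param x normalised matrix (see [normalise_attributes()])
#' @return object of class `pca_result` with `loadings` (attributes x
#'   components), `variance_pct`, `sdev`
#' @export
run_pca <- function(x) {
  if (any(!is.finite(x))) stop("non-finite entries")
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  var <- p$sdev^2
  structure(list(
    loadings = p$rotation,
    variance_pct = 100 * var / sum(var),
    sdev = p$sdev
  ), class = "pca_result")
}

#' Attributes contributing to the leading principal components
#'
#' An attribute contributes to a component when its absolute loading
#' exceeds `weight_floor` times the largest absolute loading on that
#' component; attributes with loadings orders of magnitude below the
#' component maximum are treated as non-contributing. The union over the
#' first `components` components is returned.
#'
#' @param pca a [run_pca()] result
#' @param components number of leading components to inspect
#' @param weight_floor relative loading threshold in (0, 1)
#' @return character vector of contributing attribute names (canonical
#'   loading-matrix order)
#' @export
pca_contributors <- function(pca, components = 3, weight_floor = 0.1) {
  stopifnot(inherits(pca, "pca_result"),
            components <= ncol(pca$loadings), components >= 1)
  L <- abs(pca$loadings[, seq_len(components), drop = FALSE])
  hit <- rep(FALSE, nrow(L))
  for (j in seq_len(ncol(L))) hit <- hit | (L[, j] > weight_floor * max(L[, j]))
  rownames(L)[hit]
}

#' Joint Pearson/Spearman correlation mask
#'
#' Computes the Pearson product-moment and Spearman rank correlation
#' matrices and a joint boolean mask marking attribute pairs whose
#' absolute correlation reaches `threshold` under either index. The
#' diagonal is excluded. Zero-variance columns have undefined
#' correlations; their mask entries are FALSE and their names are listed
#' in `$degenerate`.
#'
#' @param x numeric matrix or data frame, at least 3 rows
#' @param threshold absolute correlation threshold (default 0.9)
#' @return object of class `correlation_mask` with `pearson`, `spearman`,
#'   `mask`, `threshold`, `degenerate`
#' @export
correlation_mask <- function(x, threshold = 0.9) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least three rows")
  sdv <- apply(x, 2, stats::sd)
  degenerate <- colnames(x)[sdv == 0]
  pe <- suppressWarnings(stats::cor(x, method = "pearson"))
  sp <- suppressWarnings(stats::cor(x, method = "spearman"))
  m <- (abs(pe) >= threshold) | (abs(sp) >= threshold)
  m[is.na(m)] <- FALSE
  diag(m) <- FALSE
  structure(list(pearson = pe, spearman = sp, mask = m,
                 threshold = threshold, degenerate = degenerate),
            class = "correlation_mask")
}

mask_matrix <- function(mask) {
  if (inherits(mask, "correlation_mask")) mask$mask
  else {
    m <- as.matrix(mask)
    stopifnot(nrow(m) == ncol(m), isTRUE(all(m == t(m))))
    diag(m) <- FALSE
    m
  }
}

#' Augment a selected attribute set through correlation links
#'
#' Starting from an already-selected set, adds attributes that are
#' correlation-linked (mask TRUE) to at least `min_links` attributes
#' outside the selected set.
#'
#' Two modes are provided. The default (`sequential = FALSE`) counts, for
#' every attribute not in `already`, its masked links to attributes not
#' in `already`, and accepts all attributes with at least `min_links`
#' such links; the result is independent of any ordering and shrinks
#' monotonically as `min_links` grows. The redundancy-aware mode
#' (`sequential = TRUE`) processes candidates in alphabetical order and
#' adds each accepted attribute to the exclusion set before examining the
#' next, so links to an attribute whose information is already carried by
#' the selection no longer count; this consolidates clusters of mutually
#' correlated candidates into single representatives.
#'
#' @param mask a [correlation_mask()] or a symmetric logical matrix with
#'   attribute names
#' @param already character vector of attributes already selected
#' @param min_links minimum number of qualifying links (default 4)
#' @param sequential use the redundancy-aware sequential rule
#' @return character vector of augmented attribute names
#' @export
augment_by_links <- function(mask, already, min_links = 4,
                             sequential = FALSE) {
  stopifnot(min_links >= 1)
  m <- mask_matrix(mask)
  nm <- rownames(m) %||% colnames(m)
  stopifnot(!is.null(nm))
  rownames(m) <- colnames(m) <- nm
  cand <- setdiff(nm, already)
  if (!sequential) {
    deg <- vapply(cand, function(a) sum(m[a, setdiff(nm, already)]), numeric(1))
    return(cand[deg >= min_links])
  }
  excl <- already
  kept <- character(0)
  for (a in sort(cand)) {
    if (sum(m[a, setdiff(nm, excl)]) >= min_links) {
      kept <- c(kept, a)
      excl <- c(excl, a)
    }
  }
  kept
}

#' Default deterministic-dependency pruning rules
#'
#' Each removable attribute is mapped to the retained proxy that carries
#' the same information through an exact relation: the attenuation force
#' and soft-tissue thickness are affine in BMI, and the cortical
#' percentage is the complement of the trabecular percentage.
#'
#' @return named character vector (names = removable, values = proxy)
#' @export
default_dependency_rules <- function() {
  c(FAT = "BMI", STH = "BMI", CT = "TB")
}

#' Prune interdependent attributes from a candidate set
#'
#' Removes every removable attribute present in `candidates` whose proxy
#' is also present, recording the removals. Rule cycles are rejected.
#'
#' @param candidates character vector of candidate attributes
#' @param rules named character vector mapping removable -> proxy
#' @param pca_selected,augmented optional bookkeeping sets stored in the
#'   result
#' @param extension_features ordered extension list for the wide feature
#'   set
#' @return object of class `selection_result` with fields `pca_selected`,
#'   `augmented`, `removed_by_interdependence`, `final`,
#'   `extension_features`
#' @export
prune_interdependent <- function(candidates, rules = default_dependency_rules(),
                                 pca_selected = character(0),
                                 augmented = character(0),
                                 extension_features = c("NW", "NSA", "FA", "SAL")) {
  stopifnot(!is.null(names(rules)))
  ## reject cycles in removable -> proxy
  for (r in names(rules)) {
    seen <- r; p <- unname(rules[r])
    while (!is.na(p) && p %in% names(rules)) {
      if (p %in% seen) stop("cycle in dependency rules")
      seen <- c(seen, p); p <- unname(rules[p])
    }
  }
  removed <- names(rules)[names(rules) %in% candidates &
                            unname(rules) %in% candidates]
  final <- setdiff(candidates, removed)
  structure(list(
    pca_selected = pca_selected,
    augmented = augmented,
    removed_by_interdependence = removed,
    final = final,
    extension_features = setdiff(extension_features, final)
  ), class = "selection_result")
}

#' Two-step attribute selection
#'
#' The full selection pipeline: z-score normalisation, PCA, contribution
#' analysis over the leading components, joint Pearson/Spearman
#' correlation mask, link-based augmentation and interdependence pruning.
#' The extension feature list (defaults NW, NSA, FA, SAL — the least
#' correlated geometric attributes) defines the wide feature set
#' `c(final, extension)`.
#'
#' @param table attribute data frame/matrix with named columns
#' @param components leading components for contribution analysis
#' @param weight_floor relative PCA loading floor
#' @param threshold correlation threshold
#' @param min_links augmentation link minimum
#' @param sequential redundancy-aware augmentation (see
#'   [augment_by_links()])
#' @param rules pruning rules
#' @param extension_features extension list
#' @return a `selection_result` with additional fields `pca` and `mask`
#' @export
select_features <- function(table, components = 3, weight_floor = 0.1,
                            threshold = 0.9, min_links = 4,
                            sequential = TRUE,
                            rules = default_dependency_rules(),
                            extension_features = c("NW", "NSA", "FA", "SAL")) {
  z <- normalise_attributes(table)
  pca <- run_pca(z)
  pca_set <- pca_contributors(pca, components, weight_floor)
  mask <- correlation_mask(as.matrix(table), threshold)
  aug <- augment_by_links(mask, pca_set, min_links, sequential = sequential)
  res <- prune_interdependent(
    candidates = union(pca_set, aug), rules = rules,
    pca_selected = pca_set, augmented = aug,
    extension_features = extension_features
  )
  res$pca <- pca
  res$mask <- mask
  res
}

#' Published attribute link structure of the reference clinical cohort
#'
#' The correlation-link pattern (|r| >= 0.9 under Pearson or Spearman)
#' among the attributes not captured by the leading principal components
#' in the reference clinical cohort whose summary statistics drive the
#' synthetic generator defaults. Returned as a symmetric logical matrix
#' over the 39 canonical attributes.
#'
#' The published pattern is a row/column check table; where a pair of
#' attributes is checkable in both directions the link is kept only when
#' both directions agree (reciprocal consensus), which removes
#' transcription asymmetries; links involving attributes that appear only
#' as rows are taken as printed.
#'
#' @return 39 x 39 symmetric logical matrix with canonical dimnames
#' @export
study_link_mask <- function() {
  nm <- attribute_names()
  cols <- c("HP", "S3_N", "MPStress_N", "MPStrain_N", "E1_T", "E3_T",
            "MPStress_T", "MPStrain_T", "FRI_N", "FRI_T")
  ## directed check pattern: row attribute -> column attributes it checks
  checks <- list(
    STW        = "S3_N",
    HP         = c("S3_N", "MPStress_N", "MPStress_T"),
    TBE        = "S3_N",
    CTE        = "S3_N",
    S3_N       = c("HP", "MPStress_N"),
    E1_N       = c("MPStrain_N", "FRI_N"),
    E3_N       = c("MPStrain_N", "FRI_N"),
    MPStress_N = c("HP", "S3_N", "MPStress_T"),
    MPStrain_N = c("MPStrain_T", "FRI_N"),
    SED_N      = c("MPStrain_N", "MPStrain_T", "FRI_N"),
    S3_T       = c("HP", "MPStress_N", "MPStress_T"),
    E1_T       = c("E3_T", "FRI_T"),
    E3_T       = c("E1_T", "FRI_T"),
    MPStress_T = c("HP", "MPStress_N"),
    MPStrain_T = c("E1_T", "E3_T", "FRI_T"),
    SED_T      = c("E1_T", "E3_T", "MPStrain_T", "FRI_T"),
    FRI_N      = "MPStrain_N",
    FRI_T      = c("E1_T", "E3_T", "MPStrain_T")
  )
  dual <- intersect(names(checks), cols)   # checkable in both directions
  m <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (r in names(checks)) {
    for (c in checks[[r]]) {
      if (r %in% dual && c %in% dual) {
        ## reciprocal consensus for pairs checkable both ways
        if (r %in% checks[[c]]) m[r, c] <- m[c, r] <- TRUE
      } else {
        m[r, c] <- m[c, r] <- TRUE
      }
    }
  }
  m
}

#' PCA contributor set of the reference clinical cohort
#'
#' The seven attributes contributing to the three leading principal
#' components (99% of variance) in the reference clinical cohort.
#'
#' @return character vector of seven attribute names
#' @export
study_pca_set <- function() {
  c("TB", "CT", "BMI", "STH", "FPK", "FAT", "FP")
}
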