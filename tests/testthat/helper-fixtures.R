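## Shared fixtures, built lazily and cached for the session.
.fx <- new.env()

## one rendered synthetic subject (record + shape + scan), by seed
fx_subject <- function(seed = 3, group = "fractured") {
  key <- paste0("subj_", group, "_", seed)
  if (is.null(.fx[[key]])) {
    spec <- cohort_spec()
    rec <- sample_clinical(spec, group, 1, seed = seed)
    sh <- NULL
    for (s in seed + 0:40) {
      cand <- sample_shape(spec, group, seed = s)
      if (sidefall:::shape_renderable(cand)) { sh <- cand; break }
    }
    scan <- render_scan(sh, rec, seed = seed, spec = spec)
    .fx[[key]] <- list(record = rec, shape = sh, scan = scan, spec = spec)
  }
  .fx[[key]]
}

## pose-standardised scan + morphometry for the default subject
fx_measured <- function(seed = 3, group = "fractured") {
  key <- paste0("meas_", group, "_", seed)
  if (is.null(.fx[[key]])) {
    s <- fx_subject(seed, group)
    posed <- standardise_pose(s$scan, canonical_orientation = TRUE)
    .fx[[key]] <- list(posed = posed, morph = measure_morphometry(posed),
                       record = s$record, shape = s$shape)
  }
  .fx[[key]]
}

## full single-subject simulation at a light mesh density
fx_sim <- function(seed = 3, group = "fractured", target = 2500) {
  key <- paste0("sim_", group, "_", seed, "_", target)
  if (is.null(.fx[[key]])) {
    s <- fx_subject(seed, group)
    .fx[[key]] <- simulate_subject(
      s$record, s$scan, sim_options(target_elements = target),
      keep_solution = TRUE)
  }
  .fx[[key]]
}

## small clinical-style table for classifier tests: two separable-ish
## groups with a few informative and a few noise columns
fx_class_table <- function(n1 = 89, n2 = 48, gap = 1.5, seed = 42) {
  set.seed(seed)
  g1 <- data.frame(group = "fractured",
                   f1 = rnorm(n1, gap, 1), f2 = rnorm(n1, -gap / 2, 1),
                   f3 = rnorm(n1), f4 = rnorm(n1))
  g2 <- data.frame(group = "control",
                   f1 = rnorm(n2, 0, 1), f2 = rnorm(n2, gap / 2, 1),
                   f3 = rnorm(n2), f4 = rnorm(n2))
  out <- rbind(g1, g2)
  out$subject_id <- sprintf("s%03d", seq_len(nrow(out)))
  out
}

## fabricate an fe_solution-like object with prescribed per-element
## fields on a given mesh (for attribute-reduction unit tests)
fx_fake_solution <- function(mesh, E3 = NULL, VM = NULL, value = NULL) {
  ne <- nrow(mesh$tri)
  elem <- data.frame(
    exx = numeric(ne), eyy = numeric(ne), gxy = numeric(ne),
    sxx = numeric(ne), syy = numeric(ne), sxy = numeric(ne),
    szz = numeric(ne),
    S1 = numeric(ne), S3 = numeric(ne), E1 = numeric(ne),
    E3 = if (is.null(E3)) numeric(ne) else E3,
    MPStress = numeric(ne), MPStrain = numeric(ne),
    VM = if (is.null(VM)) numeric(ne) else VM,
    SED = numeric(ne),
    area = mesh$area, tag = mesh$tag
  )
  if (!is.null(value)) elem$value <- value
  structure(list(u = matrix(0, max(mesh$tri), 2), elem = elem,
                 residual = 0, applied = c(0, 0), mesh = mesh),
            class = "fe_solution")
}

## independent LSR oracle: largest threshold t such that some
## 4-adjacency-connected component of {ratio >= t} reaches the target
## area (breadth-first component search per threshold)
lsr_oracle <- function(mesh, ratio, area_target) {
  fem <- which(mesh$tag == "femur")
  adj <- sidefall:::element_adjacency(mesh, fem)
  nbr <- vector("list", length(fem))
  if (nrow(adj)) for (k in seq_len(nrow(adj))) {
    nbr[[adj[k, 1]]] <- c(nbr[[adj[k, 1]]], adj[k, 2])
    nbr[[adj[k, 2]]] <- c(nbr[[adj[k, 2]]], adj[k, 1])
  }
  areas <- mesh$area[fem]
  best <- -Inf
  for (t in sort(unique(ratio), decreasing = TRUE)) {
    active <- ratio >= t
    seen <- rep(FALSE, length(fem))
    reached <- FALSE
    for (s in which(active)) {
      if (seen[s]) next
      comp <- s; seen[s] <- TRUE; frontier <- s
      while (length(frontier)) {
        nxt <- unique(unlist(nbr[frontier]))
        nxt <- nxt[active[nxt] & !seen[nxt]]
        seen[nxt] <- TRUE
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      if (sum(areas[comp]) >= area_target) { reached <- TRUE; break }
    }
    if (reached) return(t)
  }
  stop("oracle: no region reaches the target area")
}
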