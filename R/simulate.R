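#' Plan of planted directional edge effects
#'
#' Describes a synthetic cohort in Fisher-z edge space: control-group edge
#' means are drawn once per cohort from `Normal(baseline_mean, baseline_sd)`;
#' each subject adds `Normal(0, noise_sd)` noise per edge; patients are
#' shifted by `+delta` on the increased edges and `-delta` on the decreased
#' edges. Defaults (baseline mean 0.3, baseline sd 0.2, noise sd 0.2, all in
#' Fisher-z units) sit in the range typical of resting-state connectivity
#' after r-to-z transformation.
#'
#' @param n_nodes number of atlas nodes (default 60 for a 1,770-edge
#'   test-scale connectome; use 268 for the full-scale parcellation).
#' @param increased_edges,decreased_edges disjoint integer vectors of
#'   0-based edge indices (canonical order) carrying planted effects.
#' @param delta effect magnitude in Fisher-z units (>= 0).
#' @param baseline_mean,baseline_sd distribution of control-group edge means.
#' @param noise_sd subject-level Gaussian noise sd (> 0).
#' @return An object of class `effect_plan`.
#' @export
effect_plan <- function(n_nodes = 60, increased_edges = integer(0),
                        decreased_edges = integer(0), delta = 0.2,
                        baseline_mean = 0.3, baseline_sd = 0.2,
                        noise_sd = 0.2) {
  n_edges <- n_edges_for_nodes(n_nodes)
  increased_edges <- as.integer(increased_edges)
  decreased_edges <- as.integer(decreased_edges)
  if (length(intersect(increased_edges, decreased_edges))) {
    stop("increased and decreased edge sets must be disjoint", call. = FALSE)
  }
  idx <- c(increased_edges, decreased_edges)
  if (length(idx) && (min(idx) < 0 || max(idx) >= n_edges)) {
    stop("planted edge indices must lie in [0, ", n_edges - 1L, "]",
         call. = FALSE)
  }
  stopifnot(delta >= 0, noise_sd > 0, baseline_sd >= 0)
  structure(list(n_nodes = as.integer(n_nodes), n_edges = n_edges,
                 increased_edges = increased_edges,
                 decreased_edges = decreased_edges,
                 delta = delta, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise_sd = noise_sd),
            class = "effect_plan")
}

#' @export
print.effect_plan <- function(x, ...) {
  cat("<effect_plan> ", x$n_nodes, " nodes / ", x$n_edges, " edges; ",
      length(x$increased_edges), " increased + ", length(x$decreased_edges),
      " decreased planted edges, delta ", x$delta, " (noise sd ", x$noise_sd,
      ")\n", sep = "")
  invisible(x)
}

# Draw distinct planted edge sets of the given sizes.
draw_edge_sets <- function(n_edges, sizes) {
  total <- sum(sizes)
  if (total > n_edges) {
    stop("requested ", total, " planted edges but only ", n_edges,
         " edges exist", call. = FALSE)
  }
  picked <- sample.int(n_edges, total) - 1L
  grp <- factor(rep(seq_along(sizes), times = sizes),
                levels = seq_along(sizes))
  split(picked, grp)
}

#' Generate a synthetic case-control cohort
#'
#' Draws a cohort in Fisher-z edge space according to an [effect_plan()]:
#' per-cohort edge baselines, per-subject Gaussian noise, and directional
#' shifts of `+delta` / `-delta` applied to patients on the planted edges.
#' Labels follow the study coding (patient = 1, control = 0). Output is
#' bit-identical for identical seeds.
#'
#' @param plan an [effect_plan()].
#' @param n_controls,n_patients subjects per group (each >= 2).
#' @param seed integer seed.
#' @return A [cohort_dataset()] with controls first, then patients.
#' @export
generate_cohort <- function(plan, n_controls, n_patients, seed) {
  stopifnot(inherits(plan, "effect_plan"))
  if (n_controls < 2L || n_patients < 2L) {
    stop("need at least 2 subjects per group (got ", n_controls, " controls, ",
         n_patients, " patients)", call. = FALSE)
  }
  n <- n_controls + n_patients
  with_seed(seed, {
    baseline <- stats::rnorm(plan$n_edges, plan$baseline_mean, plan$baseline_sd)
    edges <- matrix(stats::rnorm(n * plan$n_edges, sd = plan$noise_sd),
                    nrow = n)
    edges <- sweep(edges, 2L, baseline, `+`)
    if (n_patients > 0 && plan$delta > 0) {
      pat <- (n_controls + 1L):n
      if (length(plan$increased_edges)) {
        edges[pat, plan$increased_edges + 1L] <-
          edges[pat, plan$increased_edges + 1L] + plan$delta
      }
      if (length(plan$decreased_edges)) {
        edges[pat, plan$decreased_edges + 1L] <-
          edges[pat, plan$decreased_edges + 1L] - plan$delta
      }
    }
    labels <- c(rep(0L, n_controls), rep(1L, n_patients))
    ids <- c(sprintf("con%03d", seq_len(n_controls)),
             sprintf("pat%03d", seq_len(n_patients)))
    cohort_dataset(edges, labels, subject_ids = ids, n_nodes = plan$n_nodes)
  })
}

#' Two-site study design
#'
#' Encodes the structure used to emulate multi-site case-control studies in
#' which decreased-connectivity effects are shared across sites while
#' increased-connectivity effects are site-specific: both sites plant the
#' same decreased edge set, while each site's increased edge set is drawn
#' with a controllable overlap fraction (1 = identical, 0 = disjoint). Site
#' baselines are drawn independently (a site effect).
#'
#' @param n_shared_decreased number of decreased edges shared by both sites.
#' @param n_increased_per_site number of increased edges per site.
#' @param overlap fraction of increased edges shared between sites, in
#'   `[0, 1]`.
#' @param n_controls,n_patients length-2 integer vectors of per-site group
#'   sizes.
#' @return An object of class `site_design`.
#' @export
site_design <- function(n_shared_decreased = 30, n_increased_per_site = 30,
                        overlap = 0, n_controls = c(60, 60),
                        n_patients = c(60, 60)) {
  stopifnot(overlap >= 0, overlap <= 1,
            length(n_controls) == 2L, length(n_patients) == 2L,
            n_shared_decreased >= 0, n_increased_per_site >= 0)
  structure(list(n_shared_decreased = as.integer(n_shared_decreased),
                 n_increased_per_site = as.integer(n_increased_per_site),
                 overlap = overlap,
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients)),
            class = "site_design")
}

#' Generate a two-site study with shared and site-specific effects
#'
#' Draws planted edge maps per the [site_design()] -- one decreased set
#' common to both sites, per-site increased sets sharing
#' `round(overlap * n_increased_per_site)` edges -- and generates each
#' site's cohort with an independent baseline (site effect) from the shared
#' [effect_plan()] noise/effect parameters (the plan's own edge sets must be
#' empty; they are drawn here).
#'
#' @param design a [site_design()].
#' @param plan an [effect_plan()] providing `n_nodes`, `delta`, baseline and
#'   noise parameters.
#' @param seed integer seed.
#' @return list with cohorts `site1`, `site2` and `truth` (the planted edge
#'   sets and per-site seeds).
#' @export
generate_two_sites <- function(design, plan, seed) {
  stopifnot(inherits(design, "site_design"), inherits(plan, "effect_plan"))
  if (length(plan$increased_edges) || length(plan$decreased_edges)) {
    stop("the effect_plan passed to generate_two_sites must have empty edge ",
         "sets; planted maps are drawn from the site_design", call. = FALSE)
  }
  n_shared_inc <- as.integer(round(design$overlap * design$n_increased_per_site))
  n_new <- design$n_increased_per_site - n_shared_inc
  with_seed(seed, {
    sets <- draw_edge_sets(plan$n_edges,
                           c(design$n_shared_decreased,
                             n_shared_inc, n_new, n_new))
    decreased <- sets[[1]]
    inc_shared <- sets[[2]]
    inc1 <- c(inc_shared, sets[[3]])
    inc2 <- c(inc_shared, sets[[4]])
    seed1 <- draw_seed()
    seed2 <- draw_seed()
  })
  mk_plan <- function(inc) {
    effect_plan(n_nodes = plan$n_nodes, increased_edges = inc,
                decreased_edges = decreased, delta = plan$delta,
                baseline_mean = plan$baseline_mean,
                baseline_sd = plan$baseline_sd, noise_sd = plan$noise_sd)
  }
  site1 <- generate_cohort(mk_plan(inc1), design$n_controls[1],
                           design$n_patients[1], seed1)
  site2 <- generate_cohort(mk_plan(inc2), design$n_controls[2],
                           design$n_patients[2], seed2)
  list(site1 = site1, site2 = site2,
       truth = list(decreased_edges = sort(decreased),
                    increased_edges_site1 = sort(inc1),
                    increased_edges_site2 = sort(inc2),
                    overlap = design$overlap, delta = plan$delta,
                    seed = as.integer(seed), site_seeds = c(seed1, seed2)))
}

# Repair a candidate correlation matrix to positive definiteness by clipping
# eigenvalues at a small positive floor and renormalising to unit diagonal.
repair_correlation <- function(R, floor = 1e-6, tol = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  R2 <- (R2 + t(R2)) / 2
  if (min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) < floor / 2 - tol) {
    stop("target correlation matrix could not be repaired to positive ",
         "definiteness", call. = FALSE)
  }
  R2
}

#' Generate node time series with planted connectivity structure
#'
#' The slow, end-to-end counterpart of [generate_cohort()]: for each
#' subject, a target Fisher-z edge vector is drawn exactly as in
#' [generate_cohort()] (baseline + subject noise + patient shifts), mapped
#' to correlations by `tanh`, projected to the nearest valid correlation
#' matrix (eigenvalue clipping + renormalisation), and used as the
#' population correlation of a multivariate-normal time series. Running
#' [compute_fc()] on the output recovers the planted group differences as
#' `n_timepoints` grows.
#'
#' @param plan an [effect_plan()].
#' @param n_controls,n_patients subjects per group.
#' @param n_timepoints timepoints per subject (>= 50 recommended).
#' @param seed integer seed.
#' @return list with `panel` (a [timeseries_panel()]) and `labels`.
#' @export
generate_timeseries_cohort <- function(plan, n_controls, n_patients,
                                       n_timepoints = 200, seed) {
  stopifnot(inherits(plan, "effect_plan"), n_timepoints >= 3)
  zcohort <- generate_cohort(plan, n_controls, n_patients, seed)
  n <- length(zcohort$labels)
  with_seed(seed + 1L, {
    data <- vector("list", n)
    for (s in seq_len(n)) {
      R <- tanh(devectorize_edges(zcohort$edges[s, ], plan$n_nodes))
      diag(R) <- 1
      R <- repair_correlation(R)
      L <- chol(R)
      x <- matrix(stats::rnorm(n_timepoints * plan$n_nodes), n_timepoints)
      data[[s]] <- t(x %*% L)  # rows = nodes, columns = timepoints
    }
    list(panel = timeseries_panel(data, zcohort$subject_ids),
         labels = zcohort$labels)
  })
}
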