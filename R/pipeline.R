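clinical_vars <- c("sex", "age", "living_alone", "education", "nihss",
                   "mrs", "moca", "dep_self", "anx_self", "epices")

#' Assemble per-subject feature blocks for every model tier
#'
#' Runs the imaging, disconnectome and topology stages over a cohort:
#' radiological flags against the macro atlas, lesion loads against each
#' probabilistic atlas, the parcel-wise disconnectome edge vector,
#' module-wise mean disconnections (within and between each module pair,
#' over edges present in the normative graph), and the topology metric
#' vector of the spared graph.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param con A [connectome()] with streamlines.
#' @param atlases Named list of [atlas()] objects (names become tier names);
#'   may be empty.
#' @param macro_atlas An [atlas()] of kind `"macro-radiological"`; built
#'   from the config when omitted.
#' @param index Optional precomputed [index_streamlines()].
#' @param topology_on `"spared"` (default) computes graph metrics on
#'   `W * (1 - D)`; `"disconnectome"` computes them on `D` itself.
#' @return A list of feature blocks: `clinical`, `radiological`, one block
#'   per atlas, `dense_edge` (plus `edge_index`), `module_wise`, `topology`,
#'   and the outcome `y`.
#' @export
cohort_features <- function(cohort, con, atlases = list(),
                            macro_atlas = NULL, index = NULL,
                            topology_on = c("spared", "disconnectome")) {
  topology_on <- match.arg(topology_on)
  cfg <- attr(cohort, "cfg")
  n <- nrow(cohort)
  if (is.null(macro_atlas)) macro_atlas <- generate_macro_atlas(cfg)
  if (is.null(index)) index <- index_streamlines(con, cfg)

  blocks <- list(clinical = as.matrix(cohort[, clinical_vars]))

  flags <- matrix(0, n, length(macro_atlas$roi_labels),
                  dimnames = list(NULL, macro_atlas$roi_labels))
  loads <- lapply(atlases, function(a) {
    matrix(0, n, length(a$roi_labels), dimnames = list(NULL, a$roi_labels))
  })

  W <- con$W
  nz <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  dense <- matrix(0, n, nrow(nz))
  colnames(dense) <- sprintf("e_%02d_%02d", nz[, 1], nz[, 2])
  mods <- con$parcels$module
  umods <- unique(mods)
  pair_names <- outer(umods, umods, function(a, b) paste(a, b, sep = "|"))
  mod_pairs <- which(upper.tri(pair_names, diag = TRUE), arr.ind = TRUE)
  modwise <- matrix(0, n, nrow(mod_pairs))
  colnames(modwise) <- sprintf("mw_%s_%s", umods[mod_pairs[, 1]],
                               umods[mod_pairs[, 2]])
  topo <- NULL

  for (i in seq_len(n)) {
    lesion <- cohort_lesion(cohort, i)
    lidx <- cohort$lesion_voxels[[i]]
    flags[i, ] <- radiological_flags(lesion, macro_atlas)$flag
    for (a in names(atlases)) {
      loads[[a]][i, ] <- lesion_load(lesion, atlases[[a]])$load
    }
    disc <- disconnectome_from_hits(streamline_hits_idx(index, lidx),
                                    index$edges, W, cohort$subject_id[i])
    dense[i, ] <- disc$D[nz]
    for (r in seq_len(nrow(mod_pairs))) {
      sel_i <- mods[nz[, 1]] == umods[mod_pairs[r, 1]] &
               mods[nz[, 2]] == umods[mod_pairs[r, 2]]
      sel_j <- mods[nz[, 1]] == umods[mod_pairs[r, 2]] &
               mods[nz[, 2]] == umods[mod_pairs[r, 1]]
      sel <- sel_i | sel_j
      modwise[i, r] <- if (any(sel)) {
        mean(disc$D[nz[sel, , drop = FALSE]])
      } else 0
    }
    Wg <- if (topology_on == "spared") W * (1 - disc$D) else disc$D
    tv <- compute_topology(Wg, mods, W_norm = if (topology_on == "spared") W
                                             else disc$D)
    if (is.null(topo)) {
      topo <- matrix(0, n, ncol(tv), dimnames = list(NULL, names(tv)))
    }
    topo[i, ] <- as.numeric(tv[1, ])
  }
  if (topology_on == "disconnectome") {
    # the reference for the betweenness drop is the group-mean graph; with
    # D itself as the graph there is no normative reference, so drop = 0
    topo[, "max_bc_drop"] <- 0
  }
  # characteristic path length can be Inf on fully spared subgraphs with a
  # single finite pair; guard against non-finite features entering fits
  topo[!is.finite(topo)] <- 0

  c(blocks,
    list(radiological = flags),
    loads,
    list(dense_edge = dense, edge_index = nz, module_wise = modwise,
         topology = topo, y = cohort$cesd))
}

default_tiers <- c("clinical", "radiological", "gray_matter", "white_matter",
                   "functional_network", "functional_disconnection",
                   "dense_edge", "module_wise", "topology")

tier_block <- c(clinical = "clinical", radiological = "radiological",
                gray_matter = "gray_matter", white_matter = "white_matter",
                functional_network = "functional_network",
                functional_disconnection = "functional_disconnection",
                dense_edge = "dense_edge", module_wise = "module_wise",
                topology = "topology")

tier_method <- c(clinical = "glm", radiological = "glm",
                 gray_matter = "lasso", white_matter = "lasso",
                 functional_network = "lasso",
                 functional_disconnection = "lasso",
                 dense_edge = "lasso", module_wise = "lasso",
                 topology = "lasso")

# lesion load can only add risk, so atlas/disconnection tiers are sign
# constrained; topology metrics may cut either way
tier_nonneg <- c(clinical = FALSE, radiological = FALSE,
                 gray_matter = TRUE, white_matter = TRUE,
                 functional_network = TRUE, functional_disconnection = TRUE,
                 dense_edge = TRUE, module_wise = TRUE, topology = FALSE)

#' Run the full synthetic model-comparison pipeline
#'
#' Generates (or loads via config) the synthetic study, assembles all
#' feature blocks, fits every requested tier (GLM for clinical and
#' radiological; non-negative LASSO for atlas and disconnection tiers;
#' sign-free LASSO for topology) with in-sample and cross-validated
#' out-of-sample R-squared, compares the tiers by AIC, runs the NBS edge
#' screen, and combines cross-validated tier predictions into the
#' hierarchical stack. Fully reproducible from config + seed.
#'
#' @param config `NULL` for defaults, a named list of [synth_config()]
#'   arguments, or the path to a YAML file of them. May also carry `cv`
#'   (list with `n_repetitions`, `n_folds`), `nbs` (list with `threshold`,
#'   `n_perm`, `statistic`) and `tiers`.
#' @param seed Integer seed; overrides the config seed.
#' @param tiers Character vector of tiers to run (subset of
#'   `c("clinical", "radiological", "gray_matter", "white_matter",
#'   "functional_network", "functional_disconnection", "dense_edge",
#'   "module_wise", "topology")`).
#' @param cv A [cv_scheme()] for out-of-sample evaluation and stacking.
#' @param nbs_threshold,nbs_perm Primary threshold and permutation count of
#'   the NBS screen (`NULL` threshold uses a per-edge p = 0.001 F quantile).
#' @param run_nbs Set `FALSE` to skip the NBS stage.
#' @param outdir Optional directory; writes the comparison table (CSV +
#'   Markdown), tier predictions, NBS components and stack trace.
#' @return A `psd_report` list: `config`, `connectome`, `cohort`, `fits`,
#'   `comparison`, `nbs`, `correlations`, `stack`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, tiers = default_tiers,
                         cv = NULL, nbs_threshold = NULL, nbs_perm = 1000,
                         run_nbs = TRUE, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  tiers <- match.arg(tiers, default_tiers, several.ok = TRUE)
  if (!is.null(config$tiers)) tiers <- intersect(config$tiers, default_tiers)
  cv_cfg <- config$cv %||% list()
  if (is.null(cv)) {
    cv <- cv_scheme(cv_cfg$n_repetitions %||% 10, cv_cfg$n_folds %||% 10,
                    seed = 1L)
  }
  nbs_cfg <- config$nbs %||% list()
  cfg_args <- config[intersect(names(config),
                               names(formals(synth_config)))]
  cfg <- do.call(synth_config, cfg_args)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cv$seed <- derive_seed(cfg$seed, 5)

  con <- generate_connectome(cfg)
  index <- index_streamlines(con, cfg)
  cohort <- generate_cohort(cfg, con, index)

  atlas_kinds <- c(gray_matter = "gray-matter", white_matter = "white-matter",
                   functional_network = "functional-network",
                   functional_disconnection = "functional-disconnection")
  needed <- intersect(names(atlas_kinds), tiers)
  atlases <- lapply(atlas_kinds[needed], function(k) {
    generate_atlas(cfg, con, kind = k)
  })
  names(atlases) <- needed

  feats <- cohort_features(cohort, con, atlases, index = index)
  y <- feats$y

  fits <- list()
  preds <- list()
  for (tier in tiers) {
    x <- feats[[tier_block[[tier]]]]
    method <- tier_method[[tier]]
    fit <- if (method == "glm") {
      fit_glm(x, y, name = tier)
    } else {
      fit_lasso(x, y, nonnegative = tier_nonneg[[tier]], cv = cv, name = tier)
    }
    cvres <- cv_fit(x, y, cv, method = method,
                    nonnegative = tier_nonneg[[tier]])
    fit$r2_out <- cvres$r2_out
    fits[[tier]] <- fit
    preds[[tier]] <- cvres$prediction
  }
  comparison <- compare_models(fits)

  nbs <- NULL
  if (run_nbs && "dense_edge" %in% names(feats)) {
    thr <- nbs_cfg$threshold %||% nbs_threshold %||%
      f_threshold_p(0.001, length(y))
    nbs <- nbs_test(feats$dense_edge, y, feats$edge_index, threshold = thr,
                    n_perm = nbs_cfg$n_perm %||% nbs_perm,
                    seed = derive_seed(cfg$seed, 6),
                    statistic = nbs_cfg$statistic %||% "extent")
  }

  pm <- do.call(cbind, preds)
  colnames(pm) <- names(preds)
  rho <- if (ncol(pm) >= 2) prediction_correlations(pm) else NULL
  stack <- hierarchical_stack(pm, y, cv = cv)
  stack$fit$r2_out <- stack$r2_out

  report <- structure(list(config = cfg, connectome = con, cohort = cohort,
                           fits = fits, comparison = comparison, nbs = nbs,
                           correlations = rho, predictions = pm,
                           stack = stack),
                      class = "psd_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  comp <- as_tibble(report$comparison)
  srow <- glance(report$stack)
  srow$delta_aic <- srow$aic - min(comp$aic)
  srow$p_vs_best <- relative_probability(srow$aic, min(comp$aic))
  srow$p_vs_null <- relative_probability(srow$aic,
                                         attr(report$comparison, "null_aic"))
  full <- dplyr::bind_rows(comp, srow[, intersect(names(srow), c(names(comp)))])
  write_comparison(structure(full, class = class(report$comparison)),
                   file.path(outdir, "comparison"))
  readr::write_csv(as_tibble(as.data.frame(report$predictions)),
                   file.path(outdir, "tier_predictions.csv"))
  if (!is.null(report$nbs)) {
    readr::write_csv(report$nbs$components, file.path(outdir, "nbs_components.csv"))
  }
  readr::write_csv(report$stack$trace, file.path(outdir, "stack_trace.csv"))
  invisible(outdir)
}

#' @export
#' @method print psd_report
print.psd_report <- function(x, ...) {
  cat(sprintf("<psd_report> %d tiers on n = %d subjects\n",
              length(x$fits), nrow(x$cohort)))
  print(as_tibble(x$comparison), n = Inf)
  print(x$stack)
  invisible(x)
}
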