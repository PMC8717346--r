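# End-to-end orchestration: the three analysis families (sex differences,
# elaboration, dimorphism) plus phylogenetic signal, each a function over
# validated inputs, with a manifest that pins every stage parameter and
# seed so a run is reproducible byte-for-byte.

#' Run manifest: stage parameters and the master seed
#'
#' @param seed master seed; all stage/iteration seeds derive from it.
#' @param rf_trees trees for song-level forests (full-scale default 10,000).
#' @param rf_trees_element trees for element-level forests.
#' @param retain MCP retention proportion.
#' @param n_dimorphism_iter balanced-subsampling iterations per population.
#' @param prune_threshold |r| cut for correlated-feature pruning.
#' @param chain chain preset name or [chain_spec()] for all mixed models.
#' @param mds_axes classical-MDS axes for element spaces (first two used).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(seed = 1, rf_trees = 10000, rf_trees_element = rf_trees,
                         retain = 0.95, n_dimorphism_iter = 100,
                         prune_threshold = 0.95, chain = "test",
                         mds_axes = 5) {
  if (is.character(chain)) chain <- chain_preset(chain)
  structure(list(seed = as.integer(seed), rf_trees = as.integer(rf_trees),
                 rf_trees_element = as.integer(rf_trees_element),
                 retain = retain, n_dimorphism_iter = as.integer(n_dimorphism_iter),
                 prune_threshold = prune_threshold, chain = chain,
                 mds_axes = as.integer(mds_axes)),
            class = "run_manifest")
}

# element-level acoustic space -> per-song diversity, for one element set
element_diversity_for <- function(elements, manifest, seed) {
  feats <- as.matrix(as.data.frame(elements)[, feature_names(elements),
                                             drop = FALSE])
  pr <- suppressWarnings(prune_correlated_features(feats,
                                                   manifest$prune_threshold))
  prox <- fit_unsupervised_rf_proximity(
    as.data.frame(pr$reduced),
    rf_params(n_trees = manifest$rf_trees_element, mtry = 5,
              mode = "unsupervised", seed = seed))
  k <- min(manifest$mds_axes, nrow(pr$reduced) - 1)
  emb <- suppressWarnings(classical_mds(proximity_to_distance(prox), k = k))
  element_diversity_scores(emb, elements$song_id, manifest$retain)
}

song_table_with_diversity <- function(elements, manifest, seed) {
  songs <- derive_song_table(elements)
  div <- element_diversity_for(elements, manifest, seed)
  songs$element_diversity <- as.numeric(div[songs$song_id])
  songs
}

# non-intercept fixed-effect rows of a fit, Table-style
model_rows <- function(fit, response) {
  s <- summary(fit)$solutions
  s <- s[s$parameter != "(Intercept)", , drop = FALSE]
  cbind(data.frame(response = response, stringsAsFactors = FALSE), s)
}

#' Species-by-species sex classification plus per-variable mixed models
#'
#' For each species with songs of both sexes: a species-specific
#' element-level acoustic space (unsupervised RF proximity, classical MDS,
#' first two axes) yields species-specific element diversity; the
#' seven-parameter song table is then classified to sex by a supervised
#' random forest, reporting out-of-bag total and per-sex correct
#' classification and impurity variable importance. Afterwards each song
#' parameter is modelled across all species with sex, species and their
#' interaction as fixed effects, individual and population-in-species
#' random intercepts, and a phylogenetically structured species effect.
#'
#' @param elements element_table.
#' @param tree species tree.
#' @param manifest [run_manifest()].
#' @return list: `classification` (species, total/female/male % correct),
#'   `importance`, `models` (per-variable summary rows), `song_table`.
#' @export
run_sex_differences <- function(elements, tree, manifest = run_manifest()) {
  t0 <- stage_log("sex differences: species-specific acoustic spaces")
  species <- unique(elements$species)
  cls <- list(); imp <- list(); tabs <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    el <- elements[elements$species == sp, , drop = FALSE]
    attr(el, "feature_names") <- feature_names(elements)
    class(el) <- class(elements)
    if (length(unique(el$sex)) < 2) {
      warning("species ", sp, " has one sex only; excluded from classification",
              call. = FALSE)
      next
    }
    songs <- song_table_with_diversity(el, manifest,
                                       child_seed(manifest$seed, 20 + i))
    rep <- fit_supervised_rf(
      as.data.frame(songs)[, song_parameters()], songs$sex,
      rf_params(n_trees = manifest$rf_trees, mtry = 3,
                seed = child_seed(manifest$seed, 40 + i)))
    cls[[sp]] <- data.frame(
      species = sp,
      total_pct_correct = 100 * (1 - rep$oob_total_error),
      female_pct_correct = 100 * rep$per_class_correct[["female"]],
      male_pct_correct = 100 * rep$per_class_correct[["male"]],
      stringsAsFactors = FALSE)
    imp[[sp]] <- rep$importance
    tabs[[sp]] <- songs
  }
  classification <- do.call(rbind, cls)
  rownames(classification) <- NULL
  song_table <- do.call(rbind, tabs)
  rownames(song_table) <- NULL
  stage_log("sex differences: classification done", t0)

  t1 <- stage_log("sex differences: per-variable mixed models")
  many_species <- length(unique(song_table$species)) > 1
  fml_rhs <- if (many_species) "sex * species" else "sex"
  models <- lapply(seq_along(song_parameters()), function(j) {
    v <- song_parameters()[j]
    d <- song_table
    d$.resp <- d[[v]]
    fit <- suppressWarnings(phylo_mmm(
      stats::as.formula(paste(".resp ~", fml_rhs)), d,
      random = c("individual_id", if (many_species) "species",
                 "species:population"),
      tree = if (many_species) tree,
      chain = chain_spec(manifest$chain$n_iter, manifest$chain$burn_in,
                         manifest$chain$thin,
                         child_seed(manifest$seed, 60 + j))))
    model_rows(fit, v)
  })
  models <- do.call(rbind, models)
  rownames(models) <- NULL
  stage_log("sex differences: models done", t1)
  list(classification = classification, importance = imp, models = models,
       song_table = song_table)
}

#' Elaboration axes versus life-history covariates
#'
#' Builds the global (all-species) element acoustic space for element
#' diversity, reduces the five elaboration variables by PCA, and for each
#' retained component and each life-history covariate fits a univariate
#' phylogenetic mixed model with covariate, sex and their interaction as
#' fixed effects and individual, species (phylogenetic) and
#' population-in-species random intercepts. Populations missing a covariate
#' drop out of that covariate's model only.
#'
#' @param elements element_table.
#' @param lifehistory lifehistory_table.
#' @param tree species tree.
#' @param manifest [run_manifest()].
#' @param covariates covariate columns to model; default all eight.
#' @param dredge also run all-subsets DIC ranking per component?
#' @return list: `models` (Table-style rows), `pca`, `song_table`
#'   (with PC scores), `dredge` (optional).
#' @export
run_elaboration <- function(elements, lifehistory, tree,
                            manifest = run_manifest(),
                            covariates = intersect(lifehistory_covariates(),
                                                   names(lifehistory)),
                            dredge = FALSE) {
  t0 <- stage_log("elaboration: global element space")
  songs <- song_table_with_diversity(elements, manifest,
                                     child_seed(manifest$seed, 10))
  pca <- fit_pca(songs)
  S <- pc_scores(pca, songs)
  songs <- cbind(songs, S)
  d <- merge(as.data.frame(songs),
             as.data.frame(lifehistory)[, c("population", covariates)],
             by = "population", sort = TRUE)
  stage_log("elaboration: space + PCA done", t0)

  t1 <- stage_log("elaboration: univariate mixed models")
  pcs <- paste0("PC", seq_len(pca$n_components_kept))
  rows <- list(); ridx <- 0
  for (pi in seq_along(pcs)) {
    for (ci in seq_along(covariates)) {
      cv <- covariates[ci]
      dd <- d[!is.na(d[[cv]]), , drop = FALSE]
      dd$.resp <- dd[[pcs[pi]]]
      fit <- suppressWarnings(phylo_mmm(
        stats::as.formula(paste(".resp ~", cv, "* sex")), dd,
        random = c("individual_id", "species", "species:population"),
        tree = tree,
        chain = chain_spec(manifest$chain$n_iter, manifest$chain$burn_in,
                           manifest$chain$thin,
                           child_seed(manifest$seed, 100 + 10 * pi + ci))))
      ridx <- ridx + 1
      rows[[ridx]] <- model_rows(fit, pcs[pi])
    }
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  stage_log("elaboration: models done", t1)

  dr <- NULL
  if (dredge) {
    dr <- lapply(stats::setNames(pcs, pcs), function(pc) {
      dd <- d
      dd$.resp <- dd[[pc]]
      dredge_by_dic(".resp", covariates, dd, base_terms = "sex",
                    random = c("individual_id", "species",
                               "species:population"),
                    tree = tree, chain = manifest$chain, force = TRUE)
    })
  }
  list(models = models, pca = pca, song_table = songs, dredge = dr)
}

#' Song dimorphism metrics versus life-history covariates
#'
#' Builds the all-species song-level acoustic space (unsupervised RF on the
#' seven song parameters, Kruskal NMDS to two axes), computes the three
#' balanced-subsampled dimorphism metrics per population, and models each
#' metric against each covariate with species (phylogenetic) and
#' population-in-species random intercepts.
#'
#' @inheritParams run_elaboration
#' @param song_table optional precomputed song table with element diversity
#'   filled, to avoid rebuilding the element space.
#' @return list: `dimorphism` (per-population metrics), `models`
#'   (Table-style rows), `embedding`, `song_table`.
#' @export
run_dimorphism <- function(elements, lifehistory, tree,
                           manifest = run_manifest(),
                           covariates = intersect(lifehistory_covariates(),
                                                  names(lifehistory)),
                           song_table = NULL) {
  t0 <- stage_log("dimorphism: all-species song space")
  songs <- if (is.null(song_table))
    song_table_with_diversity(elements, manifest, child_seed(manifest$seed, 10))
  else song_table
  prox <- fit_unsupervised_rf_proximity(
    as.data.frame(songs)[, song_parameters()],
    rf_params(n_trees = manifest$rf_trees, mtry = 3, mode = "unsupervised",
              seed = child_seed(manifest$seed, 11)))
  emb <- kruskal_nmds(proximity_to_distance(prox), k = 2,
                      seed = child_seed(manifest$seed, 12))
  stage_log("dimorphism: embedding done", t0)

  t1 <- stage_log("dimorphism: per-population metrics")
  pops <- unique(songs$population)
  rows <- list(); ridx <- 0
  for (i in seq_along(pops)) {
    p <- pops[i]
    idx <- songs$population == p
    sx <- songs$sex[idx]
    if (length(unique(sx)) < 2) {
      warning("population ", p, " lacks a sex; skipped", call. = FALSE)
      next
    }
    pts <- emb$coords[idx, , drop = FALSE]
    if (min(table(sx)) < 3)
      warning("population ", p,
              " has < 3 songs for a sex; metrics are low-confidence",
              call. = FALSE)
    res <- balanced_subsample_dimorphism(
      pts[sx == "male", , drop = FALSE], pts[sx == "female", , drop = FALSE],
      pooled = pts, n_iter = manifest$n_dimorphism_iter,
      seed = child_seed(manifest$seed, 200 + i), retain = manifest$retain)
    ridx <- ridx + 1
    rows[[ridx]] <- data.frame(
      population = p, species = songs$species[idx][1],
      overlap_prop = res$metrics[["overlap_prop"]],
      centroid_distance = res$metrics[["centroid_distance"]],
      area_size_difference = res$metrics[["area_size_difference"]],
      n_male = res$n_male, n_female = res$n_female,
      seed = res$seed, stringsAsFactors = FALSE)
  }
  dim_tab <- do.call(rbind, rows)
  rownames(dim_tab) <- NULL
  stage_log("dimorphism: metrics done", t1)

  t2 <- stage_log("dimorphism: mixed models")
  d <- merge(dim_tab,
             as.data.frame(lifehistory)[, c("population", covariates)],
             by = "population", sort = TRUE)
  metrics <- c("overlap_prop", "centroid_distance", "area_size_difference")
  mrows <- list(); k <- 0
  for (mi in seq_along(metrics)) {
    for (ci in seq_along(covariates)) {
      cv <- covariates[ci]
      dd <- d[!is.na(d[[cv]]), , drop = FALSE]
      dd$.resp <- dd[[metrics[mi]]]
      fit <- suppressWarnings(phylo_mmm(
        stats::as.formula(paste(".resp ~", cv)), dd,
        random = c("species", "species:population"), tree = tree,
        chain = chain_spec(manifest$chain$n_iter, manifest$chain$burn_in,
                           manifest$chain$thin,
                           child_seed(manifest$seed, 300 + 10 * mi + ci))))
      k <- k + 1
      mrows[[k]] <- model_rows(fit, metrics[mi])
    }
  }
  models <- do.call(rbind, mrows)
  rownames(models) <- NULL
  stage_log("dimorphism: models done", t2)
  list(dimorphism = dim_tab, models = models, embedding = emb,
       song_table = songs)
}

#' Phylogenetic signal of the song-level parameters
#'
#' Collapses songs to species means and computes Blomberg's K per
#' parameter.
#'
#' @param elements element_table (or pass a prebuilt `song_table`).
#' @param tree species tree (>= 4 species).
#' @param manifest [run_manifest()].
#' @param song_table optional precomputed song table with diversity filled,
#'   to avoid rebuilding the element space.
#' @return data frame (variable, K, n_species).
#' @export
run_phylosig <- function(elements, tree, manifest = run_manifest(),
                         song_table = NULL) {
  if (is.null(song_table))
    song_table <- song_table_with_diversity(elements, manifest,
                                            child_seed(manifest$seed, 10))
  phylosig_table(song_table, tree)
}

#' Run the full pipeline and write its output tables
#'
#' Sex-difference classification and models, elaboration models,
#' dimorphism metrics and models, and phylogenetic signal, written as TSVs
#' under `out_dir` together with a run-metadata sidecar. Given the same
#' inputs and manifest the output files are byte-identical.
#'
#' @param data list with `elements`, `lifehistory`, `tree` (e.g. from
#'   [simulate_dataset()], or assembled from [read_element_table()],
#'   [read_lifehistory_table()], [read_newick()]).
#' @param manifest [run_manifest()].
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return (invisibly) list of all stage results.
#' @export
run_all <- function(data, manifest = run_manifest(), out_dir = NULL) {
  stopifnot(inherits(data$elements, "element_table"))
  sx <- run_sex_differences(data$elements, data$tree, manifest)
  el <- run_elaboration(data$elements, data$lifehistory, data$tree, manifest)
  dm <- run_dimorphism(data$elements, data$lifehistory, data$tree, manifest,
                       song_table = el$song_table[, !grepl("^PC",
                                                           names(el$song_table))])
  ps <- run_phylosig(data$elements, data$tree, manifest,
                     song_table = el$song_table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(sx$classification, file.path(out_dir, "classification.tsv"))
    write_tsv(sx$models, file.path(out_dir, "sexdiff_models.tsv"))
    write_tsv(el$models, file.path(out_dir, "elaboration_models.tsv"))
    ld <- data.frame(variable = rownames(el$pca$loadings),
                     round(el$pca$loadings, 6))
    write_tsv(ld, file.path(out_dir, "pca_loadings.tsv"))
    write_tsv(dm$dimorphism, file.path(out_dir, "dimorphism.tsv"))
    write_tsv(dm$models, file.path(out_dir, "dimorphism_models.tsv"))
    write_tsv(ps, file.path(out_dir, "phylosig.tsv"))
    write_sidecar(file.path(out_dir, "run_metadata.yml"), list(
      package = "songspace",
      version = as.character(utils::packageVersion("songspace")),
      seed = manifest$seed, rf_trees = manifest$rf_trees,
      rf_trees_element = manifest$rf_trees_element,
      retain = manifest$retain,
      n_dimorphism_iter = manifest$n_dimorphism_iter,
      prune_threshold = manifest$prune_threshold,
      chain = sprintf("%d/%d/%d", manifest$chain$n_iter,
                      manifest$chain$burn_in, manifest$chain$thin)))
  }
  invisible(list(sex_differences = sx, elaboration = el, dimorphism = dm,
                 phylosig = ps))
}
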