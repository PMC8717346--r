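# Hierarchical synthetic-data generator. Emulates the study design the
# pipeline expects — 9 species / 15 populations (one focal species with 5
# populations, two with 2, six with 1), sexed individuals nested in
# populations, songs nested in individuals, elements nested in songs —
# with Brownian-motion species-level trait structure on a simulated tree,
# Gaussian population/individual/song/element perturbations, configurable
# male-female effects, and population-level life-history covariates that
# can modulate the male-minus-female gap (a planted sex-by-covariate
# interaction of known magnitude). No real measurements are imitated; only
# the statistical structure is.

canonical_features <- function(n = 22) {
  base <- c("freq_5", "freq_95", "duration_90", "iqr_duration", "center_time",
            "freq_25", "freq_75", "bandwidth_90", "iqr_bandwidth",
            "peak_freq", "max_peak_freq_contour", "range_peak_freq_contour",
            "num_inflections", "dom_freq_slope", "mean_freq", "sd_freq",
            "median_freq", "skewness", "time_entropy", "entropy",
            "spectral_flatness", "modulation_index")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("feature_%02d", seq_len(n - length(base))))
}

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the emulated study's shape: 9 species over 15
#' populations (5 + 2 + 2 + six singletons), 6 individuals per population
#' (balanced sexes), 3 songs per individual, 4-12 elements per song, 22
#' element-level acoustic features. Effects are on the latent (standardised)
#' trait scale: `feature_sex_effect` shifts male elements per feature;
#' `song_sex_effect` shifts the male log-duration and log-element-count
#' latents (so derived song duration, element number and element rate carry
#' the effect); `lifehistory_slopes` is a named vector giving, per
#' covariate, the slope of the male-minus-female gap on the standardised
#' covariate — applied to the two song-level latents and to the features
#' named in `gap_features` — i.e. a planted sex-by-covariate interaction.
#'
#' @param n_species number of species (>= 4 for tree-based stages).
#' @param populations_per_species integer vector per species.
#' @param individuals_per_population individuals per population (sexes split
#'   by `sex_ratio`).
#' @param songs_per_individual songs recorded per individual.
#' @param elements_per_song length-2 range of elements per song.
#' @param n_features number of element-level acoustic features.
#' @param feature_sex_effect per-feature male shift (recycled).
#' @param song_sex_effect length-2: male shift on (log duration,
#'   log element count).
#' @param gap_features feature names whose sex gap follows
#'   `lifehistory_slopes`.
#' @param dimorphic_species `NULL` (all species dimorphic) or the subset of
#'   species labels whose males receive the sex effects — lets a run plant
#'   dimorphism in some species only.
#' @param sex_ratio proportion of male individuals.
#' @param bm_sigma2 Brownian rate of species-level trait evolution.
#' @param population_sd,individual_sd,song_sd,element_sd hierarchical SDs.
#' @param lifehistory_slopes named numeric (covariate -> gap slope).
#' @param missing_rate fraction of covariate cells blanked (latitude is
#'   always kept finite).
#' @param seed master seed (mandatory); every stage derives child seeds
#'   from it by counter.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 9,
                       populations_per_species = c(5, 2, 2, 1, 1, 1, 1, 1, 1),
                       individuals_per_population = 6,
                       songs_per_individual = 3,
                       elements_per_song = c(4, 12),
                       n_features = 22,
                       feature_sex_effect = c(0.5, 0.5, 0.5,
                                              rep(0, n_features - 3)),
                       song_sex_effect = c(0.3, 0.3),
                       gap_features = canonical_features(n_features)[3:5],
                       dimorphic_species = NULL,
                       sex_ratio = 0.5,
                       bm_sigma2 = 0.25,
                       population_sd = 0.2, individual_sd = 0.2,
                       song_sd = 0.15, element_sd = 1,
                       lifehistory_slopes = c(male_survival = 0),
                       missing_rate = 0.1,
                       seed = 1) {
  stopifnot(n_species >= 2,
            length(populations_per_species) == n_species,
            all(populations_per_species >= 1),
            individuals_per_population >= 2, songs_per_individual >= 1,
            length(elements_per_song) == 2,
            elements_per_song[1] >= 1,
            elements_per_song[1] <= elements_per_song[2],
            n_features >= 4, sex_ratio > 0, sex_ratio < 1,
            bm_sigma2 >= 0, population_sd >= 0, individual_sd >= 0,
            song_sd >= 0, element_sd >= 0,
            missing_rate >= 0, missing_rate < 1,
            is.numeric(seed), length(seed) == 1)
  structure(list(
    n_species = n_species,
    populations_per_species = as.integer(populations_per_species),
    individuals_per_population = as.integer(individuals_per_population),
    songs_per_individual = as.integer(songs_per_individual),
    elements_per_song = as.integer(elements_per_song),
    n_features = as.integer(n_features),
    feature_sex_effect = rep_len(feature_sex_effect, n_features),
    song_sex_effect = rep_len(song_sex_effect, 2),
    gap_features = gap_features, dimorphic_species = dimorphic_species,
    sex_ratio = sex_ratio, bm_sigma2 = bm_sigma2,
    population_sd = population_sd, individual_sd = individual_sd,
    song_sd = song_sd, element_sd = element_sd,
    lifehistory_slopes = lifehistory_slopes,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate an ultrametric pure-birth species tree
#'
#' Yule tree with the root-to-tip depth normalised to 1; tips labelled
#' `species_01`, `species_02`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param seed RNG seed.
#' @return `phylo`.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  stopifnot(n_species >= 2)
  set.seed(child_seed(seed, 0))
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("species_%02d", seq_len(n_species))
  tree
}

# one Brownian draw per latent trait: species means with covariance
# bm_sigma2 * C around the trait roots
sim_species_means <- function(tree, n_traits, bm_sigma2, roots = NULL,
                              seed = 1) {
  C <- phylo_vcv(tree)
  n <- nrow(C)
  if (is.null(roots)) roots <- rep(0, n_traits)
  set.seed(child_seed(seed, 0))
  L <- if (bm_sigma2 > 0) chol(bm_sigma2 * C) else matrix(0, n, n)
  M <- matrix(stats::rnorm(n * n_traits), n, n_traits)
  sweep(t(L) %*% M, 2, roots, "+")  # n_species x n_traits
}

#' Simulate a complete synthetic dataset
#'
#' Produces an element table, a life-history table and (unless supplied)
#' a species tree, with the hierarchical structure described in
#' [sim_config()]. Each element's feature value is
#' species mean (Brownian) + population + individual + song + element noise
#' (+ the male sex effect); element start/end times are laid out so the
#' derived song duration, element number and element rate carry the planted
#' song-level structure. `freq_5`/`freq_95` are mapped to Hz with
#' `freq_95 > freq_5` guaranteed element-wise.
#'
#' @param config [sim_config()].
#' @param tree optional `phylo` with `n_species` tips (simulated from the
#'   config seed when omitted).
#' @return list with `elements` (element_table), `lifehistory`
#'   (lifehistory_table), `tree`, and `truth` (the planted species means,
#'   population covariates and gap slopes, for calibration checks).
#' @export
simulate_dataset <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  if (is.null(tree)) tree <- simulate_tree(cf$n_species, child_seed(cf$seed, 1))
  if (length(tree$tip.label) != cf$n_species)
    stop("tree tip count must equal n_species", call. = FALSE)
  species <- tree$tip.label
  feats <- canonical_features(cf$n_features)

  # populations and their life-history covariates
  n_pops <- sum(cf$populations_per_species)
  pop_species <- rep(species, cf$populations_per_species)
  pops <- sprintf("pop_%02d", seq_len(n_pops))
  set.seed(child_seed(cf$seed, 2))
  lh <- data.frame(
    population = pops, species = pop_species,
    epp = stats::runif(n_pops, 0, 0.7),
    brood_size = stats::runif(n_pops, 1.5, 4),
    breeding_synchrony = stats::runif(n_pops, 0.1, 0.9),
    group_size = stats::runif(n_pops, 2, 6),
    breeding_male_density = stats::runif(n_pops, 0.1, 2),
    male_provisioning = stats::runif(n_pops, 0.2, 0.6),
    male_survival = stats::runif(n_pops, 0.4, 0.9),
    latitude = stats::runif(n_pops, 7, 39),
    stringsAsFactors = FALSE)

  # per-population male-minus-female gap from the planted slopes
  gap <- rep(0, n_pops)
  slopes <- cf$lifehistory_slopes
  for (cv in names(slopes)) {
    if (!cv %in% names(lh)) stop("unknown covariate in slopes: ", cv,
                                 call. = FALSE)
    z <- as.numeric(scale(lh[[cv]]))
    gap <- gap + slopes[[cv]] * z
  }

  # latent traits: the features plus log duration and log element count
  traits <- c(feats, ".log_duration", ".log_elements")
  roots <- c(rep(0, cf$n_features), log(1.5),
             log(mean(cf$elements_per_song)))
  mu_sp <- sim_species_means(tree, length(traits), cf$bm_sigma2, roots,
                             seed = child_seed(cf$seed, 3))
  rownames(mu_sp) <- species; colnames(mu_sp) <- traits

  set.seed(child_seed(cf$seed, 4))
  pop_eff <- matrix(stats::rnorm(n_pops * length(traits), 0, cf$population_sd),
                    n_pops, length(traits), dimnames = list(pops, traits))

  n_male <- round(cf$individuals_per_population * cf$sex_ratio)
  n_male <- max(1L, min(cf$individuals_per_population - 1L, n_male))
  is_gap_feat <- feats %in% cf$gap_features

  rows <- vector("list", 5000); nr <- 0
  set.seed(child_seed(cf$seed, 5))
  song_counter <- 0
  for (pi in seq_len(n_pops)) {
    pop <- pops[pi]; sp <- pop_species[pi]
    for (ii in seq_len(cf$individuals_per_population)) {
      sex <- if (ii <= n_male) "male" else "female"
      ind_id <- sprintf("%s_ind%02d", pop, ii)
      ind_eff <- stats::rnorm(length(traits), 0, cf$individual_sd)
      male <- as.numeric(sex == "male")
      if (!is.null(cf$dimorphic_species) && !(sp %in% cf$dimorphic_species))
        male <- 0
      # male shift per latent trait in this population
      shift <- c(cf$feature_sex_effect + is_gap_feat * gap[pi],
                 cf$song_sex_effect + gap[pi]) * male
      base <- mu_sp[sp, ] + pop_eff[pi, ] + ind_eff + shift
      for (si in seq_len(cf$songs_per_individual)) {
        song_counter <- song_counter + 1
        song_id <- sprintf("song_%05d", song_counter)
        song_eff <- stats::rnorm(length(traits), 0, cf$song_sd)
        lat <- base + song_eff
        T_dur <- exp(lat[".log_duration"])
        m <- round(exp(lat[".log_elements"]))
        m <- max(cf$elements_per_song[1], min(cf$elements_per_song[2], m))
        # element layout: ~60% voiced, gaps fill the rest
        wd <- stats::runif(m, 0.5, 1)
        wg <- if (m > 1) stats::runif(m - 1, 0.5, 1) else numeric(0)
        el_d <- wd / sum(wd) * 0.6 * T_dur
        gp <- if (m > 1) wg / sum(wg) * 0.4 * T_dur else numeric(0)
        starts <- cumsum(c(0, el_d[-m] + gp))
        ends <- starts + el_d
        F <- matrix(stats::rnorm(m * cf$n_features, 0, cf$element_sd),
                    m, cf$n_features)
        F <- sweep(F, 2, lat[seq_len(cf$n_features)], "+")
        colnames(F) <- feats
        # map frequency latents to Hz with freq_95 > freq_5 element-wise
        f5 <- 4000 + 300 * F[, "freq_5"]
        F[, "freq_95"] <- f5 + 800 * exp(0.4 * F[, "freq_95"])
        F[, "freq_5"] <- f5
        nr <- nr + 1
        rows[[nr]] <- data.frame(
          song_id = song_id, individual_id = ind_id, population = pop,
          species = sp, sex = sex, start_time = starts, end_time = ends,
          F, check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  elements <- as_element_table(do.call(rbind, rows[seq_len(nr)]))

  if (cf$missing_rate > 0) {
    set.seed(child_seed(cf$seed, 6))
    blankable <- setdiff(lifehistory_covariates(), "latitude")
    for (cv in blankable) {
      blank <- stats::runif(n_pops) < cf$missing_rate
      lh[[cv]][blank] <- NA_real_
    }
  }
  lh <- structure(lh, class = c("lifehistory_table", "data.frame"))

  list(elements = elements, lifehistory = lh, tree = tree,
       truth = list(species_means = mu_sp, gap = gap, slopes = slopes,
                    config = cf))
}

#' Simulate a dataset with every sex effect and gap slope set to zero
#'
#' The type-I calibration input: identical structure to
#' [simulate_dataset()] but no male-female difference anywhere.
#'
#' @param config [sim_config()].
#' @param tree optional tree, as in [simulate_dataset()].
#' @export
simulate_null_dataset <- function(config, tree = NULL) {
  config$feature_sex_effect[] <- 0
  config$song_sex_effect[] <- 0
  config$lifehistory_slopes[] <- 0
  simulate_dataset(config, tree)
}
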