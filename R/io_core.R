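# An element table holds one row per song element (a single continuous
# spectrogram trace separated from its neighbours by a break in time), with
# identifiers song_id/individual_id/population/species/sex, the element's
# start_time/end_time in seconds, and named acoustic measurement columns
# (frequencies in Hz, durations in s).

ID_COLS <- c("song_id", "individual_id", "population", "species", "sex")
TIME_COLS <- c("start_time", "end_time")
RAVEN_META <- c("Selection", "View", "Channel")

normalize_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- ifelse(s %in% c("male", "m"), "male",
                ifelse(s %in% c("female", "f"), "female", NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("invalid sex value(s): ", paste(sQuote(bad), collapse = ", "),
         " (expected male/female)", call. = FALSE)
  }
  out
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr(",", header))) >
      lengths(regmatches(header, gregexpr("\t", header)))) "," else "\t"
}

#' Read an element-level acoustic measurement table
#'
#' Reads delimited text (tab default, comma autodetected) with one row per
#' song element. The `raven_selection` dialect accepts a Raven selection
#' table: tab-separated with `"Begin Time (s)"`/`"End Time (s)"` columns
#' (mapped to `start_time`/`end_time`) and `Selection`/`View`/`Channel`
#' bookkeeping columns (dropped). All non-identifier numeric columns are
#' treated as acoustic features. Missing values in the slope of the peak
#' frequency contour (`dom_freq_slope`) are set to 0 — elements too short to
#' estimate a slope show no appreciable frequency modulation; missing values
#' in any other feature are an error.
#'
#' @param path file path.
#' @param dialect `"plain"` or `"raven_selection"`.
#' @return an `element_table`: a data.frame sorted by (song_id, start_time)
#'   with attribute `feature_names`.
#' @export
read_element_table <- function(path, dialect = c("plain", "raven_selection")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  sep <- if (dialect == "raven_selection") "\t" else detect_sep(path)
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (dialect == "raven_selection") {
    map <- c("Begin Time (s)" = "start_time", "End Time (s)" = "end_time")
    for (rc in names(map)) {
      if (!rc %in% names(df))
        stop("missing mandatory column: ", sQuote(rc), call. = FALSE)
      names(df)[names(df) == rc] <- map[[rc]]
    }
    df <- df[, setdiff(names(df), RAVEN_META), drop = FALSE]
  }
  as_element_table(df)
}

#' Validate a data frame as an element table
#'
#' @param df data frame with the identifier, time and feature columns.
#' @return validated, sorted `element_table`.
#' @export
as_element_table <- function(df) {
  need <- c(ID_COLS, TIME_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column: ", paste(sQuote(miss), collapse = ", "),
         call. = FALSE)
  df$sex <- normalize_sex(df$sex)
  for (cn in TIME_COLS) df[[cn]] <- as.numeric(df[[cn]])
  bad <- which(!(df$end_time > df$start_time))
  if (length(bad))
    stop("element end_time <= start_time at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)

  feat <- setdiff(names(df), need)
  for (cn in feat) df[[cn]] <- as.numeric(df[[cn]])
  if ("dom_freq_slope" %in% feat && anyNA(df$dom_freq_slope)) {
    n0 <- sum(is.na(df$dom_freq_slope))
    df$dom_freq_slope[is.na(df$dom_freq_slope)] <- 0
    message("dom_freq_slope: ", n0, " missing value(s) set to 0")
  }
  for (cn in feat) {
    if (anyNA(df[[cn]]) || any(!is.finite(df[[cn]])))
      stop("non-finite values in feature ", sQuote(cn), call. = FALSE)
  }

  # every song maps to exactly one (individual, population, species, sex)
  key <- unique(df[, ID_COLS])
  if (anyDuplicated(key$song_id))
    stop("song_id maps to more than one individual/population/species/sex: ",
         paste(unique(key$song_id[duplicated(key$song_id)]), collapse = ", "),
         call. = FALSE)

  df <- df[order(df$song_id, df$start_time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, feature_names = feat,
            class = c("element_table", "data.frame"))
}

#' Write an element table as tab-separated text
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_element_table(write_element_table(x))` round-trips exactly.
#'
#' @param x element_table.
#' @param path output path.
#' @export
write_element_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Feature column names of an element table
#' @param x element_table.
#' @export
feature_names <- function(x) attr(x, "feature_names")

#' Derive the song-level parameter table from an element table
#'
#' Per song: `song_duration` = max(end_time) - min(start_time);
#' `element_number` = element count; `element_rate` = number / duration;
#' song `freq_5` = min over elements of the element-level `freq_5`;
#' song `freq_95` = max over elements of the element-level `freq_95`;
#' `freq_range` = `freq_95 - freq_5` (the range between top and bottom
#' frequency among all of the song's elements). `element_diversity` is left
#' `NA` until filled from an element-level acoustic space (see
#' [element_diversity_scores()]).
#'
#' @param elements element_table whose features include `freq_5` and `freq_95`.
#' @return a `song_table` data.frame, one row per song.
#' @export
derive_song_table <- function(elements) {
  stopifnot(inherits(elements, "element_table"))
  feat <- feature_names(elements)
  if (!all(c("freq_5", "freq_95") %in% feat))
    stop("element features must include freq_5 and freq_95", call. = FALSE)
  sp <- split(seq_len(nrow(elements)), elements$song_id)
  rows <- lapply(sp, function(idx) {
    e <- elements[idx, ]
    dur <- max(e$end_time) - min(e$start_time)
    if (dur <= 0)
      stop("song ", sQuote(e$song_id[1]),
           " has non-positive duration (all elements at one instant)",
           call. = FALSE)
    data.frame(song_id = e$song_id[1], individual_id = e$individual_id[1],
               population = e$population[1], species = e$species[1],
               sex = e$sex[1],
               song_duration = dur, element_number = nrow(e),
               element_rate = nrow(e) / dur,
               freq_5 = min(e$freq_5), freq_95 = max(e$freq_95),
               freq_range = max(e$freq_95) - min(e$freq_5),
               element_diversity = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("song_table", "data.frame"))
}

#' The seven song-level acoustic parameters
#' @export
song_parameters <- function() {
  c("song_duration", "element_number", "element_rate",
    "freq_5", "freq_95", "freq_range", "element_diversity")
}

#' Drop highly correlated feature columns
#'
#' Greedy, deterministic pruning: zero-variance columns are dropped first
#' (their correlation is undefined), then column pairs are scanned in input
#' order and the *later* column of any pair with Pearson |r| at or above the
#' threshold is dropped. Applying the function to its own output changes
#' nothing.
#'
#' @param x numeric matrix or data frame with named columns (>= 3 rows).
#' @param threshold absolute correlation cut, in (0, 1]; default 0.95.
#' @return list with `reduced` (matrix), `dropped`, `kept`.
#' @export
prune_correlated_features <- function(x, threshold = 0.95) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3, threshold > 0, threshold <= 1)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0 | !is.finite(v)]
  if (length(dropped))
    warning("zero-variance column(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  keep <- setdiff(colnames(x), dropped)
  r <- abs(stats::cor(x[, keep, drop = FALSE]))
  alive <- rep(TRUE, length(keep))
  for (i in seq_along(keep)) {
    if (!alive[i]) next
    for (j in seq_along(keep)) {
      if (j <= i || !alive[j]) next
      if (r[i, j] >= threshold) alive[j] <- FALSE
    }
  }
  kept <- keep[alive]
  dropped <- c(dropped, keep[!alive])
  list(reduced = x[, kept, drop = FALSE], dropped = dropped, kept = kept)
}

#' Read a population-level life-history table
#'
#' Delimited text (comma autodetected) with one row per population: columns
#' `population`, `species` and numeric life-history covariates
#' (extra-pair paternity, brood size, breeding synchrony, group size,
#' breeding-male density, male provisioning proportion, male survival,
#' latitude). Any covariate cell may be missing.
#'
#' @param path file path.
#' @return data frame of class `lifehistory_table`.
#' @export
read_lifehistory_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = detect_sep(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("population", "species"), names(df))
  if (length(miss))
    stop("missing mandatory column: ", paste(sQuote(miss), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$population))
    stop("life-history table must have one row per population", call. = FALSE)
  structure(df, class = c("lifehistory_table", "data.frame"))
}

#' The life-history covariates used as predictors
#' @export
lifehistory_covariates <- function() {
  c("epp", "brood_size", "group_size", "male_provisioning", "male_survival",
    "breeding_synchrony", "latitude", "breeding_male_density")
}

#' Report collinear life-history covariates
#'
#' Pearson correlations over pairwise-complete observations; pairs with
#' |r| above the threshold are *reported*, not dropped — excluding
#' collinear predictors is an analyst decision. Covariates with fewer than 3
#' non-missing values (or no variance) are flagged `insufficient data` and
#' excluded from the pairing.
#'
#' @param lh lifehistory_table (>= 3 populations).
#' @param threshold absolute correlation to report above; default 0.7.
#' @return data frame (var1, var2, r); attribute `flagged` lists covariates
#'   excluded for insufficient data.
#' @export
check_collinearity <- function(lh, threshold = 0.7) {
  stopifnot(nrow(lh) >= 3)
  covs <- intersect(lifehistory_covariates(), names(lh))
  x <- as.matrix(as.data.frame(lh)[, covs, drop = FALSE])
  n_ok <- colSums(!is.na(x))
  vr <- apply(x, 2, function(v) stats::var(v, na.rm = TRUE))
  flagged <- covs[n_ok < 3 | !is.finite(vr) | vr == 0]
  use <- setdiff(covs, flagged)
  out <- data.frame(var1 = character(), var2 = character(), r = numeric())
  if (length(use) >= 2) {
    r <- stats::cor(x[, use, drop = FALSE], use = "pairwise.complete.obs")
    idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      out <- data.frame(var1 = use[idx[, 1]], var2 = use[idx[, 2]],
                        r = r[idx], stringsAsFactors = FALSE)
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Read a calibrated species tree in Newick format
#'
#' Parses with \pkg{ape}, requires branch lengths, and checks ultrametricity
#' to a relative tolerance of 1e-6 on root-to-tip depths (reported via the
#' `ultrametric` attribute, and a warning when it fails). Zero-length
#' terminal branches draw a warning.
#'
#' @param path Newick file.
#' @return an \pkg{ape} `phylo` object with attribute `ultrametric`.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal branch(es) present", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  ultra <- diff(range(depths)) <= 1e-6 * max(depths)
  if (!ultra) warning("tree is not ultrametric (relative tol 1e-6)",
                      call. = FALSE)
  attr(tree, "ultrametric") <- ultra
  tree
}
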