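# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry/code paths: the hull is a Graham scan written here,
# the area a separate shoelace sum.

oracle_shoelace <- function(v) {
  if (nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1)
  abs(sum(x * y[j]) - sum(x[j] * y)) / 2
}

oracle_graham_hull <- function(pts) {
  pts <- pts[!duplicated(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) return(pts)
  i0 <- order(pts[, 2], pts[, 1])[1]
  p0 <- pts[i0, ]
  rest <- pts[-i0, , drop = FALSE]
  ang <- atan2(rest[, 2] - p0[2], rest[, 1] - p0[1])
  dd <- (rest[, 1] - p0[1])^2 + (rest[, 2] - p0[2])^2
  sorted <- rest[order(ang, dd), , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  st <- list(p0, sorted[1, ])
  for (i in 2:nrow(sorted)) {
    p <- sorted[i, ]
    while (length(st) >= 2 &&
           cross(st[[length(st) - 1]], st[[length(st)]], p) <= 0)
      st[[length(st)]] <- NULL
    st[[length(st) + 1]] <- p
  }
  do.call(rbind, st)
}

# same retention definition as mcp() (it is part of the contract), but hull
# and area computed independently
oracle_mcp_area <- function(pts, retain) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  kept <- pts[order(d)[seq_len(ceiling(retain * n))], , drop = FALSE]
  oracle_shoelace(oracle_graham_hull(kept))
}

# RMS after optimal rigid alignment (translation + rotation/reflection)
procrustes_rms <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(t(Yc) %*% Xc)
  Q <- s$u %*% t(s$v)
  sqrt(mean(rowSums((Xc - Yc %*% Q)^2)))
}

# hierarchical Gaussian mixed-model data with a sex-by-covariate
# interaction: n songs from n_ind individuals in n_pop populations
sim_mm_data <- function(seed, n = 600, n_ind = 100, n_pop = 15,
                        beta = c(intercept = 1, sex = 0.5, cov = 0.3,
                                 interaction = 0.8),
                        sd_ind = sqrt(0.5), sd_pop = sqrt(0.3), sd_e = 1) {
  set.seed(seed)
  ind <- sample(n_ind, n, replace = TRUE)
  pop_of_ind <- sample(n_pop, n_ind, replace = TRUE)
  pop <- pop_of_ind[ind]
  sexm <- as.numeric(ind %% 2 == 0)
  cov_pop <- rnorm(n_pop)
  u_i <- rnorm(n_ind, 0, sd_ind)
  u_p <- rnorm(n_pop, 0, sd_pop)
  y <- beta[["intercept"]] + beta[["sex"]] * sexm +
    beta[["cov"]] * cov_pop[pop] + beta[["interaction"]] * sexm * cov_pop[pop] +
    u_i[ind] + u_p[pop] + rnorm(n, 0, sd_e)
  data.frame(y = y, sex = factor(ifelse(sexm == 1, "male", "female"),
                                 levels = c("female", "male")),
             cov = cov_pop[pop],
             individual_id = sprintf("i%03d", ind),
             population = sprintf("p%02d", pop),
             stringsAsFactors = FALSE)
}

# small hand-written element table (2 songs, 2 individuals)
tiny_element_df <- function() {
  data.frame(
    song_id = c("s1", "s1", "s1", "s2", "s2"),
    individual_id = c("i1", "i1", "i1", "i2", "i2"),
    population = "popA", species = "spA",
    sex = c("male", "male", "male", "female", "female"),
    start_time = c(0.0, 0.5, 1.0, 0.0, 0.3),
    end_time = c(0.3, 0.8, 1.5, 0.2, 0.6),
    freq_5 = c(1000, 1200, 1100, 900, 950),
    freq_95 = c(5000, 4000, 4500, 3800, 4200),
    dom_freq_slope = c(0.1, -0.2, 0.3, 0.0, 0.2),
    entropy = c(0.5, 0.6, 0.4, 0.7, 0.65),
    stringsAsFactors = FALSE)
}

write_tmp_table <- function(df, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}
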