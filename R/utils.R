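#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages (or resampling iterations) get child seeds by counter so any stage
#' can be regenerated in isolation. Kept strictly below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param n non-negative integer counter.
#' @return an integer seed.
#' @export
child_seed <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(n), length(n) == 1L, n >= 0)
  as.integer((abs(master) + 1000003 * n) %% .Machine$integer.max)
}

#' Standardize covariates and mean-impute missing values as zero
#'
#' Each column is centred and scaled to unit SD using its non-missing values;
#' missing cells are then set to 0, i.e. the (scaled) mean. This is the
#' convention used before all-subsets DIC model ranking so models with
#' different covariates share one row set.
#'
#' @param x data frame or matrix of numeric covariates.
#' @return numeric matrix, attributes `center` and `scale` attached.
#' @export
scale_impute <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  ctr <- apply(x, 2, function(v) mean(v, na.rm = TRUE))
  scl <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE))
  scl[!is.finite(scl) | scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  z[is.na(z)] <- 0
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

# deterministic TSV writer used by the pipeline (fixed formatting => a run is
# byte-reproducible given its seed)
write_tsv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 10, format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# YAML-like run-metadata sidecar
write_sidecar <- function(path, fields) {
  lines <- c("# run metadata",
             vapply(names(fields), function(k) {
               paste0(k, ": ", paste(format(fields[[k]]), collapse = ", "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# stage logging to stderr with timing
stage_log <- function(msg, t0 = NULL) {
  if (!is.null(t0)) {
    msg <- sprintf("%s [%.1fs]", msg, as.numeric(proc.time()[3] - t0))
  }
  message("[songspace] ", msg)
  invisible(proc.time()[3])
}
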