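#' APEX proximity-proteomics deconvolution and time-course statistics
#'
#' The receptor-APEX stage answers two questions from protein-intensity
#' matrices: *where* the receptor is (spatial deconvolution of receptor
#' samples against plasma-membrane / early-endosome / lysosome reference
#' profiles, using location-specific indicator proteins) and *which*
#' proteins change proximity over the stimulation time course (per-protein
#' polynomial fit with an F-test against the intercept-only model,
#' gated on |log2 fold change| and p-value).
#'
#' @name apex
NULL

#' Nonnegative location-coefficient deconvolution
#'
#' Solves `min || y - X b ||^2` with `b >= 0` (Lawson-Hanson NNLS via
#' [pracma::lsqnonneg()]), where `y` holds a receptor sample's indicator-
#' protein intensities and the columns of `X` are the spatial reference
#' profiles restricted to the same indicator proteins. Receptor fractions
#' at a location cannot be negative, hence the nonnegativity default;
#' unconstrained least squares is available behind `nonneg = FALSE`.
#'
#' @param y numeric vector, receptor-sample intensities over indicator
#'   proteins
#' @param X numeric matrix (indicator proteins x locations) of reference
#'   profiles; must have full column rank
#' @param nonneg constrain coefficients to be nonnegative
#' @param normalize also report coefficients rescaled to sum to 1
#' @return list with `beta` (named by location), `beta_norm` (sum-1
#'   version, NULL if the sum is 0 or `normalize` is FALSE) and
#'   `residual_norm`
#' @export
compute_location_coefficients <- function(y, X, nonneg = TRUE,
                                          normalize = TRUE) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("reference profiles are rank-deficient; collinear location(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  if (nonneg) {
    sol <- pracma::lsqnonneg(X, as.numeric(y))
    beta <- sol$x
  } else {
    beta <- qr.coef(qrX, as.numeric(y))
  }
  names(beta) <- colnames(X)
  rn <- sqrt(sum((y - X %*% beta)^2))
  bn <- NULL
  if (normalize) {
    s <- sum(beta)
    if (s > 0) bn <- beta / s
  }
  list(beta = beta, beta_norm = bn, residual_norm = rn)
}

#' Mean reference profiles over indicator proteins
#'
#' Builds the `X` matrix for [compute_location_coefficients()] from a
#' long-format intensity table: one column per location, one row per
#' indicator protein (union over locations), entries averaged over
#' reference replicates.
#'
#' @param df long intensity table with columns `protein_id`,
#'   `sample_type` (`"receptor"` or `"reference:<location>"`),
#'   `location_or_time`, `replicate`, `intensity`
#' @param indicator_map named list: location -> indicator protein ids;
#'   sets must be disjoint
#' @return list with `X` (matrix) and `proteins` (row order)
#' @export
apex_reference_profiles <- function(df, indicator_map) {
  if (anyDuplicated(unlist(indicator_map))) {
    stop("indicator proteins must be disjoint across locations", call. = FALSE)
  }
  locs <- names(indicator_map)
  prots <- unlist(indicator_map, use.names = FALSE)
  X <- sapply(locs, function(l) {
    sub <- df[df$sample_type == paste0("reference:", l), , drop = FALSE]
    vapply(prots, function(p) {
      v <- sub$intensity[sub$protein_id == p]
      if (!length(v)) stop("indicator '", p, "' absent from reference '",
                           l, "'", call. = FALSE)
      mean(v)
    }, numeric(1))
  })
  rownames(X) <- prots
  list(X = X, proteins = prots)
}

#' Deconvolve every receptor sample of a time course
#'
#' @param df long intensity table (see [apex_reference_profiles()])
#' @param indicator_map named list: location -> indicator protein ids
#' @param ... passed to [compute_location_coefficients()]
#' @return data frame with `time`, `replicate`, one coefficient column per
#'   location (sum-normalized), and `residual_norm`
#' @export
deconvolve_timecourse <- function(df, indicator_map, ...) {
  ref <- apex_reference_profiles(df, indicator_map)
  rec <- df[df$sample_type == "receptor", , drop = FALSE]
  keys <- unique(rec[, c("location_or_time", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- rec[rec$location_or_time == keys$location_or_time[k] &
                 rec$replicate == keys$replicate[k], , drop = FALSE]
    y <- vapply(ref$proteins, function(p) {
      v <- sub$intensity[sub$protein_id == p]
      if (!length(v)) stop("indicator '", p, "' absent from receptor sample",
                           call. = FALSE)
      mean(v)
    }, numeric(1))
    cc <- compute_location_coefficients(y, ref$X, ...)
    b <- if (!is.null(cc$beta_norm)) cc$beta_norm else cc$beta
    data.frame(time = as.numeric(keys$location_or_time[k]),
               replicate = keys$replicate[k], t(b),
               residual_norm = cc$residual_norm, check.names = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$time, res$replicate), , drop = FALSE]
}

#' Vectorized polynomial time-course F-tests
#'
#' For each row of `Y` (a protein's log2 intensities over samples), fits
#' an ordinary least-squares polynomial in time of degree `degree` and
#' tests it against the intercept-only model: F with (d, N - d - 1)
#' degrees of freedom. Proteins with zero residual variance under the full
#' model are flagged and reported at the machine floor rather than p = 0.
#'
#' @param Y numeric matrix, proteins x samples, log2 intensities
#' @param time numeric vector of sample times (length `ncol(Y)`)
#' @param degree polynomial degree (default 2)
#' @return data frame with `F`, `p`, `zero_residual` per row of `Y`
#' @export
timecourse_ftest <- function(Y, time, degree = 2L) {
  Y <- as.matrix(Y)
  stopifnot(length(time) == ncol(Y))
  if (length(unique(time)) < degree + 2L) {
    stop("need at least degree + 2 distinct time points", call. = FALSE)
  }
  N <- ncol(Y); d <- degree
  X <- stats::poly(time, degree = d, raw = TRUE)
  X <- cbind(1, X)
  qrX <- qr(X)
  resid_full <- t(qr.resid(qrX, t(Y)))
  rss1 <- rowSums(resid_full^2)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  df2 <- N - d - 1L
  Fstat <- ((rss0 - rss1) / d) / (rss1 / df2)
  zero <- rss1 <= 1e-12 * pmax(rss0, .Machine$double.eps)
  p <- stats::pf(Fstat, d, df2, lower.tail = FALSE)
  p[zero] <- .Machine$double.xmin
  Fstat[zero] <- Inf
  # a flat series has rss0 == rss1 == 0: no change, not a significant one
  flat <- rss0 <= 1e-12
  Fstat[flat] <- 0; p[flat] <- 1; zero[flat] <- FALSE
  data.frame(F = Fstat, p = p, zero_residual = zero,
             row.names = rownames(Y))
}

#' Single-protein polynomial time-course fit
#'
#' Convenience wrapper around [timecourse_ftest()] that also returns the
#' fitted curve.
#'
#' @param log2_intensity numeric vector of log2 intensities
#' @param time numeric vector of times (same length; replicates share a
#'   time value)
#' @param degree polynomial degree
#' @return list with `F`, `p`, `zero_residual`, `fitted`
#' @export
fit_timecourse <- function(log2_intensity, time, degree = 2L) {
  res <- timecourse_ftest(matrix(log2_intensity, nrow = 1L), time, degree)
  X <- cbind(1, stats::poly(time, degree = degree, raw = TRUE))
  fitted <- as.numeric(X %*% qr.coef(qr(X), log2_intensity))
  list(F = res$F[1], p = res$p[1], zero_residual = res$zero_residual[1],
       fitted = fitted)
}

#' Per-time log2 fold changes against the baseline time point
#'
#' Ratios are formed per replicate (intensity at time t over the same
#' replicate's baseline intensity) and the log2 ratios averaged across
#' replicates.
#'
#' @param intensity numeric vector of linear-scale intensities
#' @param time numeric vector of time points (same length)
#' @param replicate replicate id per entry
#' @param baseline_time baseline time point (default 0)
#' @return data frame with `time` and `log2fc` (baseline row included,
#'   log2fc 0)
#' @export
log2fc <- function(intensity, time, replicate, baseline_time = 0) {
  stopifnot(length(intensity) == length(time),
            length(time) == length(replicate))
  reps <- unique(replicate)
  base <- vapply(reps, function(r) {
    v <- intensity[replicate == r & time == baseline_time]
    if (!length(v)) stop("replicate '", r, "' lacks the baseline time point",
                         call. = FALSE)
    mean(v)
  }, numeric(1))
  if (any(base <= 0)) stop("zero or negative baseline intensity", call. = FALSE)
  names(base) <- as.character(reps)
  times <- sort(unique(time))
  lfc <- vapply(times, function(tt) {
    per_rep <- vapply(reps, function(r) {
      v <- intensity[replicate == r & time == tt]
      if (!length(v)) return(NA_real_)
      log2(mean(v) / base[[as.character(r)]])
    }, numeric(1))
    mean(per_rep, na.rm = TRUE)
  }, numeric(1))
  data.frame(time = times, log2fc = lfc)
}

#' Call proximity-network hits
#'
#' A protein is a hit iff `max |log2FC| > lfc_threshold` AND
#' `p < p_threshold`, both strict; no multiple-testing correction is
#' applied (the gate is a joint effect-size/p-value criterion).
#'
#' @param stats data frame with columns `protein_id`, `lfc_max`, `p` (and
#'   optionally `F`)
#' @param lfc_threshold log2 fold-change gate (default 0.58, ~1.5-fold)
#' @param p_threshold p-value gate (default 0.001)
#' @return `stats` with a logical `hit` column appended
#' @export
call_hits <- function(stats, lfc_threshold = 0.58, p_threshold = 0.001) {
  stopifnot(all(c("protein_id", "lfc_max", "p") %in% names(stats)))
  stats$hit <- abs(stats$lfc_max) > lfc_threshold & stats$p < p_threshold
  stats
}

#' Log2 transform with a pseudo-count
#'
#' Adds half the smallest positive value of `x` before the log2, the
#' preprocessing applied to intensity matrices ahead of the time-course
#' statistics.
#'
#' @param x nonnegative numeric
#' @param pseudo optional explicit pseudo-count
#' @export
apex_log2 <- function(x, pseudo = NULL) {
  if (is.null(pseudo)) {
    pos <- x[x > 0]
    if (!length(pos)) stop("no positive intensities", call. = FALSE)
    pseudo <- min(pos) / 2
  }
  log2(x + pseudo)
}

#' Full APEX stage: deconvolution, time-course statistics, hit calling
#'
#' Runs the complete receptor-APEX analysis from a long intensity table:
#' location coefficients for each (time, replicate) receptor sample,
#' per-protein polynomial F-tests on log2 intensities over the time
#' course, per-time log2 fold changes versus the pre-stimulation baseline,
#' and the joint threshold hit call.
#'
#' Location-indicator proteins are excluded from the hit table by default:
#' their labeling follows receptor trafficking between compartments --
#' that signal is exactly what the deconvolution consumes -- so flagging
#' them as interaction-network changes would double-count the location
#' shift as a proximity change.
#'
#' @param df long intensity table (see [apex_reference_profiles()])
#' @param indicator_map named list: location -> indicator protein ids
#' @param degree polynomial degree for the time-course fit
#' @param lfc_threshold,p_threshold hit-calling gates
#' @param baseline_time baseline time point for fold changes
#' @param exclude_indicators drop indicator proteins from the hit table
#' @return list with `coefficients` (deconvolution table), `hits`
#'   (HitTable data frame: `protein_id`, `lfc_max`, `F`, `p`, `hit`) and
#'   `log2fc` (long per-protein, per-time table)
#' @export
apex_pipeline <- function(df, indicator_map, degree = 2L,
                          lfc_threshold = 0.58, p_threshold = 0.001,
                          baseline_time = 0, exclude_indicators = TRUE) {
  coefs <- deconvolve_timecourse(df, indicator_map)
  rec <- df[df$sample_type == "receptor", , drop = FALSE]
  rec$time <- as.numeric(rec$location_or_time)
  prots <- sort(unique(rec$protein_id))
  if (exclude_indicators) prots <- setdiff(prots, unlist(indicator_map))

  # intensity matrix keyed by (time, replicate) column order
  keys <- unique(rec[, c("time", "replicate")])
  keys <- keys[order(keys$time, keys$replicate), , drop = FALSE]
  M <- matrix(NA_real_, nrow = length(prots), ncol = nrow(keys),
              dimnames = list(prots, NULL))
  for (k in seq_len(nrow(keys))) {
    sub <- rec[rec$time == keys$time[k] & rec$replicate == keys$replicate[k], ]
    sub <- sub[sub$protein_id %in% prots, , drop = FALSE]
    M[sub$protein_id, k] <- sub$intensity
  }
  if (anyNA(M)) stop("incomplete intensity matrix: missing (protein, sample) cells",
                     call. = FALSE)
  ft <- timecourse_ftest(apex_log2(M), keys$time, degree)

  lfc_tabs <- lapply(prots, function(p) {
    idx <- match(p, prots)
    l2 <- log2fc(M[idx, ], keys$time, keys$replicate, baseline_time)
    cbind(protein_id = p, l2)
  })
  lfc_long <- do.call(rbind, lfc_tabs)
  lfc_max <- vapply(lfc_tabs, function(t2) max(abs(t2$log2fc)), numeric(1))

  stats_tab <- data.frame(protein_id = prots, lfc_max = lfc_max,
                          F = ft$F, p = ft$p, stringsAsFactors = FALSE)
  hits <- call_hits(stats_tab, lfc_threshold, p_threshold)
  list(coefficients = coefs, hits = hits, log2fc = lfc_long)
}
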