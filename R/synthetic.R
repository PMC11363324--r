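#' Synthetic-data generators with known ground truth
#'
#' Every input the pipeline consumes can be generated here with a designed
#' truth: structural frames whose water-bridge topology is built
#' geometrically, 4PL concentration-response data, APEX time-course
#' intensity matrices with location-indicator block structure and a small
#' set of truly changing proteins, and graded %MPE antinociception data.
#' All generators take explicit integer seeds and restore the caller's
#' RNG state, so regenerating with the same seed is byte-identical and no
#' global random state leaks.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# ---- frame generator --------------------------------------------------------

#' Specification for synthetic bridge frames
#'
#' @param labels character vector of designed per-frame classes, each in
#'   `direct`, `water1`, `water2`, `none`; its length sets `n_frames`
#' @param jitter_sd Gaussian coordinate jitter SD (Angstrom)
#' @param seed integer seed
#' @param replicate_id replicate identifier carried through to outputs
#' @export
frame_spec <- function(labels, jitter_sd = 0, seed = 1L, replicate_id = "rep1") {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("need at least one frame", call. = FALSE)
  bad <- setdiff(unique(labels), BRIDGE_CLASSES)
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  structure(list(labels = labels, n_frames = length(labels),
                 jitter_sd = jitter_sd, seed = as.integer(seed),
                 replicate_id = replicate_id), class = "frame_spec")
}

# Base geometry in a local axis system: carboxylate OD1 at the origin, the
# engagement path extending along +x. Distances on the path are 2.7-2.8 A
# (inside the 2.5-3 A window observed for these bonds); off-path decoy
# waters sit > 4.5 A from every path atom.
bridge_template <- function(label) {
  asp <- rbind(OD1 = c(0, 0, 0), OD2 = c(-1.1, 1.91, 0), CG = c(-0.55, 0.95, 0))
  lig <- switch(label,
    direct = c(2.7, 0, 0),
    water1 = c(5.6, 0, 0),
    water2 = c(8.4, 0, 0),
    none   = c(5.6, 0, 0))
  path_waters <- switch(label,
    direct = rbind(c(1.35, 2.453, 0)),       # a valid one-water path too:
    water1 = rbind(c(2.8, 0, 0)),            # direct must still win
    water2 = rbind(c(2.8, 0, 0), c(5.6, 0, 0)),
    none   = NULL)
  # every frame carries exactly 4 waters (multi-model PDB requires a
  # constant atom table): off-path decoys > 4.5 A from all path atoms
  decoy_pool <- rbind(c(0, -6, 3), c(6, 6, -4), c(-5, -5, -5), c(8, -6, 5))
  n_decoy <- 4L - NROW(path_waters)
  waters <- rbind(path_waters, decoy_pool[seq_len(n_decoy), , drop = FALSE])
  list(asp = asp, lig = lig, waters = waters)
}

frame_from_template <- function(tmpl, frame_id, jitter_sd) {
  jit <- function(m) m + matrix(stats::rnorm(length(m), sd = jitter_sd),
                                ncol = 3L)
  asp <- jit(tmpl$asp)
  lig <- jit(matrix(tmpl$lig, ncol = 3L))
  wat <- jit(tmpl$waters)
  n_w <- nrow(wat)
  atoms <- data.frame(
    frame = frame_id,
    eleno = seq_len(3L + 1L + n_w),
    elety = c("OD1", "OD2", "CG", "O1", rep("O", n_w)),
    resname = c(rep("ASP", 3L), "LIG", rep("HOH", n_w)),
    chain = c(rep("A", 3L), "B", rep("W", n_w)),
    resno = c(rep(114L, 3L), 900L, 1000L + seq_len(n_w)),
    element = c("O", "O", "C", "O", rep("O", n_w)),
    x = c(asp[, 1], lig[, 1], wat[, 1]),
    y = c(asp[, 2], lig[, 2], wat[, 2]),
    z = c(asp[, 3], lig[, 3], wat[, 3]),
    stringsAsFactors = FALSE)
  atoms
}

#' Generate structural frames with designed bridge topology
#'
#' Builds each frame in a local axis system (carboxylate at the origin)
#' realizing its designed class, applies Gaussian coordinate jitter, and
#' verifies with [classify_frame()] that the jittered geometry still
#' realizes the designed class -- re-sampling the jitter (not clamping)
#' when it would flip the class, so truth labels stay valid by
#' construction. Direct frames deliberately also contain a valid one-water
#' path, exercising the classifier's exclusion hierarchy.
#'
#' @param spec a [frame_spec()]
#' @param roles roles config used for the verification pass
#' @param window hydrogen-bond window used for verification
#' @param max_tries re-sampling attempts per frame before failing
#' @return list with `frames` (frame-set data frame), `truth` (data frame
#'   `frame`, `label`, `replicate`), and `spec`
#' @export
gen_bridge_frames <- function(spec, roles = default_roles(lig_resname = "LIG"),
                              window = c(2.2, 3.0), max_tries = 200L) {
  stopifnot(inherits(spec, "frame_spec"))
  with_seed(spec$seed, {
    frames <- vector("list", spec$n_frames)
    for (k in seq_len(spec$n_frames)) {
      lab <- spec$labels[k]
      tmpl <- bridge_template(lab)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        fr <- frame_from_template(tmpl, k, spec$jitter_sd)
        if (classify_frame(fr, roles, window)$label == lab) { ok <- TRUE; break }
      }
      if (!ok) stop("impossible geometry request: jitter_sd ", spec$jitter_sd,
                    " cannot realize class '", lab, "' (frame ", k, ")",
                    call. = FALSE)
      frames[[k]] <- fr
    }
    list(frames = do.call(rbind, frames),
         truth = data.frame(frame = seq_len(spec$n_frames),
                            label = spec$labels,
                            replicate = spec$replicate_id,
                            stringsAsFactors = FALSE),
         spec = spec)
  })
}

# ---- concentration-response generator ---------------------------------------

#' Generating truth for a 4PL concentration-response experiment
#'
#' @param pec50_true -log10 molar EC50
#' @param emax_true maximal response, percent of the reference maximum
#' @param hill Hill slope
#' @param baseline response at zero concentration (percent)
#' @param noise_sd additive Gaussian noise SD (percent)
#' @param n_conc number of log-spaced concentrations (>= 4)
#' @param n_reps replicates per concentration (>= 1)
#' @param conc_range molar range spanned by the concentration series
#'   (default 0.1 nM to 100 uM)
#' @param seed integer seed
#' @export
curve_truth <- function(pec50_true, emax_true, hill = 1, baseline = 0,
                        noise_sd = 5, n_conc = 8L, n_reps = 4L,
                        conc_range = c(1e-10, 1e-4), seed = 1L) {
  if (n_conc < 4L) stop("n_conc must be >= 4", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (emax_true < baseline) stop("emax_true must be >= baseline", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(pec50_true = pec50_true, emax_true = emax_true, hill = hill,
                 baseline = baseline, noise_sd = noise_sd,
                 n_conc = as.integer(n_conc), n_reps = as.integer(n_reps),
                 conc_range = conc_range, seed = as.integer(seed)),
            class = "curve_truth")
}

#' Generate a 4PL concentration-response dataset
#'
#' Responses follow the closed-form 4PL at log-spaced concentrations with
#' additive Gaussian noise; with `noise_sd = 0` they lie exactly on the
#' curve.
#'
#' @param truth a [curve_truth()]
#' @return data frame `conc_M`, `response_pct`, `replicate`, with the
#'   truth attached as attribute `"truth"`
#' @export
gen_dose_response <- function(truth) {
  stopifnot(inherits(truth, "curve_truth"))
  conc <- 10^seq(log10(truth$conc_range[1]), log10(truth$conc_range[2]),
                 length.out = truth$n_conc)
  with_seed(truth$seed, {
    grid <- expand.grid(conc_M = conc, replicate = seq_len(truth$n_reps))
    mu <- fourpl(grid$conc_M, truth$emax_true, truth$pec50_true,
                 truth$hill, truth$baseline)
    grid$response_pct <- mu + stats::rnorm(nrow(grid), sd = truth$noise_sd)
    attr(grid, "truth") <- truth
    grid[, c("conc_M", "response_pct", "replicate")]
  })
}

# ---- APEX time-course generator ---------------------------------------------

#' Generating truth for an APEX time-course intensity matrix
#'
#' Default conditions: 500 proteins, three subcellular locations (plasma
#' membrane, early endosome, lysosome) with 8 indicator proteins each, a
#' 0/1/5/10/20/30-minute course with 3 biological replicates, and a
#' receptor mixing series that moves from the plasma membrane into
#' endosomes over the course -- the internalization behaviour the
#' deconvolution is meant to resolve. Changing proteins rise to a
#' sustained peak log2 fold change of 1.0 by 10 minutes.
#'
#' @param n_proteins total proteins
#' @param changing_ids ids of truly changing proteins (subset of the
#'   protein set `P0001...`)
#' @param effect_profile log2 fold change per time point for changing
#'   proteins (length = number of time points, first entry 0)
#' @param null_sd SD of mean-zero log2 deviations of null proteins
#' @param indicator_map named list location -> indicator ids; `NULL`
#'   builds the default disjoint 8-per-location map
#' @param mixing_series matrix time points x locations, rows nonnegative
#'   summing to 1; `NULL` uses the default internalization series
#' @param time_points minutes
#' @param n_reps biological replicates
#' @param ref_noise_sd log2 noise SD of reference replicate measurements
#' @param seed integer seed
#' @export
apex_truth <- function(n_proteins = 500L, changing_ids = c("P0001", "P0002", "P0003"),
                       effect_profile = c(0, 0.25, 0.75, 1.0, 1.0, 0.8),
                       null_sd = 0.15, indicator_map = NULL,
                       mixing_series = NULL,
                       time_points = c(0, 1, 5, 10, 20, 30), n_reps = 3L,
                       ref_noise_sd = 0.1, seed = 1L) {
  prots <- sprintf("P%04d", seq_len(n_proteins))
  if (is.null(indicator_map)) {
    # indicators drawn from the top of the id range, away from the
    # default changing ids
    pool <- utils::tail(prots, 24L)
    indicator_map <- list(plasma_membrane = pool[1:8],
                          early_endosome = pool[9:16],
                          lysosome = pool[17:24])
  }
  if (is.null(mixing_series)) {
    mixing_series <- rbind(c(1.0, 0.0, 0.0),
                           c(0.8, 0.2, 0.0),
                           c(0.5, 0.4, 0.1),
                           c(0.3, 0.5, 0.2),
                           c(0.25, 0.5, 0.25),
                           c(0.2, 0.5, 0.3))
    colnames(mixing_series) <- c("plasma_membrane", "early_endosome",
                                 "lysosome")
  }
  mixing_series <- as.matrix(mixing_series)
  if (is.null(colnames(mixing_series))) {
    colnames(mixing_series) <- names(indicator_map)
  }
  if (anyDuplicated(unlist(indicator_map))) {
    stop("indicator proteins must be disjoint across locations", call. = FALSE)
  }
  if (!all(unlist(indicator_map) %in% prots)) {
    stop("indicator ids outside the protein set", call. = FALSE)
  }
  if (!all(changing_ids %in% prots)) {
    stop("changing_ids outside the protein set", call. = FALSE)
  }
  if (any(mixing_series < 0) ||
      any(abs(rowSums(mixing_series) - 1) > 1e-12)) {
    stop("each mixing vector must be nonnegative and sum to 1", call. = FALSE)
  }
  if (nrow(mixing_series) != length(time_points)) {
    stop("mixing_series needs one row per time point", call. = FALSE)
  }
  if (length(effect_profile) != length(time_points)) {
    stop("effect_profile needs one entry per time point", call. = FALSE)
  }
  structure(list(proteins = prots, changing_ids = changing_ids,
                 effect_profile = effect_profile, null_sd = null_sd,
                 indicator_map = indicator_map,
                 mixing_series = mixing_series, time_points = time_points,
                 n_reps = as.integer(n_reps), ref_noise_sd = ref_noise_sd,
                 seed = as.integer(seed)), class = "apex_truth")
}

#' Generate an APEX time-course intensity table
#'
#' Reference samples express one location's profile each (indicator
#' proteins strongly enriched in their own location); receptor samples are
#' linear mixtures of the location profiles per `mixing_series`. Changing
#' proteins follow `effect_profile` on the log2 scale; null proteins get
#' mean-zero log2 deviations with SD `null_sd`. With all noise at 0, a
#' receptor sample's indicator intensities are an exact nonnegative
#' combination of the reference profiles.
#'
#' @param truth an [apex_truth()]
#' @return list with `data` (long table: `protein_id`, `sample_type`,
#'   `location_or_time`, `replicate`, `intensity`) and `truth`
#' @export
gen_apex_timecourse <- function(truth) {
  stopifnot(inherits(truth, "apex_truth"))
  with_seed(truth$seed, {
    prots <- truth$proteins
    locs <- names(truth$indicator_map)
    n_p <- length(prots)
    base_l2 <- stats::runif(n_p, 18, 24)          # baseline log2 abundance
    names(base_l2) <- prots
    # linear-scale profile per location: indicators 32-fold enriched in
    # their own location, background elsewhere
    profile <- sapply(locs, function(l) {
      v <- 2^base_l2
      ind <- truth$indicator_map[[l]]
      other <- setdiff(unlist(truth$indicator_map), ind)
      v[ind] <- v[ind] * 32
      v[other] <- v[other] / 8
      v
    })
    rownames(profile) <- prots

    rows <- list()
    for (l in locs) {
      for (r in seq_len(truth$n_reps)) {
        noise <- if (truth$ref_noise_sd > 0) {
          stats::rnorm(n_p, sd = truth$ref_noise_sd)
        } else 0
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = prots, sample_type = paste0("reference:", l),
          location_or_time = l, replicate = r,
          intensity = profile[, l] * 2^noise, stringsAsFactors = FALSE)
      }
    }
    chg <- prots %in% truth$changing_ids
    for (ti in seq_along(truth$time_points)) {
      mix <- as.numeric(profile %*% truth$mixing_series[ti, locs])
      for (r in seq_len(truth$n_reps)) {
        dev <- numeric(n_p)
        if (truth$null_sd > 0) dev[!chg] <- stats::rnorm(sum(!chg),
                                                         sd = truth$null_sd)
        dev[chg] <- truth$effect_profile[ti] +
          if (truth$null_sd > 0) stats::rnorm(sum(chg), sd = truth$null_sd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = prots, sample_type = "receptor",
          location_or_time = as.character(truth$time_points[ti]),
          replicate = r, intensity = mix * 2^dev, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    list(data = out, truth = truth)
  })
}

# ---- %MPE dose-response generator -------------------------------------------

#' Generating truth for a graded %MPE antinociception experiment
#'
#' @param ed50_true dose (mg/kg) producing 50 %MPE
#' @param slope log-logistic slope
#' @param doses strictly increasing positive doses, mg/kg
#' @param n_subjects subjects per dose
#' @param noise_sd subject-level Gaussian noise SD, %MPE units
#' @param seed integer seed
#' @export
mpe_truth <- function(ed50_true, slope = 2, doses = c(3, 10, 30),
                      n_subjects = 8L, noise_sd = 10, seed = 1L) {
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly positive and increasing", call. = FALSE)
  }
  if (ed50_true <= 0) stop("ed50_true must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(ed50_true = ed50_true, slope = slope, doses = doses,
                 n_subjects = as.integer(n_subjects), noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "mpe_truth")
}

#' Generate graded %MPE antinociception data
#'
#' Mean %MPE per dose follows the bounded two-parameter log-logistic
#' `100 / (1 + (ed50/dose)^slope)` (floor 0, ceiling 100: %MPE is bounded
#' by definition); subject-level Gaussian noise is added and the result
#' clamped to [0, 100].
#'
#' @param truth an [mpe_truth()]
#' @return data frame `dose_mg_kg`, `subject`, `mpe_pct`, truth attached
#'   as attribute `"truth"`
#' @export
gen_mpe_doses <- function(truth) {
  stopifnot(inherits(truth, "mpe_truth"))
  with_seed(truth$seed, {
    grid <- expand.grid(subject = seq_len(truth$n_subjects),
                        dose_mg_kg = truth$doses)
    mu <- 100 / (1 + (truth$ed50_true / grid$dose_mg_kg)^truth$slope)
    v <- mu + stats::rnorm(nrow(grid), sd = truth$noise_sd)
    grid$mpe_pct <- pmin(100, pmax(0, v))
    out <- grid[, c("dose_mg_kg", "subject", "mpe_pct")]
    attr(out, "truth") <- truth
    out
  })
}
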