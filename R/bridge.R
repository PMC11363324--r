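#' Water-bridge classification of ligand-carboxylate engagement
#'
#' Each frame is assigned exactly one label describing how the ligand
#' hydroxyl oxygen engages the sodium-site carboxylate: `direct` (a
#' hydrogen bond straight to a carboxylate oxygen), `water1` (bridged by a
#' single water, excluding frames that also contain a direct contact),
#' `water2` (bridged by two consecutive distinct waters, excluding frames
#' with a direct or one-water engagement), or `none`. Paths through three
#' or more waters are not classified. This exclusion hierarchy makes the
#' four per-replicate class fractions sum to exactly 1.
#'
#' @name water_bridge
NULL

#' The four engagement classes, in exclusion-hierarchy order
#' @export
BRIDGE_CLASSES <- c("direct", "water1", "water2", "none")

in_window <- function(d, window) d >= window[1] & d <= window[2]

#' Classify one frame's ligand-carboxylate engagement
#'
#' Builds the hydrogen-bond graph over the ligand hydroxyl O, all water O
#' and the two carboxylate O (edges = heavy-atom distances inside
#' `window`), then applies the exclusion hierarchy: direct beats one-water
#' beats two-water beats none. Either carboxylate oxygen is an equivalent
#' endpoint. When several qualifying paths of the winning order exist, the
#' one with the smallest total length is reported, so the output does not
#' depend on atom ordering.
#'
#' @param frame single-frame atom table
#' @param roles roles list (see [default_roles()]); `ligand_hydroxyl`,
#'   `carboxylate` and `water` must resolve
#' @param window hydrogen-bond heavy-atom distance window (Angstrom)
#' @return list with `label` (one of direct/water1/water2/none) and
#'   `path` (atom serials from ligand O to carboxylate O; `NA` for none)
#' @export
classify_frame <- function(frame, roles = default_roles(),
                           window = c(2.2, 3.0)) {
  lig <- select_role(frame, roles$ligand_hydroxyl, "ligand_hydroxyl")
  if (nrow(lig) != 1L) stop("role 'ligand_hydroxyl' must resolve to one atom",
                            call. = FALSE)
  carb <- select_role(frame, roles$carboxylate, "carboxylate")
  wat <- select_role(frame, roles$water, "water", required = FALSE)

  lp <- as.numeric(lig[1, c("x", "y", "z")])
  cp <- xyz_mat(carb)
  wp <- xyz_mat(wat)
  nw <- nrow(wat)

  d_lc <- sqrt(colSums((t(cp) - lp)^2))                 # ligand -> carboxylate
  if (any(in_window(d_lc, window))) {
    j <- which(in_window(d_lc, window))
    j <- j[which.min(d_lc[j])]
    return(list(label = "direct", path = c(lig$eleno, carb$eleno[j])))
  }
  if (nw > 0L) {
    d_lw <- sqrt(colSums((t(wp) - lp)^2))               # ligand -> waters
    d_wc <- outer(rowSums(wp^2), rowSums(cp^2), "+") -
      2 * wp %*% t(cp)                                  # waters x carboxylate
    d_wc[d_wc < 0] <- 0
    d_wc <- sqrt(d_wc)
    ok1 <- outer(in_window(d_lw, window), rep(TRUE, nrow(carb))) &
      in_window(d_wc, window)
    if (any(ok1)) {
      idx <- which(ok1, arr.ind = TRUE)
      tot <- d_lw[idx[, 1]] + d_wc[ok1]
      best <- idx[which.min(tot), ]
      return(list(label = "water1",
                  path = c(lig$eleno, wat$eleno[best[1]], carb$eleno[best[2]])))
    }
    if (nw > 1L) {
      d_ww <- as.matrix(stats::dist(wp))
      best_tot <- Inf; best_path <- NULL
      w1s <- which(in_window(d_lw, window))
      for (w1 in w1s) {
        w2s <- which(in_window(d_ww[w1, ], window))
        w2s <- setdiff(w2s, w1)
        for (w2 in w2s) {
          cs <- which(in_window(d_wc[w2, ], window))
          if (!length(cs)) next
          c2 <- cs[which.min(d_wc[w2, cs])]
          tot <- d_lw[w1] + d_ww[w1, w2] + d_wc[w2, c2]
          if (tot < best_tot) {
            best_tot <- tot
            best_path <- c(lig$eleno, wat$eleno[w1], wat$eleno[w2],
                           carb$eleno[c2])
          }
        }
      }
      if (!is.null(best_path)) return(list(label = "water2", path = best_path))
    }
  }
  list(label = "none", path = NA_integer_)
}

#' Classify every frame of a frame set
#'
#' @param frames frame-set data frame
#' @param roles,window passed to [classify_frame()]
#' @return data frame with `frame`, `label`, `path` (dash-joined serials)
#' @export
classify_frames <- function(frames, roles = default_roles(),
                            window = c(2.2, 3.0)) {
  per <- split_frames(frames)
  res <- lapply(per, function(fr) {
    cl <- classify_frame(fr, roles, window)
    data.frame(frame = fr$frame[1], label = cl$label,
               path = paste(cl$path, collapse = "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-replicate class frequencies with mean and SEM
#'
#' Computes, for each replicate, the fraction of frames in each of the
#' four engagement classes, then the across-replicate mean and standard
#' error of the mean (sample SD / sqrt(R), matching SEM bars drawn over
#' per-replicate points).
#'
#' @param labels character vector of per-frame class labels
#' @param replicate replicate identifier per frame (same length)
#' @return list with `per_replicate` (replicate x class fraction table as
#'   a data frame) and `summary` (class, mean, sem)
#' @export
bridge_frequencies <- function(labels, replicate) {
  stopifnot(length(labels) == length(replicate))
  bad <- setdiff(unique(labels), BRIDGE_CLASSES)
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  reps <- unique(replicate)
  tab <- t(vapply(reps, function(r) {
    lab <- labels[replicate == r]
    if (!length(lab)) stop("replicate '", r, "' has no frames", call. = FALSE)
    counts <- table(factor(lab, levels = BRIDGE_CLASSES))
    as.numeric(counts) / length(lab)
  }, numeric(length(BRIDGE_CLASSES))))
  colnames(tab) <- BRIDGE_CLASSES
  per <- data.frame(replicate = reps, tab, check.names = FALSE,
                    stringsAsFactors = FALSE)
  mu <- colMeans(tab)
  sem <- if (nrow(tab) > 1L) apply(tab, 2L, stats::sd) / sqrt(nrow(tab)) else
    rep(NA_real_, ncol(tab))
  list(per_replicate = per,
       summary = data.frame(class = BRIDGE_CLASSES, mean = as.numeric(mu),
                            sem = as.numeric(sem), stringsAsFactors = FALSE))
}

# U statistic for group x against group y (ties count 1/2)
u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' Mann-Whitney U comparison of per-replicate frequencies
#'
#' Two-sided test of per-replicate interaction frequencies between two
#' conditions. For small samples (both groups <= `exact_max`) the p-value
#' comes from full enumeration of all group assignments of the pooled
#' values, which remains exact under ties; larger samples use the normal
#' approximation with tie correction (via [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors of per-replicate frequencies (>= 2 each)
#' @param exact_max largest per-group size for the exact branch
#' @return list with `U` (statistic for `x`), `p`, `method`
#' @export
compare_frequencies <- function(x, y, exact_max = 8L) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  u_obs <- u_statistic(x, y)
  if (length(x) <= exact_max && length(y) <= exact_max) {
    pooled <- c(x, y)
    n <- length(pooled); n1 <- length(x)
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2L, function(idx) {
      u_statistic(pooled[idx], pooled[-idx])
    })
    p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
    list(U = u_obs, p = p, method = "exact_enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(U = u_obs, p = wt$p.value, method = "normal_approx_tie_corrected")
  }
}

#' Fraction of frames with a qualifying pi-pi stacking contact
#'
#' @param frames frame-set data frame
#' @param rings named list of ring atom-serial vectors (see
#'   [detect_pipi()]); serials must be stable across frames
#' @param replicate optional replicate id per frame (defaults to one
#'   replicate)
#' @param ... stacking criteria passed to [detect_pipi()]
#' @return as [bridge_frequencies()]: per-replicate fractions plus
#'   mean/SEM summary (single class `stacked`)
#' @export
stacking_frequency <- function(frames, rings, replicate = NULL, ...) {
  per <- split_frames(frames)
  hit <- vapply(per, function(fr) nrow(detect_pipi(fr, rings, ...)) > 0L,
                logical(1))
  freq_by_replicate(hit, per, replicate, "stacked")
}

#' Fraction of frames with a hydrogen bond between two roles
#'
#' Scores e.g. the tyrosine-7.43 hydroxyl to glutamine-2.60 amide bond
#' across a trajectory: a frame counts when [detect_hbonds()] reports at
#' least one bond joining the two role atom sets.
#'
#' @param frames frame-set data frame
#' @param roles roles list
#' @param role_a,role_b role names within `roles`
#' @param replicate optional replicate id per frame
#' @param ... criteria passed to [detect_hbonds()]
#' @return as [stacking_frequency()]
#' @export
hbond_frequency <- function(frames, roles, role_a, role_b,
                            replicate = NULL, ...) {
  if (is.null(roles[[role_a]]) || is.null(roles[[role_b]])) {
    stop("roles '", role_a, "' and '", role_b, "' must be configured",
         call. = FALSE)
  }
  per <- split_frames(frames)
  hit <- vapply(per, function(fr) {
    sa <- select_role(fr, roles[[role_a]], role_a)$eleno
    sb <- select_role(fr, roles[[role_b]], role_b)$eleno
    hb <- detect_hbonds(fr, ...)
    if (nrow(hb) == 0L) return(FALSE)
    any((hb$i %in% sa & hb$j %in% sb) | (hb$i %in% sb & hb$j %in% sa))
  }, logical(1))
  freq_by_replicate(hit, per, replicate, "bonded")
}

freq_by_replicate <- function(hit, per, replicate, what) {
  if (is.null(replicate)) replicate <- rep(1L, length(per))
  stopifnot(length(replicate) == length(per))
  reps <- unique(replicate)
  fr <- vapply(reps, function(r) mean(hit[replicate == r]), numeric(1))
  sem <- if (length(fr) > 1L) stats::sd(fr) / sqrt(length(fr)) else NA_real_
  list(per_replicate = data.frame(replicate = reps, fraction = fr,
                                  stringsAsFactors = FALSE),
       summary = data.frame(class = what, mean = mean(fr), sem = sem,
                            stringsAsFactors = FALSE))
}
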