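#' Geometric interaction detectors
#'
#' Single-frame detectors for hydrogen bonds, direct polar contacts, ring
#' centroids/normals and face-to-face pi-pi stacking. All distances are in
#' Angstrom and all angles in degrees. Frames are assumed pre-imaged (no
#' periodic-boundary handling): inputs are snapshots, not raw trajectories.
#'
#' @name geometry
NULL

xyz_mat <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

dist2 <- function(a, b) sum((a - b)^2)

residue_key <- function(atoms) {
  paste(atoms$resname, atoms$chain, atoms$resno, sep = "|")
}

#' Detect hydrogen bonds between polar heavy atoms
#'
#' Scans every O/N--O/N pair in different residues and reports those whose
#' heavy-atom distance falls in `window` (default 2.2--3.0 Angstrom; the
#' observed bridge bonds in this system fall in 2.5--3, the lower bound
#' guards against steric clashes). When a candidate donor carries explicit
#' hydrogens (element H within 1.2 Angstrom in the same residue), the
#' D-H...A angle must also reach `angle_min` for at least one hydrogen on
#' at least one of the two atoms; heavy-atom-only frames are scored on
#' distance alone.
#'
#' Each qualifying pair is listed once, with atom serials in increasing
#' order.
#'
#' @param frame single-frame atom table
#' @param window numeric length-2, heavy-atom distance window (Angstrom)
#' @param angle_min minimum D-H...A angle in degrees (vertex at H)
#' @param elements heavy-atom elements considered donors/acceptors
#' @return data frame with columns `i`, `j` (atom serials, `i < j`),
#'   `distance`, `angle` (NA when no hydrogens were available)
#' @export
detect_hbonds <- function(frame, window = c(2.2, 3.0), angle_min = 120,
                          elements = c("N", "O")) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  empty <- data.frame(i = integer(), j = integer(),
                      distance = numeric(), angle = numeric())
  if (nrow(frame) == 0L) return(empty)
  heavy <- frame[frame$element %in% elements, , drop = FALSE]
  if (nrow(heavy) < 2L) return(empty)
  co <- xyz_mat(heavy)
  dmat <- as.matrix(stats::dist(co))
  res <- residue_key(heavy)
  hyd <- frame[frame$element == "H", , drop = FALSE]
  hco <- xyz_mat(hyd)
  hres <- residue_key(hyd)

  attached_h <- function(k) {
    if (nrow(hyd) == 0L) return(integer())
    same <- which(hres == res[k])
    if (!length(same)) return(integer())
    d <- sqrt(colSums((t(hco[same, , drop = FALSE]) - co[k, ])^2))
    same[d <= 1.2]
  }
  dha_ok <- function(donor, acceptor) {
    hs <- attached_h(donor)
    if (!length(hs)) return(NA)
    best <- -Inf
    for (h in hs) {
      v1 <- co[donor, ] - hco[h, ]
      v2 <- co[acceptor, ] - hco[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      best <- max(best, acos(max(-1, min(1, cosang))) * 180 / pi)
    }
    best
  }

  out <- empty
  n <- nrow(heavy)
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      if (res[a] == res[b]) next
      d <- dmat[a, b]
      if (d < window[1] || d > window[2]) next
      ang_a <- dha_ok(a, b)
      ang_b <- dha_ok(b, a)
      # distance-only when neither atom carries hydrogens
      pass <- (is.na(ang_a) && is.na(ang_b)) ||
        (!is.na(ang_a) && ang_a >= angle_min) ||
        (!is.na(ang_b) && ang_b >= angle_min)
      if (!pass) next
      ang <- suppressWarnings(max(c(ang_a, ang_b), na.rm = TRUE))
      if (!is.finite(ang)) ang <- NA_real_
      ij <- sort(c(heavy$eleno[a], heavy$eleno[b]))
      out <- rbind(out, data.frame(i = ij[1], j = ij[2],
                                   distance = d, angle = ang))
    }
  }
  rownames(out) <- NULL
  out
}

#' Direct polar contact between an atom and an atom set
#'
#' `TRUE` iff the minimum distance from atom `a` to any atom in `b_set`
#' lies within the hydrogen-bond window. Used for the "direct" leg of the
#' ligand--carboxylate engagement classification.
#'
#' @param frame single-frame atom table
#' @param a atom serial of the probe atom
#' @param b_set atom serials of the target set
#' @param window distance window (Angstrom)
#' @export
contact_direct <- function(frame, a, b_set, window = c(2.2, 3.0)) {
  ia <- match(a, frame$eleno)
  ib <- match(b_set, frame$eleno)
  if (is.na(ia)) stop("probe atom ", a, " not present in frame", call. = FALSE)
  if (anyNA(ib)) stop("target atoms missing from frame: ",
                      paste(b_set[is.na(ib)], collapse = ", "), call. = FALSE)
  co <- xyz_mat(frame)
  d <- sqrt(colSums((t(co[ib, , drop = FALSE]) - co[ia, ])^2))
  any(d >= window[1] & d <= window[2])
}

#' Centroid and unit normal of an aromatic ring
#'
#' The centroid is the coordinate mean; the normal is the eigenvector of
#' the smallest eigenvalue of the coordinate covariance (the best-fit
#' plane's normal). The sign is fixed deterministically: positive z
#' component, ties broken by x then y.
#'
#' @param coords numeric matrix (>= 3 rows) of ring-atom coordinates
#' @return list with `centroid` (length 3) and `normal` (unit length 3)
#' @export
ring_centroid_normal <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) stop("need at least 3 ring atoms", call. = FALSE)
  centroid <- colMeans(coords)
  cent <- sweep(coords, 2L, centroid)
  ev <- eigen(crossprod(cent) / nrow(coords), symmetric = TRUE)
  # eigenvalues descending; collinear atoms leave the plane undefined
  if (ev$values[2] <= 1e-10 * max(ev$values[1], 1e-300)) {
    stop("ring atoms are collinear; plane normal undefined", call. = FALSE)
  }
  n <- ev$vectors[, 3L]
  s <- sign(n[3])
  if (s == 0) s <- sign(n[1])
  if (s == 0) s <- sign(n[2])
  if (s == 0) s <- 1
  list(centroid = as.numeric(centroid), normal = as.numeric(n * s))
}

#' Detect face-to-face pi-pi stacking between ring pairs
#'
#' A contact is reported when the ring-centroid distance is at most
#' `d_max`, the interplanar angle at most `angle_max`, and the lateral
#' offset (displacement of one centroid from the other ring's normal axis,
#' minimum over the two rings) at most `offset_max`. The 5.0 Angstrom
#' centroid default encodes the exclusion bound beyond which stacking is
#' not considered robust; angle and offset gates follow common stacking
#' conventions and are configurable.
#'
#' @param frame single-frame atom table
#' @param rings named list; each element a vector of atom serials forming
#'   one ring (>= 3 atoms each)
#' @param d_max centroid-centroid cutoff (Angstrom)
#' @param angle_max interplanar angle cutoff (degrees)
#' @param offset_max lateral offset cutoff (Angstrom)
#' @return data frame with `ring_a`, `ring_b`, `centroid_distance`,
#'   `interplanar_angle`, `lateral_offset`, one row per qualifying pair
#' @export
detect_pipi <- function(frame, rings, d_max = 5.0, angle_max = 30,
                        offset_max = 2.0) {
  geo <- lapply(names(rings), function(nm) {
    idx <- match(rings[[nm]], frame$eleno)
    if (anyNA(idx)) stop("ring '", nm, "' references atoms absent from frame",
                         call. = FALSE)
    ring_centroid_normal(xyz_mat(frame)[idx, , drop = FALSE])
  })
  names(geo) <- names(rings)
  out <- data.frame(ring_a = character(), ring_b = character(),
                    centroid_distance = numeric(),
                    interplanar_angle = numeric(),
                    lateral_offset = numeric())
  nms <- names(rings)
  if (length(nms) < 2L) return(out)
  for (a in seq_len(length(nms) - 1L)) {
    for (b in seq.int(a + 1L, length(nms))) {
      ga <- geo[[a]]; gb <- geo[[b]]
      dvec <- gb$centroid - ga$centroid
      d <- sqrt(sum(dvec^2))
      cosang <- abs(sum(ga$normal * gb$normal))
      ang <- acos(min(1, cosang)) * 180 / pi
      off_a <- sqrt(max(0, d^2 - sum(dvec * ga$normal)^2))
      off_b <- sqrt(max(0, d^2 - sum(dvec * gb$normal)^2))
      off <- min(off_a, off_b)
      if (d <= d_max && ang <= angle_max && off <= offset_max) {
        out <- rbind(out, data.frame(ring_a = nms[a], ring_b = nms[b],
                                     centroid_distance = d,
                                     interplanar_angle = ang,
                                     lateral_offset = off))
      }
    }
  }
  rownames(out) <- NULL
  out
}
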