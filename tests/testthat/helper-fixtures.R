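# Shared fixtures and independent oracles, built in code at test time.

# Atom table builder: coords is an n x 3 matrix.
make_atoms <- function(coords, elety, resname, resno, element,
                       chain = "A", frame = 1L, eleno = NULL) {
  coords <- matrix(coords, ncol = 3L)
  n <- nrow(coords)
  data.frame(frame = frame,
             eleno = if (is.null(eleno)) seq_len(n) else eleno,
             elety = elety, resname = resname, chain = chain,
             resno = resno, element = element,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

# Regular hexagon of radius 1.39 A (aromatic C-C ring), in the plane with
# the given unit normal, centered at `center`.
hexagon_coords <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                           radius = 1.39, phase = 0) {
  normal <- normal / sqrt(sum(normal^2))
  # orthonormal in-plane basis
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal; u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- phase + seq(0, 2 * pi, length.out = 7L)[1:6]
  t(vapply(ang, function(a) center + radius * (cos(a) * u + sin(a) * v),
           numeric(3)))
}

# Frame holding two rings (ligand ring + tyrosine ring) at configurable
# geometry, for stacking tests.
two_ring_frame <- function(centerB = c(0, 0, 3.8), normalB = c(0, 0, 1),
                           frame = 1L) {
  a <- make_atoms(hexagon_coords(), c("C1", "C2", "C3", "C4", "C5", "C6"),
                  "LIG", 900L, "C", chain = "B", frame = frame)
  b <- make_atoms(hexagon_coords(centerB, normalB),
                  c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  "TYR", 326L, "C", frame = frame, eleno = 7:12)
  rbind(a, b)
}

ring_ids <- function(frame) {
  list(lig = frame$eleno[frame$resname == "LIG"],
       tyr = frame$eleno[frame$resname == "TYR"])
}

# Random rigid-body rotation (uniform via QR) + translation.
random_rigid <- function() {
  M <- matrix(rnorm(9), 3L)
  qrm <- qr(M)
  R <- qr.Q(qrm)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(atoms, rigid) {
  co <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rigid$R)
  co <- sweep(co, 2L, -rigid$t)
  atoms$x <- co[, 1]; atoms$y <- co[, 2]; atoms$z <- co[, 3]
  atoms
}

# Independent oracle: all O/N pairs in different residues with distance in
# the window (heavy-atom frames only; no angle term).
oracle_hbond_pairs <- function(frame, window = c(2.2, 3.0)) {
  heavy <- frame[frame$element %in% c("N", "O"), , drop = FALSE]
  co <- as.matrix(heavy[, c("x", "y", "z")])
  res <- paste(heavy$resname, heavy$chain, heavy$resno)
  out <- NULL
  n <- nrow(heavy)
  if (n >= 2L) for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    if (res[a] == res[b]) next
    d <- sqrt(sum((co[a, ] - co[b, ])^2))
    if (d >= window[1] && d <= window[2]) {
      out <- rbind(out, sort(c(heavy$eleno[a], heavy$eleno[b])))
    }
  }
  out
}

# Independent oracle: classify by brute-force enumeration of all simple
# paths of length <= 4 (ligand O -> [waters] -> carboxylate O) in the
# distance graph, then apply the exclusion order.
oracle_classify <- function(frame, roles = default_roles(),
                            window = c(2.2, 3.0)) {
  lig <- select_role(frame, roles$ligand_hydroxyl)$eleno
  carb <- select_role(frame, roles$carboxylate)$eleno
  wat <- select_role(frame, roles$water, required = FALSE)$eleno
  co <- as.matrix(frame[, c("x", "y", "z")])
  rownames(co) <- frame$eleno
  link <- function(a, b) {
    d <- sqrt(sum((co[as.character(a), ] - co[as.character(b), ])^2))
    d >= window[1] && d <= window[2]
  }
  if (any(vapply(carb, function(cb) link(lig, cb), logical(1)))) return("direct")
  for (w in wat) if (link(lig, w)) {
    for (cb in carb) if (link(w, cb)) return("water1")
  }
  for (w1 in wat) if (link(lig, w1)) {
    for (w2 in setdiff(wat, w1)) if (link(w1, w2)) {
      for (cb in carb) if (link(w2, cb)) return("water2")
    }
  }
  "none"
}

# A random bridge-test frame: ligand O, carboxylate pair, n waters uniform
# in a box around the axis. Produces a mix of all four classes.
random_bridge_frame <- function(n_waters, frame = 1L, span = 7) {
  asp <- make_atoms(rbind(c(0, 0, 0), c(-1.1, 1.91, 0)), c("OD1", "OD2"),
                    "ASP", 114L, "O", frame = frame)
  lig_pos <- c(runif(1, 2.5, 8), runif(1, -2, 2), runif(1, -2, 2))
  lig <- make_atoms(rbind(lig_pos), "O1", "LIG", 900L, "O", chain = "B",
                    frame = frame, eleno = 3L)
  wat <- make_atoms(matrix(runif(3 * n_waters, -2, span), ncol = 3L),
                    "O", "HOH", 1000L + seq_len(n_waters), "O", chain = "W",
                    frame = frame, eleno = 3L + seq_len(n_waters))
  rbind(asp, lig, wat)
}

# Independent exact Mann-Whitney oracle: recursive enumeration of all
# assignments of pooled values into the two groups.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x); n <- length(pooled)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  us <- c()
  rec <- function(chosen, start) {
    if (length(chosen) == n1) {
      us <<- c(us, u_of(pooled[chosen], pooled[-chosen]))
      return(invisible())
    }
    if (start > n) return(invisible())
    for (k in seq.int(start, n)) rec(c(chosen, k), k + 1L)
  }
  rec(integer(), 1L)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exhaustive grid oracle for 3-location NNLS on the simplex-and-beyond:
# dense search over beta >= 0 minimizing ||y - X b||.
oracle_nnls_grid <- function(y, X, bmax = 1.5, step = 0.01) {
  g <- seq(0, bmax, by = step)
  best <- NULL; best_v <- Inf
  for (b1 in g) for (b2 in g) {
    r12 <- y - X[, 1] * b1 - X[, 2] * b2
    # optimal b3 given b1, b2 is a 1-d nonnegative LS solve
    b3 <- max(0, sum(r12 * X[, 3]) / sum(X[, 3]^2))
    v <- sum((r12 - X[, 3] * b3)^2)
    if (v < best_v) { best_v <- v; best <- c(b1, b2, b3) }
  }
  best
}
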