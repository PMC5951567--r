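## Independent brute-force oracles and shared (cached) fixtures.

.fixtures <- new.env(parent = emptyenv())

# rasterized sphere r = 10 mm at 0.5 mm spacing, with mesh and curvature;
# computed once per test run
sphereFixture <- function() {
  if (is.null(.fixtures$sphere)) {
    ph <- generatePhantom(phantomSpec(baseRadius = 10,
                                      spacing = c(0.5, 0.5, 0.5)), seed = 7)
    mesh <- extractMesh(ph@mask)
    field <- principalCurvatures(mesh)
    .fixtures$sphere <- list(phantom = ph, mesh = mesh, field = field)
  }
  .fixtures$sphere
}

phantom40Fixture <- function() {
  if (is.null(.fixtures$phantom40))
    .fixtures$phantom40 <- simulatePhantomCohort(nBenign = 20,
                                                 nMalignant = 20, seed = 2)
  .fixtures$phantom40
}

# AUC by exhaustive concordant-pair counting, ties counted 1/2
oracleAuc <- function(scores, pos) {
  sm <- scores[pos]
  sb <- scores[!pos]
  tot <- 0
  for (a in sm) for (b in sb)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sm) * length(sb))
}

# Youden cutoff by sweeping every candidate threshold (all observed scores
# plus midpoints plus outside values), rule: score >= cutoff is positive
oracleYouden <- function(scores, pos) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2,
                        min(u) - 1, max(u) + 1)))
  best <- -Inf
  bestRow <- NULL
  for (ct in cand) {
    sens <- mean(scores[pos] >= ct)
    spec <- mean(scores[!pos] < ct)
    J <- sens + spec - 1
    if (J > best + 1e-12) {
      best <- J
      bestRow <- c(cutoff = ct, sens = sens, spec = spec, J = J)
    }
  }
  bestRow
}

# Spearman rho via explicit midranks and Pearson on ranks
oracleSpearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# two-sided Fisher exact p by full hypergeometric enumeration over all tables
# with the observed margins
oracleFisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  aRange <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(aRange, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  pObs <- probs[aRange == tab[1, 1]]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# SILA from the definition, summed term by term
oracleSila <- function(p) {
  K <- length(p)
  tot <- 0
  for (i in 1:(K - 1)) {
    Fi <- sum(p[1:i])
    tot <- tot + (1 - Fi)^2
  }
  tot / (K - 1)
}

# per-vertex geodesic class proportions by an O(n^2) Dijkstra in plain R
oracleLocalSila <- function(V, F, cls, areas, K, radius) {
  n <- nrow(V)
  adj <- vector("list", n)
  addE <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  for (f in seq_len(nrow(F))) {
    tri <- F[f, ]
    for (a in tri) for (b in tri) if (a != b) addE(a, b)
  }
  scores <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      cand <- which(!done & is.finite(dist) & dist <= radius)
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      for (u in adj[[v]]) {
        d <- dist[v] + sqrt(sum((V[u, ] - V[v, ])^2))
        if (d < dist[u]) dist[u] <- d
      }
    }
    sel <- done
    mass <- vapply(seq_len(K), function(k) sum(areas[sel & cls == k]),
                   numeric(1))
    p <- mass / sum(mass)
    scores[s] <- oracleSila(p)
  }
  scores
}

# brute-force nearest-surface-voxel distance (exhaustive, for small grids)
oracleEdtSq <- function(mask, spacing) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    dd <- ((pts[, 1] - i) * spacing[1])^2 + ((pts[, 2] - j) * spacing[2])^2 +
      ((pts[, 3] - k) * spacing[3])^2
    out[i, j, k] <- min(dd)
  }
  out
}

# quick capsule mask: voxels within radius of the segment z in [-hl, hl]
capsuleMask <- function(radius = 5, halfLen = 10, spacing = 1) {
  ext <- radius + halfLen + 4
  n <- 2 * ceiling(ext / spacing) + 1
  cc <- (seq_len(n) - 1) * spacing - ext
  X <- array(cc, c(n, n, n))
  Y <- array(rep(cc, each = n), c(n, n, n))
  Z <- array(rep(cc, each = n * n), c(n, n, n))
  Zc <- pmin(pmax(Z, -halfLen), halfLen)
  m <- (X^2 + Y^2 + (Z - Zc)^2) <= radius^2
  noduleMask(m, spacing = rep(spacing, 3), origin = rep(-ext, 3))
}

# torus mask: (sqrt(x^2+y^2) - R)^2 + z^2 <= r^2
torusMask <- function(R = 8, r = 3, spacing = 0.7) {
  ext <- R + r + 3
  n <- 2 * ceiling(ext / spacing) + 1
  cc <- (seq_len(n) - 1) * spacing - ext
  X <- array(cc, c(n, n, n))
  Y <- array(rep(cc, each = n), c(n, n, n))
  Z <- array(rep(cc, each = n * n), c(n, n, n))
  m <- (sqrt(X^2 + Y^2) - R)^2 + Z^2 <= r^2
  noduleMask(m, spacing = rep(spacing, 3), origin = rep(-ext, 3))
}
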