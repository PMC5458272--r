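# Independent oracles used across the suite. Everything here is written
# from first principles (direct enumeration, closed forms, generic
# numerics) and deliberately avoids the implementation paths it checks.

# brute-force interface enumeration: O(n*m) double loop
oracle_interface <- function(structure, anchor, cutoff) {
  a <- structure$atoms
  anc <- a[a$chain == anchor$chain & a$resno %in% anchor$resnos &
             !a$het & !a$elem %in% c("H", "D"), ]
  rec <- a[!(a$chain == anchor$chain & a$resno %in% anchor$resnos) &
             !a$het & !a$elem %in% c("H", "D"), ]
  hit <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(anc))) {
      d <- sqrt((rec$x[i] - anc$x[j])^2 + (rec$y[i] - anc$y[j])^2 +
                  (rec$z[i] - anc$z[j])^2)
      if (d <= cutoff) {
        hit[i] <- TRUE
        break
      }
    }
  }
  out <- rec[hit, ]
  out[order(out$chain, out$resno, out$name), ]
}

# brute-force side-chain contact count for the alanine-scan surrogate
oracle_sc_contacts <- function(structure, anchor, resno, cutoff) {
  a <- structure$atoms
  res <- a[a$chain == anchor$chain & a$resno == resno, ]
  sc <- res[!res$name %in% c("N", "CA", "C", "O", "CB", "OXT") &
              !res$elem %in% c("H", "D"), ]
  rec <- a[!(a$chain == anchor$chain & a$resno %in% anchor$resnos) &
             !a$het & !a$elem %in% c("H", "D"), ]
  n <- 0L
  for (i in seq_len(nrow(sc)))
    for (j in seq_len(nrow(rec))) {
      d <- sqrt((sc$x[i] - rec$x[j])^2 + (sc$y[i] - rec$y[j])^2 +
                  (sc$z[i] - rec$z[j])^2)
      if (d <= cutoff) n <- n + 1L
    }
  n
}

# ---- exhaustive pharmacophore matching oracle ------------------------------

oracle_proj_ok <- function(f, p, proj_len) {
  if (is.null(f$proj)) return(TRUE)
  if (is.null(p$dirs)) {
    d <- sqrt(sum((p$pos - f$proj)^2))
    return(abs(d - proj_len) <= f$proj_radius)
  }
  for (r in seq_len(nrow(p$dirs))) {
    q <- p$pos + proj_len * p$dirs[r, ]
    if (sqrt(sum((q - f$proj)^2)) <= f$proj_radius) return(TRUE)
  }
  FALSE
}

oracle_kind_ok <- function(fk, pk) fk == pk || (fk == "hydrophobic" && pk == "aromatic")

# All injective feature->point maps, enumerated outright; returns the best
# (max size, then min RMSD) valid correspondence or NULL.
oracle_match_absolute <- function(hyp, points, min_match = hyp$min_match) {
  nf <- length(hyp$features)
  np <- length(points)
  ess <- vapply(hyp$features, function(f) isTRUE(f$essential), logical(1))
  # exclusion check on the point positions (matches the points-input contract)
  if (nrow(hyp$exclusions) > 0) {
    for (p in points) {
      d <- sqrt(colSums((t(as.matrix(hyp$exclusions[, c("x", "y", "z")])) - p$pos)^2))
      if (any(d < hyp$exclusions$r)) return(NULL)
    }
  }
  ok <- matrix(FALSE, nf, np)
  for (fi in seq_len(nf)) for (pi in seq_len(np)) {
    f <- hyp$features[[fi]]
    p <- points[[pi]]
    ok[fi, pi] <- oracle_kind_ok(f$kind, p$kind) &&
      sqrt(sum((p$pos - f$center)^2)) <= f$radius &&
      oracle_proj_ok(f, p, hyp$proj_len)
  }
  best <- NULL
  # enumerate assignments feature by feature (including "unmatched")
  enum <- function(fi, used, pairs) {
    if (fi > nf) {
      n <- nrow(pairs)
      if (n < min_match || n == 0) return()
      if (!all(which(ess) %in% pairs[, 1])) return()
      rmsd <- sqrt(mean(apply(pairs, 1, function(pr)
        sum((points[[pr[2]]]$pos - hyp$features[[pr[1]]]$center)^2))))
      if (is.null(best) || n > best$n || (n == best$n && rmsd < best$rmsd))
        best <<- list(n = n, rmsd = rmsd)
      return()
    }
    enum(fi + 1, used, pairs)
    for (pi in which(ok[fi, ])) {
      if (used[pi]) next
      used[pi] <- TRUE
      enum(fi + 1, used, rbind(pairs, c(fi, pi)))
      used[pi] <- FALSE
    }
  }
  enum(1, rep(FALSE, np), matrix(integer(), 0, 2))
  best
}

# minimal independent rigid superposition (for the align-mode oracle)
oracle_superpose <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  s <- svd(t(P - matrix(cp, nrow(P), 3, byrow = TRUE)) %*%
             (Q - matrix(cq, nrow(Q), 3, byrow = TRUE)))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cq - as.vector(R %*% cp))
}

# exhaustive align-mode oracle: every ordered triplet of distinct
# compatible feature/point pairs seeds a superposition
oracle_match_align <- function(hyp, points, min_match = hyp$min_match) {
  nf <- length(hyp$features)
  np <- length(points)
  if (nf < 3 || np < 3) return(NULL)
  fcent <- do.call(rbind, lapply(hyp$features, `[[`, "center"))
  ppos <- do.call(rbind, lapply(points, `[[`, "pos"))
  best <- NULL
  for (f1 in 1:nf) for (f2 in 1:nf) for (f3 in 1:nf) {
    if (length(unique(c(f1, f2, f3))) < 3) next
    for (p1 in 1:np) for (p2 in 1:np) for (p3 in 1:np) {
      if (length(unique(c(p1, p2, p3))) < 3) next
      if (!oracle_kind_ok(hyp$features[[f1]]$kind, points[[p1]]$kind)) next
      if (!oracle_kind_ok(hyp$features[[f2]]$kind, points[[p2]]$kind)) next
      if (!oracle_kind_ok(hyp$features[[f3]]$kind, points[[p3]]$kind)) next
      tr <- oracle_superpose(ppos[c(p1, p2, p3), ], fcent[c(f1, f2, f3), ])
      tp <- lapply(points, function(p) {
        p$pos <- as.vector(tr$R %*% p$pos + tr$t)
        if (!is.null(p$dirs)) p$dirs <- p$dirs %*% t(tr$R)
        p
      })
      res <- oracle_match_absolute(hyp, tp, min_match)
      if (!is.null(res) && (is.null(best) || res$n > best$n ||
                            (res$n == best$n && res$rmsd < best$rmsd)))
        best <- res
    }
  }
  best
}

# random small matching instances shared by unit and acceptance tests
random_match_instance <- function(seed, with_proj = TRUE) {
  set.seed(seed)
  kinds <- c("aromatic", "donor", "acceptor", "hydrophobic")
  nf <- sample(3:6, 1)
  np <- sample(3:8, 1)
  feats <- lapply(seq_len(nf), function(i) {
    ctr <- runif(3, -4, 4)
    proj <- if (with_proj && runif(1) < 0.4) ctr + 3 * rand_unit() else NULL
    list(kind = sample(kinds, 1), center = ctr, radius = runif(1, 0.8, 1.5),
         proj = proj, proj_radius = 1.4,
         essential = runif(1) < 0.3, source = sprintf("F%d", i), partner = "")
  })
  if (!any(vapply(feats, `[[`, logical(1), "essential")))
    feats[[1]]$essential <- TRUE
  excl <- if (runif(1) < 0.3)
    data.frame(x = runif(1, -4, 4), y = runif(1, -4, 4), z = runif(1, -4, 4),
               r = runif(1, 0.5, 1.5))
  else data.frame(x = numeric(), y = numeric(), z = numeric(), r = numeric())
  hyp <- structure(list(features = feats, exclusions = excl,
                        min_match = 3, proj_len = 3.0),
                   class = "pharmacophore")
  points <- lapply(seq_len(np), function(i) {
    # half the points sit near some feature center, the rest are scattered
    pos <- if (i <= nf && runif(1) < 0.7)
      feats[[i]]$center + runif(3, -0.9, 0.9)
    else runif(3, -6, 6)
    dirs <- if (runif(1) < 0.5) matrix(rand_unit(), 1) else NULL
    list(kind = sample(kinds, 1), pos = pos, dirs = dirs, atom = i)
  })
  list(hyp = hyp, points = points)
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# union-find single-linkage clustering oracle
oracle_components <- function(sim, threshold) {
  n <- nrow(sim)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sim[i, j] >= threshold) parent[find(i)] <- find(j)
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force graph automorphisms by permutation filtering (n! so n <= 8)
oracle_automorphisms <- function(mol) {
  hv <- which(!mol$atoms$elem %in% c("H", "D"))
  n <- length(hv)
  stopifnot(n <= 8)
  el <- mol$atoms$elem[hv]
  adj <- matrix(0L, n, n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- match(mol$bonds$i[r], hv)
    j <- match(mol$bonds$j[r], hv)
    if (!is.na(i) && !is.na(j)) adj[i, j] <- adj[j, i] <- mol$bonds$order[r]
  }
  pm <- perms_of(n)
  keep <- list()
  for (r in seq_len(nrow(pm))) {
    p <- pm[r, ]
    if (all(el[p] == el) && all(adj[p, p] == adj))
      keep[[length(keep) + 1]] <- as.integer(p)
  }
  keep
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# numeric competitive-equilibrium IC50: root of occ(I) = occ(0)/2
oracle_numeric_ic50 <- function(kd, tconc, ki) {
  occ <- function(I) (tconc / kd) / (1 + tconc / kd + I / ki)
  target <- occ(0) / 2
  stats::uniroot(function(I) occ(I) - target, c(1e-12, 1), tol = 1e-14)$root
}

# dense torsion-scan oracle for the shipped torsion potential: counts the
# distinct minima a 1-degree scan + local descent finds
oracle_butane_minima <- function(v1 = 0.8, v3 = 2.9) {
  e <- function(phi) v1 / 2 * (1 + cos(phi * pi / 180)) +
    v3 / 2 * (1 + cos(3 * phi * pi / 180))
  phis <- seq(-179, 180, by = 1)
  ee <- e(phis)
  mins <- c()
  for (i in seq_along(phis)) {
    prev <- if (i == 1) length(phis) else i - 1
    nxt <- if (i == length(phis)) 1 else i + 1
    if (ee[i] < ee[prev] && ee[i] < ee[nxt]) mins <- c(mins, phis[i])
  }
  list(angles = mins, energies = e(mins))
}
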