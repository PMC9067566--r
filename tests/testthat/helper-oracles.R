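# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the code paths they check.

# Reference Steinhardt values computed independently (direct spherical-
# harmonic sums over the ideal bond sets, double precision).
Q_REF <- list(
  tet_q6 = 0.628539361054709,   # 4 tetrahedral neighbours (ice first shell)
  tet_q4 = 0.5091750772173156,
  fcc_q6 = 0.5745242597140697,  # 12 fcc nearest neighbours
  fcc_q4 = 0.1909406539564933
)

# 13-atom fcc first-shell cluster (central atom index 1), open boundaries
fcc_cluster_config <- function(scale = 2) {
  shell <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
    c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1)
  )
  coords <- rbind(c(0, 0, 0), shell) * scale
  configuration(rep("OW", 13), coords + 25, box = c(50, 50, 50),
                molecule_ids = 1:13, periodic = c(FALSE, FALSE, FALSE))
}

# brute-force O(n^2) neighbour pairs, independent of neighbor_list()
oracle_pairs <- function(config, cutoff) {
  n <- n_atoms(config)
  out <- NULL
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (j > n) break
      d <- config$coords[j, ] - config$coords[i, ]
      for (k in 1:3) {
        if (config$periodic[k]) {
          d[k] <- d[k] - config$box[k] * round(d[k] / config$box[k])
        }
      }
      if (sqrt(sum(d^2)) <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  out
}

# brute-force connected components by BFS over an adjacency list restricted
# to `keep` vertices; returns a list of sorted integer vectors
oracle_components <- function(adj, keep) {
  keep <- which(keep)
  seen <- logical(length(adj))
  comps <- list()
  for (s in keep) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[nb %in% keep & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

canonical_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, min, numeric(1)))]
}

# --- cage oracles -----------------------------------------------------------

# primitive 6-rings via igraph subgraph isomorphism (LAD) + igraph distances;
# a completely different enumeration engine from enumerate_rings()
oracle_rings <- function(graph) {
  g <- igraph::graph_from_edgelist(as.matrix(graph$pairs[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, graph$n_atoms - igraph::vcount(g)))
  maps <- igraph::subgraph_isomorphisms(igraph::make_ring(6), g,
                                        method = "lad", induced = FALSE)
  D <- igraph::distances(g)
  rings <- list()
  seen <- character(0)
  for (m in maps) {
    ring <- as.integer(m)
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    ok <- TRUE
    for (i in 1:5) for (j in (i + 1):6) {
      cd <- min(j - i, 6L - (j - i))
      if (D[ring[i], ring[j]] < cd) ok <- FALSE
    }
    if (!ok) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- ring  # in cycle order from the map
  }
  rings
}

# HC oracle: pair up oracle rings; exactly three inter-ring bonds forming a
# matching whose endpoints are mutually non-adjacent within each ring
oracle_hc <- function(graph) {
  rings <- oracle_rings(graph)
  adjmat <- matrix(FALSE, graph$n_atoms, graph$n_atoms)
  for (e in seq_len(nrow(graph$pairs))) {
    i <- graph$pairs$i[e]; j <- graph$pairs$j[e]
    adjmat[i, j] <- TRUE; adjmat[j, i] <- TRUE
  }
  found <- character(0)
  nr <- length(rings)
  for (a in seq_len(max(nr - 1L, 0L))) {
    for (b in (a + 1L):nr) {
      if (b > nr) break
      r1 <- rings[[a]]; r2 <- rings[[b]]
      if (length(intersect(r1, r2))) next
      sub <- adjmat[r1, r2, drop = FALSE]
      if (sum(sub) != 3L) next
      if (any(rowSums(sub) > 1L) || any(colSums(sub) > 1L)) next
      e1 <- r1[rowSums(sub) == 1L]
      e2 <- r2[colSums(sub) == 1L]
      if (any(adjmat[e1, e1])) next  # endpoints non-adjacent within ring
      if (any(adjmat[e2, e2])) next
      found <- c(found, paste(sort(c(r1, r2)), collapse = ","))
    }
  }
  unique(found)
}

# DDC oracle: apex-driven exhaustive search, no ring enumeration involved
oracle_ddc <- function(graph) {
  adj <- graph$adj
  adjmat <- matrix(FALSE, graph$n_atoms, graph$n_atoms)
  for (e in seq_len(nrow(graph$pairs))) {
    i <- graph$pairs$i[e]; j <- graph$pairs$j[e]
    adjmat[i, j] <- TRUE; adjmat[j, i] <- TRUE
  }
  found <- character(0)
  for (t in seq_len(graph$n_atoms)) {
    nb_t <- adj[[t]]
    if (length(nb_t) < 3L) next
    for (bt in utils::combn(nb_t, 3L, simplify = FALSE)) {
      # odd ring members: one neighbour (besides t) of each top bridge
      cand <- lapply(bt, function(x) setdiff(adj[[x]], t))
      for (v1 in cand[[1L]]) for (v3 in cand[[2L]]) for (v5 in cand[[3L]]) {
        odd <- c(v1, v3, v5)
        if (anyDuplicated(odd) || any(odd %in% bt) || t %in% odd) next
        # even members joining consecutive odd members
        ev12 <- setdiff(which(adjmat[v1, ] & adjmat[v3, ]), c(bt, t, odd))
        ev23 <- setdiff(which(adjmat[v3, ] & adjmat[v5, ]), c(bt, t, odd))
        ev31 <- setdiff(which(adjmat[v5, ] & adjmat[v1, ]), c(bt, t, odd))
        for (v2 in ev12) for (v4 in ev23) for (v6 in ev31) {
          evens <- c(v2, v4, v6)
          if (anyDuplicated(evens)) next
          ring <- c(v1, v2, v3, v4, v5, v6)
          # bottom bridges: a neighbour of each even member, sharing an apex
          bb_cand <- lapply(evens, function(v) setdiff(adj[[v]], c(ring, bt, t)))
          for (y1 in bb_cand[[1L]]) for (y2 in bb_cand[[2L]]) for (y3 in bb_cand[[3L]]) {
            if (anyDuplicated(c(y1, y2, y3))) next
            apexes <- setdiff(which(adjmat[y1, ] & adjmat[y2, ] & adjmat[y3, ]),
                              c(ring, bt, t, y1, y2, y3))
            for (bb in apexes) {
              members <- sort(c(t, bt, ring, y1, y2, y3, bb))
              if (length(unique(members)) == 14L) {
                found <- c(found, paste(members, collapse = ","))
              }
            }
          }
        }
      }
    }
  }
  unique(found)
}

# --- misc -------------------------------------------------------------------

random_rotation_oracle <- function() {
  # QR-based random rotation, independent of the package helper
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# water built so its dipole (H-midpoint minus O) points along `dir`
water_with_bisector <- function(o_pos, dir) {
  dir <- dir / sqrt(sum(dir^2))
  tmpl <- rbind(
    c(0.9572 * sin(104.52 / 2 * pi / 180), 0, 0.9572 * cos(104.52 / 2 * pi / 180)),
    c(-0.9572 * sin(104.52 / 2 * pi / 180), 0, 0.9572 * cos(104.52 / 2 * pi / 180))
  )
  z <- c(0, 0, 1)
  v <- c(z[2] * dir[3] - z[3] * dir[2],
         z[3] * dir[1] - z[1] * dir[3],
         z[1] * dir[2] - z[2] * dir[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * dir)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  h <- tmpl %*% t(R)
  rbind(o_pos, o_pos + h[1, ], o_pos + h[2, ])
}

# assay study conditions shared by recovery tests: lambda rises linearly
# from 0 at -5 C to 4 at -30 C
ASSAY_X <- 1e15
assay_site_density <- function(T) 1.6e-16 * pmax(-T - 5, 0)
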