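# Primitive six-membered rings and the topological water cages of cubic and
# hexagonal ice.
#
# A ring is primitive when no pair of its members is connected by a shorter
# path through the graph than along the ring (no shortcuts / chords).
#
# Cage motifs (topological, hydrogen-bond-network definitions):
#   HC  (hexagonal cage, building block of ice Ih): two vertex-disjoint
#       primitive 6-rings whose inter-ring bonds are exactly three, form a
#       matching, and attach to alternating members of each ring.
#   DDC (double-diamond cage, building block of ice Ic): an equatorial
#       primitive 6-ring plus two caps; each cap consists of three bridge
#       molecules bonded to alternating ring members and to one shared apex
#       molecule (14 molecules in total, two fused adamantane-like halves).

# BFS distances from each vertex, capped at `cap` hops
bfs_distances <- function(adj, cap) {
  n <- length(adj)
  D <- matrix(cap + 1L, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0L
    frontier <- s
    for (d in seq_len(cap)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[D[s, nxt] > d]
      if (!length(nxt)) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

#' Enumerate primitive six-membered rings
#'
#' Finds every 6-cycle of the neighbour graph and keeps those that are
#' primitive (shortest-path: the graph distance between any two ring
#' members equals their distance along the ring).  Each ring is reported
#' once, in canonical cycle order starting from its smallest member.
#'
#' @param graph A [neighbor_list()] result (typically the O-O
#'   hydrogen-bond network at ~3.5 angstrom cutoff).
#' @param size Ring size; only 6 is supported.
#' @return An object of class `ring_set`: `rings` (list of length-6 integer
#'   vectors in cycle order) and the graph fingerprint.
#' @export
enumerate_rings <- function(graph, size = 6L) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (size != 6L) stop("only six-membered rings are supported")
  adj <- lapply(graph$adj, sort)
  n <- graph$n_atoms
  D <- bfs_distances(adj, cap = 3L)

  rings <- list()
  seen <- new.env(hash = TRUE)
  for (a in seq_len(n)) {
    nb_a <- adj[[a]][adj[[a]] > a]
    for (b in nb_a) {
      for (c3 in adj[[b]]) {
        if (c3 <= a || c3 == a) next
        if (c3 == a) next
        for (d4 in adj[[c3]]) {
          if (d4 <= a || d4 == b) next
          for (e5 in adj[[d4]]) {
            if (e5 <= a || e5 == b || e5 == c3) next
            for (f6 in adj[[e5]]) {
              if (f6 <= a || f6 == b || f6 == c3 || f6 == d4) next
              if (!(a %in% adj[[f6]])) next
              if (b > f6) next  # canonical direction
              ring <- c(a, b, c3, d4, e5, f6)
              # primitivity: distances match the cyclic distance
              ok <- TRUE
              for (i in 1:5) {
                for (j in (i + 1):6) {
                  cd <- min(j - i, 6L - (j - i))
                  if (D[ring[i], ring[j]] < cd) { ok <- FALSE; break }
                }
                if (!ok) break
              }
              if (!ok) next
              key <- paste(sort(ring), collapse = ",")
              if (!is.null(seen[[key]])) next
              seen[[key]] <- TRUE
              rings[[length(rings) + 1L]] <- ring
            }
          }
        }
      }
    }
  }
  structure(list(rings = rings, size = 6L,
                 graph_info = graph_fingerprint(graph)),
            class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("<ring_set> %d primitive %d-rings\n", length(x$rings), x$size))
  invisible(x)
}

# positions (1-based, in cycle order) of `what` inside ring `r`
ring_positions <- function(r, what) match(what, r)

#' Detect double-diamond and hexagonal cages
#'
#' Searches the ring set for the HC and DDC motifs described above.  Each
#' cage is keyed by its member set, so a cage reachable from several rings
#' is counted once; DDC and HC lists may share molecules but never a member
#' set.
#'
#' @param rings An [enumerate_rings()] result.
#' @param graph The same neighbour graph the rings were computed on.
#' @return An object of class `cage_set`: `ddc` and `hc` (lists of sorted
#'   member-index vectors), `n_ddc`, `n_hc`.
#' @export
detect_cages <- function(rings, graph) {
  stopifnot(inherits(rings, "ring_set"), inherits(graph, "neighbor_graph"))
  if (!isTRUE(all.equal(rings$graph_info, graph_fingerprint(graph)))) {
    stop("ring set was not computed on this neighbour graph")
  }
  adj <- lapply(graph$adj, sort)
  n <- graph$n_atoms
  rl <- rings$rings

  # ring membership index
  member_of <- vector("list", n)
  for (ri in seq_along(rl)) {
    for (v in rl[[ri]]) member_of[[v]] <- c(member_of[[v]], ri)
  }

  hc <- new.env(hash = TRUE)
  # candidate ring pairs share an inter-ring bond
  p <- graph$pairs
  cand <- new.env(hash = TRUE)
  if (nrow(p)) {
    for (e in seq_len(nrow(p))) {
      r_i <- member_of[[p$i[e]]]
      r_j <- member_of[[p$j[e]]]
      if (is.null(r_i) || is.null(r_j)) next
      for (a in r_i) for (b in r_j) {
        if (a == b) next
        key <- if (a < b) paste(a, b) else paste(b, a)
        cand[[key]] <- TRUE
      }
    }
  }
  for (key in ls(cand)) {
    ab <- as.integer(strsplit(key, " ")[[1L]])
    r1 <- rl[[ab[1L]]]; r2 <- rl[[ab[2L]]]
    if (length(intersect(r1, r2))) next
    # inter-ring bonds
    u <- integer(0); v <- integer(0)
    for (x in r1) {
      hit <- intersect(adj[[x]], r2)
      for (y in hit) { u <- c(u, x); v <- c(v, y) }
    }
    if (length(u) != 3L) next
    if (anyDuplicated(u) || anyDuplicated(v)) next  # must be a matching
    # endpoints attach to alternating members of each ring
    pos1 <- sort(ring_positions(r1, u))
    pos2 <- sort(ring_positions(r2, v))
    alt <- function(pp) all(diff(pp) == 2L)
    if (!alt(pos1) || !alt(pos2)) next
    members <- sort(c(r1, r2))
    hc[[paste(members, collapse = ",")]] <- members
  }

  ddc <- new.env(hash = TRUE)
  for (r in rl) {
    # the two alternating triples of the equatorial ring
    tri1 <- r[c(1L, 3L, 5L)]
    tri2 <- r[c(2L, 4L, 6L)]
    caps1 <- find_caps(tri1, r, adj)
    if (!length(caps1)) next
    caps2 <- find_caps(tri2, r, adj)
    if (!length(caps2)) next
    for (c1 in caps1) for (c2 in caps2) {
      members <- sort(c(r, c1, c2))
      if (length(unique(members)) != 14L) next
      ddc[[paste(members, collapse = ",")]] <- members
    }
  }

  ddc_list <- mget(ls(ddc), envir = ddc)
  hc_list <- mget(ls(hc), envir = hc)
  structure(list(ddc = unname(ddc_list), hc = unname(hc_list),
                 n_ddc = length(ddc_list), n_hc = length(hc_list)),
            class = "cage_set")
}

# caps for one alternating triple: three distinct bridges (one neighbour of
# each triple member, outside the ring) sharing a single apex outside the
# ring; returns a list of length-4 vectors (b1, b2, b3, apex)
find_caps <- function(triple, ring, adj) {
  cands <- lapply(triple, function(t) setdiff(adj[[t]], ring))
  out <- list()
  for (b1 in cands[[1L]]) for (b2 in cands[[2L]]) {
    if (b2 == b1) next
    for (b3 in cands[[3L]]) {
      if (b3 == b1 || b3 == b2) next
      apex <- setdiff(intersect(intersect(adj[[b1]], adj[[b2]]), adj[[b3]]),
                      c(ring, b1, b2, b3))
      for (a in apex) out[[length(out) + 1L]] <- c(b1, b2, b3, a)
    }
  }
  out
}

#' @export
print.cage_set <- function(x, ...) {
  cat(sprintf("<cage_set> %d DDC, %d HC\n", x$n_ddc, x$n_hc))
  invisible(x)
}
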