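# Graphlet-orbit counting and GDD agreement.
#
# A graphlet is a small connected induced subgraph; an orbit is an
# automorphism-equivalence class of its node positions.  Counting, for
# every node, how often it touches each orbit gives the graphlet degree
# distribution (GDD); the GDD agreement summarises how similar two
# networks' normalized GDDs are, orbit by orbit.
#
# Orbits 0..14 (graphlets on 2-4 nodes) follow the standard numbering:
#   0 edge; 1/2 path end/middle; 3 triangle; 4/5 P4 end/middle;
#   6/7 claw leaf/centre; 8 C4; 9/10/11 paw pendant/rim/hub;
#   12/13 diamond rim/hub; 14 K4.
# Orbits 15+ (5-node graphlets) are numbered deterministically from a
# programmatically built atlas (sorted by edge count, degree sequence
# and a canonical colour signature); the numbering is internal but
# stable, and GDD agreement is invariant to orbit numbering.

N_ORBITS_4 <- 15L

#' Per-node graphlet orbit counts
#'
#' Counts, for every node, the number of times it touches each
#' automorphism orbit of connected graphlets on 2..`max_size` nodes, by
#' exhaustive enumeration of connected induced subgraphs (ESU).
#'
#' @param net a [ppi_network()] (desk scale: up to a few thousand
#'   nodes).
#' @param max_size largest graphlet size, 4 (15 orbits, default) or 5
#'   (73 orbits; substantially slower).
#' @return integer matrix, nodes x orbits, with orbit names `o0`,
#'   `o1`, ... and node labels as rownames.
#' @export
orbit_counts <- function(net, max_size = 4) {
  if (!max_size %in% c(4, 5)) stop("max_size must be 4 or 5")
  n <- n_nodes(net)
  if (n > 3000) stop("orbit counting is desk-scale: n <= 3000")
  K <- if (max_size == 4) N_ORBITS_4 else N_ORBITS_4 + graphlet5_table()$n_orbits
  counts <- matrix(0L, n, K,
                   dimnames = list(net$nodes, sprintf("o%d", seq_len(K) - 1L)))
  if (n_edges(net) == 0) return(counts)

  A <- adjacency_logical(net)
  deg <- as.integer(colSums(A))
  adj <- lapply(seq_len(n), function(v) which(A[, v]))

  ## sizes 2 and 3 in closed form
  A1 <- A * 1L
  tri_edge <- colSums(A[, net$edges[, 1], drop = FALSE] &
                      A[, net$edges[, 2], drop = FALSE])
  T_v <- numeric(n)
  acc <- rowsum(c(tri_edge, tri_edge), c(net$edges[, 1], net$edges[, 2]))
  T_v[as.integer(rownames(acc))] <- acc / 2
  s_v <- as.vector(A1 %*% deg)
  counts[, 1] <- deg                              # o0
  counts[, 2] <- as.integer(s_v - deg - 2 * T_v)  # o1: P3 end
  counts[, 3] <- as.integer(choose(deg, 2) - T_v) # o2: P3 middle
  counts[, 4] <- as.integer(T_v)                  # o3: triangle

  ## size 4 by enumeration
  env <- environment()
  visit4 <- function(sub) {
    subA <- A[sub, sub]
    dg <- colSums(subA)
    e <- sum(dg) / 2
    orb <- if (e == 3) {
      if (max(dg) == 3) ifelse(dg == 1, 6L, 7L) else ifelse(dg == 1, 4L, 5L)
    } else if (e == 4) {
      if (max(dg) == 3) c(9L, 10L, 11L)[dg] else rep(8L, 4)
    } else if (e == 5) {
      ifelse(dg == 2, 12L, 13L)
    } else rep(14L, 4)
    idx <- cbind(sub, orb + 1L)
    env$counts[idx] <- env$counts[idx] + 1L
  }
  esu_enumerate(adj, n, 4L, visit4)

  ## size 5 by enumeration with the atlas lookup
  if (max_size == 5) {
    tab <- graphlet5_table()
    visit5 <- function(sub) {
      subA <- A[sub, sub]
      colr <- wl_colors(subA)
      key <- paste0(sum(colSums(subA)) / 2, "|",
                    paste(sort(colr), collapse = ";"))
      orb <- tab$orbit_of[[key]][colr]
      idx <- cbind(sub, orb + 1L)
      env$counts[idx] <- env$counts[idx] + 1L
    }
    esu_enumerate(adj, n, 5L, visit5)
  }
  counts
}

# ESU (FANMOD) enumeration of connected induced k-subgraphs, each
# visited exactly once.
esu_enumerate <- function(adj, n, k, visit) {
  extend <- function(sub, ext, nsub, v) {
    if (length(sub) == k - 1L) {
      for (w in ext) visit(c(sub, w))
      return(invisible())
    }
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      nbw <- adj[[w]]
      excl <- nbw[nbw > v & !(nbw %in% nsub)]
      extend(c(sub, w), c(ext, excl), c(nsub, excl), v)
    }
  }
  for (v in seq_len(n)) {
    nbv <- adj[[v]]
    ext <- nbv[nbv > v]
    if (k == 1L) { visit(v); next }
    if (length(ext) == 0) next
    extend(v, ext, c(v, nbv), v)
  }
  invisible()
}

# Weisfeiler-Lehman colour refinement on a small adjacency matrix;
# two refinement rounds after the degree initialisation, which is
# orbit-exact for connected graphs on <= 5 nodes (asserted when the
# atlas is built).
wl_colors <- function(A) {
  k <- ncol(A)
  col <- sprintf("%d", colSums(A))
  for (r in 1:2) {
    col <- vapply(seq_len(k), function(i) {
      paste0(col[i], "(", paste(sort(col[A[, i]]), collapse = ","), ")")
    }, character(1))
  }
  col
}

# ---- 5-node graphlet atlas -------------------------------------------------
# Built once per session: enumerate all connected graphs on 5 labelled
# nodes, group them into isomorphism classes, find each class's orbits
# by brute force over all 120 vertex permutations, and verify that the
# WL colour signature identifies both the class and the orbit.  Orbit
# ids 15.. are assigned in a deterministic class/colour order.

.graphlet_cache <- new.env(parent = emptyenv())

graphlet5_table <- function() {
  if (!is.null(.graphlet_cache$tab5)) return(.graphlet_cache$tab5)
  perms <- permutations5()
  reps <- list()      # representative adjacency per class
  keys <- character(0)
  orbit_colors <- list()  # per class: colour string per orbit (sorted)
  for (mask in 0:1023) {
    A <- mask_to_adj5(mask)
    if (!connected5(A)) next
    colr <- wl_colors(A)
    key <- paste0(sum(colSums(A)) / 2, "|", paste(sort(colr), collapse = ";"))
    hit <- match(key, keys)
    if (is.na(hit)) {
      # verify against genuine isomorphism: key must be new class
      for (r in seq_along(reps)) {
        if (iso5(A, reps[[r]], perms)) {
          stop("graphlet atlas: WL signature failed to separate classes")
        }
      }
      orbs <- orbits5(A, perms)
      # orbit <-> colour must be one-to-one within the class
      by_orbit <- split(colr, orbs)
      if (any(vapply(by_orbit, function(cc) length(unique(cc)), 1L) != 1L) ||
          length(unique(vapply(by_orbit, `[`, character(1), 1))) !=
            length(by_orbit)) {
        stop("graphlet atlas: WL colours do not match orbits")
      }
      reps[[length(reps) + 1L]] <- A
      keys <- c(keys, key)
      orbit_colors[[length(orbit_colors) + 1L]] <-
        sort(vapply(by_orbit, `[`, character(1), 1))
    } else {
      # same key: must really be isomorphic to the representative
      if (!iso5(A, reps[[hit]], perms)) {
        stop("graphlet atlas: WL signature collision between classes")
      }
    }
  }
  # deterministic global orbit numbering
  ord <- order(keys)
  orbit_of <- new.env(hash = TRUE, parent = emptyenv())
  next_id <- N_ORBITS_4
  for (cl in ord) {
    map <- integer(length(orbit_colors[[cl]]))
    names(map) <- orbit_colors[[cl]]
    for (cname in orbit_colors[[cl]]) {
      map[cname] <- next_id
      next_id <- next_id + 1L
    }
    assign(keys[cl], map, envir = orbit_of)
  }
  .graphlet_cache$tab5 <- list(orbit_of = orbit_of,
                               n_orbits = next_id - N_ORBITS_4,
                               n_classes = length(keys))
  .graphlet_cache$tab5
}

permutations5 <- function() {
  p <- as.matrix(expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5))
  p[apply(p, 1, function(r) length(unique(r)) == 5), , drop = FALSE]
}

mask_to_adj5 <- function(mask) {
  A <- matrix(FALSE, 5, 5)
  P <- t(utils::combn(5, 2))
  on <- bitwAnd(mask, 2^(seq_len(10) - 1)) > 0
  A[P[on, , drop = FALSE]] <- TRUE
  A[P[on, c(2, 1), drop = FALSE]] <- TRUE
  A
}

connected5 <- function(A) {
  seen <- c(TRUE, rep(FALSE, 4))
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(apply(A[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

iso5 <- function(A, B, perms) {
  if (sum(A) != sum(B)) return(FALSE)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(A[p, p] == B)) return(TRUE)
  }
  FALSE
}

# orbit labels (small integers) of the 5 nodes under the automorphism
# group, by brute force
orbits5 <- function(A, perms) {
  orb <- 1:5
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(A[p, p] == A)) {
      # union-find-lite: v and p[v] are in the same orbit
      for (v in 1:5) {
        a <- min(orb[v], orb[p[v]])
        orb[orb == orb[v] | orb == orb[p[v]]] <- a
      }
    }
  }
  match(orb, unique(orb))
}

# ---- GDD profiles and agreement -------------------------------------------

#' Graphlet degree distribution profile
#'
#' For each orbit, the histogram over `k >= 1` of the number of nodes
#' touching that orbit exactly `k` times, scaled by `1/k` and
#' normalised to total mass 1 (so doubling a network by disjoint
#' duplication leaves the profile unchanged).
#'
#' @param counts node x orbit count matrix from [orbit_counts()].
#' @return a list of class `gdd_profile`: per orbit, a named numeric
#'   vector of normalised masses indexed by `k` (empty orbits are
#'   zero-length).
#' @export
gdd_profile <- function(counts) {
  profs <- lapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j]
    v <- v[v >= 1]
    if (length(v) == 0) return(numeric(0))
    tab <- table(v)
    k <- as.numeric(names(tab))
    s <- as.numeric(tab) / k
    stats::setNames(s / sum(s), names(tab))
  })
  names(profs) <- colnames(counts)
  structure(profs, class = "gdd_profile")
}

#' GDD agreement between two networks
#'
#' Per orbit `j`, the agreement is
#' `A_j = 1 - (1/sqrt(2)) * ||N_j^A - N_j^B||_2` over the union support
#' of the two normalised GDD profiles; the overall agreement is the
#' arithmetic (default) or geometric mean over orbits where at least
#' one network has mass.  Ranges from 0 to 1, reaching 1 exactly for
#' identical profiles.
#'
#' @param net_a,net_b two [ppi_network()] objects (nonempty).
#' @param max_size largest graphlet size (4 or 5).
#' @param mean `"arithmetic"` or `"geometric"` mean over orbits.
#' @return scalar agreement in `[0, 1]`, with attributes `"per_orbit"`
#'   (named vector, `NA` for orbits empty in both networks) and
#'   `"orbits_used"`.
#' @export
gdd_agreement <- function(net_a, net_b, max_size = 4,
                          mean = c("arithmetic", "geometric")) {
  mean <- match.arg(mean)
  if (n_edges(net_a) == 0 || n_edges(net_b) == 0) {
    stop("gdd_agreement needs nonempty networks")
  }
  pa <- gdd_profile(orbit_counts(net_a, max_size))
  pb <- gdd_profile(orbit_counts(net_b, max_size))
  per <- vapply(seq_along(pa), function(j) {
    va <- pa[[j]]; vb <- pb[[j]]
    if (length(va) == 0 && length(vb) == 0) return(NA_real_)
    ks <- union(names(va), names(vb))
    da <- stats::setNames(numeric(length(ks)), ks)
    db <- da
    da[names(va)] <- va
    db[names(vb)] <- vb
    max(0, min(1, 1 - sqrt(sum((da - db)^2)) / sqrt(2)))
  }, numeric(1))
  names(per) <- names(pa)
  used <- which(!is.na(per))
  agg <- if (mean == "arithmetic") base::mean(per[used]) else
    exp(base::mean(log(pmax(per[used], .Machine$double.xmin))))
  structure(agg, per_orbit = per, orbits_used = length(used))
}
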