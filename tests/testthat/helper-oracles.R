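# Independent brute-force oracles for the vertex-graph operators. These
# deliberately share no code with the package: adjacency is enumerated
# directly from faces into a plain list, and all set operators are literal
# queue-based BFS translations of their definitions.

# Plain adjacency list straight from the face matrix.
oracle_adjacency <- function(faces, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(faces))) {
    tri <- faces[r, ]
    for (p in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tri[p[1]]; b <- tri[p[2]]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

# Multi-source BFS hop distances (Inf where unreachable).
oracle_bfs_dist <- function(adj, sources) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

oracle_erode <- function(set, adj, depth) {
  n <- length(adj)
  comp <- setdiff(seq_len(n), set)
  if (length(comp) == 0) return(sort(set))
  dist <- oracle_bfs_dist(adj, comp)
  sort(set[dist[set] > depth])
}

oracle_dilate <- function(set, adj, depth) {
  if (length(set) == 0) return(integer(0))
  dist <- oracle_bfs_dist(adj, set)
  which(dist <= depth)
}

oracle_open <- function(set, adj, depth) {
  sort(intersect(oracle_dilate(oracle_erode(set, adj, depth), adj, depth),
                 set))
}

# Components of the subgraph induced by `set`, ordered by smallest member.
oracle_components <- function(set, adj) {
  inset <- logical(length(adj))
  inset[set] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (s in sort(set)) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Small fixture meshes.
tetrahedron <- function() {
  fs_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
             rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

single_triangle <- function() {
  fs_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
             matrix(c(1, 2, 3), 1))
}

# A random blob: BFS ball of random radius around a random centre, plus
# random sprinkles -- exercises both compact and ragged sets.
random_vertex_set <- function(adj, p_sprinkle = 0.05) {
  n <- length(adj)
  ctr <- sample.int(n, 1)
  r <- sample(2:6, 1)
  ball <- which(oracle_bfs_dist(adj, ctr) <= r)
  extra <- which(stats::runif(n) < p_sprinkle)
  sort(unique(c(ball, extra)))
}
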