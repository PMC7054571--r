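# Vertex-graph operators against brute-force BFS oracles, and discrete
# geometry against closed forms.

test_that("adjacency equals the mesh edge relation", {
  tri <- single_triangle()
  g <- build_adjacency(tri)
  expect_equal(nrow(g$edges), 3)

  tet <- tetrahedron()
  gt <- build_adjacency(tet)
  expect_equal(nrow(gt$edges), 6)  # complete graph on 4 vertices

  grid <- grid_surface(10, 10)
  gg <- build_adjacency(grid)
  adj <- oracle_adjacency(grid$faces, 100)
  # interior vertices of the split-quad triangulation have degree 6
  interior <- setdiff(1:100, boundary <- c(1:10, 91:100, seq(1, 91, 10),
                                           seq(10, 100, 10)))
  degrees <- tabulate(c(gg$edges), nbins = 100)
  expect_true(all(degrees[interior] == 6))
  # full relation matches the brute-force enumeration
  for (v in c(1, 5, 10, 35, 55, 100))
    expect_identical(sort(which(as.vector(gg$adjacency[v, ]))), adj[[v]])
})

test_that("connected components match the BFS oracle and order deterministically", {
  grid <- grid_surface(15, 15)
  g <- build_adjacency(grid)
  adj <- oracle_adjacency(grid$faces, g$n)
  expect_identical(connected_components(integer(0), g), list())
  set.seed(11)
  for (i in 1:20) {
    set <- random_vertex_set(adj)
    got <- connected_components(set, g)
    want <- oracle_components(set, adj)
    expect_identical(got, want)
    expect_identical(order(vapply(got, min, integer(1))),
                     seq_along(got))  # sorted by smallest member
  }
})

test_that("erosion, dilation and opening match the literal BFS oracle", {
  grid <- grid_surface(15, 15)
  g <- build_adjacency(grid)
  adj <- oracle_adjacency(grid$faces, g$n)
  set.seed(12)
  for (i in 1:10) {
    set <- random_vertex_set(adj)
    for (depth in 1:3) {
      expect_identical(erode_vertices(set, g, depth),
                       oracle_erode(set, adj, depth))
      expect_identical(dilate_vertices(set, g, depth),
                       oracle_dilate(set, adj, depth))
      expect_identical(morphological_open(set, g, depth),
                       oracle_open(set, adj, depth))
    }
  }
  expect_identical(morphological_open(integer(0), g, 3), integer(0))
  expect_error(morphological_open(1:5, g, 0), "positive")
})

test_that("opening is anti-extensive, increasing and idempotent", {
  grid <- grid_surface(20, 20)
  g <- build_adjacency(grid)
  adj <- oracle_adjacency(grid$faces, g$n)
  set.seed(13)
  for (i in 1:10) {
    s <- random_vertex_set(adj)
    o <- morphological_open(s, g, 3)
    expect_true(all(o %in% s))                       # anti-extensive
    expect_identical(morphological_open(o, g, 3), o)  # idempotent
    s_big <- sort(union(s, random_vertex_set(adj)))
    expect_true(all(o %in% morphological_open(s_big, g, 3)))  # increasing
  }
})

test_that("opening at depth 3 kills width-6 strips but keeps wide blobs", {
  # disk of graph-radius 10 with a 6-vertex-wide strip attached to its rim
  grid <- grid_surface(40, 30)
  g <- build_adjacency(grid)
  adj <- oracle_adjacency(grid$faces, g$n)
  ctr <- which.min(rowSums(sweep(grid$coords[, 1:2], 2, c(12, 15))^2))
  disk <- which(oracle_bfs_dist(adj, ctr) <= 10)
  strip <- which(grid$coords[, 2] >= 12 & grid$coords[, 2] <= 17 &
                   grid$coords[, 1] >= 22 & grid$coords[, 1] <= 39)
  stopifnot(length(setdiff(strip, disk)) > 50)
  opened <- morphological_open(union(disk, strip), g, 3)
  expect_length(intersect(opened, setdiff(strip, disk)), 0)
  expect_gte(length(intersect(opened, disk)) / length(disk), 0.99)
})

test_that("region growing equals components-of-allowed filtered by seeds", {
  grid <- grid_surface(15, 15)
  g <- build_adjacency(grid)
  adj <- oracle_adjacency(grid$faces, g$n)
  expect_identical(region_grow(integer(0), 1:20, g), integer(0))
  expect_identical(region_grow(1:20, 1:20, g), 1:20)
  expect_error(region_grow(c(1, 50), 1:20, g), "within the allowed")
  set.seed(14)
  for (i in 1:10) {
    allowed <- random_vertex_set(adj)
    seeds <- sample(allowed, max(1, length(allowed) %/% 10))
    got <- region_grow(seeds, allowed, g)
    comps <- oracle_components(allowed, adj)
    want <- sort(unlist(comps[vapply(comps, function(c)
      any(seeds %in% c), logical(1))]))
    expect_identical(got, as.integer(want))
    # closed under adjacency within allowed, contains seeds
    expect_true(all(seeds %in% got))
    nb <- unique(unlist(adj[got]))
    expect_length(setdiff(intersect(nb, allowed), got), 0)
  }
})

test_that("vertex areas are exact on analytic fixtures and conserved", {
  tri <- single_triangle()  # right triangle, legs 1: area 1/2
  a <- field_values(vertex_areas(tri))
  expect_equal(a, rep(1 / 6, 3))

  ico <- icosphere(10, 4)
  expect_equal(sum(field_values(vertex_areas(ico))), 4 * pi * 100,
               tolerance = 0.01)

  set.seed(15)
  bumpy <- grid_surface(12, 12, height = rnorm(144))
  av <- field_values(vertex_areas(bumpy))
  fg <- bumpy$coords
  f <- bumpy$faces
  tot <- sum(vapply(seq_len(nrow(f)), function(r) {
    e1 <- fg[f[r, 2], ] - fg[f[r, 1], ]; e2 <- fg[f[r, 3], ] - fg[f[r, 1], ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    0.5 * sqrt(sum(cr^2))
  }, numeric(1)))
  expect_equal(sum(av), tot, tolerance = 1e-12)
})

test_that("discrete curvatures match sphere and plane closed forms", {
  flat <- grid_surface(15, 15)
  cv <- discrete_curvatures(flat)
  interior <- setdiff(1:225, c(1:15, 211:225, seq(1, 211, 15),
                               seq(15, 225, 15)))
  expect_lt(max(abs(field_values(cv$mean)[interior])), 1e-10)
  expect_lt(max(abs(field_values(cv$gaussian)[interior])), 1e-10)

  ico <- icosphere(10, 3)
  cvi <- discrete_curvatures(ico)
  expect_equal(mean(field_values(cvi$mean)), -0.1, tolerance = 0.05)
  expect_equal(mean(field_values(cvi$gaussian)), 0.01, tolerance = 0.05)
  # Gauss-Bonnet on the closed sphere: sum K a = 4 pi
  a <- field_values(vertex_areas(ico))
  expect_equal(sum(field_values(cvi$gaussian) * a), 4 * pi,
               tolerance = 0.01)
})

test_that("mean curvature is negative on ridge crests, positive in valleys", {
  sub <- synth_subject(synth_spec("fpd", seed = 2))
  cv <- field_values(sub$curv)
  expect_true(all(cv[sub$truth$crest1] < 0))
  expect_true(all(cv[sub$truth$crest2] < 0))
  # the separating sulcus floor between the two ridges is concave
  fl <- hgseg:::synth_fields(sub$spec)
  floor <- which(abs(fl$s1 + fl$s2) < 0.5 & fl$x > 5 & fl$x < 55)
  expect_true(mean(cv[floor] > 0) > 0.95)
})

test_that("weighted centroid equals the direct weighted-mean oracle", {
  grid <- grid_surface(10, 10, height = 0.3)
  expect_equal(weighted_centroid(7, grid), grid$coords[7, ])
  a <- vertex_areas(grid)
  set.seed(16)
  set <- sample(100, 30)
  got <- weighted_centroid(set, grid, a)
  av <- field_values(a)[set]
  want <- colSums(grid$coords[set, ] * av) / sum(av)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(weighted_centroid(integer(0), grid), "empty")
  # symmetric set about the patch centre has a central centroid
  sym <- which(abs(grid$coords[, 1] - 4.5) <= 1.5 &
                 abs(grid$coords[, 2] - 4.5) <= 2.5)
  expect_equal(weighted_centroid(sym, grid)[1:2], c(4.5, 4.5),
               tolerance = 1e-9)
})
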