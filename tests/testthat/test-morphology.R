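test_that("read_swc preserves geometry and topology", {
  m <- read_swc(swc_simple())
  # one dendritic section beyond the soma root
  expect_length(m$sections, 2L)
  dend <- m$sections[[2]]
  seg <- sqrt(rowSums(diff(dend$points)^2))
  expect_equal(seg, c(10, 5), ignore_attr = TRUE)   # inter-point distances
  expect_equal(dend$radii[-1], c(1, 0.5), ignore_attr = TRUE)

  mb <- read_swc(swc_branched())
  # two children of the root: branch point at the soma
  parents <- vapply(mb$sections, function(s)
    if (is.na(s$parent)) -1L else s$parent, integer(1))
  expect_equal(sum(parents == 1L), 2L)
})

test_that("read_swc rejects malformed input", {
  bad <- write_swc_fixture(c("1 1 0 0 0 2 -1", "2 3 10 0 0 1"))
  expect_error(read_swc(bad), "line 2")
  nonnum <- write_swc_fixture(c("1 1 0 0 0 2 -1", "2 3 x 0 0 1 1"))
  expect_error(read_swc(nonnum), "line 2")
})

test_that("write_swc / read_swc round-trips coordinates and radii", {
  m <- read_swc(swc_branched())
  out <- tempfile(fileext = ".swc")
  write_swc(m, out)
  m2 <- read_swc(out)
  expect_length(m2$sections, length(m$sections))
  pts <- function(mm) do.call(rbind, lapply(mm$sections, `[[`, "points"))
  rad <- function(mm) unlist(lapply(mm$sections, `[[`, "radii"))
  expect_equal(pts(m2), pts(m), tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(rad(m2), rad(m), tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("radius correction divides radii and composes", {
  m <- read_swc(swc_simple())
  m2 <- apply_radius_correction(m, 2)
  expect_equal(m2$sections[[2]]$radii, m$sections[[2]]$radii / 2)
  m1 <- apply_radius_correction(m, 1)
  expect_identical(m1$sections, m$sections)
  m4 <- apply_radius_correction(apply_radius_correction(m, 2), 2)
  expect_equal(m4$sections[[2]]$radii, m$sections[[2]]$radii / 4)
  expect_error(apply_radius_correction(m, 0), "positive")
  expect_error(apply_radius_correction(m, -1), "positive")
})

test_that("star SAC generator meets its geometric contract", {
  m <- generate_star_sac(n_primary = 6L, total_extent = 210,
                         branch_orders = 2L, rng_seed = 1L)
  tips <- retsim:::morphology_tips(m)
  expect_length(tips$section, 6L * (1L + 2L))       # 18 terminal tips
  expect_true(all(abs(tips$dist - 210) <= 1))
  # determinism
  m2 <- generate_star_sac(n_primary = 6L, total_extent = 210,
                          branch_orders = 2L, rng_seed = 1L)
  expect_identical(m, m2)
  # 60-degree rotational symmetry: rotating all points maps the point cloud
  # onto itself
  pts <- do.call(rbind, lapply(m$sections, `[[`, "points"))[, 1:2]
  th <- pi / 3
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  d <- vapply(seq_len(nrow(rot)), function(i)
    min(sqrt(colSums((t(pts) - rot[i, ])^2))), numeric(1))
  expect_lt(max(d), 1e-6)
  expect_error(generate_star_sac(n_primary = 2L), "at least 3")
})

test_that("discretization respects segment length and conserves area", {
  m <- cable_morphology(length_um = 70, radius_um = 1)
  tr <- discretize(m, 7)
  expect_equal(sum(!tr$is_soma), 10L)               # 70 / 7
  expect_true(all(tr$length <= 7 + 1e-9))
  # membrane area conserved relative to the frustum sum of the morphology
  for (seg in c(7, 3, 1.3)) {
    tt <- discretize(m, seg)
    expect_equal(sum(tt$area_cm2) * 1e8, retsim:::morphology_area(m),
                 tolerance = 1e-3)
  }
  # halving the segment cap never decreases the compartment count
  n <- vapply(c(14, 7, 3.5, 1.75), function(s) nrow(discretize(m, s)),
              numeric(1))
  expect_true(all(diff(n) >= 0))
})

test_that("path distances accumulate from the soma outward", {
  m <- generate_star_sac()
  tr <- discretize(m)
  expect_equal(path_distance(tr, 1L), 0)            # soma
  # every tip compartment sits at the full extent
  tip <- which(!(tr$comp %in% tr$parent))
  expect_true(all(abs(tr$path_dist[tip] - 210) <= 1))
  # non-decreasing along every root-to-tip path
  for (i in tip) {
    j <- i
    while (!is.na(tr$parent[j])) {
      expect_gte(tr$path_dist[j], tr$path_dist[tr$parent[j]])
      j <- tr$parent[j]
    }
  }
  expect_error(path_distance(tr, nrow(tr) + 1L), "unknown")
})
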