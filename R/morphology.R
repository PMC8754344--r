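#' @useDynLib retsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rnorm runif rpois sd coef lm approx setNames
#' @importFrom utils tail
NULL

# ---------------------------------------------------------------------------
# Morphology container
#
# A morphology is a connected tree of sections rooted at the soma.  Each
# section is an unbranched run of 3-D sample points with a radius per point;
# its first point duplicates the attachment point on the parent so that arc
# length along the section includes the connecting segment.  The soma is a
# single root section: an equivalent-area cylinder oriented along z so that
# planar (x-y) geometry is untouched.
# ---------------------------------------------------------------------------

new_morphology <- function(sections, soma_center, cell_kind = "SAC") {
  stopifnot(length(sections) >= 1L)
  m <- structure(list(sections = sections,
                      soma_center = as.numeric(soma_center),
                      cell_kind = match.arg(cell_kind, c("SAC", "DSGC"))),
                 class = "morphology")
  validate_morphology(m)
}

validate_morphology <- function(m) {
  ids <- vapply(m$sections, function(s) s$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate section ids")
  for (s in m$sections) {
    if (nrow(s$points) < 2L) stop("section ", s$id, " has fewer than 2 points")
    if (any(s$radii <= 0)) stop("non-positive radius in section ", s$id)
    d <- sqrt(rowSums(diff(s$points)^2))
    if (any(d <= 0)) stop("zero-length segment in section ", s$id)
    if (!is.na(s$parent) && !(s$parent %in% ids))
      stop("section ", s$id, " has unknown parent ", s$parent)
  }
  roots <- sum(vapply(m$sections, function(s) is.na(s$parent), logical(1)))
  if (roots != 1L) stop("morphology must have exactly one root section")
  m
}

#' Read a neuronal morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (index, type, x, y, z, radius,
#' parent; 1-based indices, -1 for the root).  Soma samples (type 1) are
#' collapsed to a single equivalent-area cylindrical root section; all other
#' samples become unbranched sections split at branch points.
#'
#' @param path path to an SWC file.
#' @param cell_kind `"SAC"` or `"DSGC"`; metadata only.
#' @return an object of class `morphology`.
#' @export
read_swc <- function(path, cell_kind = "SAC") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(raw), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1]], ": expected 7 columns")
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 7L, byrow = TRUE)
  if (anyNA(tab)) {
    bad <- which(apply(tab, 1L, anyNA))[1]
    stop("malformed SWC line ", lineno[bad], ": non-numeric field")
  }
  colnames(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  id <- as.integer(tab[, "id"]); parent <- as.integer(tab[, "parent"])
  idx <- match(parent, id)                 # row index of each point's parent
  if (any(parent != -1L & is.na(idx)))
    stop("SWC parent index refers to a missing sample")
  # cycle check by walking to root from every node
  for (i in seq_along(id)) {
    seen <- 0L; j <- i
    while (!is.na(j) && parent[j] != -1L) {
      j <- idx[j]; seen <- seen + 1L
      if (seen > length(id)) stop("cyclic parent links in SWC file")
    }
  }
  is_soma <- tab[, "type"] == 1
  if (!any(is_soma)) {
    # no explicit soma: treat the root sample as the soma
    is_soma <- parent == -1L
  }
  soma_rows <- which(is_soma)
  soma_center <- colMeans(tab[soma_rows, c("x", "y", "z"), drop = FALSE])
  soma_r <- max(tab[soma_rows, "radius"])

  sections <- list(list(id = 1L, parent = NA_integer_,
                        points = rbind(soma_center - c(0, 0, soma_r),
                                       soma_center + c(0, 0, soma_r)),
                        radii = c(soma_r, soma_r)))
  # section id carried per SWC sample once assigned
  sec_of <- integer(length(id))
  sec_of[soma_rows] <- 1L
  children <- split(seq_along(id), factor(idx, levels = seq_along(id)))
  n_children <- lengths(children)
  # section start rows: non-soma whose parent is soma or a branch point
  starts <- which(!is_soma &
                  (is.na(idx) | is_soma[idx] | n_children[idx] > 1L))
  next_id <- 2L
  for (s0 in starts) {
    pr <- idx[s0]
    if (is.na(pr) || is_soma[pr]) {
      psec <- 1L
      p0 <- soma_center
      r0 <- tab[s0, "radius"]          # do not let soma radius leak distally
    } else {
      psec <- sec_of[pr]
      p0 <- tab[pr, c("x", "y", "z")]
      r0 <- tab[pr, "radius"]
    }
    chain <- s0
    while (n_children[tail(chain, 1L)] == 1L) {
      nxt <- children[[tail(chain, 1L)]]
      if (is_soma[nxt]) break
      chain <- c(chain, nxt)
    }
    sec_of[chain] <- next_id
    sections[[next_id]] <- list(
      id = next_id, parent = psec,
      points = rbind(p0, tab[chain, c("x", "y", "z"), drop = FALSE]),
      radii = c(r0, tab[chain, "radius"]))
    next_id <- next_id + 1L
  }
  # continue sections that start at a branch point deeper in the tree: the
  # `starts` rule above already covers them (parent has >1 children).
  new_morphology(sections, soma_center, cell_kind)
}

#' Write a morphology to an SWC file
#'
#' The soma root section is written as a single type-1 sample at the soma
#' center; dendritic sections are written as type-3 samples.  Reading the
#' result back reproduces coordinates and radii.
#'
#' @param m a `morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  root <- which(vapply(m$sections, function(s) is.na(s$parent), logical(1)))
  soma_r <- m$sections[[root]]$radii[1]
  rows <- list(c(1, 1, m$soma_center, soma_r, -1))
  last_of_sec <- c(1L)                       # swc id of last sample, by section
  names(last_of_sec) <- as.character(m$sections[[root]]$id)
  nid <- 2L
  # emit in an order where parents precede children
  done <- m$sections[[root]]$id
  todo <- m$sections[!vapply(m$sections, function(s) is.na(s$parent), logical(1))]
  while (length(todo)) {
    ready <- vapply(todo, function(s) s$parent %in% done, logical(1))
    for (s in todo[ready]) {
      pid <- last_of_sec[[as.character(s$parent)]]
      for (k in 2:nrow(s$points)) {
        rows[[length(rows) + 1L]] <- c(nid, 3, s$points[k, ], s$radii[k], pid)
        pid <- nid
        nid <- nid + 1L
      }
      last_of_sec[[as.character(s$id)]] <- pid
      done <- c(done, s$id)
    }
    todo <- todo[!ready]
  }
  tab <- do.call(rbind, rows)
  writeLines(apply(tab, 1L, function(r)
    sprintf("%d %d %.6f %.6f %.6f %.6f %d", r[1], r[2], r[3], r[4], r[5],
            r[6], r[7])), path)
  invisible(path)
}

#' Scale all section radii by a correction factor
#'
#' Reconstruction pipelines can mislabel process calibers; this hook divides
#' every radius by `factor` (so `factor = 2` halves all radii), leaving
#' topology and coordinates untouched.
#'
#' @param m a `morphology`.
#' @param factor positive divisor applied to every radius.
#' @return the corrected `morphology`.
#' @export
apply_radius_correction <- function(m, factor) {
  stopifnot(inherits(m, "morphology"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("radius correction factor must be a positive number")
  m$sections <- lapply(m$sections, function(s) {
    s$radii <- s$radii / factor
    s
  })
  m
}

#' Generate a synthetic planar starburst-like morphology
#'
#' Builds a rotationally symmetric tree of `n_primary` radial processes in
#' the z = 0 plane.  Each primary process bifurcates `branch_orders` times at
#' equally spaced path distances; at each bifurcation one daughter continues
#' outward and the other runs straight to a tip, so every primary carries
#' `branch_orders + 1` terminal tips, all at path distance `total_extent`
#' from the soma.  Radii taper linearly from `radius_proximal` at the soma to
#' `radius_distal` at the tips.
#'
#' @param n_primary number of primary processes (at least 3).
#' @param total_extent soma-to-tip path length, micrometres.
#' @param branch_orders bifurcations per primary process.
#' @param rng_seed seed for the optional angular jitter (the default jitter
#'   of 0 makes the cell exactly rotationally symmetric).
#' @param jitter_deg s.d. of angular jitter applied to branch angles, degrees.
#' @param branch_angle_deg deviation of the side daughter at each bifurcation.
#' @param soma_radius soma radius, micrometres.
#' @param radius_proximal,radius_distal process radii at soma and tip.
#' @param cell_kind `"SAC"` or `"DSGC"`.
#' @return a `morphology`.
#' @export
generate_star_sac <- function(n_primary = 6L, total_extent = 210,
                              branch_orders = 2L, rng_seed = 1L,
                              jitter_deg = 0, branch_angle_deg = 16,
                              soma_radius = 5, radius_proximal = 0.5,
                              radius_distal = 0.2, cell_kind = "SAC") {
  if (n_primary < 3L) stop("n_primary must be at least 3")
  if (total_extent <= 0) stop("total_extent must be positive")
  rng <- local({ set.seed(rng_seed); NULL })
  jit <- function() if (jitter_deg > 0) rnorm(1L, 0, jitter_deg * pi / 180) else 0
  rad_at <- function(d)
    radius_proximal + (radius_distal - radius_proximal) * d / total_extent
  seg_pts <- function(p0, ang, d0, d1) {
    # straight run from path distance d0 to d1 in direction ang, sampled so
    # that no inter-point gap exceeds 10 um (keeps radii piecewise-linear on
    # a fine grid for plotting; discretization interpolates anyway)
    len <- d1 - d0
    n <- max(1L, ceiling(len / 10))
    t <- seq(0, len, length.out = n + 1L)
    pts <- cbind(p0[1] + t * cos(ang), p0[2] + t * sin(ang), 0)
    list(points = pts, radii = rad_at(d0 + t))
  }
  sections <- list(list(id = 1L, parent = NA_integer_,
                        points = rbind(c(0, 0, -soma_radius),
                                       c(0, 0, soma_radius)),
                        radii = c(soma_radius, soma_radius)))
  next_id <- 2L
  bif <- total_extent * seq_len(branch_orders) / (branch_orders + 1L)
  dev <- branch_angle_deg * pi / 180
  for (i in seq_len(n_primary)) {
    ang <- 2 * pi * (i - 1L) / n_primary + jit()
    p <- c(0, 0); d <- 0; parent <- 1L
    for (b in seq_len(branch_orders)) {
      sp <- seg_pts(p, ang, d, bif[b])
      sections[[next_id]] <- list(id = next_id, parent = parent,
                                  points = sp$points, radii = sp$radii)
      parent <- next_id; next_id <- next_id + 1L
      p <- sp$points[nrow(sp$points), 1:2]; d <- bif[b]
      # side daughter straight to tip
      side <- seg_pts(p, ang + dev + jit(), d, total_extent)
      sections[[next_id]] <- list(id = next_id, parent = parent,
                                  points = side$points, radii = side$radii)
      next_id <- next_id + 1L
      ang <- ang - dev / (branch_orders + 1L)   # continuing daughter bends back
    }
    fin <- seg_pts(p, ang, d, total_extent)
    sections[[next_id]] <- list(id = next_id, parent = parent,
                                points = fin$points, radii = fin$radii)
    next_id <- next_id + 1L
  }
  new_morphology(sections, c(0, 0, 0), cell_kind)
}

#' Generate a synthetic planar ganglion-cell morphology
#'
#' Convenience wrapper around [generate_star_sac()] with defaults emulating a
#' planar direction-selective ganglion cell dendritic field.
#'
#' @inheritParams generate_star_sac
#' @export
generate_star_dsgc <- function(n_primary = 8L, total_extent = 150,
                               branch_orders = 2L, rng_seed = 1L, ...) {
  generate_star_sac(n_primary = n_primary, total_extent = total_extent,
                    branch_orders = branch_orders, rng_seed = rng_seed,
                    soma_radius = 8, radius_proximal = 0.8,
                    radius_distal = 0.3, cell_kind = "DSGC", ...)
}

# frustum (slant) lateral area of the whole morphology, um^2
morphology_area <- function(m) {
  sum(vapply(m$sections, function(s) {
    seg <- sqrt(rowSums(diff(s$points)^2))
    r <- s$radii
    sum(pi * (r[-length(r)] + r[-1]) *
          sqrt(seg^2 + diff(r)^2))
  }, numeric(1)))
}

#' Discretize a morphology into electrical compartments
#'
#' Splits every section into compartments of length at most `max_seg_len`.
#' Compartment nodes sit at the distal boundary of each compartment; the
#' soma section maps to the single root compartment with path distance 0.
#' Frustum membrane area is conserved exactly (sub-interval frusta are
#' additive under a piecewise-linear radius profile).
#'
#' @param m a `morphology`.
#' @param max_seg_len maximal compartment length, micrometres (default 7).
#' @return a `compartment_tree`: a data frame with one row per compartment
#'   (planar position, length, mid radius, membrane area in cm^2, path
#'   distance to the soma in micrometres, parent index) plus attributes.
#' @export
discretize <- function(m, max_seg_len = 7) {
  stopifnot(inherits(m, "morphology"))
  if (max_seg_len <= 0) stop("max_seg_len must be positive")
  root <- which(vapply(m$sections, function(s) is.na(s$parent), logical(1)))
  rows <- list()
  # root/soma compartment
  soma <- m$sections[[root]]
  soma_len <- sum(sqrt(rowSums(diff(soma$points)^2)))
  soma_area <- pi * (soma$radii[1] + soma$radii[2]) *
    sqrt(soma_len^2 + diff(range(soma$radii))^2)
  rows[[1]] <- data.frame(parent = NA_integer_,
                          x = m$soma_center[1], y = m$soma_center[2], z = 0,
                          length = soma_len, r_mid = soma$radii[1],
                          area_cm2 = soma_area * 1e-8, path_dist = 0,
                          section = soma$id, is_soma = TRUE)
  last_comp <- setNames(1L, as.character(soma$id))
  base_path <- setNames(0, as.character(soma$id))
  done <- soma$id
  todo <- m$sections[-root]
  while (length(todo)) {
    ready <- vapply(todo, function(s) s$parent %in% done, logical(1))
    if (!any(ready)) stop("section graph is not a tree")
    for (s in todo[ready]) {
      seg <- sqrt(rowSums(diff(s$points)^2))
      cum <- c(0, cumsum(seg))
      len <- cum[length(cum)]
      n <- max(1L, ceiling(len / max_seg_len))
      bnd <- len * (0:n) / n
      pos <- apply(s$points, 2L, function(v) approx(cum, v, xout = bnd)$y)
      rad <- approx(cum, s$radii, xout = bnd)$y
      parent <- last_comp[[as.character(s$parent)]]
      p0 <- base_path[[as.character(s$parent)]]
      for (k in seq_len(n)) {
        # exact frustum area over [bnd[k], bnd[k+1]] via original samples
        a <- frustum_area_interval(cum, s$radii, bnd[k], bnd[k + 1L])
        rows[[length(rows) + 1L]] <- data.frame(
          parent = parent,
          x = pos[k + 1L, 1L], y = pos[k + 1L, 2L], z = pos[k + 1L, 3L],
          length = bnd[k + 1L] - bnd[k],
          r_mid = approx(cum, s$radii, xout = (bnd[k] + bnd[k + 1L]) / 2)$y,
          area_cm2 = a * 1e-8,
          path_dist = p0 + bnd[k + 1L],
          section = s$id, is_soma = FALSE)
        parent <- length(rows)
      }
      last_comp[[as.character(s$id)]] <- length(rows)
      base_path[[as.character(s$id)]] <- p0 + len
      done <- c(done, s$id)
    }
    todo <- todo[!ready]
  }
  tree <- do.call(rbind, rows)
  tree$comp <- seq_len(nrow(tree))
  rownames(tree) <- NULL
  structure(tree, class = c("compartment_tree", "data.frame"),
            cell_kind = m$cell_kind, soma_center = m$soma_center,
            max_extent = max(tree$path_dist), max_seg_len = max_seg_len)
}

# lateral frustum area of a piecewise-linear radius profile over [a, b]
frustum_area_interval <- function(cum, radii, a, b) {
  total <- 0
  for (i in seq_len(length(cum) - 1L)) {
    lo <- max(a, cum[i]); hi <- min(b, cum[i + 1L])
    if (hi <= lo) next
    L <- cum[i + 1L] - cum[i]
    r_lo <- radii[i] + (radii[i + 1L] - radii[i]) * (lo - cum[i]) / L
    r_hi <- radii[i] + (radii[i + 1L] - radii[i]) * (hi - cum[i]) / L
    total <- total + pi * (r_lo + r_hi) * sqrt((hi - lo)^2 + (r_hi - r_lo)^2)
  }
  total
}

#' Path distance from the soma to a compartment
#'
#' @param tree a `compartment_tree`.
#' @param comp compartment index (row).
#' @return path distance along the tree in micrometres; 0 for the soma.
#' @export
path_distance <- function(tree, comp) {
  stopifnot(inherits(tree, "compartment_tree"))
  if (any(comp < 1L | comp > nrow(tree)))
    stop("unknown compartment id")
  tree$path_dist[comp]
}

#' @export
print.morphology <- function(x, ...) {
  n <- length(x$sections)
  tips <- morphology_tips(x)
  cat(sprintf("<morphology: %s, %d sections, %d tips, max path %.1f um>\n",
              x$cell_kind, n, length(tips$section),
              if (length(tips$dist)) max(tips$dist) else 0))
  invisible(x)
}

# terminal sections and their soma-to-tip path distances
morphology_tips <- function(m) {
  ids <- vapply(m$sections, function(s) s$id, integer(1))
  parents <- vapply(m$sections, function(s)
    if (is.na(s$parent)) -1L else s$parent, integer(1))
  is_tip <- !(ids %in% parents) & parents != -1L
  lens <- vapply(m$sections, function(s)
    sum(sqrt(rowSums(diff(s$points)^2))), numeric(1))
  path_to <- function(i) {
    d <- 0
    while (parents[i] != -1L) {
      d <- d + lens[i]
      i <- match(parents[i], ids)
    }
    d
  }
  tip_idx <- which(is_tip)
  list(section = ids[tip_idx], dist = vapply(tip_idx, path_to, numeric(1)))
}

#' @export
print.compartment_tree <- function(x, ...) {
  cat(sprintf(
    "<compartment_tree: %s, %d compartments, extent %.1f um, area %.1f um^2>\n",
    attr(x, "cell_kind"), nrow(x), attr(x, "max_extent"),
    sum(x$area_cm2) * 1e8))
  invisible(x)
}

#' @export
plot.morphology <- function(x, ...) {
  xy <- do.call(rbind, lapply(x$sections, function(s) rbind(s$points[, 1:2], NA)))
  graphics::plot(xy, type = "l", asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  graphics::points(x$soma_center[1], x$soma_center[2], pch = 16)
  invisible(x)
}
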