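# Parametric simplified 2D head geometries and conforming meshes.
#
# Both species are built from a common template: a quad "butterfly" core
# inside the brain ellipse, conforming elliptical ring shells outward
# through the remaining tissue layers, and mapped wedge blocks (beak /
# face / neck) attached to outer-boundary nodes. Region interfaces always
# coincide with grid lines, so region areas are exact to the polygonal
# approximation of the ellipses and feature ablation is a pure relabel
# with bit-identical node and connectivity arrays.

ellipse_point <- function(a, b, phi) cbind(a * cos(phi), b * sin(phi))

# Ramanujan approximation, plenty for sizing decisions
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# ---------------------------------------------------------------------------
# generic shell + wedge mesh builder
#
# shells: list of list(a, b, region, label_fn = NULL, sub = NULL)
#   shell 1 is the innermost full ellipse (meshed with the butterfly core),
#   shell k >= 2 the annulus between ellipse k-1 and ellipse k. label_fn,
#   if given, maps element centroid parametric angle -> region label.
# wedges: list of list(type = "taper"|"extrude", phi_center, phi_half,
#   length, region, taper_to (for extrude: bottom y and width factor))
build_shell_mesh <- function(shells, wedges, element_size, species) {
  e <- element_size
  a1 <- shells[[1]]$a; b1 <- shells[[1]]$b
  for (k in seq_along(shells)[-1]) {
    th <- ((shells[[k]]$a - shells[[k - 1]]$a) +
           (shells[[k]]$b - shells[[k - 1]]$b)) / 2
    th_chk <- if (!is.null(shells[[k]]$check_th)) shells[[k]]$check_th else th
    if (e > 2.5 * th_chk)
      stop("element_size too coarse to resolve region '",
           shells[[k]]$region, "'")
  }
  n_theta <- 8L * max(3L, as.integer(round(ellipse_perimeter(a1, b1) / (8 * e))))
  nq <- n_theta / 4L
  phi <- pi / 4 + 2 * pi * (0:(n_theta - 1)) / n_theta

  nodes <- matrix(0, 0, 2)
  add_nodes <- function(xy) {
    i0 <- nrow(nodes)
    nodes <<- rbind(nodes, xy)
    (i0 + 1):nrow(nodes)
  }
  quads <- matrix(0L, 0, 4); quad_region <- character(0)
  tris <- matrix(0L, 0, 3); tri_region <- character(0)

  # --- butterfly core -------------------------------------------------------
  rho0 <- 0.45
  # core half-widths strictly inside the rho0 ring so the corner
  # transition quads keep positive width
  ax <- 0.5 * rho0 * a1; by <- 0.5 * rho0 * b1
  gx <- seq(-ax, ax, length.out = nq + 1)
  gy <- seq(-by, by, length.out = nq + 1)
  core_id <- matrix(add_nodes(cbind(rep(gx, times = nq + 1),
                                    rep(gy, each = nq + 1))),
                    nrow = nq + 1)          # core_id[i+1, j+1], i over x, j over y
  for (j in 1:nq) for (i in 1:nq) {
    quads <- rbind(quads, c(core_id[i, j], core_id[i + 1, j],
                            core_id[i + 1, j + 1], core_id[i, j + 1]))
    quad_region <- c(quad_region, shells[[1]]$region)
  }
  # core perimeter CCW starting at corner (+ax, +by) = parametric angle 45 deg
  perim <- c(core_id[seq(nq + 1, 1), nq + 1],          # top edge, x decreasing
             core_id[1, seq(nq, 1)],                   # left edge, y decreasing
             core_id[seq(2, nq + 1), 1],               # bottom edge, x increasing
             core_id[nq + 1, seq(2, nq)])              # right edge, y increasing
  stopifnot(length(perim) == n_theta)

  # --- transition from core to the rho0 ellipse ring ------------------------
  ring0_xy <- rho0 * ellipse_point(a1, b1, phi)
  perim_xy <- nodes[perim, , drop = FALSE]
  nt <- max(1L, as.integer(round(0.35 * rho0 * b1 / e)))
  prev_ring <- perim
  for (t in 1:nt) {
    s <- t / nt
    ring <- add_nodes((1 - s) * perim_xy + s * ring0_xy)
    for (j in 1:n_theta) {
      jp <- if (j == n_theta) 1L else j + 1L
      quads <- rbind(quads, c(prev_ring[j], ring[j], ring[jp], prev_ring[jp]))
      quad_region <- c(quad_region, shells[[1]]$region)
    }
    prev_ring <- ring
  }

  # --- ring stack through shells -------------------------------------------
  phi_mid <- phi + pi / n_theta   # centroid parametric angle of ring sector j
  push_rings <- function(from_xy, to_xy, n_layers, region, label_fn) {
    for (t in 1:n_layers) {
      s <- t / n_layers
      ring <- add_nodes((1 - s) * from_xy + s * to_xy)
      for (j in 1:n_theta) {
        jp <- if (j == n_theta) 1L else j + 1L
        quads <<- rbind(quads, c(prev_ring[j], ring[j], ring[jp], prev_ring[jp]))
        rg <- if (is.null(label_fn)) region else label_fn(phi_mid[j])
        quad_region <<- c(quad_region, rg)
      }
      prev_ring <<- ring
    }
  }
  cur_xy <- ring0_xy
  edge1_xy <- ellipse_point(a1, b1, phi)
  n1 <- max(1L, as.integer(round((1 - rho0) * (a1 + b1) / 2 / e)))
  push_rings(cur_xy, edge1_xy, n1, shells[[1]]$region, shells[[1]]$label_fn)
  cur_xy <- edge1_xy
  for (k in seq_along(shells)[-1]) {
    sh <- shells[[k]]
    nxt_xy <- ellipse_point(sh$a, sh$b, phi)
    th <- ((sh$a - shells[[k - 1]]$a) + (sh$b - shells[[k - 1]]$b)) / 2
    nk <- max(1L, as.integer(round(th / e)))
    push_rings(cur_xy, nxt_xy, nk, sh$region, sh$label_fn)
    cur_xy <- nxt_xy
  }
  outer_ring <- prev_ring

  # --- wedge blocks ---------------------------------------------------------
  wrap_idx <- function(j) ((j - 1L) %% n_theta) + 1L
  for (w in wedges) {
    # contiguous outer-ring nodes covering phi_center +/- phi_half
    jc <- which.min(abs(((phi - w$phi_center + pi) %% (2 * pi)) - pi))
    dphi <- 2 * pi / n_theta
    hk <- max(1L, as.integer(round(w$phi_half / dphi)))
    jj <- wrap_idx(jc + (-hk:hk))          # ordered by increasing phi
    root <- outer_ring[jj]
    root_xy <- nodes[root, , drop = FALSE]
    m <- max(2L, as.integer(round(w$length / e)))
    if (w$type == "taper") {
      ctr <- colMeans(root_xy[c(1, nrow(root_xy)), , drop = FALSE])
      dir <- ctr / sqrt(sum(ctr^2))
      apex <- ctr + dir * w$length
      ncol_w <- length(root) - 1L
      W0 <- sqrt(sum((root_xy[nrow(root_xy), ] - root_xy[1, ])^2))
      # quads taper to a finite-width tip row (half an element size per
      # column) and a triangle fan with apex depth of half the tip width
      # closes the point: near-tip elements keep a sane characteristic
      # length, triangles stay close to isotropic
      tipW <- min(0.6 * W0, ncol_w * 0.5 * e)
      tipsc <- tipW / W0
      depth <- tipW / 2
      pre_tip <- apex - dir * depth
      final_xy <- sweep(tipsc * root_xy, 2,
                        pre_tip - tipsc * colMeans(root_xy), "+")
      m <- max(2L, as.integer(round((w$length - depth) / e)))
      prev_row <- root
      for (i in 1:m) {
        s <- i / m
        row <- add_nodes((1 - s) * root_xy + s * final_xy)
        for (j in 1:ncol_w) {
          quads <- rbind(quads, c(prev_row[j], row[j], row[j + 1], prev_row[j + 1]))
          quad_region <- c(quad_region, w$region)
        }
        prev_row <- row
      }
      tip <- add_nodes(matrix(apex, 1))
      for (j in 1:ncol_w) {
        tris <- rbind(tris, c(prev_row[j], tip, prev_row[j + 1]))
        tri_region <- c(tri_region, w$region)
      }
    } else {                                # "extrude": straight bottom edge
      bot_xy <- cbind(mean(root_xy[, 1]) +
                        (root_xy[, 1] - mean(root_xy[, 1])) * w$width_factor,
                      min(root_xy[, 2]) - w$length)
      prev_row <- root
      for (i in 1:m) {
        s <- i / m
        row <- add_nodes((1 - s) * root_xy + s * bot_xy)
        for (j in 1:(length(root) - 1)) {
          quads <- rbind(quads, c(prev_row[j], row[j], row[j + 1], prev_row[j + 1]))
          quad_region <- c(quad_region, w$region)
        }
        prev_row <- row
      }
    }
  }

  mesh <- structure(list(
    nodes = nodes,
    quads = quads, tris = tris,
    elem_region = c(quad_region, tri_region),
    elem_size = e, species = species,
    n_theta = n_theta
  ), class = "mesh2d")
  mesh$boundary_nodes <- find_boundary_nodes(mesh)
  areas <- element_areas(mesh)
  if (any(areas <= 0)) stop("mesh build produced non-positive element areas")
  mesh$elem_area <- areas
  mesh
}

# ---------------------------------------------------------------------------

#' Element areas of a 2D mesh
#'
#' Shoelace areas of quads and triangles, in element order (quads first).
#'
#' @param mesh a `mesh2d`
#' @return numeric vector, m^2
#' @export
element_areas <- function(mesh) {
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  qa <- numeric(0)
  if (nrow(mesh$quads) > 0) {
    q <- mesh$quads
    qa <- 0.5 * ((x[q[, 1]] * y[q[, 2]] - x[q[, 2]] * y[q[, 1]]) +
                 (x[q[, 2]] * y[q[, 3]] - x[q[, 3]] * y[q[, 2]]) +
                 (x[q[, 3]] * y[q[, 4]] - x[q[, 4]] * y[q[, 3]]) +
                 (x[q[, 4]] * y[q[, 1]] - x[q[, 1]] * y[q[, 4]]))
  }
  ta <- numeric(0)
  if (nrow(mesh$tris) > 0) {
    tr <- mesh$tris
    ta <- 0.5 * ((x[tr[, 1]] * (y[tr[, 2]] - y[tr[, 3]])) +
                 (x[tr[, 2]] * (y[tr[, 3]] - y[tr[, 1]])) +
                 (x[tr[, 3]] * (y[tr[, 1]] - y[tr[, 2]])))
  }
  c(qa, ta)
}

#' Number of elements in a mesh
#' @param mesh a `mesh2d`
#' @return integer count (quads + triangles)
#' @export
n_elements <- function(mesh) nrow(mesh$quads) + nrow(mesh$tris)

# characteristic length per element: area over the longest diagonal for
# quads (the conservative explicit-stability measure; area over longest
# edge overestimates the critical step of square elements by sqrt(2)),
# area over longest edge for triangles
element_char_length <- function(mesh) {
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  seg <- function(i, j) sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
  lq <- if (nrow(mesh$quads)) {
    q <- mesh$quads
    pmax(seg(q[, 1], q[, 3]), seg(q[, 2], q[, 4]))
  } else numeric(0)
  lt <- if (nrow(mesh$tris)) {
    tr <- mesh$tris
    pmax(seg(tr[, 1], tr[, 2]), seg(tr[, 2], tr[, 3]), seg(tr[, 3], tr[, 1]))
  } else numeric(0)
  abs(element_areas(mesh)) / c(lq, lt)
}

# nodes on edges used by exactly one element
find_boundary_nodes <- function(mesh) {
  edges <- matrix(0L, 0, 2)
  if (nrow(mesh$quads)) {
    q <- mesh$quads
    edges <- rbind(edges, q[, c(1, 2)], q[, c(2, 3)], q[, c(3, 4)], q[, c(4, 1)])
  }
  if (nrow(mesh$tris)) {
    tr <- mesh$tris
    edges <- rbind(edges, tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  }
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  once <- key %in% bkey
  sort(unique(as.integer(edges[once, ])))
}

# density-weighted head centre of mass
head_cm <- function(mesh, library = material_library()) {
  ar <- mesh$elem_area
  rho <- vapply(mesh$elem_region, function(rg)
    resolve_card(library, rg, mesh$species)$rho, numeric(1))
  cx <- element_centroids(mesh)
  m <- rho * ar
  colSums(cx * m) / sum(m)
}

#' Element centroids
#' @param mesh a `mesh2d`
#' @return matrix (n_elements x 2), m
#' @export
element_centroids <- function(mesh) {
  ctr <- function(conn) {
    cbind(rowMeans(matrix(mesh$nodes[conn, 1], nrow(conn))),
          rowMeans(matrix(mesh$nodes[conn, 2], nrow(conn))))
  }
  rbind(if (nrow(mesh$quads)) ctr(mesh$quads) else matrix(0, 0, 2),
        if (nrow(mesh$tris)) ctr(mesh$tris) else matrix(0, 0, 2))
}

# ---------------------------------------------------------------------------

#' Simplified woodpecker head mesh
#'
#' Parametric 2D plane-strain head: elliptical brain (semi-axes 10 x 7 mm
#' at scale 1) inside an elliptical skull (outer semi-axes 20 x 16 mm),
#' wrapped in a flesh shell (outer semi-axes 23 x 19 mm) that carries a
#' slender curved hyoid band, plus a tapering beak wedge (35 mm) at the
#' front. The full five-region topology is always built; excluded
#' features are relabelled `flesh`, so all ablation variants share
#' bit-identical node and connectivity arrays and are element-wise
#' comparable. The reference point for the pecking drive sits 117 mm x
#' `scale` below the head centre of mass.
#'
#' @param scale geometric scale factor (> 0)
#' @param include_hyoid keep the hyoid band (else relabelled flesh)
#' @param include_beak keep the beak wedge (else relabelled flesh)
#' @param element_size target element edge length, m (at scale 1)
#' @return a `mesh2d`
#' @export
build_simplified_woodpecker <- function(scale = 1, include_hyoid = TRUE,
                                        include_beak = TRUE,
                                        element_size = 1e-3) {
  stopifnot(scale > 0, element_size > 0)
  hy_lo <- 0.30; hy_hi <- 0.60          # hyoid band, fraction of flesh shell
  hy_gap <- pi / 6                      # no hyoid within 30 deg of the beak axis
  hyoid_label <- function(pm) {
    d <- abs(((pm + pi) %% (2 * pi)) - pi)     # distance from phi = 0
    if (d > hy_gap) "hyoid" else "flesh"
  }
  a_sk <- 20e-3; b_sk <- 16e-3
  a_fl <- 23e-3; b_fl <- 19e-3
  blend <- function(f) list(a = (1 - f) * a_sk + f * a_fl,
                            b = (1 - f) * b_sk + f * b_fl)
  # flesh is partitioned into three sub-shells so the hyoid band edges
  # fall exactly on grid lines; the resolvability check applies to the
  # full flesh thickness, not the sub-bands
  th_flesh <- ((a_fl - a_sk) + (b_fl - b_sk)) / 2
  shells <- list(
    list(a = 10e-3, b = 7e-3, region = "brain"),
    list(a = a_sk, b = b_sk, region = "skull"),
    c(blend(hy_lo), list(region = "flesh", check_th = th_flesh)),
    c(blend(hy_hi), list(region = "hyoid", label_fn = hyoid_label,
                         check_th = th_flesh)),
    list(a = a_fl, b = b_fl, region = "flesh", check_th = th_flesh)
  )
  wedges <- list(list(type = "taper", phi_center = 0, phi_half = 12 * pi / 180,
                      length = 35e-3, region = "beak"))
  mesh <- build_shell_mesh(shells, wedges, element_size, "woodpecker")

  # analytic region areas (elliptical sector areas are exact in the
  # parametric angle; the meshed outline is the inscribed polygon)
  wrap_frac <- 1 - 2 * hy_gap / (2 * pi)
  e1 <- blend(hy_lo); e2 <- blend(hy_hi)
  hy_area <- pi * (e2$a * e2$b - e1$a * e1$b) * wrap_frac
  root_h <- b_fl * sin(12 * pi / 180)
  beak_area <- NA  # computed from mesh (discrete root arc), see below
  mesh$region_areas_analytic <- c(
    brain = pi * 10e-3 * 7e-3,
    skull = pi * (a_sk * b_sk - 10e-3 * 7e-3),
    hyoid = hy_area,
    flesh = pi * (a_fl * b_fl - a_sk * b_sk) - hy_area,
    beak = sum(mesh$elem_area[mesh$elem_region == "beak"])
  )
  mesh <- finalize_head(mesh, scale, lever_arm = 0.117)
  if (!include_hyoid) mesh <- relabel_regions(mesh, "hyoid", "flesh")
  if (!include_beak)  mesh <- relabel_regions(mesh, "beak", "flesh")
  mesh
}

#' Simplified human head mesh
#'
#' Elliptical brain (semi-axes 86 x 66 mm at scale 1) surrounded by a thin
#' subarachnoid layer (outer 90 x 70 mm) and skull (outer 98 x 78 mm),
#' with a facial wedge at the front and a neck block extending to the base
#' of the neck. The reference point for the pecking drive sits 191 mm x
#' `scale` below the head centre of mass (base of the neck).
#'
#' @param scale geometric scale factor (> 0)
#' @param element_size target element edge length, m (at scale 1)
#' @return a `mesh2d`
#' @export
build_simplified_human <- function(scale = 1, element_size = 5e-3) {
  stopifnot(scale > 0, element_size > 0)
  shells <- list(
    list(a = 86e-3, b = 66e-3, region = "brain"),
    list(a = 90e-3, b = 70e-3, region = "subarachnoid"),
    list(a = 98e-3, b = 78e-3, region = "skull")
  )
  wedges <- list(
    list(type = "taper", phi_center = 0, phi_half = 22 * pi / 180,
         length = 65e-3, region = "face"),
    list(type = "extrude", phi_center = 3 * pi / 2, phi_half = 24 * pi / 180,
         length = 115e-3, width_factor = 0.9, region = "neck")
  )
  mesh <- build_shell_mesh(shells, wedges, element_size, "human")
  mesh$region_areas_analytic <- c(
    brain = pi * 86e-3 * 66e-3,
    subarachnoid = pi * (90e-3 * 70e-3 - 86e-3 * 66e-3),
    skull = pi * (98e-3 * 78e-3 - 90e-3 * 70e-3),
    face = sum(mesh$elem_area[mesh$elem_region == "face"]),
    neck = sum(mesh$elem_area[mesh$elem_region == "neck"])
  )
  finalize_head(mesh, scale, lever_arm = 0.191)
}

# apply scale about origin, compute CM and reference point
finalize_head <- function(mesh, scale, lever_arm) {
  if (scale != 1) {
    mesh$nodes <- mesh$nodes * scale
    mesh$elem_area <- mesh$elem_area * scale^2
    mesh$region_areas_analytic <- mesh$region_areas_analytic * scale^2
    mesh$elem_size <- mesh$elem_size * scale
  }
  mesh$scale <- scale
  mesh$cm <- head_cm(mesh)
  mesh$lever_arm <- lever_arm * scale
  mesh$ref_point <- mesh$cm - c(0, lever_arm * scale)
  mesh
}

#' Relabel mesh regions (feature ablation)
#'
#' Replaces the material label of every element in `from` with `to`,
#' leaving node coordinates and connectivity untouched. Used to ablate
#' the beak and hyoid (replaced by flesh, conserving a closed domain).
#'
#' @param mesh a `mesh2d`
#' @param from character vector of region labels to replace
#' @param to replacement label
#' @return a `mesh2d`
#' @export
relabel_regions <- function(mesh, from, to) {
  hit <- mesh$elem_region %in% from
  mesh$elem_region[hit] <- to
  if (!is.null(mesh$region_areas_analytic)) {
    moved <- sum(mesh$region_areas_analytic[names(mesh$region_areas_analytic) %in% from])
    ra <- mesh$region_areas_analytic[!names(mesh$region_areas_analytic) %in% from]
    ra[to] <- ra[to] + moved
    mesh$region_areas_analytic <- ra
  }
  mesh
}

#' Geometrically scale a head mesh about its centre of mass
#'
#' Coordinates scale by `factor` about the head CM; densities are
#' unchanged (2D mass scales by `factor^2`). The reference point is
#' re-placed at the given lever arm below the CM (the woodpecker's
#' 0.117 m for the scaling-study runs).
#'
#' @param mesh a `mesh2d`
#' @param factor scale factor (> 0)
#' @param lever_arm distance from head CM to the drive reference point, m
#' @return a `mesh2d`
#' @export
scale_head <- function(mesh, factor, lever_arm = mesh$lever_arm) {
  stopifnot(inherits(mesh, "mesh2d"), factor > 0)
  cm <- mesh$cm
  mesh$nodes <- sweep(sweep(mesh$nodes, 2, cm) * factor, 2, cm, "+")
  mesh$elem_area <- mesh$elem_area * factor^2
  mesh$region_areas_analytic <- mesh$region_areas_analytic * factor^2
  mesh$elem_size <- mesh$elem_size * factor
  mesh$scale <- mesh$scale * factor
  mesh$cm <- cm
  mesh$lever_arm <- lever_arm
  mesh$ref_point <- cm - c(0, lever_arm)
  mesh
}

#' Region area summary of a mesh
#'
#' Summed element areas per region label, alongside the analytic areas of
#' the defining outlines where available.
#'
#' @param mesh a `mesh2d`
#' @return data.frame with columns region, mesh_area, analytic_area
#' @export
region_areas <- function(mesh) {
  ar <- tapply(mesh$elem_area, mesh$elem_region, sum)
  out <- data.frame(region = names(ar), mesh_area = as.numeric(ar))
  out$analytic_area <- mesh$region_areas_analytic[out$region]
  out
}

#' Positive-Jacobian audit of a mesh at rest
#'
#' Checks the corner Jacobians of every quad (cross products of adjacent
#' edges) and the area of every triangle.
#'
#' @param mesh a `mesh2d`
#' @return TRUE invisibly; stops with the offending element otherwise
#' @export
audit_jacobians <- function(mesh) {
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  if (nrow(mesh$quads)) {
    q <- mesh$quads
    for (k in 1:4) {
      km <- ((k - 2) %% 4) + 1; kp <- (k %% 4) + 1
      e1x <- x[q[, kp]] - x[q[, k]]; e1y <- y[q[, kp]] - y[q[, k]]
      e2x <- x[q[, km]] - x[q[, k]]; e2y <- y[q[, km]] - y[q[, k]]
      jac <- e1x * e2y - e1y * e2x
      if (any(jac <= 0))
        stop("non-positive corner Jacobian in quad ", which(jac <= 0)[1])
    }
  }
  if (nrow(mesh$tris)) {
    ta <- element_areas(mesh)[(nrow(mesh$quads) + 1):n_elements(mesh)]
    if (any(ta <= 0)) stop("non-positive triangle area ", which(ta <= 0)[1])
  }
  invisible(TRUE)
}

#' Structured rectangular patch mesh (verification utility)
#'
#' `nx` by `ny` grid of quads over a rectangle, single region label.
#' Used by patch tests, the implicit time-integration oracle, and the
#' mesh-convergence utility.
#'
#' @param nx,ny cell counts
#' @param Lx,Ly side lengths, m
#' @param region region label for every element
#' @param species species context for material resolution
#' @param ref_point drive reference point (default: rectangle centre)
#' @return a `mesh2d`
#' @export
patch_mesh <- function(nx, ny, Lx, Ly, region = "brain",
                       species = "woodpecker", ref_point = NULL) {
  gx <- seq(0, Lx, length.out = nx + 1)
  gy <- seq(0, Ly, length.out = ny + 1)
  nodes <- cbind(rep(gx, times = ny + 1), rep(gy, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  quads <- matrix(0L, nx * ny, 4)
  k <- 0L
  for (j in 1:ny) for (i in 1:nx) {
    k <- k + 1L
    quads[k, ] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
  }
  mesh <- structure(list(
    nodes = nodes, quads = quads, tris = matrix(0L, 0, 3),
    elem_region = rep(region, nx * ny),
    elem_size = Lx / nx, species = species, n_theta = NA_integer_,
    scale = 1
  ), class = "mesh2d")
  mesh$boundary_nodes <- find_boundary_nodes(mesh)
  mesh$elem_area <- element_areas(mesh)
  mesh$region_areas_analytic <- stats::setNames(Lx * Ly, region)
  mesh$cm <- c(Lx / 2, Ly / 2)
  mesh$lever_arm <- NA_real_
  mesh$ref_point <- if (is.null(ref_point)) mesh$cm else ref_point
  mesh
}
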