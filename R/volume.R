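#' @include tissue.R
NULL

#' Create a grid specification
#'
#' @param shape voxel counts `c(nx, ny, nz)`.
#' @param spacing_mm isotropic voxel edge length (mm).
#' @param origin_mm corner of voxel (1,1,1) in mm.
#' @return A [GridSpec-class].
#' @export
GridSpec <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  new("GridSpec", shape = as.integer(shape), spacing = as.numeric(spacing_mm),
      origin = as.numeric(origin_mm))
}

#' Voxel center coordinates of a grid
#'
#' @param grid a [GridSpec-class].
#' @return List with numeric vectors `x`, `y`, `z` of voxel centers (mm).
#' @export
voxelCenters <- function(grid) {
  ctr <- function(n, o) o + (seq_len(n) - 0.5) * grid@spacing
  list(x = ctr(grid@shape[1], grid@origin[1]),
       y = ctr(grid@shape[2], grid@origin[2]),
       z = ctr(grid@shape[3], grid@origin[3]))
}

#' Create a geometric structure
#'
#' Geometry parameters by kind (all mm, world coordinates):
#' * `layer`: `z_start`, `z_end` (a horizontal slab).
#' * `sphere`: `center` (3-vector), `radius`.
#' * `elliptical_tube`: `start`, `end` (axis endpoints), `radius_a`,
#'   optional `radius_b` (defaults to `radius_a`).
#' * `cuboid`: `corner` (3-vector), `extent` (3-vector, axis-aligned).
#' * `parallelepiped`: `corner`, edge vectors `e1`, `e2`, `e3`.
#' * `vessel_tree`: `segments`, a data frame as returned by
#'   [growVesselTree()].
#' * `background`: no parameters; fills the whole grid.
#'
#' @param kind structure kind.
#' @param params list of geometry parameters, see above.
#' @param composition a [MolecularComposition-class].
#' @param priority non-negative number; higher priorities claim voxels
#'   first. The background is always ranked last regardless of priority.
#' @param partial_volume if `TRUE`, boundary voxels get fractional
#'   occupancy from sub-voxel sampling (see [rasterizeStructure()]).
#' @param adhere_to_deformation if `TRUE`, membership tests use the
#'   deformation-shifted depth.
#' @return A [Structure-class].
#' @export
Structure <- function(kind, params = list(), composition,
                      priority = 1, partial_volume = TRUE,
                      adhere_to_deformation = FALSE) {
  new("Structure", kind = kind, params = params, composition = composition,
      priority = as.numeric(priority),
      partialVolume = isTRUE(partial_volume),
      adhereToDeformation = isTRUE(adhere_to_deformation))
}

# run expr with a temporarily fixed RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# rotate a unit vector away from itself by acos(cost) at azimuth phi
.deflect <- function(u, cost, phi) {
  sint <- sqrt(max(0, 1 - cost^2))
  if (abs(u[3]) > 0.999999) {
    v <- c(sint * cos(phi), sint * sin(phi), cost * sign(u[3]))
  } else {
    tmp <- sqrt(1 - u[3]^2)
    v <- c(sint * (u[1] * u[3] * cos(phi) - u[2] * sin(phi)) / tmp +
             u[1] * cost,
           sint * (u[2] * u[3] * cos(phi) + u[1] * sin(phi)) / tmp +
             u[2] * cost,
           -sint * cos(phi) * tmp + u[3] * cost)
  }
  v / sqrt(sum(v^2))
}

#' Grow a random-walk vessel tree
#'
#' Grows a vascular tree by a random walk: each step advances the walker by
#' `step_mm` along a direction perturbed by a random deflection of at most
#' `max_bend_deg`; with probability `bifurcation_prob` the walker splits
#' into two children whose radii shrink by `radius_decay` and whose
#' directions are separated symmetrically by `branch_angle_deg`. A branch
#' terminates when its radius falls below `min_radius_mm` or the walker
#' leaves the bounding box. The same `rng_seed` always reproduces the same
#' tree.
#'
#' @param seed_position_mm 3-vector, root of the tree (mm).
#' @param direction initial direction (normalized with a warning if not
#'   unit length).
#' @param radius_mm root radius (mm), must be >= `min_radius_mm`.
#' @param params list overriding any of `step_mm` (1), `max_bend_deg` (15),
#'   `bifurcation_prob` (0.05), `radius_decay` (`2^(-1/3)`, a Murray-type
#'   rule), `min_radius_mm` (0.5), `branch_angle_deg` (40),
#'   `max_segments` (5000).
#' @param rng_seed integer seed.
#' @param bounds 2 x 3 matrix (rows min/max) of the box the tree may occupy.
#' @return Data frame with columns `x0,y0,z0,x1,y1,z1,radius`, one tube
#'   segment per row.
#' @export
growVesselTree <- function(seed_position_mm, direction, radius_mm,
                           params = list(), rng_seed = 1,
                           bounds) {
  p <- modifyList(list(step_mm = 1, max_bend_deg = 15,
                       bifurcation_prob = 0.05, radius_decay = 2^(-1 / 3),
                       min_radius_mm = 0.5, branch_angle_deg = 40,
                       max_segments = 5000), params)
  if (p$step_mm <= 0) stop("step_mm must be > 0")
  if (any(unlist(p[c("max_bend_deg", "bifurcation_prob", "radius_decay",
                     "min_radius_mm")]) < 0))
    stop("vessel tree parameters must be non-negative")
  if (radius_mm < p$min_radius_mm)
    stop("root radius must be >= min_radius_mm")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) {
    warning("direction is not unit length; normalizing")
  }
  direction <- direction / nrm
  inside <- function(q) all(q >= bounds[1, ]) && all(q <= bounds[2, ])

  .with_seed(rng_seed, {
    segs <- vector("list", 0L)
    stack <- list(list(pos = as.numeric(seed_position_mm), dir = direction,
                       radius = radius_mm))
    while (length(stack) > 0L && length(segs) < p$max_segments) {
      w <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      while (length(segs) < p$max_segments) {
        if (w$radius < p$min_radius_mm) break
        bend <- stats::runif(1, 0, p$max_bend_deg) * pi / 180
        az <- stats::runif(1, 0, 2 * pi)
        d <- .deflect(w$dir, cos(bend), az)
        q <- w$pos + p$step_mm * d
        segs[[length(segs) + 1L]] <-
          c(w$pos, q, w$radius)
        if (!inside(q)) break
        w$pos <- q
        w$dir <- d
        if (stats::runif(1) < p$bifurcation_prob) {
          rchild <- w$radius * p$radius_decay
          half <- p$branch_angle_deg / 2 * pi / 180
          az2 <- stats::runif(1, 0, 2 * pi)
          d1 <- .deflect(d, cos(half), az2)
          d2 <- .deflect(d, cos(half), az2 + pi)
          stack[[length(stack) + 1L]] <-
            list(pos = q, dir = d2, radius = rchild)
          w$dir <- d1
          w$radius <- rchild
        }
      }
    }
    out <- do.call(rbind, segs)
    if (is.null(out)) out <- matrix(numeric(0), ncol = 7)
    colnames(out) <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius")
    as.data.frame(out)
  })
}

#' Create a surface deformation height field
#'
#' A smooth height field over the lateral plane, built as a sum of
#' `n_modes` random-phase sinusoids and rescaled so that the maximum
#' absolute vertical offset over the grid does not exceed `amplitude_mm`.
#'
#' @param amplitude_mm maximum |offset| in mm (>= 0); 0 gives the
#'   identically zero field.
#' @param n_modes number of sinusoid modes.
#' @param rng_seed integer seed (same seed, same field).
#' @param grid the [GridSpec-class] the field will be applied to.
#' @return A [DeformationField-class].
#' @export
makeDeformation <- function(amplitude_mm, n_modes = 5, rng_seed = 1, grid) {
  stopifnot(amplitude_mm >= 0)
  ext <- grid@shape[1:2] * grid@spacing
  coef <- .with_seed(rng_seed, {
    cbind(a = stats::runif(n_modes, 0.5, 1),
          kx = sample(0:3, n_modes, replace = TRUE),
          ky = sample(0:3, n_modes, replace = TRUE),
          phase = stats::runif(n_modes, 0, 2 * pi))
  })
  def <- new("DeformationField", amplitude = 0, coefficients = coef,
             extent = as.numeric(ext))
  if (amplitude_mm > 0) {
    cc <- voxelCenters(grid)
    g <- expand.grid(x = cc$x, y = cc$y)
    raw <- .eval_deformation_raw(def, g$x, g$y)
    m <- max(abs(raw))
    if (m > 0)
      def@coefficients[, "a"] <- coef[, "a"] * amplitude_mm / m
    def@amplitude <- amplitude_mm
  } else {
    def@coefficients[, "a"] <- 0
  }
  def
}

.eval_deformation_raw <- function(def, x, y) {
  out <- numeric(length(x))
  for (i in seq_len(nrow(def@coefficients))) {
    cf <- def@coefficients[i, ]
    out <- out + cf["a"] *
      sin(2 * pi * (cf["kx"] * x / def@extent[1] +
                    cf["ky"] * y / def@extent[2]) + cf["phase"])
  }
  out
}

#' Evaluate a deformation field
#'
#' @param def a [DeformationField-class].
#' @param x,y lateral coordinates (mm), recycled to a common length.
#' @return Vertical offsets in mm, `abs(offset) <= amplitude`.
#' @export
evalDeformation <- function(def, x, y) {
  if (def@amplitude == 0) return(numeric(length(x)) * x * 0)
  .eval_deformation_raw(def, x, y)
}

# membership test of a structure at explicit world coordinates (vectors)
.membership <- function(structure, X, Y, Z) {
  p <- structure@params
  switch(structure@kind,
    background = rep(TRUE, length(X)),
    layer = Z >= p$z_start & Z < p$z_end,
    sphere = {
      ctr <- p$center
      (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= p$radius^2
    },
    cuboid = {
      co <- p$corner; ex <- p$extent
      X >= co[1] & X < co[1] + ex[1] & Y >= co[2] & Y < co[2] + ex[2] &
        Z >= co[3] & Z < co[3] + ex[3]
    },
    parallelepiped = {
      M <- cbind(p$e1, p$e2, p$e3)
      Mi <- solve(M)
      dx <- X - p$corner[1]; dy <- Y - p$corner[2]; dz <- Z - p$corner[3]
      c1 <- Mi[1, 1] * dx + Mi[1, 2] * dy + Mi[1, 3] * dz
      c2 <- Mi[2, 1] * dx + Mi[2, 2] * dy + Mi[2, 3] * dz
      c3 <- Mi[3, 1] * dx + Mi[3, 2] * dy + Mi[3, 3] * dz
      c1 >= 0 & c1 <= 1 & c2 >= 0 & c2 <= 1 & c3 >= 0 & c3 <= 1
    },
    elliptical_tube = {
      a <- p$end - p$start
      L <- sqrt(sum(a^2)); a <- a / L
      ra <- p$radius_a
      rb <- if (is.null(p$radius_b)) ra else p$radius_b
      ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- c(a[2] * ref[3] - a[3] * ref[2], a[3] * ref[1] - a[1] * ref[3],
             a[1] * ref[2] - a[2] * ref[1])
      u <- u / sqrt(sum(u^2))
      v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
             a[1] * u[2] - a[2] * u[1])
      dx <- X - p$start[1]; dy <- Y - p$start[2]; dz <- Z - p$start[3]
      t <- dx * a[1] + dy * a[2] + dz * a[3]
      px <- dx - t * a[1]; py <- dy - t * a[2]; pz <- dz - t * a[3]
      du <- px * u[1] + py * u[2] + pz * u[3]
      dv <- px * v[1] + py * v[2] + pz * v[3]
      t >= 0 & t <= L & (du / ra)^2 + (dv / rb)^2 <= 1
    },
    vessel_tree = {
      segs <- p$segments
      inside <- rep(FALSE, length(X))
      for (i in seq_len(nrow(segs))) {
        s0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
        s1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
        r <- segs$radius[i]
        lo <- pmin(s0, s1) - r; hi <- pmax(s0, s1) + r
        cand <- which(!inside & X >= lo[1] & X <= hi[1] & Y >= lo[2] &
                        Y <= hi[2] & Z >= lo[3] & Z <= hi[3])
        if (length(cand) == 0L) next
        d <- s1 - s0
        dd <- sum(d^2)
        wx <- X[cand] - s0[1]; wy <- Y[cand] - s0[2]; wz <- Z[cand] - s0[3]
        t <- if (dd > 0) pmin(1, pmax(0, (wx * d[1] + wy * d[2] +
                                          wz * d[3]) / dd)) else 0
        dist2 <- (wx - t * d[1])^2 + (wy - t * d[2])^2 + (wz - t * d[3])^2
        inside[cand[dist2 <= r^2]] <- TRUE
      }
      inside
    },
    stop("unsupported structure kind '", structure@kind, "'"))
}

#' Rasterize a structure into a voxel occupancy field
#'
#' Computes the per-voxel occupancy fraction of a structure on a grid. With
#' `partial_volume` set on the structure, each voxel is probed at a regular
#' `subdiv^3` sub-grid of points and the fraction of hits is returned;
#' otherwise membership of the voxel center gives a binary field. A
#' structure entirely outside the grid yields an all-zero field.
#'
#' @param structure a [Structure-class].
#' @param grid a [GridSpec-class].
#' @param deformation optional [DeformationField-class], applied only if
#'   the structure has `adhereToDeformation` set.
#' @param subdiv sub-sampling order per axis (default 3, i.e. 27 probe
#'   points; a documented accuracy/cost trade-off).
#' @return 3-D array of fractions in `[0, 1]` with the grid's shape.
#' @export
rasterizeStructure <- function(structure, grid, deformation = NULL,
                               subdiv = 3) {
  validObject(structure)
  shp <- grid@shape
  if (structure@kind == "background")
    return(array(1, dim = shp))
  cc <- voxelCenters(grid)
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  deform <- structure@adhereToDeformation && !is.null(deformation)
  eval_at <- function(ox, oy, oz) {
    X <- rep(cc$x + ox, times = ny * nz)
    Y <- rep(rep(cc$y + oy, each = nx), times = nz)
    Z <- rep(cc$z + oz, each = nx * ny)
    if (deform) Z <- Z - evalDeformation(deformation, X, Y)
    .membership(structure, X, Y, Z)
  }
  if (!structure@partialVolume) {
    occ <- eval_at(0, 0, 0)
    return(array(as.numeric(occ), dim = shp))
  }
  off <- ((seq_len(subdiv) - 0.5) / subdiv - 0.5) * grid@spacing
  acc <- numeric(prod(shp))
  for (ox in off) for (oy in off) for (oz in off)
    acc <- acc + eval_at(ox, oy, oz)
  array(acc / subdiv^3, dim = shp)
}

# assemble a PropertyVolumes from per-structure claims
.blend_properties <- function(structures, claims, grid, wavelengths,
                              bg_index) {
  shp <- grid@shape
  zero <- function() array(0, dim = shp)
  wl_names <- as.character(wavelengths)
  mua <- mus <- g <- setNames(vector("list", length(wavelengths)), wl_names)
  for (w in wl_names) {
    mua[[w]] <- zero(); mus[[w]] <- zero(); g[[w]] <- zero()
  }
  gamma <- zero(); sos <- zero(); rho <- zero(); alpha <- zero()
  so2_num <- zero(); so2_den <- zero()
  seg <- array(bg_index, dim = shp)
  for (i in seq_along(structures)) {
    cl <- claims[[i]]
    if (all(cl == 0)) next
    comp <- structures[[i]]@composition
    hbf <- .hemoglobin_fraction(comp)
    for (k in seq_along(wavelengths)) {
      props <- mixComposition(comp, wavelengths[k])
      w <- wl_names[k]
      mua[[w]] <- mua[[w]] + cl * props$mua
      mus[[w]] <- mus[[w]] + cl * props$mus
      g[[w]] <- g[[w]] + cl * props$g
      if (k == 1L) {
        gamma <- gamma + cl * props$gamma
        sos <- sos + cl * props$sos
        rho <- rho + cl * props$rho
        alpha <- alpha + cl * props$alpha
        if (hbf > 0 && !is.na(props$so2)) {
          so2_num <- so2_num + cl * hbf * props$so2
          so2_den <- so2_den + cl * hbf
        }
      }
    }
    seg[cl > 0.5] <- i
  }
  so2 <- so2_num / so2_den
  so2[so2_den == 0] <- NA_real_
  new("PropertyVolumes", mua = mua, mus = mus, g = g, gamma = gamma,
      sos = sos, rho = rho, alpha = alpha, so2 = so2, segmentation = seg,
      grid = grid, wavelengths = as.numeric(wavelengths))
}

#' Create property volumes from a prioritized structure scene
#'
#' Rasterizes every structure and distributes each voxel's unit capacity by
#' descending priority: the highest-priority structure claims its
#' (fractional) occupancy first, lower priorities claim from what remains,
#' and the single background structure absorbs the rest. Voxel properties
#' are the occupancy-weighted mixture of the claimants' mixed compositions;
#' the segmentation label is the structure holding more than half of the
#' voxel (background otherwise). Ties in priority are broken by list order
#' (earlier wins).
#'
#' @param structures list of [Structure-class] objects, exactly one of
#'   which must have kind `"background"`.
#' @param grid a [GridSpec-class].
#' @param wavelengths_nm wavelengths (nm) at which to evaluate the optical
#'   properties.
#' @param deformation optional [DeformationField-class].
#' @param subdiv sub-voxel sampling order, see [rasterizeStructure()].
#' @return A [PropertyVolumes-class]. Segmentation labels are the indices
#'   of the structures in the input list.
#' @export
createModelBasedVolume <- function(structures, grid, wavelengths_nm,
                                   deformation = NULL, subdiv = 3) {
  is_bg <- vapply(structures, function(s) s@kind == "background", logical(1))
  if (sum(is_bg) != 1L)
    stop("invalid scene: exactly one background structure is required")
  bg_index <- which(is_bg)
  prio <- vapply(structures, function(s) s@priority, numeric(1))
  prio[bg_index] <- -Inf
  ord <- order(-prio, seq_along(structures))
  remaining <- array(1, dim = grid@shape)
  claims <- vector("list", length(structures))
  for (i in ord) {
    occ <- rasterizeStructure(structures[[i]], grid, deformation, subdiv)
    claim <- pmin(occ, remaining)
    remaining <- remaining - claim
    claims[[i]] <- claim
  }
  claims[[bg_index]] <- claims[[bg_index]] + remaining
  .blend_properties(structures, claims, grid, wavelengths_nm, bg_index)
}

#' Create property volumes from a segmentation mask
#'
#' Maps an integer label grid to tissue compositions voxel by voxel: every
#' voxel receives the mixed properties of the composition its label maps
#' to, without partial-volume blending (interfaces stay sharp). The
#' segmentation grid of the result is the mask verbatim.
#'
#' @param mask integer 3-D array with the grid's shape.
#' @param label_map named list mapping label values (as names) to
#'   [MolecularComposition-class] objects.
#' @param grid a [GridSpec-class].
#' @param wavelengths_nm wavelengths (nm).
#' @return A [PropertyVolumes-class].
#' @export
createSegmentationBasedVolume <- function(mask, label_map, grid,
                                          wavelengths_nm) {
  if (!identical(dim(mask), grid@shape))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match the grid shape ",
         paste(grid@shape, collapse = "x"))
  labels <- sort(unique(as.vector(mask)))
  missing <- setdiff(as.character(labels), names(label_map))
  if (length(missing) > 0L)
    stop("missing composition mapping for label(s): ",
         paste(missing, collapse = ", "))
  shp <- grid@shape
  wl_names <- as.character(wavelengths_nm)
  zero <- function() array(0, dim = shp)
  mua <- mus <- g <- setNames(vector("list", length(wavelengths_nm)),
                              wl_names)
  for (w in wl_names) {
    mua[[w]] <- zero(); mus[[w]] <- zero(); g[[w]] <- zero()
  }
  gamma <- zero(); sos <- zero(); rho <- zero(); alpha <- zero()
  so2 <- array(NA_real_, dim = shp)
  for (lab in labels) {
    sel <- mask == lab
    comp <- label_map[[as.character(lab)]]
    for (k in seq_along(wavelengths_nm)) {
      props <- mixComposition(comp, wavelengths_nm[k])
      w <- wl_names[k]
      mua[[w]][sel] <- props$mua
      mus[[w]][sel] <- props$mus
      g[[w]][sel] <- props$g
      if (k == 1L) {
        gamma[sel] <- props$gamma
        sos[sel] <- props$sos
        rho[sel] <- props$rho
        alpha[sel] <- props$alpha
        so2[sel] <- props$so2
      }
    }
  }
  new("PropertyVolumes", mua = mua, mus = mus, g = g, gamma = gamma,
      sos = sos, rho = rho, alpha = alpha, so2 = so2,
      segmentation = array(as.numeric(mask), dim = shp), grid = grid,
      wavelengths = as.numeric(wavelengths_nm))
}

#' Read a segmentation mask from NIfTI or raw binary
#'
#' Convenience loader for segmentation-based volume creation: either a
#' NIfTI file (read through the RNifti package) or a raw binary file of
#' integers together with an explicit shape.
#'
#' @param path file path.
#' @param shape required for raw binary input: voxel counts `c(nx, ny, nz)`.
#' @param what storage type of the raw binary file (`"integer"` default).
#' @param size bytes per element for raw binary input (default 4).
#' @return Integer 3-D array.
#' @export
readSegmentationMask <- function(path, shape = NULL, what = "integer",
                                 size = 4L) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI masks requires the RNifti package")
    img <- RNifti::readNifti(path)
    return(array(as.integer(round(as.vector(img))), dim = dim(img)))
  }
  if (is.null(shape))
    stop("raw binary masks need an explicit 'shape'")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = what, n = prod(shape), size = size)
  if (length(v) != prod(shape))
    stop("raw mask holds ", length(v), " values, expected ", prod(shape))
  array(as.integer(v), dim = as.integer(shape))
}
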