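#' Photoseed specification
#'
#' Geometry and absorption of an implantable plasmonic nanocomposite seed.
#' The bulk absorption coefficient is derived from the measured NIR
#' absorbance via [absorbance_to_mua()].
#'
#' @param shape `"cylinder"` or `"cube"`.
#' @param d_s cylinder diameter, m (ignored for cubes).
#' @param L cylinder length, m, or cube side.
#' @param A810 dimensionless absorbance of the nanocomposite at 810 nm.
#' @param path_length optical path length of the absorbance measurement, m.
#' @param thermo [thermo_properties] of the seed material. Must have zero
#'   perfusion and metabolic heat (implants do not perfuse).
#' @return An object of class `photoseed_spec` with the dimensions and the
#'   derived `mu_a_seed` (m^-1).
#' @examples
#' photoseed_spec("cylinder", d_s = 1e-3, L = 0.015, A810 = 1.54)
#' @export
photoseed_spec <- function(shape = c("cylinder", "cube"),
                           d_s = 1e-3, L = 0.015,
                           A810 = 1.54, path_length = 30e-6,
                           thermo = material_table()$seed$thermo) {
  shape <- match.arg(shape)
  stopifnot(L > 0, A810 >= 0)
  if (shape == "cylinder" && d_s <= 0) stop("seed diameter must be > 0")
  if (thermo$omega_b0 != 0 || thermo$q_met != 0)
    stop("seed material must have omega_b0 = 0 and q_met = 0")
  structure(list(
    shape = shape, d_s = d_s, L = L,
    A810 = A810, path_length = path_length,
    mu_a_seed = absorbance_to_mua(A810, path_length),
    thermo = thermo
  ), class = "photoseed_spec")
}

#' Laser beam description
#'
#' @param P0 laser power, W (>= 0).
#' @param entry_point length-3 position of the beam entry on the phantom
#'   surface, m.
#' @param direction length-3 beam direction; normalised internally, must be
#'   non-zero.
#' @return An object of class `laser_beam`.
#' @export
laser_beam <- function(P0, entry_point, direction = c(0, 0, 1)) {
  stopifnot(is.numeric(P0), length(P0) == 1L, P0 >= 0,
            length(entry_point) == 3L, length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("beam direction must be non-zero")
  structure(list(P0 = P0, entry_point = as.numeric(entry_point),
                 direction = as.numeric(direction) / nrm),
            class = "laser_beam")
}

new_tissue_phantom <- function(dims, spacing, labels, materials, probes,
                               fluence_kernel, seeds = NULL) {
  structure(list(
    dims = as.integer(dims), spacing = spacing, labels = labels,
    materials = materials, probes = probes,
    fluence_kernel = fluence_kernel, seeds = seeds
  ), class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("tissue_phantom: %d x %d x %d voxels, spacing %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing * 1e3))
  cat("labels:", paste(sprintf("%s (%d)", names(table(x$labels)),
                               as.integer(table(x$labels))), collapse = ", "),
      "\n")
  cat("probes:", paste(names(x$probes), collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-centre coordinates along one axis
#' @param phantom a `tissue_phantom`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of centre coordinates, m.
#' @export
voxel_centers <- function(phantom, axis) {
  (seq_len(phantom$dims[axis]) - 0.5) * phantom$spacing
}

#' Map a physical point to its voxel index
#'
#' Points exactly on a voxel face map to the higher-index voxel.
#'
#' @param phantom a `tissue_phantom`.
#' @param point a length-3 position (m) or the name of a registered probe.
#' @return integer length-3 (i, j, k) voxel index, 1-based.
#' @export
probe_index <- function(phantom, point) {
  if (is.character(point)) {
    if (!point %in% names(phantom$probes))
      stop("unknown probe: ", point)
    point <- phantom$probes[[point]]
  }
  idx <- pmin(pmax(floor(point / phantom$spacing) + 1L, 1L), phantom$dims)
  if (any(point < 0 | point > phantom$dims * phantom$spacing))
    stop("probe point lies outside the grid")
  as.integer(idx)
}

flat_index <- function(phantom, ijk) {
  as.integer(ijk[1] + phantom$dims[1] * ((ijk[2] - 1) +
             phantom$dims[2] * (ijk[3] - 1)))
}

#' Default breast phantom configuration
#'
#' A multi-layer tissue block (fat layer over gland along the beam axis z)
#' hosting a centrally placed array of cylindrical photoseeds. Block size and
#' the fat:gland split are configurable; defaults keep the seed array deep in
#' the gland layer.
#'
#' @param block length-3 block dimensions, m.
#' @param spacing voxel spacing (uniform), m.
#' @param fat_thickness thickness of the superficial fat layer along z, m.
#' @param seed_rows,seed_cols photoseed array layout (rows x cols in x-y).
#' @param seed_spacing centre-to-centre spacing of the array, m.
#' @param seed [photoseed_spec] for every seed in the array.
#' @param seed_center length-3 centre of the array (mid-length of the seed
#'   axes), m; default block centre.
#' @param materials property table, see [material_table()].
#' @return configuration list for [build_breast_phantom()].
#' @export
breast_phantom_config <- function(block = c(0.06, 0.06, 0.06),
                                  spacing = 1e-3,
                                  fat_thickness = 0.01,
                                  seed_rows = 2, seed_cols = 2,
                                  seed_spacing = 5e-3,
                                  seed = photoseed_spec(),
                                  seed_center = NULL,
                                  materials = material_table()) {
  list(block = block, spacing = spacing, fat_thickness = fat_thickness,
       seed_rows = seed_rows, seed_cols = seed_cols,
       seed_spacing = seed_spacing, seed = seed,
       seed_center = if (is.null(seed_center)) block / 2 else seed_center,
       materials = materials)
}

#' Build the voxelized breast phantom with an implanted photoseed array
#'
#' Voxelizes a layered fat/gland block with `seed_rows x seed_cols`
#' cylindrical photoseeds (axes parallel to z, the beam axis). Voxels are
#' assigned by centre-point membership. The control point `P1` is registered
#' at the centroid of the seed axes (mid-length); an `interface` probe sits
#' in the first tissue voxel adjacent to the first seed. With zero seeds, P1
#' falls at the block centre.
#'
#' @param config see [breast_phantom_config()].
#' @return a `tissue_phantom`.
#' @export
build_breast_phantom <- function(config = breast_phantom_config()) {
  with(config, {
    stopifnot(all(block > 0), spacing > 0, fat_thickness > 0,
              fat_thickness < block[3], seed_rows >= 0, seed_cols >= 0)
    n_seeds <- seed_rows * seed_cols
    if (n_seeds > 0 && spacing > seed$d_s)
      stop("resolution error: grid spacing (", spacing,
           " m) is coarser than the seed diameter (", seed$d_s, " m)")
    dims <- as.integer(round(block / spacing))
    xc <- (seq_len(dims[1]) - 0.5) * spacing
    yc <- (seq_len(dims[2]) - 0.5) * spacing
    zc <- (seq_len(dims[3]) - 0.5) * spacing

    labels <- array("gland", dim = dims)
    labels[, , zc <= fat_thickness] <- "fat"

    seeds <- NULL
    if (n_seeds > 0) {
      offx <- (seq_len(seed_rows) - (seed_rows + 1) / 2) * seed_spacing
      offy <- (seq_len(seed_cols) - (seed_cols + 1) / 2) * seed_spacing
      axes <- expand.grid(x = seed_center[1] + offx,
                          y = seed_center[2] + offy)
      r <- seed$d_s / 2
      z_lo <- seed_center[3] - seed$L / 2
      z_hi <- seed_center[3] + seed$L / 2
      if (any(axes$x - r < 0 | axes$x + r > block[1] |
              axes$y - r < 0 | axes$y + r > block[2]) ||
          z_lo < 0 || z_hi > block[3])
        stop("geometry error: seed array exceeds the block bounds")
      if (z_lo < fat_thickness)
        stop("geometry error: seeds must lie entirely in the gland layer")
      zin <- which(zc >= z_lo & zc <= z_hi)
      for (s in seq_len(nrow(axes))) {
        hit <- 0L
        inx <- which(abs(xc - axes$x[s]) <= r)
        for (i in inx) {
          iny <- which((xc[i] - axes$x[s])^2 + (yc - axes$y[s])^2 <= r^2)
          if (length(iny)) {
            labels[i, iny, zin] <- "seed"
            hit <- hit + length(iny)
          }
        }
        if (hit == 0L)
          stop("resolution error: seed ", s, " contains no voxel centre ",
               "(it would vanish at this grid spacing/alignment)")
      }
      seeds <- list(axes = axes, spec = seed, z_range = c(z_lo, z_hi))
    }

    materials$seed$optical <- NULL  # kernel comes from the host tissue
    materials$seed$mu_a <- if (n_seeds > 0) seed$mu_a_seed else NULL
    if (n_seeds > 0) materials$seed$thermo <- seed$thermo

    p1 <- seed_center
    probes <- list(P1 = p1)
    if (n_seeds > 0) {
      probes$interface <- c(seeds$axes$x[1] + seed$d_s / 2 + spacing / 4,
                            seeds$axes$y[1], seed_center[3])
    }
    new_tissue_phantom(dims, spacing, labels, materials, probes,
                       fluence_kernel = c(fat = "fat", gland = "gland",
                                          seed = "gland"),
                       seeds = seeds)
  })
}

#' Height of a water column of given volume in a cylindrical container
#'
#' @param volume water volume, m^3.
#' @param radius container inner radius, m.
#' @return column height, m.
#' @examples
#' water_column_height(0.5e-6, 0.0045)  # ~ 0.786 cm
#' @export
water_column_height <- function(volume, radius) {
  stopifnot(volume > 0, radius > 0)
  volume / (pi * radius^2)
}

#' Configuration for the bench validation water model
#'
#' @param water_volume water volume, m^3 (default 0.5 mL).
#' @param container_radius inner radius of the sample tube, m.
#' @param cube_side side of the cubic photoseed, m (0 for a water-only
#'   model).
#' @param spacing voxel spacing, m.
#' @param A810,path_length absorbance inputs for the seed, see
#'   [photoseed_spec()].
#' @param margin air margin around the water column, voxels.
#' @param materials property table.
#' @return configuration list for [build_water_model()].
#' @export
water_model_config <- function(water_volume = 0.5e-6,
                               container_radius = 0.0045,
                               cube_side = 0.005,
                               spacing = 5e-4,
                               A810 = 1.54, path_length = 30e-6,
                               margin = 2L,
                               materials = material_table()) {
  list(water_volume = water_volume, container_radius = container_radius,
       cube_side = cube_side, spacing = spacing, A810 = A810,
       path_length = path_length, margin = as.integer(margin),
       materials = materials)
}

#' Build the bench validation water model
#'
#' A cylindrical water column (volume and container radius as configured,
#' height from the volume) holding a single cubic photoseed, surrounded by an
#' air margin. The probe `bottom` is registered at the centre of the seed's
#' bottom face, where the bench temperature was recorded; `P1` aliases the
#' seed centre. With `cube_side = 0` the model contains water only.
#'
#' @param config see [water_model_config()].
#' @return a `tissue_phantom`.
#' @export
build_water_model <- function(config = water_model_config()) {
  with(config, {
    stopifnot(water_volume > 0, container_radius > 0, cube_side >= 0,
              spacing > 0)
    has_seed <- cube_side > 0
    v_seed <- cube_side^3
    col_h <- water_column_height(water_volume + if (has_seed) v_seed else 0,
                                 container_radius)
    if (has_seed &&
        (cube_side > 2 * container_radius || cube_side > col_h))
      stop("geometry error: seed cube larger than the water domain")
    dims <- c(rep(ceiling(2 * container_radius / spacing) + 2L * margin, 2),
              ceiling(col_h / spacing) + 2L * margin)
    dims <- as.integer(dims)
    xc <- (seq_len(dims[1]) - 0.5) * spacing
    yc <- (seq_len(dims[2]) - 0.5) * spacing
    zc <- (seq_len(dims[3]) - 0.5) * spacing
    cx <- dims[1] * spacing / 2
    cy <- dims[2] * spacing / 2
    z0 <- margin * spacing           # bottom of the water column

    labels <- array("air", dim = dims)
    rad2 <- outer((xc - cx)^2, (yc - cy)^2, `+`)
    in_col_z <- zc >= z0 & zc <= z0 + col_h
    in_rad <- rad2 <= container_radius^2
    for (k in which(in_col_z)) labels[, , k][in_rad] <- "water"

    probes <- list()
    seeds <- NULL
    if (has_seed) {
      half <- cube_side / 2
      sc <- c(cx, cy, z0 + col_h / 2)   # seed centred in the column
      inx <- abs(xc - sc[1]) <= half
      iny <- abs(yc - sc[2]) <= half
      inz <- abs(zc - sc[3]) <= half
      labels[inx, iny, inz] <- "seed"
      spec <- photoseed_spec("cube", d_s = cube_side, L = cube_side,
                             A810 = A810, path_length = path_length)
      seeds <- list(spec = spec, center = sc)
      # just inside the bottom face, so the probe voxel is the seed surface
      probes$bottom <- c(sc[1], sc[2], sc[3] - half + spacing / 4)
      probes$P1 <- sc
      materials$seed$mu_a <- spec$mu_a_seed
      materials$seed$thermo <- spec$thermo
    } else {
      probes$bottom <- c(cx, cy, z0 + spacing / 2)
      probes$P1 <- c(cx, cy, z0 + col_h / 2)
    }
    new_tissue_phantom(dims, spacing, labels, materials, probes,
                       fluence_kernel = c(water = "water", air = "air",
                                          seed = "water"),
                       seeds = seeds)
  })
}

#' Per-voxel solver property fields of a phantom
#'
#' Expands the phantom's label array into the per-voxel fields the bioheat
#' solver consumes: volumetric heat capacity `rho_c` (J m^-3 K^-1), reference
#' conductivity `lambda37`, baseline volumetric perfusion conductance
#' `perf0 = rho_b c_b omega_b0` (W m^-3 K^-1) and metabolic heat `qmet`
#' (W m^-3).
#'
#' @param phantom a `tissue_phantom`.
#' @return list of numeric vectors, one value per voxel (x fastest).
#' @export
phantom_fields <- function(phantom) {
  labs <- as.vector(phantom$labels)
  ulab <- unique(labs)
  bl <- blood_properties()
  pick <- function(what) {
    lut <- vapply(ulab, function(l) {
      th <- phantom$materials[[l]]$thermo
      if (is.null(th)) stop("no thermo-physical properties for label ", l)
      switch(what,
             rho_c = th$rho * th$c,
             lambda37 = th$lambda_37,
             perf0 = bl$rho_b * bl$c_b * th$omega_b0,
             qmet = th$q_met)
    }, numeric(1))
    unname(lut[match(labs, ulab)])
  }
  list(rho_c = pick("rho_c"), lambda37 = pick("lambda37"),
       perf0 = pick("perf0"), qmet = pick("qmet"))
}

#' Per-voxel absorption coefficient field
#'
#' `mu_a` by label: tissue voxels use their optical-property table entry,
#' seed voxels the absorbance-derived `mu_a_seed`, and labels with no optical
#' data (water, air -- essentially transparent at 810 nm) zero.
#'
#' @param phantom a `tissue_phantom`.
#' @return numeric vector, m^-1, one value per voxel.
#' @export
phantom_mua_field <- function(phantom) {
  labs <- as.vector(phantom$labels)
  ulab <- unique(labs)
  lut <- vapply(ulab, function(l) {
    m <- phantom$materials[[l]]
    if (!is.null(m$optical)) m$optical$mu_a
    else if (!is.null(m$mu_a)) m$mu_a
    else 0
  }, numeric(1))
  unname(lut[match(labs, ulab)])
}
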