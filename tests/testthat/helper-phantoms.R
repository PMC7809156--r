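# Shared phantom builders for the tracing tests.

tube_phantom <- function(radius_vox = 4, shape = c(64, 64, 64),
                         noise_sd = 0, seed = 1L, voxel_nm = 100) {
  vox <- voxel_nm / 1000
  ext <- (shape - 1) * vox
  mid_y <- ext[2] / 2
  mid_z <- ext[1] / 2
  tube <- make_parametric_curve("line", list(
    start = c(4 * vox, mid_y, mid_z), direction = c(1, 0, 0),
    length = ext[3] - 8 * vox, radius = radius_vox * vox), 50)
  spec <- phantom_spec(shape = shape, voxel_size_nm = voxel_nm,
                       curves = list(list(polyline = tube)),
                       noise_sd = noise_sd, seed = seed)
  c(render_volume(spec), list(axis_y = mid_y, axis_z = mid_z, vox = vox,
                              radius_um = radius_vox * vox))
}

helix_phantom <- function(shape = c(128, 72, 72), noise_sd = 0, seed = 1L,
                          a = 2, b = 1, tube_radius = 0.4, voxel_nm = 100) {
  vox <- voxel_nm / 1000
  hx <- make_parametric_curve("helix", list(
    a = a, b = b, turns = 1.5,
    center = c((shape[3] - 1) * vox / 2, (shape[2] - 1) * vox / 2, 8 * vox),
    radius = tube_radius), 200)
  spec <- phantom_spec(shape = shape, voxel_size_nm = voxel_nm,
                       curves = list(list(polyline = hx)),
                       noise_sd = noise_sd, seed = seed)
  c(render_volume(spec), list(kappa_true = a / (a^2 + b^2),
                              tau_true = b / (a^2 + b^2)))
}

spiny_phantom <- function(n_spine_seed = 4L, shape = c(72, 72, 72),
                          voxel_nm = 100) {
  vox <- voxel_nm / 1000
  ext <- (shape - 1) * vox
  parent <- make_parametric_curve("line", list(
    start = c(5 * vox, ext[2] / 2, ext[1] / 2), direction = c(1, 0, 0),
    length = ext[3] - 10 * vox, radius = 0.3), 60)
  spines <- attach_spines(parent, density = 2,
                          length_dist = function(n) rep(1, n),
                          radius_dist = function(n) rep(0.15, n),
                          seed = n_spine_seed)
  curves <- c(list(list(polyline = parent, type = "neurite", id = "P")),
              lapply(spines, function(s) list(polyline = s$polyline,
                                              type = "spine",
                                              parent_id = "P")))
  spec <- phantom_spec(shape = shape, voxel_size_nm = voxel_nm,
                       curves = curves, noise_sd = 0)
  c(render_volume(spec), list(n_true_spines = length(spines)))
}

random_model <- function(seed) {
  withr::with_seed(seed, {
    n_con <- sample(1:6, 1)
    cons <- vector("list", n_con)
    for (i in seq_len(n_con)) {
      n_nodes <- sample(2:12, 1)
      pts <- matrix(runif(3 * n_nodes, 0, 50), ncol = 3)
      # ensure consecutive distinctness
      pts <- pts + outer(seq_len(n_nodes), c(1e-3, 0, 0))
      type <- sample(c("neurite", "apical_dendrite", "soma", "vessel"), 1)
      cons[[i]] <- list(id = sprintf("c%02d", i), type = type,
                        nodes = polyline(pts, runif(n_nodes, 0.05, 2)))
    }
    # attach a spine to a random parent node
    parent <- sample(n_con, 1)
    pn <- sample(nrow(cons[[parent]]$nodes), 1)
    sp_pts <- matrix(runif(9, 0, 50), ncol = 3) +
      outer(1:3, c(1e-3, 0, 0))
    cons[[n_con + 1L]] <- list(
      id = "sp01", type = "spine",
      nodes = polyline(sp_pts, runif(3, 0.05, 0.5)),
      attachment = list(parent_id = cons[[parent]]$id, parent_node = pn))
    node_model(cons, metadata = list(dataset = sprintf("D%03d", seed %% 999),
                                     case = "S1", group = "schizophrenia",
                                     area = "BA22"))
  })
}

demo_inputs <- function(root, n_cases = 2L, datasets_per_area = 1L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  vox_nm <- 100
  cases <- tidyr::expand_grid(
    case = sprintf("C%d", seq_len(n_cases)),
    area = c("BA22", "BA24"),
    rep = seq_len(datasets_per_area))
  cases$group <- ifelse(as.integer(sub("C", "", cases$case)) %% 2 == 1,
                        "schizophrenia", "control")
  cases$dataset <- sprintf("%s-%s-%d", cases$case, cases$area, cases$rep)
  vols <- list()
  for (i in seq_len(nrow(cases))) {
    # one curved neurite + two fixed spines per dataset; area-dependent
    # curvature via the arc radius
    arc_a <- if (cases$area[i] == "BA22") 2.2 else 3.5
    curve <- make_parametric_curve("circle", list(
      a = arc_a, turns = 0.12, center = c(2.35 - arc_a, 2.35, 2.35),
      phase = -0.15, radius = 0.25), 60)
    spines <- attach_spines(curve, density = 0.7,
                            length_dist = function(n) rep(0.9, n),
                            radius_dist = function(n) rep(0.14, n),
                            seed = 100 + i)
    curves <- c(list(list(polyline = curve, type = "neurite", id = "P")),
                lapply(spines, function(s) list(polyline = s$polyline,
                                                type = "spine",
                                                parent_id = "P")))
    ph <- phantom_spec(shape = c(48, 48, 48), voxel_size_nm = vox_nm,
                       curves = curves, noise_sd = 0.02, seed = 200 + i)
    rendered <- render_volume(ph)
    path <- file.path(root, paste0(cases$dataset[i], ".tif"))
    write_volume(rendered$volume, path)
    vols[[i]] <- tibble(path = path, dataset = cases$dataset[i],
                        voxel_size_nm = vox_nm)
  }
  list(volumes = dplyr::bind_rows(vols),
       case_table = dplyr::distinct(cases[, c("dataset", "case", "group",
                                              "area")]))
}

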