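#' Bite load case
#'
#' One cell of the study design: bilateral vs unilateral prehension,
#' anterior vs posterior bite position, at a given gape. In unilateral
#' cases only the biting side's prehension patch is constrained (the other
#' side balances); muscles on both sides are always active — asymmetry is
#' in the constraint pattern, not in muscle recruitment.
#'
#' @param id case label (the study used A–H).
#' @param symmetry `"bilateral"` or `"unilateral"`.
#' @param prehension `"anterior"` or `"posterior"`.
#' @param side biting side for unilateral cases.
#' @param gape a [gape_spec()].
#' @param scaled logical flag recorded in reports: loads scaled from a
#'   reference specimen.
#' @param scaling_method `"volume"` or `"area"` (recorded when `scaled`).
#' @return object of class `load_case`.
#' @export
load_case <- function(id, symmetry = c("bilateral", "unilateral"),
                      prehension = c("anterior", "posterior"),
                      side = c("left", "right"), gape = gape_spec(),
                      scaled = FALSE, scaling_method = c("volume", "area")) {
  structure(list(id = id, symmetry = match.arg(symmetry),
                 prehension = match.arg(prehension),
                 side = match.arg(side), gape = gape,
                 scaled = isTRUE(scaled),
                 scaling_method = match.arg(scaling_method)),
            class = "load_case")
}

# constraint entries for a load case on a skull-fixture patch layout
.case_constraints <- function(mesh, case) {
  pre <- paste0("prehension_", case$prehension)
  pre_patches <- if (case$symmetry == "bilateral")
    paste0(pre, c("_left", "_right")) else paste0(pre, "_", case$side)
  missing <- setdiff(c(pre_patches, "quadrate_left", "quadrate_right",
                       "condyle_left", "condyle_right"),
                     names(mesh$patches))
  if (length(missing))
    stop("mesh lacks patch(es) required by the case: ",
         paste(missing, collapse = ", "))
  entries <- c(
    lapply(pre_patches, function(p)
      list(patch = p, axes = c("x", "y", "z"), role = "prehension")),
    list(list(patch = "quadrate_left", axes = "y", role = "jaw_joint"),
         list(patch = "quadrate_right", axes = "y", role = "jaw_joint"),
         list(patch = "condyle_left", axes = "x", role = "condyle"),
         list(patch = "condyle_right", axes = "x", role = "condyle")))
  list(set = constraint_set(mesh, entries), prehension_patches = pre_patches)
}

.vm_region_means <- function(mesh, vm_node) {
  vapply(names(mesh$patches), function(nm) {
    ns <- patch_nodes(mesh, nm)
    mean(vm_node[ns])
  }, numeric(1))
}

.mesh_fingerprint <- function(mesh) {
  sprintf("n%d_e%d_%.6e", nrow(mesh$nodes), nrow(mesh$elems),
          sum(mesh$nodes^2) + sum(as.double(mesh$elems)))
}

#' Run one bite load case
#'
#' Assembles the muscle loads (both sides always active), applies the
#' case's constraint pattern (prehension fixed in x, y, z; jaw joints in
#' y; occipital condyles in x), solves the static problem, and extracts
#' the bite force as the resultant prehension reaction together with Von
#' Mises summaries.
#'
#' @param mesh skull mesh with the canonical patch layout (see
#'   [make_skull()]).
#' @param muscles list of [muscle_definition()].
#' @param case a [load_case()].
#' @param mat a [material()].
#' @param K optional pre-assembled stiffness (reused across cases on the
#'   same mesh).
#' @param out_dir optional directory: the solved field is written there as
#'   `case_<id>.vtu`.
#' @return object of class `bite_case_result`: the case, `bite_force`
#'   (resultant, magnitude, per-side), `vm_max`, `vm_mean`
#'   (volume-weighted), `region_mean` (nodal mean per patch), a per-role
#'   reaction breakdown, the applied-load total, the equilibrium residual,
#'   output paths and provenance.
#' @export
run_case <- function(mesh, muscles, case, mat, K = NULL, out_dir = NULL) {
  stopifnot(inherits(case, "load_case"), inherits(mat, "fem_material"))
  t0 <- proc.time()[["elapsed"]]
  cs <- .case_constraints(mesh, case)
  loads <- assemble_load_vector(mesh, muscles, case$gape)
  sol <- solve_mesh(mesh, mat, loads, cs$set, K = K)
  per_side <- lapply(cs$prehension_patches, function(p) {
    bf <- bite_force(sol, patch_nodes(mesh, p))
    bf$patch <- p
    bf
  })
  names(per_side) <- cs$prehension_patches
  total <- colSums(do.call(rbind, lapply(per_side, `[[`, "force")))
  roles <- unique(vapply(cs$set$entries, `[[`, "", "role"))
  reactions_by_role <- do.call(rbind, lapply(roles, function(rl) {
    f <- c(0, 0, 0)
    for (en in Filter(function(en) en$role == rl, cs$set$entries))
      f[en$axes] <- f[en$axes] +
        colSums(sol$reactions[en$nodes, en$axes, drop = FALSE])
    data.frame(role = rl, fx = f[1], fy = f[2], fz = f[3],
               magnitude = sqrt(sum(f^2)))
  }))
  vols <- element_volumes(mesh)
  applied <- colSums(matrix(loads, ncol = 3L, byrow = TRUE))
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, paste0("case_", case$id, ".vtu"))
    write_field_vtk(mesh, sol, p)
    paths <- p
  }
  res <- structure(list(
    case = case,
    bite_force = list(force = total, magnitude = sqrt(sum(total^2)),
                      per_side = per_side),
    vm_max = max(sol$stress$vm_elem),
    vm_mean = sum(sol$stress$vm_elem * vols) / sum(vols),
    region_mean = .vm_region_means(mesh, sol$stress$vm_node),
    reactions_by_role = reactions_by_role,
    applied_total = applied,
    equilibrium_residual = sol$equilibrium_residual,
    solution = sol,
    paths = paths,
    provenance = list(
      mesh = .mesh_fingerprint(mesh),
      label = mesh$metadata$label,
      gape = unclass(case$gape)[c(1, 2)],
      n_muscles = length(muscles),
      package_version = as.character(utils::packageVersion("biteFEM")),
      elapsed_s = proc.time()[["elapsed"]] - t0)),
    class = "bite_case_result")
  res
}

#' @export
print.bite_case_result <- function(x, ...) {
  cat(sprintf("case %s: %s %s prehension, gape %g deg%s\n", x$case$id,
              x$case$symmetry, x$case$prehension, x$case$gape$total_deg,
              if (x$case$scaled) paste0(" (", x$case$scaling_method,
                                        "-scaled)") else ""))
  cat(sprintf("  bite force %.4g N  (fx %.4g, fy %.4g, fz %.4g)\n",
              x$bite_force$magnitude, x$bite_force$force[1],
              x$bite_force$force[2], x$bite_force$force[3]))
  cat(sprintf("  Von Mises max %.4g MPa, mean %.4g MPa\n",
              x$vm_max, x$vm_mean))
  invisible(x)
}

#' Scale a reference muscle set onto a target specimen
#'
#' Recomputes each muscle's contraction pressure for the target mesh from
#' the reference mesh using the volume (two-thirds power) or enclosing-
#' surface scaling law, with insertion areas measured on both meshes.
#'
#' @param mesh_ref,mesh_tgt reference and target skull meshes.
#' @param muscles_ref reference muscle list (e.g. [skull_muscles()]).
#' @param method `"volume"` or `"area"`.
#' @return list of target [muscle_definition()] with scaled pressures; the
#'   per-muscle scaled pressures are attached as attribute
#'   `scaled_pressures`.
#' @export
scale_muscles <- function(mesh_ref, mesh_tgt, muscles_ref,
                          method = c("volume", "area")) {
  method <- match.arg(method)
  V_ref <- mesh_volume(mesh_ref); V_tgt <- mesh_volume(mesh_tgt)
  S_ref <- mesh_surface_area(mesh_ref); S_tgt <- mesh_surface_area(mesh_tgt)
  tgt <- skull_muscles(mesh_tgt, pressure = 0)
  ps <- numeric(0)
  for (i in seq_along(muscles_ref)) {
    m <- muscles_ref[[i]]
    s <- scaling_inputs(V_ref = V_ref, V_tgt = V_tgt,
                        S_ref = S_ref, S_tgt = S_tgt,
                        SM_ref = patch_area(mesh_ref, m$patch),
                        SM_tgt = patch_area(mesh_tgt, m$patch))
    p <- if (method == "volume") scale_pressure_volume(m$pressure, s)
         else scale_pressure_area(m$pressure, s)
    j <- which(vapply(tgt, `[[`, "", "name") == m$name)
    if (length(j) != 1L)
      stop("target mesh has no muscle matching '", m$name, "'")
    tgt[[j]]$pressure <- p
    ps[m$name] <- p
  }
  attr(tgt, "scaled_pressures") <- ps
  tgt
}

#' Run the full case matrix on a specimen pair
#'
#' Reproduces the study design: bilateral/unilateral x anterior/posterior
#' prehension on the reference specimen with its nominal muscle pressures
#' (cases A–D) and on the target specimen with pressures scaled by the
#' chosen law (cases E–H). The stiffness of each mesh is assembled once
#' and reused across its four cases.
#'
#' @param mesh_ref,mesh_tgt reference (adult) and target (subadult) meshes.
#' @param scenario list with entries `material` (a [material()] or list
#'   with E, nu), `pressure` (reference contraction pressure, MPa), `gape`
#'   (a [gape_spec()]), `scaling` (`"volume"` or `"area"`), and optional
#'   `side` for unilateral cases; see [read_scenario()].
#' @param out_dir optional output directory for per-case VTK fields and a
#'   `cases.csv` summary.
#' @return list of eight `bite_case_result`; the scaled target pressures
#'   are attached as attribute `scaled_pressures`.
#' @export
run_matrix <- function(mesh_ref, mesh_tgt, scenario = list(),
                       out_dir = NULL) {
  mat <- scenario$material
  if (is.null(mat)) mat <- material()
  if (!inherits(mat, "fem_material")) mat <- material(mat$E, mat$nu)
  pressure <- if (is.null(scenario$pressure)) 0.3 else scenario$pressure
  gape <- if (is.null(scenario$gape)) gape_spec() else scenario$gape
  method <- if (is.null(scenario$scaling)) "volume" else scenario$scaling
  side <- if (is.null(scenario$side)) "left" else scenario$side

  mus_ref <- skull_muscles(mesh_ref, pressure = pressure)
  mus_tgt <- scale_muscles(mesh_ref, mesh_tgt, mus_ref, method = method)

  grid <- expand.grid(prehension = c("anterior", "posterior"),
                      symmetry = c("bilateral", "unilateral"),
                      specimen = c("ref", "tgt"), stringsAsFactors = FALSE)
  grid <- grid[order(grid$specimen == "tgt", grid$symmetry, grid$prehension), ]
  ids <- LETTERS[1:8]
  K_ref <- assemble(mesh_ref, mat)
  K_tgt <- assemble(mesh_tgt, mat)
  results <- vector("list", 8L)
  for (i in 1:8) {
    g <- grid[i, ]
    case <- load_case(ids[i], symmetry = g$symmetry,
                      prehension = g$prehension, side = side, gape = gape,
                      scaled = g$specimen == "tgt", scaling_method = method)
    mesh <- if (g$specimen == "ref") mesh_ref else mesh_tgt
    mus <- if (g$specimen == "ref") mus_ref else mus_tgt
    K <- if (g$specimen == "ref") K_ref else K_tgt
    message(sprintf("case %s: %s %s (%s)", ids[i], g$symmetry,
                    g$prehension, g$specimen))
    results[[i]] <- run_case(mesh, mus, case, mat, K = K, out_dir = out_dir)
  }
  names(results) <- ids
  if (!is.null(out_dir)) {
    tab <- do.call(rbind, lapply(results, function(r)
      data.frame(case = r$case$id, symmetry = r$case$symmetry,
                 prehension = r$case$prehension,
                 scaled = r$case$scaled, gape_deg = r$case$gape$total_deg,
                 bite_force_N = r$bite_force$magnitude,
                 vm_max_MPa = r$vm_max, vm_mean_MPa = r$vm_mean)))
    utils::write.csv(tab, file.path(out_dir, "cases.csv"),
                     row.names = FALSE)
  }
  attr(results, "scaled_pressures") <- attr(mus_tgt, "scaled_pressures")
  results
}

#' Compare two case results
#'
#' Ratios and differences (target over reference) of bite force and Von
#' Mises summaries, per shared reporting region — the cross-specimen
#' comparison the scaling laws exist for.
#'
#' @param ref,tgt `bite_case_result` objects with the same case structure
#'   (symmetry and prehension position).
#' @return list with `bite_force_ratio`, `vm_max_ratio`, `vm_mean_ratio`,
#'   and a `regions` data.frame of per-region mean ratios and differences.
#' @export
compare_results <- function(ref, tgt) {
  stopifnot(inherits(ref, "bite_case_result"),
            inherits(tgt, "bite_case_result"))
  if (ref$case$symmetry != tgt$case$symmetry ||
      ref$case$prehension != tgt$case$prehension)
    stop("case structures differ (symmetry/prehension); results are not ",
         "comparable")
  shared <- intersect(names(ref$region_mean), names(tgt$region_mean))
  list(bite_force_ratio = tgt$bite_force$magnitude / ref$bite_force$magnitude,
       vm_max_ratio = tgt$vm_max / ref$vm_max,
       vm_mean_ratio = tgt$vm_mean / ref$vm_mean,
       regions = data.frame(
         region = shared,
         ref_mean = ref$region_mean[shared],
         tgt_mean = tgt$region_mean[shared],
         ratio = tgt$region_mean[shared] / ref$region_mean[shared],
         difference = tgt$region_mean[shared] - ref$region_mean[shared],
         row.names = NULL))
}

#' Read a scenario configuration file
#'
#' YAML with sections `material` (E, nu), `muscles` (pressure, or a
#' per-muscle table with name/patch/pressure/jaw_point/side), `gape`
#' (elevation_deg, depression_deg), `scaling` (method), `cases` (side for
#' unilateral cases).
#'
#' @param path YAML file path.
#' @return scenario list as consumed by [run_matrix()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$material))
    out$material <- material(cfg$material$E, cfg$material$nu)
  if (!is.null(cfg$muscles$pressure)) out$pressure <- cfg$muscles$pressure
  if (!is.null(cfg$muscles$table))
    out$muscles <- lapply(cfg$muscles$table, function(m)
      muscle_definition(m$name, m$patch, m$pressure,
                        as.numeric(m$jaw_point), m$side))
  if (!is.null(cfg$gape))
    out$gape <- gape_spec(cfg$gape$elevation_deg %||% 6,
                          cfg$gape$depression_deg %||% 0)
  if (!is.null(cfg$scaling)) out$scaling <- cfg$scaling$method %||% cfg$scaling
  if (!is.null(cfg$cases$side)) out$side <- cfg$cases$side
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration file
#'
#' @param scenario scenario list (see [run_matrix()]).
#' @param path output YAML path.
#' @return invisibly `path`.
#' @export
write_scenario <- function(scenario, path) {
  cfg <- list()
  if (!is.null(scenario$material))
    cfg$material <- list(E = scenario$material$E, nu = scenario$material$nu)
  if (!is.null(scenario$pressure))
    cfg$muscles <- list(pressure = scenario$pressure)
  if (!is.null(scenario$muscles))
    cfg$muscles$table <- lapply(scenario$muscles, function(m)
      list(name = m$name, patch = m$patch, pressure = m$pressure,
           jaw_point = m$jaw_point, side = m$side))
  if (!is.null(scenario$gape))
    cfg$gape <- list(elevation_deg = scenario$gape$skull_elevation_deg,
                     depression_deg = scenario$gape$mandible_depression_deg)
  if (!is.null(scenario$scaling))
    cfg$scaling <- list(method = scenario$scaling)
  if (!is.null(scenario$side)) cfg$cases <- list(side = scenario$side)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
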