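#' Deterministic synthetic mesh fixtures
#'
#' Parametric closed meshes with known analytic volumes, for oracle tests
#' and toy benchmarks: spheres and ellipsoids (subdivided icosahedra),
#' boxes, and two-lobe shapes (two disjoint spheres), optionally with
#' Gaussian vertex jitter. The analytic volume of the smooth counterpart is
#' attached as the `analytic_volume` attribute (sphere 4*pi*r^3/3, box
#' 8*a*b*c, ellipsoid 4*pi*a*b*c/3, two_lobe the sum of its spheres); the
#' inscribed triangulation approaches it from below. Identical parameters
#' and seed give bit-identical output.
#'
#' @param kind `"sphere"`, `"box"`, `"ellipsoid"` or `"two_lobe"`.
#' @param radius sphere radius (Å).
#' @param half_extents box half-extents (length 3, Å).
#' @param radii ellipsoid semi-axes (length 3) or two_lobe sphere radii
#'   (length 2), Å.
#' @param separation center-to-center distance of the two lobes (default:
#'   just disjoint).
#' @param subdivisions icosphere subdivision level (default 3).
#' @param jitter_sd Gaussian vertex jitter (Å, default 0).
#' @param seed RNG seed used when `jitter_sd > 0`.
#' @return a [tri_mesh] with attribute `analytic_volume`.
#' @export
make_mesh_fixture <- function(kind = c("sphere", "box", "ellipsoid",
                                       "two_lobe"),
                              radius = 1, half_extents = c(1, 1, 1),
                              radii = c(1, 0.7, 0.4), separation = NULL,
                              subdivisions = 3, jitter_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  m <- switch(kind,
    sphere = {
      out <- generate_sphere_mesh(radius, subdivisions)
      attr(out, "analytic_volume") <- 4 * pi * radius^3 / 3
      out
    },
    box = {
      out <- generate_box_mesh(half_extents)
      attr(out, "analytic_volume") <- 8 * prod(half_extents)
      out
    },
    ellipsoid = {
      stopifnot(length(radii) == 3, all(radii > 0))
      s <- generate_sphere_mesh(1, subdivisions)
      out <- tri_mesh(sweep(s$vertices, 2, radii, `*`), s$facets)
      attr(out, "analytic_volume") <- 4 * pi * prod(radii) / 3
      out
    },
    two_lobe = {
      r <- radii[1:2]
      stopifnot(all(r > 0))
      if (is.null(separation)) separation <- sum(r) * 1.25
      s1 <- generate_sphere_mesh(r[1], subdivisions)
      s2 <- generate_sphere_mesh(r[2], subdivisions)
      out <- merge_meshes(list(
        tri_mesh(sweep(s1$vertices, 2, c(-separation / 2, 0, 0)), s1$facets),
        tri_mesh(sweep(s2$vertices, 2, c(separation / 2, 0, 0)), s2$facets)))
      attr(out, "analytic_volume") <- 4 * pi * (r[1]^3 + r[2]^3) / 3
      out
    })
  if (jitter_sd > 0) {
    av <- attr(m, "analytic_volume")
    set.seed(seed)
    m <- tri_mesh(m$vertices +
                    matrix(stats::rnorm(length(m$vertices), 0, jitter_sd),
                           ncol = 3),
                  m$facets)
    attr(m, "analytic_volume") <- av
  }
  m
}

# One ideal-helix residue: CA on a helix of 2.3 Å radius, 1.5 Å rise and
# 100 degrees per residue; N/C flank the CA along the helix, O and CB point
# outward. Geometrically plausible, which is all the pipeline needs.
helix_residue_atoms <- function(i, origin = c(0, 0, 0)) {
  ang <- function(k) (k * 100) * pi / 180
  pos <- function(k, r = 2.3) {
    origin + c(r * cos(ang(k)), r * sin(ang(k)), 1.5 * k)
  }
  ca <- pos(i)
  out_dir <- c(cos(ang(i)), sin(ang(i)), 0)
  list(N = pos(i - 0.35), CA = ca, C = pos(i + 0.35),
       O = pos(i + 0.35) + 1.23 * out_dir, CB = ca + 1.53 * out_dir)
}

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1, alt = "", record = "ATOM",
                          element = substring(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resid, chain, resno, "", xyz[1], xyz[2], xyz[3], occ, 0,
          element)
}

#' Generate a synthetic mini-protein PDB file
#'
#' Ideal alpha-helical chains (backbone + CB) written as PDB text, with
#' optional decorations exercising every cleaning and selection rule: water
#' molecules, an altloc pair, a selenomethionine with its MODRES record, a
#' REMARK 350 assembly with n copies, and a distal disordered tail placed
#' at >= 5 times the body radius so the outlier stage flags exactly the
#' tail.
#'
#' @param n_res residues per chain.
#' @param chains chain identifiers (one helix each, offset in y).
#' @param tail_len residues of the planted distal tail (on the first
#'   chain).
#' @param waters number of water (HOH) molecules to add.
#' @param altloc add an A/B altloc pair on residue 2's CB (occupancies
#'   0.4/0.6).
#' @param modres make residue 3 a selenomethionine (MSE) with a MODRES
#'   record.
#' @param assembly_copies if > 0, write a REMARK 350 assembly whose BIOMT
#'   operators produce this many copies (identity plus x-translations).
#' @return character vector of PDB lines.
#' @export
make_mini_protein <- function(n_res = 20, chains = "A", tail_len = 0,
                              waters = 0, altloc = FALSE, modres = FALSE,
                              assembly_copies = 0) {
  lines <- character(0)
  if (modres) {
    lines <- c(lines, paste0("MODRES ", sprintf("%4s %3s %1s %4d%1s %3s",
                                                "XXXX", "MSE", chains[1],
                                                3L, " ", "MET")))
  }
  if (assembly_copies > 0) {
    lines <- c(lines, "REMARK 350 BIOMOLECULE: 1",
               paste0("REMARK 350 APPLY THE FOLLOWING TO CHAINS: ",
                      paste(chains, collapse = ", ")))
    for (i in seq_len(assembly_copies)) {
      shift <- (i - 1) * 50
      rows <- rbind(c(1, 0, 0, shift), c(0, 1, 0, 0), c(0, 0, 1, 0))
      for (rr in 1:3) {
        lines <- c(lines, sprintf(
          "REMARK 350   BIOMT%d %3d %9.6f %9.6f %9.6f %14.5f",
          rr, i, rows[rr, 1], rows[rr, 2], rows[rr, 3], rows[rr, 4]))
      }
    }
  }
  serial <- 0L
  emit <- function(name, resid, chain, resno, xyz, occ = 1, alt = "",
                   record = "ATOM", element = substring(name, 1, 1)) {
    serial <<- serial + 1L
    pdb_atom_line(serial, name, resid, chain, resno, xyz, occ, alt,
                  record, element)
  }
  body_radius <- sqrt(2.3^2 + (1.5 * n_res / 2)^2)
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    origin <- c(0, (ci - 1) * 14, 0)
    for (i in seq_len(n_res)) {
      at <- helix_residue_atoms(i, origin)
      resid <- "ALA"
      if (modres && ci == 1 && i == 3) {
        # selenomethionine: HETATM records, MODRES maps it back to MET
        lines <- c(lines,
                   emit("N", "MSE", ch, i, at$N, record = "HETATM"),
                   emit("CA", "MSE", ch, i, at$CA, record = "HETATM"),
                   emit("C", "MSE", ch, i, at$C, record = "HETATM"),
                   emit("O", "MSE", ch, i, at$O, record = "HETATM"),
                   emit("SE", "MSE", ch, i, at$CB, record = "HETATM",
                        element = "SE"))
        next
      }
      lines <- c(lines, emit("N", resid, ch, i, at$N),
                 emit("CA", resid, ch, i, at$CA),
                 emit("C", resid, ch, i, at$C),
                 emit("O", resid, ch, i, at$O))
      if (altloc && ci == 1 && i == 2) {
        lines <- c(lines,
                   emit("CB", resid, ch, i, at$CB, occ = 0.4, alt = "A"),
                   emit("CB", resid, ch, i, at$CB + c(0.4, 0, 0),
                        occ = 0.6, alt = "B"))
      } else {
        lines <- c(lines, emit("CB", resid, ch, i, at$CB))
      }
    }
    if (ci == 1 && tail_len > 0) {
      # disordered tail: residues flung to >= 5 body radii in spread
      # directions, so no single principal axis can absorb their variance
      base <- 5 * body_radius
      center <- origin + c(0, 0, 0.75 * n_res)
      for (t in seq_len(tail_len)) {
        dir <- c(cos(2.4 * t), sin(2.4 * t), 0.5)
        dir <- dir / sqrt(sum(dir^2))
        xyz <- center + dir * (base + 6 * t)
        resno <- n_res + t
        lines <- c(lines, emit("N", "GLY", ch, resno, xyz + c(-0.5, 0, 0)),
                   emit("CA", "GLY", ch, resno, xyz),
                   emit("C", "GLY", ch, resno, xyz + c(0.5, 0, 0)),
                   emit("O", "GLY", ch, resno, xyz + c(0.5, 1.2, 0)))
      }
    }
    lines <- c(lines, "TER")
  }
  for (w in seq_len(waters)) {
    lines <- c(lines, emit("O", "HOH", "W", w, c(8 + w, -5, 3),
                           record = "HETATM", element = "O"))
  }
  c(lines, "END")
}

#' Generate a point cloud with planted structural outliers
#'
#' Isotropic Gaussian core plus planted points at a stated distance (in
#' units of the core standard deviation) along random directions — the test
#' bed for the outlier detection stage. Deterministic under a fixed seed.
#'
#' @param n_core Gaussian core points.
#' @param n_out planted outliers.
#' @param distance_sigma outlier distance from the center, in core sigmas.
#' @param sigma core standard deviation (Å, default 1).
#' @param seed RNG seed.
#' @return list with `points` (a [point_cloud]) and `is_outlier` (logical,
#'   TRUE for the planted rows, which come last).
#' @export
make_outlier_cloud <- function(n_core, n_out = 0, distance_sigma = 10,
                               sigma = 1, seed = 1) {
  set.seed(seed)
  core <- matrix(stats::rnorm(3 * n_core, 0, sigma), ncol = 3)
  if (n_out > 0) {
    dirs <- matrix(stats::rnorm(3 * n_out), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    out <- dirs * distance_sigma * sigma
    coords <- rbind(core, out)
  } else {
    coords <- core
  }
  list(points = point_cloud(coords),
       is_outlier = c(rep(FALSE, n_core), rep(TRUE, n_out)))
}
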