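# Standard amino acids recognised as protein residues after cleaning.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

WATER_NAMES <- c("HOH", "DOD", "WAT", "H2O")

structure_obj <- function(atoms, modres, assemblies, chain_order,
                          cleaned = FALSE) {
  structure(list(atoms = atoms, modres = modres, assemblies = assemblies,
                 chain_order = chain_order, cleaned = cleaned),
            class = "zc_structure")
}

#' @export
print.zc_structure <- function(x, ...) {
  cat(sprintf(paste0("zc_structure: %d atoms, %d chains (%s), %d MODRES, ",
                     "%d assemblies%s\n"),
              nrow(x$atoms), length(x$chain_order),
              paste(x$chain_order, collapse = ""),
              length(x$modres), length(x$assemblies),
              if (x$cleaned) ", cleaned" else ""))
  invisible(x)
}

#' Parse a PDB file
#'
#' ATOM and HETATM records are parsed with fixed-column semantics through
#' bio3d; the MODRES map (modified residue name to standard parent) and the
#' REMARK 350 biological assemblies (assembly id, APPLY-TO chain lists,
#' BIOMT rigid transforms) are parsed from the header, which bio3d does not
#' expose. For multi-model (NMR) files only the first conformer is kept.
#' A missing REMARK 350 block yields an empty assembly list.
#'
#' @param path path to a PDB-format text file.
#' @return an object of class `zc_structure` with elements `atoms` (data
#'   frame: type, eleno, elety, alt, resid, chain, resno, insert, x, y, z,
#'   o, elesy), `modres` (named character vector), `assemblies` (list of
#'   `list(id, chains, transforms)` with 3x4 matrices) and `chain_order`
#'   (chain identifiers in file order).
#' @export
parse_pdb <- function(path) {
  if (!file.exists(path)) stop("parse_pdb: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("parse_pdb: ", conditionMessage(e)))
  a <- pdb$atom
  atoms <- data.frame(
    type = a$type, eleno = a$eleno, elety = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid, chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    elesy = ifelse(is.na(a$elesy), "", trimws(a$elesy)),
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) |
                   !is.finite(atoms$z))[1]
    stop("parse_pdb: unreadable coordinates for atom record ", bad)
  }
  # MODRES: columns 13-15 modified name, 25-27 standard parent name
  modres <- character(0)
  for (ln in grep("^MODRES", lines, value = TRUE)) {
    mod <- trimws(substring(ln, 13, 15))
    std <- trimws(substring(ln, 25, 27))
    if (nzchar(mod) && nzchar(std)) modres[mod] <- std
  }
  assemblies <- parse_remark350(lines)
  structure_obj(atoms, modres, assemblies, unique(atoms$chain))
}

parse_remark350 <- function(lines) {
  r350 <- grep("^REMARK 350", lines, value = TRUE)
  assemblies <- list()
  cur <- NULL
  rows <- list()
  flush_assembly <- function() {
    if (is.null(cur)) return()
    k <- length(rows)
    if (k %% 3 != 0) stop("parse_pdb: incomplete BIOMT block in REMARK 350")
    transforms <- lapply(seq_len(k %/% 3), function(i) {
      m <- do.call(rbind, rows[(3 * i - 2):(3 * i)])
      dimnames(m) <- NULL
      m
    })
    cur$transforms <- transforms
    assemblies[[length(assemblies) + 1L]] <<- cur
  }
  for (ln in r350) {
    if (grepl("BIOMOLECULE:", ln)) {
      flush_assembly()
      rows <- list()
      cur <- list(id = trimws(sub(".*BIOMOLECULE:", "", ln)),
                  chains = character(0), transforms = list())
    } else if (grepl("(APPLY THE FOLLOWING TO CHAINS:|AND CHAINS:)", ln)) {
      ch <- sub(".*CHAINS:", "", ln)
      ch <- trimws(strsplit(ch, ",")[[1]])
      if (!is.null(cur)) cur$chains <- c(cur$chains, ch[nzchar(ch)])
    } else if (grepl("BIOMT[123]", ln)) {
      tk <- strsplit(trimws(sub(".*BIOMT[123]", "", ln)),
                     "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(tk))
      if (length(vals) < 5 || any(is.na(vals))) {
        stop("parse_pdb: malformed BIOMT record: ", ln)
      }
      rows[[length(rows) + 1L]] <- vals[2:5]  # drop the operator index
    }
  }
  flush_assembly()
  assemblies
}

is_hydrogen <- function(elety, elesy) {
  sy <- toupper(elesy)
  known <- sy %in% c("H", "D")
  # fall back on the atom-name convention when the element column is absent
  noel <- !nzchar(sy)
  first_alpha <- sub("^[0-9']*", "", toupper(elety))
  known | (noel & substring(first_alpha, 1, 1) %in% c("H", "D"))
}

#' Clean a parsed structure
#'
#' Applies the standard preparation: waters removed; for each alternative
#' location group only the rotamer with the highest occupancy is kept (ties
#' broken by file order, typically altloc A); hydrogen and deuterium atoms
#' removed; non-protein entities (nucleic acids, ligands, ions) removed,
#' where "protein" means the 20 standard amino acids plus any MODRES residue
#' whose standard parent is one of them. Idempotent.
#'
#' @param s a `zc_structure`.
#' @return the cleaned `zc_structure` (possibly with zero atoms).
#' @export
clean_structure <- function(s) {
  stopifnot(inherits(s, "zc_structure"))
  a <- s$atoms
  a <- a[!(a$resid %in% WATER_NAMES), , drop = FALSE]
  a <- a[!is_hydrogen(a$elety, a$elesy), , drop = FALSE]
  if (nrow(a) > 0) {
    key <- paste(a$chain, a$resno, a$insert, a$resid, a$elety)
    ord <- order(-a$o)                       # stable: file order breaks ties
    keep <- !duplicated(key[ord])
    sel <- sort(ord[keep])
    a <- a[sel, , drop = FALSE]
    a$alt <- ""
  }
  protein <- a$resid %in% AA3 |
    (a$resid %in% names(s$modres) & s$modres[a$resid] %in% AA3)
  a <- a[protein, , drop = FALSE]
  rownames(a) <- NULL
  structure_obj(a, s$modres, s$assemblies, unique(a$chain), cleaned = TRUE)
}

# (resno, insert) lexicographic comparison keys; "" sorts before "A".
residue_sort_key <- function(resno, insert) {
  resno * 128 + match(toupper(ifelse(insert == "", " ", insert)),
                      c(" ", LETTERS)) - 1
}

parse_residue_endpoint <- function(tok) {
  m <- regmatches(tok, regexec("^(-?[0-9]+)([A-Za-z]?)$", tok))[[1]]
  if (length(m) == 0) {
    stop("select_fragment: malformed residue endpoint '", tok, "'")
  }
  residue_sort_key(as.integer(m[2]), m[3])
}

#' Select chains and residue ranges from a structure
#'
#' Selection expressions follow the `CODE:CHAINS[(FROM-TO)]` convention used
#' for PDB fragments: `1KFV:A` (one chain), `1KFV:A+D+G` (an explicit list),
#' `1KFV:B-H` (an implicit list expanded over the file's chain order), and
#' `1KFV:(A+B)(30-100)` (residues 30-100 of chains A and B). The `CODE:`
#' prefix is optional, and when the chain part is omitted all chains are
#' selected. ASCII hyphen, Unicode minus and en-dash are all accepted as the
#' range separator. Residue ranges compare (number, insertion code)
#' lexicographically.
#'
#' @param s a `zc_structure`.
#' @param expr selection string.
#' @return the selected `zc_structure`.
#' @export
select_fragment <- function(s, expr) {
  stopifnot(inherits(s, "zc_structure"), is.character(expr),
            length(expr) == 1)
  e <- gsub("−|–", "-", trimws(expr))
  e <- sub("^[A-Za-z0-9_]+:", "", e)
  chain_part <- e
  range_part <- NULL
  m <- regmatches(e, regexec("^\\(([^)]*)\\)\\(([^)]*)\\)$", e))[[1]]
  if (length(m) == 3) {
    chain_part <- m[2]; range_part <- m[3]
  } else {
    m <- regmatches(e, regexec("^\\(([^)]*)\\)$", e))[[1]]
    if (length(m) == 2) {
      chain_part <- m[2]
    } else {
      m <- regmatches(e, regexec("^([^()]*)\\(([^)]*)\\)$", e))[[1]]
      if (length(m) == 3) {
        chain_part <- m[2]; range_part <- m[3]
      } else if (grepl("[()]", e)) {
        stop("select_fragment: malformed selection '", expr, "'")
      }
    }
  }
  chain_part <- trimws(chain_part)
  chains <- if (!nzchar(chain_part)) {
    s$chain_order
  } else if (grepl("\\+", chain_part)) {
    strsplit(chain_part, "+", fixed = TRUE)[[1]]
  } else if (grepl("-", chain_part, fixed = TRUE)) {
    ends <- strsplit(chain_part, "-", fixed = TRUE)[[1]]
    if (length(ends) != 2) {
      stop("select_fragment: malformed chain range '", chain_part, "'")
    }
    i <- match(ends, s$chain_order)
    if (any(is.na(i))) {
      stop("select_fragment: chain '", ends[which(is.na(i))[1]],
           "' not present")
    }
    s$chain_order[i[1]:i[2]]
  } else {
    chain_part
  }
  missing <- setdiff(chains, s$chain_order)
  if (length(missing) > 0) {
    stop("select_fragment: chain '", missing[1], "' not present")
  }
  a <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  if (!is.null(range_part)) {
    ends <- strsplit(trimws(range_part), "-", fixed = TRUE)[[1]]
    if (length(ends) != 2) {
      stop("select_fragment: malformed residue range '", range_part, "'")
    }
    lo <- parse_residue_endpoint(trimws(ends[1]))
    hi <- parse_residue_endpoint(trimws(ends[2]))
    key <- residue_sort_key(a$resno, a$insert)
    a <- a[key >= lo & key <= hi, , drop = FALSE]
  }
  rownames(a) <- NULL
  structure_obj(a, s$modres, s$assemblies, unique(a$chain), s$cleaned)
}

#' Reconstruct a biological assembly
#'
#' Applies each BIOMT rigid transform of the requested REMARK 350 assembly to
#' the chains it names, concatenating the transformed copies. Copies beyond
#' the first get distinct chain identifiers (a copy index is appended), so
#' the output atom count equals the per-transform selected atom count times
#' the number of transforms.
#'
#' @param s a `zc_structure` whose `assemblies` contain `assembly_id`.
#' @param assembly_id assembly identifier as given in REMARK 350
#'   (character or integer).
#' @return a `zc_structure` of the expanded assembly.
#' @export
build_assembly <- function(s, assembly_id) {
  stopifnot(inherits(s, "zc_structure"))
  ids <- vapply(s$assemblies, function(a) as.character(a$id), "")
  hit <- which(ids == as.character(assembly_id))
  if (length(hit) != 1) {
    stop("build_assembly: unknown assembly id '", assembly_id, "'")
  }
  asm <- s$assemblies[[hit]]
  chains <- if (length(asm$chains) > 0) asm$chains else s$chain_order
  base <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  if (nrow(base) == 0) stop("build_assembly: assembly selects no atoms")
  copies <- lapply(seq_along(asm$transforms), function(i) {
    tr <- asm$transforms[[i]]
    xyz <- as.matrix(base[, c("x", "y", "z")]) %*% t(tr[, 1:3])
    out <- base
    out$x <- xyz[, 1] + tr[1, 4]
    out$y <- xyz[, 2] + tr[2, 4]
    out$z <- xyz[, 3] + tr[3, 4]
    if (i > 1) out$chain <- paste0(out$chain, i)
    out
  })
  a <- do.call(rbind, copies)
  rownames(a) <- NULL
  structure_obj(a, s$modres, s$assemblies, unique(a$chain), s$cleaned)
}

#' Effective atoms of a structure
#'
#' One pseudo-atom per residue at the unweighted mean position of the
#' residue's heavy atoms — the standard per-residue reduction used by the
#' outlier detection and the distance-histogram feature. The structure
#' should be cleaned first so hydrogens cannot shift the centroids.
#'
#' @param s a cleaned `zc_structure`.
#' @return an object of class `point_cloud`: list with `coords` (n x 3
#'   matrix, Å) and `labels` (chain:resno identifiers, aligned with rows).
#' @export
effective_atoms <- function(s) {
  stopifnot(inherits(s, "zc_structure"))
  a <- s$atoms
  if (nrow(a) == 0) stop("effective_atoms: structure has no atoms")
  key <- paste0(a$chain, ":", a$resno, a$insert)
  key <- factor(key, levels = unique(key))   # keep file order
  cx <- rowsum(cbind(a$x, a$y, a$z), key, reorder = FALSE)
  n <- as.vector(rowsum(rep(1, nrow(a)), key, reorder = FALSE))
  point_cloud(cx / n, levels(key))
}

#' @rdname effective_atoms
#' @param coords n x 3 numeric matrix of points (Å).
#' @param labels identifiers aligned with the rows of `coords`.
#' @export
point_cloud <- function(coords, labels = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3, dimnames = NULL)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(coords)))
  stopifnot(length(labels) == nrow(coords))
  structure(list(coords = coords, labels = as.character(labels)),
            class = "point_cloud")
}

#' Split a structure into per-chain backbones
#'
#' Strips the structure down to its N, CA, C, O backbone atoms and splits it
#' into one structure per chain. The backbone-mode surface workflow sends
#' each chain separately to the surface program and merges the resulting
#' meshes by plain concatenation.
#'
#' @param s a cleaned `zc_structure`.
#' @return a named list of per-chain `zc_structure` objects.
#' @export
backbone_chains <- function(s) {
  stopifnot(inherits(s, "zc_structure"))
  a <- s$atoms[s$atoms$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  out <- lapply(s$chain_order, function(ch) {
    ai <- a[a$chain == ch, , drop = FALSE]
    rownames(ai) <- NULL
    structure_obj(ai, s$modres, s$assemblies, ch, s$cleaned)
  })
  names(out) <- s$chain_order
  out
}

#' Merge meshes by concatenation
#'
#' Concatenates vertex and facet arrays with index offsets, without vertex
#' welding; adequate for per-chain molecular surfaces, which do not touch.
#'
#' @param meshes list of [tri_mesh] objects.
#' @return a single [tri_mesh].
#' @export
merge_meshes <- function(meshes) {
  stopifnot(length(meshes) >= 1)
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), 0L)))
  v <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  f <- do.call(rbind, lapply(seq_along(meshes),
                             function(i) meshes[[i]]$facets + offs[i]))
  tri_mesh(v, f)
}

#' Van der Waals radius tables
#'
#' `load_radii()` reads a NACCESS-style residue library: a whitespace-
#' delimited text file with columns residue name, atom name, radius (Å).
#' The table shipped with the package assigns the NACCESS radius classes
#' (aliphatic C 1.87, aromatic/carbonyl C 1.76, N 1.65, O 1.40, S 1.85) to
#' the heavy atoms of the 20 standard amino acids. `load_element_radii()`
#' reads the per-element fallback table used for atoms absent from the
#' residue library; its values are conventional van der Waals radii.
#'
#' @param path optional path to an alternative table.
#' @return named numeric vector: `"RES ATOM"` keys (or element symbols) to
#'   radii in Å.
#' @export
load_radii <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_radii.txt", package = "zcmesh")
  }
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("resid", "elety", "radius"),
                    stringsAsFactors = FALSE)
  stats::setNames(tab$radius, paste(tab$resid, tab$elety))
}

#' @rdname load_radii
#' @export
load_element_radii <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "element_radii.txt", package = "zcmesh")
  }
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("elesy", "radius"),
                    stringsAsFactors = FALSE)
  stats::setNames(tab$radius, toupper(tab$elesy))
}

#' Write an xyzr file for the surface program
#'
#' One line per atom: `x y z r` with fixed three-decimal formatting, the
#' input format of MSMS. Radii resolve in order: the (residue, atom) entry
#' of the radii table; the (standard parent, atom) entry via the MODRES map
#' (a selenomethionine CA inherits the methionine CA radius); the
#' per-element default.
#'
#' @param s a cleaned `zc_structure`.
#' @param path output path.
#' @param radii named radius table from [load_radii].
#' @param element_radii named per-element fallback from
#'   [load_element_radii].
#' @return invisibly, the number of lines written.
#' @export
write_xyzr <- function(s, path, radii = load_radii(),
                       element_radii = load_element_radii()) {
  stopifnot(inherits(s, "zc_structure"))
  a <- s$atoms
  r <- radii[paste(a$resid, a$elety)]
  parent <- s$modres[a$resid]
  miss <- is.na(r) & !is.na(parent)
  r[miss] <- radii[paste(parent[miss], a$elety[miss])]
  miss <- is.na(r)
  r[miss] <- element_radii[toupper(a$elesy[miss])]
  if (any(is.na(r))) {
    bad <- which(is.na(r))
    stop("write_xyzr: no radius for atom(s): ",
         paste(unique(paste(a$resid[bad], a$elety[bad])), collapse = ", "))
  }
  writeLines(sprintf("%.3f %.3f %.3f %.3f", a$x, a$y, a$z, r), path)
  invisible(nrow(a))
}
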