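# Structure I/O and geometry: parse PDB files, locate Fe-S cofactor sites and
# answer the neighborhood queries every descriptor is built on. Parsing and
# writing of the PDB format go through bio3d; this file owns the altloc policy,
# site detection and distance rules.

.water_codes <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), applies the alternate-location
#' policy (keep the highest-occupancy altloc, ties broken by altloc letter,
#' 'A' first), keeps only the first MODEL of multi-model files, drops
#' hydrogen/deuterium atoms, and captures the crystallographic resolution from
#' the REMARK 2 header when present.
#'
#' @param path path to a PDB file.
#' @param id structure identifier; defaults to the file name without extension.
#' @return An object of class `fes_structure`: a list with `id`, `atoms`
#'   (a data.frame with one row per retained atom: `eleno`, `elety`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `occ`, `altloc`, `element`,
#'   `het`) and `resolution` (Angstrom, `NA` if not reported).
#' @examples
#' pdb <- write_structure_pdb(make_toy_structure(toy_structure_spec(seed = 1))$structure,
#'                            tempfile(fileext = ".pdb"))
#' s <- read_pdb(pdb)
#' s
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", path)
  # pre-scan coordinate fields so a malformed file errors with its line number
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("parse error at line ", i, " of ", path, ": record too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop("parse error at line ", i, " of ", path,
           ": non-numeric coordinates")
  }
  resolution <- .parse_resolution(lines)
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1])]
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    eleno = at$eleno,
    elety = trimws(at$elety),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    element = .atom_element(at),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- .resolve_altlocs(atoms)
  if (nrow(atoms) == 0L) stop("empty structure after filtering: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  new_fes_structure(atoms, id = id, resolution = resolution)
}

.parse_resolution <- function(lines) {
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  m <- regmatches(rem[1], regexpr("[0-9]+\\.[0-9]+", rem[1]))
  if (!length(m)) return(NA_real_)
  as.numeric(m[1])
}

.atom_element <- function(at) {
  el <- toupper(trimws(at$elesy))
  el[is.na(el)] <- ""
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  fe <- grepl("^FE", toupper(trimws(at$elety)))
  guess[fe] <- "FE"
  ifelse(el == "", guess, el)
}

# keep one atom per (chain, resno, insert, elety): highest occupancy,
# ties by altloc letter ascending (blank/'A' first)
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$elety,
               sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$eleno), , drop = FALSE]
}

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by [read_pdb()] and the synthetic toy-structure
#' generator.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `occ`, `altloc`, `element`, `het`.
#' @param id structure identifier.
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @return `fes_structure` object.
#' @export
new_fes_structure <- function(atoms, id = "structure", resolution = NA_real_) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0,
            all(c("elety", "resid", "chain", "resno", "insert",
                  "x", "y", "z", "element", "het") %in% colnames(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  # order by chain then residue number then insertion code
  atoms <- atoms[order(atoms$het, atoms$chain, atoms$resno, atoms$insert), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, resolution = resolution),
            class = "fes_structure")
}

#' @exportS3Method base::print
print.fes_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat("<fes_structure> ", x$id, "\n", sep = "")
  cat("  ", sum(!res$het), " standard residues, ",
      sum(res$het), " hetero groups, ", nrow(x$atoms), " atoms\n", sep = "")
  if (!is.na(x$resolution))
    cat("  resolution: ", x$resolution, " A\n", sep = "")
  invisible(x)
}

#' Residue table of a structure
#'
#' One row per residue / hetero group, ordered by chain then residue number.
#'
#' @param structure an `fes_structure`.
#' @return data.frame with columns `key`, `chain`, `resno`, `insert`, `resid`,
#'   `het`, `is_standard`.
#' @export
structure_residues <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = ":")
  first <- !duplicated(paste(key, a$het))
  out <- data.frame(key = key[first], chain = a$chain[first],
                    resno = a$resno[first], insert = a$insert[first],
                    resid = a$resid[first], het = a$het[first],
                    stringsAsFactors = FALSE)
  out$is_standard <- !out$het & out$resid %in% .aa_codes
  out[order(out$het, out$chain, out$resno, out$insert), , drop = FALSE]
}

.res_key <- function(df) paste(df$chain, df$resno, df$insert, sep = ":")

# atoms of standard residues only (no het, no waters)
.standard_atoms <- function(structure) {
  a <- structure$atoms
  a[!a$het & a$resid %in% .aa_codes, , drop = FALSE]
}

#' Detect Fe-S cofactor sites in a structure
#'
#' Scans hetero groups for binuclear \[2Fe-2S\] clusters (FES groups with two
#' Fe and two inorganic S atoms) and mononuclear rubredoxin-type sites (hetero
#' groups consisting of a single Fe ion). Coordinating residues are the
#' standard residues with any side-chain atom within `bond_cutoff` of any Fe.
#'
#' @param structure an `fes_structure`.
#' @param selector optional `list(chain =, resno =)` restricting the result to
#'   the site whose hetero group matches.
#' @param bond_cutoff Fe-ligand bond cutoff in Angstrom (default 3.0, covering
#'   Fe-S(Cys) ~2.3 A and Fe-N(His) ~2.1 A with margin).
#' @return list of `fes_site` objects, each with `kind` ("mono_fe" or
#'   "fe2s2"), `atoms` (cofactor atom table), `coord_residues`, `barycenter`,
#'   and the hetero-group key (`chain`, `resno`, `insert`).
#' @export
detect_cluster_sites <- function(structure, selector = NULL, bond_cutoff = 3.0) {
  a <- structure$atoms
  het <- a[a$het & !(a$resid %in% .water_codes), , drop = FALSE]
  if (nrow(het) == 0L) stop("no cofactor: structure has no hetero groups")
  gkey <- paste(het$chain, het$resno, het$insert, het$resid, sep = "\r")
  sites <- list()
  for (k in unique(gkey)) {
    g <- het[gkey == k, , drop = FALSE]
    nfe <- sum(g$element == "FE")
    ns <- sum(g$element == "S")
    kind <- NULL
    if (toupper(g$resid[1]) == "FES" && nfe == 2 && ns == 2) {
      kind <- "fe2s2"
    } else if (nrow(g) == 1 && nfe == 1) {
      kind <- "mono_fe"
    }
    if (is.null(kind)) next
    cof <- g[g$element %in% c("FE", "S"), , drop = FALSE]
    site <- .build_site(structure, cof, kind, bond_cutoff)
    sites[[length(sites) + 1L]] <- site
  }
  if (!length(sites)) stop("no cofactor: no FES or isolated Fe hetero group found")
  if (!is.null(selector)) {
    hit <- vapply(sites, function(s)
      s$chain == selector$chain && s$resno == selector$resno, logical(1))
    if (!any(hit))
      stop("site selector (chain ", selector$chain, ", resno ",
           selector$resno, ") matches no detected site")
    sites <- sites[hit]
  }
  sites
}

.build_site <- function(structure, cof, kind, bond_cutoff) {
  coords <- as.matrix(cof[, c("x", "y", "z")])
  bary <- colMeans(coords)
  fe_xyz <- coords[cof$element == "FE", , drop = FALSE]
  sa <- .standard_atoms(structure)
  side <- sa[!(sa$elety %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
  cres <- NULL
  if (nrow(side)) {
    d2 <- .min_dist2_to_points(as.matrix(side[, c("x", "y", "z")]), fe_xyz)
    hit <- d2 <= bond_cutoff^2
    if (any(hit)) {
      h <- side[hit, , drop = FALSE]
      h$dist <- sqrt(d2[hit])
      key <- .res_key(h)
      ord <- order(key, h$dist)
      h <- h[ord, , drop = FALSE]
      h <- h[!duplicated(.res_key(h)), , drop = FALSE]
      cres <- data.frame(chain = h$chain, resno = h$resno, insert = h$insert,
                         resid = h$resid, lig_atom = h$elety,
                         distance = h$dist, stringsAsFactors = FALSE)
      cres <- cres[order(cres$chain, cres$resno, cres$insert), , drop = FALSE]
      rownames(cres) <- NULL
    }
  }
  structure(list(
    kind = kind,
    atoms = data.frame(elety = cof$elety, element = cof$element,
                       x = cof$x, y = cof$y, z = cof$z,
                       stringsAsFactors = FALSE),
    coord_residues = cres,
    barycenter = bary,
    chain = cof$chain[1], resno = cof$resno[1], insert = cof$insert[1]
  ), class = "fes_site")
}

#' @exportS3Method base::print
print.fes_site <- function(x, ...) {
  cat("<fes_site> ", x$kind, " (chain ", x$chain, ", resno ", x$resno, ")\n",
      sep = "")
  cat("  cofactor atoms: ", paste(x$atoms$elety, collapse = " "), "\n", sep = "")
  nl <- if (is.null(x$coord_residues)) 0 else nrow(x$coord_residues)
  cat("  coordinating residues: ", nl, "\n", sep = "")
  invisible(x)
}

#' Barycenter of a cofactor site
#'
#' Unweighted mean of the cofactor atom coordinates; the center of the
#' medium-range descriptor sphere. For a mononuclear site it is the Fe
#' position itself.
#'
#' @param site an `fes_site`.
#' @return numeric 3-vector (Angstrom).
#' @export
site_barycenter <- function(site) {
  stopifnot(inherits(site, "fes_site"), nrow(site$atoms) >= 1)
  colMeans(as.matrix(site$atoms[, c("x", "y", "z")]))
}

# squared min distance from each row of `xyz` to any row of `points`
.min_dist2_to_points <- function(xyz, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  n <- nrow(xyz)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(points))) {
    d2 <- (xyz[, 1] - points[j, 1])^2 + (xyz[, 2] - points[j, 2])^2 +
      (xyz[, 3] - points[j, 3])^2
    best <- pmin(best, d2)
  }
  best
}

#' Residues within a sphere (or union of spheres)
#'
#' Returns the standard residues assigned to the neighborhood of one or more
#' center points. Under the default ANY-atom rule a residue belongs to the
#' neighborhood if any of its (non-hydrogen) atoms lies within `radius` of any
#' center, boundary inclusive. Hetero groups and waters are never returned.
#'
#' @param structure an `fes_structure`.
#' @param center numeric 3-vector, or a matrix with one center per row (the
#'   neighborhood is then the union of the spheres).
#' @param radius sphere radius in Angstrom; must be positive.
#' @param rule residue-to-region assignment rule: `"any"` (default, any atom),
#'   `"ca"` (C-alpha position), or `"centroid"` (side-chain centroid; backbone
#'   centroid for glycine).
#' @return data.frame of residues (columns `key`, `chain`, `resno`, `insert`,
#'   `resid`), ordered by chain and residue number.
#' @export
residues_within <- function(structure, center, radius,
                            rule = c("any", "ca", "centroid")) {
  rule <- match.arg(rule)
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a positive number")
  pts <- if (is.null(dim(center))) matrix(center, nrow = 1) else as.matrix(center)
  stopifnot(ncol(pts) == 3)
  sa <- .standard_atoms(structure)
  empty <- data.frame(key = character(), chain = character(),
                      resno = integer(), insert = character(),
                      resid = character(), stringsAsFactors = FALSE)
  if (nrow(sa) == 0L) return(empty)
  key <- .res_key(sa)
  # inclusive boundary, robust to float round-off on exact-radius atoms
  rmax <- (radius + 1e-9)^2
  if (rule == "any") {
    d2 <- .min_dist2_to_points(as.matrix(sa[, c("x", "y", "z")]), pts)
    resmin <- tapply(d2, key, min)
    keep <- names(resmin)[resmin <= rmax]
  } else if (rule == "ca") {
    ca <- sa[sa$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) return(empty)
    d2 <- .min_dist2_to_points(as.matrix(ca[, c("x", "y", "z")]), pts)
    keep <- .res_key(ca)[d2 <= rmax]
  } else {
    side <- sa[!(sa$elety %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
    base <- if (nrow(side)) side else sa
    # residues lacking side-chain atoms (Gly) fall back to all atoms
    missing <- setdiff(unique(key), unique(.res_key(base)))
    base <- rbind(base, sa[key %in% missing, , drop = FALSE])
    bkey <- .res_key(base)
    cx <- tapply(base$x, bkey, mean)
    cy <- tapply(base$y, bkey, mean)
    cz <- tapply(base$z, bkey, mean)
    cent <- cbind(cx, cy, cz)
    d2 <- .min_dist2_to_points(cent, pts)
    keep <- rownames(cent)[d2 <= rmax]
  }
  first <- !duplicated(key)
  out <- data.frame(key = key[first], chain = sa$chain[first],
                    resno = sa$resno[first], insert = sa$insert[first],
                    resid = sa$resid[first], stringsAsFactors = FALSE)
  out <- out[out$key %in% keep, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure to a PDB file
#'
#' Column-exact fixed-width PDB output (via bio3d), so generated toy
#' structures round-trip through [read_pdb()] and any standard PDB reader.
#'
#' @param structure an `fes_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  if (!is.na(structure$resolution)) {
    lines <- readLines(path, warn = FALSE)
    hdr <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                   structure$resolution)
    writeLines(c(hdr, lines), path)
  }
  invisible(path)
}
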