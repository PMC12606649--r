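# Multiscale molecular descriptors. Every spatial region of a structure is
# summarized by the same 66-descriptor block (counts of residue classes, counts
# per amino-acid type, sums and means of the parametrized property table);
# regions at the three spatial scales, the nearest-residue and
# sequence-neighborhood blocks, the cofactor inventory and pH are concatenated
# into a fixed-length feature vector.

.inventory_vocab <- c("FES", "SF4", "F3S", "FE", "FE2", "HEM", "HEC", "HEA",
                      "FAD", "FMN", "NAD", "NAP", "MOS", "OTHER")

.technique_levels <- c("voltammetry", "potentiometry", "optical", "other",
                       "unknown")

# ---- region block ----------------------------------------------------------

.region_names <- local({
  counts <- c("n.res", "n.polar.neutral", "n.hydrophobic", "n.aromatic",
              "n.basic", "n.acidic", "n.charged", "n.polar.all",
              "n.cys", "n.his", "n.glypro")
  aa <- paste0("n.aa.", .aa_codes)
  sums <- c(paste0("sum.", .aa_numeric_props), "sum.steric.flex")
  means <- paste0("mean.", .aa_numeric_props)
  c(counts, aa, sums, means)
})

# count-type region descriptors: monotone under region growth
.region_count_names <- local({
  c(.region_names[1:31],
    paste0("sum.", c("hb.don", "hb.acc", "sc.n", "sc.o", "sc.s")))
})

#' The 66-descriptor block of a residue region
#'
#' Summarizes a set of residues by counts (total residues, residues per
#' physicochemical class, His/Cys counts, per-amino-acid counts) and by sums
#' and means of each numeric property in the residue property table, plus the
#' steric-hindrance + flexibility composite. The same block is evaluated for
#' every spatial region of the feature schema; an empty region yields the
#' all-zero vector.
#'
#' @param residues residues of the region: a character vector of three-letter
#'   codes, or a data.frame with a `resid` column (as returned by
#'   [residues_within()]).
#' @param table residue property table (default [aa_properties()]).
#' @param on_noncanonical what to do with residues outside the 20 canonical
#'   amino acids: `"skip"` (default, with a warning) or `"error"`.
#' @return named numeric vector of length 66.
#' @examples
#' region_descriptors(c("GLY", "GLY", "GLY"))[c("n.res", "n.glypro")]
#' @export
region_descriptors <- function(residues, table = aa_properties(),
                               on_noncanonical = c("skip", "error")) {
  on_noncanonical <- match.arg(on_noncanonical)
  codes <- if (is.data.frame(residues)) residues$resid else as.character(residues)
  bad <- setdiff(unique(codes), .aa_codes)
  if (length(bad)) {
    if (on_noncanonical == "error")
      stop("non-canonical residues in region: ", paste(bad, collapse = ", "))
    warning("skipping non-canonical residues: ", paste(bad, collapse = ", "))
    codes <- codes[codes %in% .aa_codes]
  }
  out <- stats::setNames(numeric(length(.region_names)), .region_names)
  n <- length(codes)
  out["n.res"] <- n
  if (n == 0L) return(out)
  sub <- table[codes, , drop = FALSE]
  out["n.polar.neutral"] <- sum(sub$polar.neutral)
  out["n.hydrophobic"] <- sum(sub$hydrophobic)
  out["n.aromatic"] <- sum(sub$aromatic)
  out["n.basic"] <- sum(sub$basic)
  out["n.acidic"] <- sum(sub$acidic)
  out["n.charged"] <- sum(sub$basic) + sum(sub$acidic)
  out["n.polar.all"] <- sum(sub$polar.neutral) + sum(sub$basic) + sum(sub$acidic)
  out["n.cys"] <- sum(sub$is.cys)
  out["n.his"] <- sum(sub$is.his)
  out["n.glypro"] <- sum(sub$glypro)
  tab <- table(factor(codes, levels = .aa_codes))
  out[paste0("n.aa.", .aa_codes)] <- as.numeric(tab)
  for (p in .aa_numeric_props) {
    out[paste0("sum.", p)] <- sum(sub[[p]])
    out[paste0("mean.", p)] <- mean(sub[[p]])
  }
  out["sum.steric.flex"] <- sum(sub$steric.flex)
  out
}

# ---- region residue sets ---------------------------------------------------

.site_element_coords <- function(site, element) {
  a <- site$atoms[site$atoms$element == element, , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  as.matrix(a[, c("x", "y", "z")])
}

# the ten region residue sets of the default schema, in schema order;
# NULL marks an absent region (zero-filled block)
.region_sets <- function(structure, site, r1, r2, rule = "any") {
  bary <- site_barycenter(site)
  fe <- .site_element_coords(site, "FE")
  s <- .site_element_coords(site, "S")
  all_xyz <- as.matrix(site$atoms[, c("x", "y", "z")])
  res <- structure_residues(structure)
  protein <- res[res$is_standard, , drop = FALSE]
  shell1 <- site$coord_residues
  atom_region <- function(xyz, i) {
    if (is.null(xyz) || nrow(xyz) < i) return(NULL)
    residues_within(structure, xyz[i, ], r2, rule = rule)
  }
  list(
    Protein = protein,
    Bar = residues_within(structure, bary, r1, rule = rule),
    Shell1 = shell1,
    CofAtom.Fe = if (is.null(fe)) NULL else
      residues_within(structure, fe, r2, rule = rule),
    CofAtom.S = if (is.null(s)) NULL else
      residues_within(structure, s, r2, rule = rule),
    CofAtom.Fe1 = atom_region(fe, 1),
    CofAtom.Fe2 = atom_region(fe, 2),
    CofAtom.S1 = atom_region(s, 1),
    CofAtom.S2 = atom_region(s, 2),
    CofAtom.All = residues_within(structure, all_xyz, r2, rule = rule)
  )
}

.block_values <- function(region, table) {
  if (is.null(region)) stats::setNames(numeric(length(.region_names)),
                                       .region_names)
  else region_descriptors(region, table)
}

#' Long-range descriptor block (whole protein)
#'
#' The 66-descriptor region block over all standard residues of the structure
#' (`Protein.X`). Coordinate-free: invariant under any rigid motion.
#'
#' @inheritParams featurize
#' @return named numeric vector of length 66.
#' @export
long_range <- function(structure, table = aa_properties()) {
  res <- structure_residues(structure)
  region_descriptors(res[res$is_standard, , drop = FALSE], table)
}

#' Medium-range descriptor block (barycenter sphere)
#'
#' The 66-descriptor block over the residues within `r1` of the cofactor
#' barycenter (`Bar.X`). The replication range is 8-16 Angstrom; other values
#' are allowed with a warning.
#'
#' @inheritParams featurize
#' @return named numeric vector of length 66.
#' @export
medium_range <- function(structure, site, r1, table = aa_properties(),
                         rule = "any") {
  if (r1 < 8 || r1 > 16)
    warning("r1 = ", r1, " is outside the replication range 8-16 A")
  region_descriptors(
    residues_within(structure, site_barycenter(site), r1, rule = rule), table)
}

#' Short-range descriptor blocks (per cofactor element)
#'
#' For each cofactor element Y in {Fe, S}: the 66-descriptor block over the
#' union of residues within `r2` of any cofactor atom of element Y
#' (`CofAtom.Fe.X`, `CofAtom.S.X`). For mononuclear sites the S block is
#' zero-filled.
#'
#' @inheritParams featurize
#' @return named numeric vector of length 132 (Fe block followed by S block).
#' @export
short_range <- function(structure, site, r2, table = aa_properties(),
                        rule = "any") {
  if (r2 < 3 || r2 > 5)
    warning("r2 = ", r2, " is outside the replication range 3-5 A")
  fe <- .site_element_coords(site, "FE")
  s <- .site_element_coords(site, "S")
  fe_block <- .block_values(
    if (is.null(fe)) NULL else residues_within(structure, fe, r2, rule = rule),
    table)
  s_block <- .block_values(
    if (is.null(s)) NULL else residues_within(structure, s, r2, rule = rule),
    table)
  c(stats::setNames(fe_block, paste0("CofAtom.Fe.", names(fe_block))),
    stats::setNames(s_block, paste0("CofAtom.S.", names(s_block))))
}

# ---- nearest / around ------------------------------------------------------

.nearest_names <- c(paste0("flag.", .aa_class_flags),
                    "hydropathy", "volume", "bulkiness", "flexibility",
                    "net.charge", "steric.flex")

.around_names <- c(paste0("n.", .aa_class_flags),
                   paste0("sum.", c("hydropathy", "volume", "bulkiness",
                                    "flexibility", "polarity", "net.charge",
                                    "sc.n", "steric.flex")))

# nearest standard residue to any cofactor atom of `element`; ties broken by
# (chain, residue number) ascending. NULL when the element is absent.
.nearest_residue <- function(structure, site, element) {
  xyz <- .site_element_coords(site, element)
  if (is.null(xyz)) return(NULL)
  sa <- .standard_atoms(structure)
  if (nrow(sa) == 0L) return(NULL)
  d2 <- .min_dist2_to_points(as.matrix(sa[, c("x", "y", "z")]), xyz)
  key <- .res_key(sa)
  dmin <- tapply(d2, key, min)
  first <- !duplicated(key)
  res <- data.frame(key = key[first], chain = sa$chain[first],
                    resno = sa$resno[first], insert = sa$insert[first],
                    resid = sa$resid[first], stringsAsFactors = FALSE)
  # distances are compared at 0.01 A granularity (coarser than the 1e-3 A
  # PDB coordinate precision, so written/reread structures rank identically);
  # closer ties break by (chain, residue number)
  res$d <- round(sqrt(as.numeric(dmin[res$key])), 2)
  res <- res[order(res$d, res$chain, res$resno, res$insert), , drop = FALSE]
  res[1, , drop = FALSE]
}

.nearest_block <- function(structure, site, element, table) {
  out <- stats::setNames(numeric(length(.nearest_names)), .nearest_names)
  nr <- .nearest_residue(structure, site, element)
  if (is.null(nr)) return(out)
  row <- table[nr$resid, ]
  out[paste0("flag.", .aa_class_flags)] <-
    as.numeric(row[, .aa_class_flags])
  out["hydropathy"] <- row$hydropathy
  out["volume"] <- row$volume
  out["bulkiness"] <- row$bulkiness
  out["flexibility"] <- row$flexibility
  out["net.charge"] <- row$net.charge
  out["steric.flex"] <- row$steric.flex
  out
}

#' Nearest-residue descriptor blocks
#'
#' Properties of the amino acid residue closest (minimum atom-atom distance)
#' to any Fe atom and to any inorganic S atom of the cofactor
#' (`NearestFe.X`, `NearestS.X`; 14 descriptors per element, 28 in total).
#' Distance ties are broken by chain id then residue number, ascending. For
#' mononuclear sites the S half is zero-filled.
#'
#' @inheritParams featurize
#' @return named numeric vector of length 28.
#' @export
nearest_residue_descriptors <- function(structure, site,
                                        table = aa_properties()) {
  fe <- .nearest_block(structure, site, "FE", table)
  s <- .nearest_block(structure, site, "S", table)
  c(stats::setNames(fe, paste0("NearestFe.", names(fe))),
    stats::setNames(s, paste0("NearestS.", names(s))))
}

# nearest residue plus its sequence neighbors (i-1, i+1) in the same chain
.around_triplet <- function(structure, site, element) {
  nr <- .nearest_residue(structure, site, element)
  if (is.null(nr)) return(NULL)
  res <- structure_residues(structure)
  chain <- res[res$is_standard & res$chain == nr$chain, , drop = FALSE]
  chain <- chain[order(chain$resno, chain$insert), , drop = FALSE]
  i <- which(chain$key == nr$key)
  idx <- intersect(c(i - 1L, i, i + 1L), seq_len(nrow(chain)))
  chain[idx, , drop = FALSE]
}

.around_block <- function(structure, site, element, table) {
  out <- stats::setNames(numeric(length(.around_names)), .around_names)
  trip <- .around_triplet(structure, site, element)
  if (is.null(trip)) return(out)
  sub <- table[trip$resid, , drop = FALSE]
  for (f in .aa_class_flags) out[paste0("n.", f)] <- sum(sub[[f]])
  for (p in c("hydropathy", "volume", "bulkiness", "flexibility",
              "polarity", "net.charge", "sc.n", "steric.flex"))
    out[paste0("sum.", p)] <- sum(sub[[p]])
  out
}

#' Sequence-neighborhood descriptor blocks
#'
#' Properties aggregated over the nearest residue to each cofactor element and
#' its two sequentially adjacent residues in the same chain (`AroundFe.X`,
#' `AroundS.X`; 16 descriptors per element, 32 in total). At a chain terminus
#' only the existing neighbor is used. The `AroundFe.sum.steric.flex` entry is
#' the steric-hindrance + flexibility composite of the three residues closest
#' in sequence to Fe.
#'
#' @inheritParams featurize
#' @return named numeric vector of length 32.
#' @export
around_descriptors <- function(structure, site, table = aa_properties()) {
  fe <- .around_block(structure, site, "FE", table)
  s <- .around_block(structure, site, "S", table)
  c(stats::setNames(fe, paste0("AroundFe.", names(fe))),
    stats::setNames(s, paste0("AroundS.", names(s))))
}

# ---- cofactor inventory ----------------------------------------------------

#' Cofactor type and multiplicity descriptors
#'
#' Counts the other cofactors present in the structure, per hetero-group code
#' of a fixed vocabulary and per scope: the whole structure, the `r1` sphere
#' and the `r2` sphere around the focal site's barycenter (a group is in scope
#' when its own barycenter is). The focal site and waters are excluded; codes
#' outside the vocabulary are bucketed into `OTHER`. Two additional entries
#' give the focal site's own multiplicity (number of Fe and of inorganic S
#' atoms).
#'
#' @inheritParams featurize
#' @return named numeric vector of length 44 (14 codes x 3 scopes + 2).
#' @export
cofactor_inventory <- function(structure, site, r1, r2) {
  a <- structure$atoms
  het <- a[a$het & !(a$resid %in% .water_codes), , drop = FALSE]
  gkey <- paste(het$chain, het$resno, het$insert, het$resid, sep = "\r")
  focal <- paste(site$chain, site$resno, site$insert, sep = "\r")
  bary <- site_barycenter(site)
  counts <- matrix(0, nrow = length(.inventory_vocab), ncol = 3,
                   dimnames = list(.inventory_vocab, c("whole", "r1", "r2")))
  for (k in unique(gkey)) {
    g <- het[gkey == k, , drop = FALSE]
    if (paste(g$chain[1], g$resno[1], g$insert[1], sep = "\r") == focal) next
    code <- toupper(g$resid[1])
    if (!(code %in% .inventory_vocab)) code <- "OTHER"
    gb <- colMeans(as.matrix(g[, c("x", "y", "z")]))
    d <- sqrt(sum((gb - bary)^2))
    counts[code, "whole"] <- counts[code, "whole"] + 1
    if (d <= r1) counts[code, "r1"] <- counts[code, "r1"] + 1
    if (d <= r2) counts[code, "r2"] <- counts[code, "r2"] + 1
  }
  out <- c(as.numeric(t(counts)),
           sum(site$atoms$element == "FE"),
           sum(site$atoms$element == "S"))
  names(out) <- c(paste0("Global.Inv.",
                         rep(.inventory_vocab, each = 3), ".",
                         rep(c("whole", "r1", "r2"),
                             times = length(.inventory_vocab))),
                  "Global.Site.n.fe", "Global.Site.n.s")
  out
}

# ---- schema ----------------------------------------------------------------

.schema_version <- "fesred-schema-1"

.region_blocks <- data.frame(
  block = c("Protein", "Bar", "Shell1", "CofAtom.Fe", "CofAtom.S",
            "CofAtom.Fe1", "CofAtom.Fe2", "CofAtom.S1", "CofAtom.S2",
            "CofAtom.All"),
  scale = c("long", "medium", "short", "short", "short",
            "short", "short", "short", "short", "short"),
  radius = c("none", "r1", "none", "r2", "r2", "r2", "r2", "r2", "r2", "r2"),
  stringsAsFactors = FALSE
)

.schema_rows_A <- function() {
  rows <- list()
  for (i in seq_len(nrow(.region_blocks))) {
    b <- .region_blocks[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(b$block, ".", .region_names),
      block = b$block, scale = b$scale, radius = b$radius,
      count_type = .region_names %in% .region_count_names,
      stringsAsFactors = FALSE)
  }
  near <- c(paste0("NearestFe.", .nearest_names),
            paste0("NearestS.", .nearest_names))
  rows[[length(rows) + 1L]] <- data.frame(
    name = near, block = rep(c("NearestFe", "NearestS"), each = 14),
    scale = "short", radius = "none",
    count_type = FALSE, stringsAsFactors = FALSE)
  arnd <- c(paste0("AroundFe.", .around_names),
            paste0("AroundS.", .around_names))
  rows[[length(rows) + 1L]] <- data.frame(
    name = arnd, block = rep(c("AroundFe", "AroundS"), each = 16),
    scale = "short", radius = "none",
    count_type = grepl("\\.n\\.", arnd), stringsAsFactors = FALSE)
  inv_scope <- rep(c("whole", "r1", "r2"), times = length(.inventory_vocab))
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste0("Global.Inv.", rep(.inventory_vocab, each = 3), ".", inv_scope),
    block = "Inventory",
    scale = c(whole = "long", r1 = "medium", r2 = "short")[inv_scope],
    radius = c(whole = "none", r1 = "r1", r2 = "r2")[inv_scope],
    count_type = TRUE, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("Global.Site.n.fe", "Global.Site.n.s"),
    block = "Site", scale = "short", radius = "none",
    count_type = TRUE, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "Global.pH", block = "Condition", scale = "condition",
    radius = "none", count_type = FALSE, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Feature schema of the descriptor vector
#'
#' The ordered, named layout of the feature vector. Strategy `"A"` is the
#' fixed-radii layout: ten 66-descriptor regions (whole protein; barycenter
#' sphere at `r1`; first coordination sphere; per-element, per-atom and
#' all-atom cofactor neighborhoods at `r2`), the 28 nearest-residue and 32
#' sequence-neighborhood descriptors, the cofactor inventory (14 codes x 3
#' scopes + site multiplicity) and pH — 765 features in total. Strategy
#' `"B"` is the deduplicated union across the full radii grids:
#' radius-independent blocks appear once, `r1`-dependent blocks once per `r1`
#' value, `r2`-dependent blocks once per `r2` value.
#'
#' @param strategy `"A"` (per radii pair) or `"B"` (all radii at once).
#' @param r1 medium-range radius (Angstrom), strategy A.
#' @param r2 short-range radius (Angstrom), strategy A; must satisfy `r2 < r1`.
#' @param r1_grid,r2_grid radii grids for strategy B (defaults 8:16 and 3:5).
#' @param technique include the one-hot measurement-technique block (variant
#'   schema; off by default).
#' @return data.frame of class `fes_schema` with columns `name`, `block`,
#'   `scale` (long / medium / short / condition), `radius` (none / r1 / r2),
#'   `count_type`, and (strategy B) `r1` / `r2` values per row; attributes
#'   `strategy`, `r1`, `r2`, `version`.
#' @examples
#' nrow(feature_schema("A", 11, 4))  # 765
#' @export
feature_schema <- function(strategy = c("A", "B"), r1 = 11, r2 = 4,
                           r1_grid = 8:16, r2_grid = 3:5,
                           technique = FALSE) {
  strategy <- match.arg(strategy)
  if (strategy == "A") {
    if (r2 >= r1) stop("r2 must be strictly smaller than r1")
    sc <- .schema_rows_A()
    sc$r1 <- ifelse(sc$radius == "r1", r1, NA_real_)
    sc$r2 <- ifelse(sc$radius == "r2", r2, NA_real_)
  } else {
    if (max(r2_grid) >= min(r1_grid))
      stop("every r2 must be strictly smaller than every r1")
    base <- .schema_rows_A()
    fixed <- base[base$radius == "none", , drop = FALSE]
    fixed$r1 <- NA_real_; fixed$r2 <- NA_real_
    rows <- list(fixed)
    for (r1v in r1_grid) {
      b <- base[base$radius == "r1", , drop = FALSE]
      b$name <- paste0(b$name, ".r1_", r1v)
      b$r1 <- r1v; b$r2 <- NA_real_
      rows[[length(rows) + 1L]] <- b
    }
    for (r2v in r2_grid) {
      b <- base[base$radius == "r2", , drop = FALSE]
      b$name <- paste0(b$name, ".r2_", r2v)
      b$r1 <- NA_real_; b$r2 <- r2v
      rows[[length(rows) + 1L]] <- b
    }
    sc <- do.call(rbind, rows)
    r1 <- NA_real_; r2 <- NA_real_
  }
  if (technique) {
    sc <- rbind(sc, data.frame(
      name = paste0("Global.Tech.", .technique_levels),
      block = "Condition", scale = "condition", radius = "none",
      count_type = FALSE, r1 = NA_real_, r2 = NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(sc) <- NULL
  structure(sc, class = c("fes_schema", "data.frame"),
            strategy = strategy, r1 = r1, r2 = r2,
            r1_grid = if (strategy == "B") r1_grid else NULL,
            r2_grid = if (strategy == "B") r2_grid else NULL,
            technique = technique, version = .schema_version)
}

#' Map strategy-A feature names into the strategy-B schema
#'
#' Radius-independent names are unchanged; `r1`- and `r2`-dependent names get
#' the radius suffix used by the B schema.
#'
#' @param schema_a a strategy-A `fes_schema`.
#' @return character vector of B-schema names, aligned to `schema_a` rows.
#' @export
schema_a_names_in_b <- function(schema_a) {
  stopifnot(attr(schema_a, "strategy") == "A")
  n <- schema_a$name
  n[schema_a$radius == "r1"] <- paste0(n[schema_a$radius == "r1"],
                                       ".r1_", attr(schema_a, "r1"))
  n[schema_a$radius == "r2"] <- paste0(n[schema_a$radius == "r2"],
                                       ".r2_", attr(schema_a, "r2"))
  n
}

# ---- featurize -------------------------------------------------------------

.one_hot_technique <- function(technique) {
  lev <- .technique_levels
  tech <- if (is.null(technique) || is.na(technique) || !nzchar(technique))
    "unknown" else tolower(technique)
  if (!(tech %in% lev)) tech <- "other"
  stats::setNames(as.numeric(lev == tech), paste0("Global.Tech.", lev))
}

#' Compute the fixed-radii (strategy A) feature vector of a site
#'
#' Concatenates, in schema order: the whole-protein block, the barycenter
#' sphere at `r1`, the first coordination sphere, the cofactor-atom
#' neighborhoods at `r2` (per element, per atom and all atoms), the
#' nearest-residue and sequence-neighborhood blocks, the cofactor inventory
#' and pH. Length is exactly 765 in the default schema. Blocks whose region is
#' absent (e.g. the inorganic-S blocks of a mononuclear site) are zero-filled.
#'
#' @param structure an `fes_structure`.
#' @param site an `fes_site` from [detect_cluster_sites()].
#' @param r1 medium-range radius, Angstrom (replication grid 8-16).
#' @param r2 short-range radius, Angstrom (replication grid 3-5); `r2 < r1`.
#' @param ph pH of the measurement, in \[0, 14\].
#' @param technique optional measurement-technique label (used only when the
#'   schema includes the one-hot technique block).
#' @param schema optional pre-built strategy-A [feature_schema()].
#' @param table residue property table.
#' @param rule residue-to-region assignment rule (see [residues_within()]).
#' @return named numeric vector aligned to the schema, with attributes
#'   `structure_id`, `r1`, `r2`, `ph`.
#' @export
featurize <- function(structure, site, r1 = 11, r2 = 4, ph = 7,
                      technique = NULL, schema = NULL,
                      table = aa_properties(), rule = "any") {
  if (r2 >= r1) stop("r2 must be strictly smaller than r1")
  if (!is.finite(ph) || ph < 0 || ph > 14) stop("pH must lie in [0, 14]")
  if (is.null(schema)) schema <- feature_schema("A", r1 = r1, r2 = r2)
  regions <- .region_sets(structure, site, r1, r2, rule = rule)
  vals <- c(
    unlist(lapply(names(regions), function(b) {
      v <- .block_values(regions[[b]], table)
      stats::setNames(v, paste0(b, ".", names(v)))
    })),
    nearest_residue_descriptors(structure, site, table),
    around_descriptors(structure, site, table),
    cofactor_inventory(structure, site, r1, r2),
    stats::setNames(ph, "Global.pH")
  )
  if (isTRUE(attr(schema, "technique")))
    vals <- c(vals, .one_hot_technique(technique))
  stopifnot(identical(names(vals), schema$name))
  attr(vals, "structure_id") <- structure$id
  attr(vals, "r1") <- r1
  attr(vals, "r2") <- r2
  attr(vals, "ph") <- ph
  vals
}

#' Compute the all-radii (strategy B) feature vector of a site
#'
#' The deduplicated union of strategy-A features across the radii grids:
#' radius-independent blocks are computed once, the barycenter-sphere block
#' once per `r1` value, the cofactor-atom blocks once per `r2` value, and the
#' sphere-scoped inventory entries per corresponding radius.
#'
#' @inheritParams featurize
#' @param r1_grid,r2_grid radii grids (defaults 8:16 and 3:5 Angstrom).
#' @return named numeric vector aligned to the strategy-B schema.
#' @export
featurize_all_radii <- function(structure, site, ph = 7, technique = NULL,
                                r1_grid = 8:16, r2_grid = 3:5,
                                schema = NULL, table = aa_properties(),
                                rule = "any") {
  if (is.null(schema))
    schema <- feature_schema("B", r1_grid = r1_grid, r2_grid = r2_grid)
  if (!is.finite(ph) || ph < 0 || ph > 14) stop("pH must lie in [0, 14]")
  ref <- feature_schema("A", r1 = max(r1_grid), r2 = min(r2_grid))
  base <- featurize(structure, site, r1 = max(r1_grid), r2 = min(r2_grid),
                    ph = ph, technique = technique, schema = ref,
                    table = table, rule = rule)
  fixed <- base[ref$radius == "none"]
  out <- stats::setNames(numeric(nrow(schema)), schema$name)
  out[names(fixed)] <- fixed
  bary <- site_barycenter(site)
  for (r1v in r1_grid) {
    block <- region_descriptors(
      residues_within(structure, bary, r1v, rule = rule), table)
    out[paste0("Bar.", names(block), ".r1_", r1v)] <- block
    inv <- cofactor_inventory(structure, site, r1 = r1v, r2 = min(r2_grid))
    sel <- grep("\\.r1$", names(inv), value = TRUE)
    out[paste0(sel, ".r1_", r1v)] <- inv[sel]
  }
  for (r2v in r2_grid) {
    regions <- .region_sets(structure, site, r1 = max(r1_grid), r2 = r2v,
                            rule = rule)
    for (b in c("CofAtom.Fe", "CofAtom.S", "CofAtom.Fe1", "CofAtom.Fe2",
                "CofAtom.S1", "CofAtom.S2", "CofAtom.All")) {
      v <- .block_values(regions[[b]], table)
      out[paste0(b, ".", names(v), ".r2_", r2v)] <- v
    }
    inv <- cofactor_inventory(structure, site, r1 = max(r1_grid), r2 = r2v)
    sel <- grep("\\.r2$", names(inv), value = TRUE)
    out[paste0(sel, ".r2_", r2v)] <- inv[sel]
  }
  if (isTRUE(attr(schema, "technique")))
    out[paste0("Global.Tech.", .technique_levels)] <-
      .one_hot_technique(technique)
  attr(out, "structure_id") <- structure$id
  attr(out, "ph") <- ph
  out
}

#' Write a feature matrix with its schema manifest
#'
#' The matrix goes to `path` as delimited text with the schema names as
#' header; the sidecar manifest (`<path>.schema.tsv`) records name, block,
#' scale tag and radius dependence per feature.
#'
#' @param x numeric matrix with schema-named columns.
#' @param schema the `fes_schema` describing the columns.
#' @param path output path for the matrix (tab-separated).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, schema, path) {
  stopifnot(identical(colnames(x), schema$name))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- as.data.frame(schema)[, c("name", "block", "scale", "radius")]
  utils::write.table(man, paste0(path, ".schema.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
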