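# Synthetic fixtures: desk-scale toy structures with Fe-S sites whose geometry
# is known exactly by construction, and synthetic reduction-potential data sets
# generated from a known linear model over schema features. These make every
# other module testable offline, with no structure downloads.

#' Specification of a toy Fe-S structure
#'
#' @param site_kind `"fe2s2"` (planar rhombus core, Fe-Fe 2.7 A, Fe-S 2.2 A)
#'   or `"mono_fe"` (single Fe ion).
#' @param ligands three-letter codes of the four first-sphere residues (their
#'   ligating atom is placed at 2.3 A from an Fe).
#' @param residues three-letter codes of the remaining (shell) residues.
#' @param shells distance (Angstrom) of each shell residue's nearest atom from
#'   the cluster barycenter; same length as `residues`. Defaults draw from
#'   3.5-18 A, off the radii grid.
#' @param extra_cofactors optional data.frame with columns `code` and
#'   `distance`: additional one-atom hetero groups placed at the given
#'   barycenter distance (inventory-descriptor fixtures).
#' @param seed integer seed controlling residue directions.
#' @param id structure identifier.
#' @param resolution nominal resolution (Angstrom) written to the header,
#'   or `NA`.
#' @return object of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(site_kind = c("fe2s2", "mono_fe"),
                               ligands = rep("CYS", 4),
                               residues = NULL, shells = NULL,
                               extra_cofactors = NULL,
                               seed = 1, id = NULL, resolution = NA_real_) {
  site_kind <- match.arg(site_kind)
  if (is.null(residues)) {
    set.seed(seed)
    n <- sample(14:26, 1)
    residues <- sample(.aa_codes, n, replace = TRUE)
    shells <- round(stats::runif(n, 3.5, 18), 2)
  }
  if (is.null(shells)) {
    set.seed(seed + 7L)
    shells <- round(stats::runif(length(residues), 3.5, 18), 2)
  }
  stopifnot(length(shells) == length(residues), all(shells > 0),
            all(ligands %in% .aa_codes), all(residues %in% .aa_codes))
  if (is.null(id)) id <- paste0("toy_", site_kind, "_", seed)
  structure(list(site_kind = site_kind, ligands = ligands,
                 residues = residues, shells = shells,
                 extra_cofactors = extra_cofactors, seed = seed, id = id,
                 resolution = resolution),
            class = "toy_structure_spec")
}

# deterministic unit vector stream; rejection keeps new atoms clash-free
.unit_vec <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

.tangent <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t <- a - sum(a * u) * u
  t / sqrt(sum(t^2))
}

#' Build a toy Fe-S structure with known geometry
#'
#' Places the cofactor core at the origin (so the barycenter is exactly the
#' origin), the four ligating residues with their ligating atom (SG for Cys,
#' ND1 for His, OD1/other side-chain atom otherwise) at exactly 2.3 A from an
#' Fe, and every shell residue with its nearest atom (C-alpha) at exactly its
#' specified barycenter distance; remaining backbone atoms are placed strictly
#' farther out, so the per-residue minimum distances are known by
#' construction. Directions are randomized (seeded) with a small jitter and a
#' clash rejection step; placement fails with an error if any two atoms end up
#' closer than 0.8 A.
#'
#' @param spec a [toy_structure_spec()].
#' @return list with `structure` (an `fes_structure`) and `ground_truth`, a
#'   data.frame with one row per standard residue: residue key, code, ligand
#'   flag, exact distance of the nearest atom to the barycenter
#'   (`bary_dist`), and the minimum atom distance to each cofactor atom
#'   (`d_<atomname>` columns).
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  set.seed(spec$seed)
  core <- if (spec$site_kind == "fe2s2") {
    h <- sqrt(2.2^2 - 1.35^2)  # Fe-S 2.2, Fe-Fe 2.7 planar rhombus
    data.frame(elety = c("FE1", "FE2", "S1", "S2"),
               element = c("FE", "FE", "S", "S"),
               x = c(-1.35, 1.35, 0, 0), y = c(0, 0, h, -h), z = c(0, 0, 0, 0),
               resid = "FES", stringsAsFactors = FALSE)
  } else {
    data.frame(elety = "FE", element = "FE", x = 0, y = 0, z = 0,
               resid = "FE", stringsAsFactors = FALSE)
  }
  fe_xyz <- as.matrix(core[core$element == "FE", c("x", "y", "z"), drop = FALSE])
  extra <- NULL
  if (!is.null(spec$extra_cofactors) && nrow(spec$extra_cofactors)) {
    ex <- spec$extra_cofactors
    dirs <- diag(3)[rep(1:3, length.out = nrow(ex)), , drop = FALSE]
    sgn <- rep(c(1, -1), length.out = nrow(ex))
    extra <- do.call(rbind, lapply(seq_len(nrow(ex)), function(j) {
      xyz <- sgn[j] * dirs[j, ] * ex$distance[j]
      data.frame(eleno = 9000L + j, elety = "C1", resid = ex$code[j],
                 chain = "B", resno = j, insert = "",
                 x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, altloc = "",
                 element = "C", het = TRUE, stringsAsFactors = FALSE)
    }))
  }
  placed <- rbind(as.matrix(core[, c("x", "y", "z")]),
                  if (!is.null(extra)) as.matrix(extra[, c("x", "y", "z")]))

  lig_atom_name <- function(code) {
    switch(code, CYS = "SG", HIS = "ND1", ASP = "OD1", SER = "OG", "CB")
  }
  n_lig <- length(spec$ligands)
  # interleave ligands into the chain so sequence neighborhoods vary
  n_shell <- length(spec$residues)
  total <- n_lig + n_shell
  lig_pos <- unique(pmin(round(seq(2, total - 1, length.out = n_lig)), total))
  while (length(lig_pos) < n_lig)
    lig_pos <- sort(unique(c(lig_pos, setdiff(seq_len(total), lig_pos)[1])))
  lig_pos <- sort(lig_pos[seq_len(n_lig)])
  seq_codes <- character(total)
  seq_codes[lig_pos] <- spec$ligands
  seq_codes[-lig_pos] <- spec$residues
  shell_of <- rep(NA_real_, total)
  shell_of[-lig_pos] <- spec$shells

  atoms <- list()
  eleno <- nrow(core)
  add_atom <- function(elety, element, xyz, resid, resno, het = FALSE) {
    eleno <<- eleno + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      eleno = eleno, elety = elety, resid = resid, chain = "A", resno = resno,
      insert = "", x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, altloc = "",
      element = element, het = het, stringsAsFactors = FALSE)
  }
  clash_free <- function(xyz, min_d = 1.5) {
    all(.min_dist2_to_points(matrix(xyz, 1), placed) >= min_d^2)
  }

  lig_i <- 0L
  gt_rows <- list()
  for (i in seq_len(total)) {
    code <- seq_codes[i]
    is_lig <- i %in% lig_pos
    ok <- FALSE
    for (try in 1:200) {
      if (is_lig) {
        lig_fe <- fe_xyz[((lig_i) %% nrow(fe_xyz)) + 1L, ]
        u0 <- if (sum(lig_fe^2) > 1e-9) lig_fe / sqrt(sum(lig_fe^2)) else .unit_vec()
        u <- u0 + 0.8 * .unit_vec()
        u <- u / sqrt(sum(u^2))
        anchor <- lig_fe + 2.3 * u
      } else {
        u <- .unit_vec()
        anchor <- spec$shells[match(i, setdiff(seq_len(total), lig_pos))] * u
        # exact radial placement: nearest atom sits at the shell distance
        anchor <- shell_of[i] * u
      }
      t1 <- .tangent(u)
      t2 <- c(u[2] * t1[3] - u[3] * t1[2],
              u[3] * t1[1] - u[1] * t1[3],
              u[1] * t1[2] - u[2] * t1[1])
      if (is_lig) {
        cb <- anchor + 1.8 * u
        ca <- cb + 1.5 * u
      } else {
        ca <- anchor
        cb <- ca + 1.5 * u + 1.2 * t2
      }
      nn <- ca + 1.4 * u + 0.6 * t1
      cc <- ca + 1.4 * u - 0.6 * t1
      oo <- cc + 1.2 * u
      coords <- rbind(anchor, if (code != "GLY") cb, ca, nn, cc, oo)
      if (all(apply(coords, 1, clash_free))) { ok <- TRUE; break }
    }
    if (!ok) stop("impossible placement: could not position residue ", i,
                  " without atom overlap")
    resno <- i
    if (is_lig) {
      lig_i <- lig_i + 1L
      add_atom(lig_atom_name(code), substr(lig_atom_name(code), 1, 1),
               anchor, code, resno)
      if (code != "GLY") add_atom("CB", "C", cb, code, resno)
      add_atom("CA", "C", ca, code, resno)
    } else {
      add_atom("CA", "C", ca, code, resno)
      if (code != "GLY") add_atom("CB", "C", cb, code, resno)
    }
    add_atom("N", "N", nn, code, resno)
    add_atom("C", "C", cc, code, resno)
    add_atom("O", "O", oo, code, resno)
    res_xyz <- rbind(anchor, ca, if (code != "GLY") cb, nn, cc, oo)
    placed <- rbind(placed, res_xyz)
    d_cof <- apply(as.matrix(core[, c("x", "y", "z")]), 1, function(p)
      sqrt(min(.min_dist2_to_points(res_xyz, matrix(p, 1)))))
    gt_rows[[i]] <- data.frame(
      key = paste("A", resno, "", sep = ":"), resno = resno, resid = code,
      is_ligand = is_lig,
      bary_dist = sqrt(min(rowSums(res_xyz^2))),
      t(stats::setNames(d_cof, paste0("d_", core$elety))),
      stringsAsFactors = FALSE)
  }
  core_atoms <- data.frame(
    eleno = seq_len(nrow(core)), elety = core$elety, resid = core$resid,
    chain = "A", resno = total + 10L, insert = "",
    x = core$x, y = core$y, z = core$z, occ = 1, altloc = "",
    element = core$element, het = TRUE, stringsAsFactors = FALSE)
  all_atoms <- rbind(do.call(rbind, atoms), core_atoms, extra)
  xyz <- as.matrix(all_atoms[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  diag(dmat) <- Inf
  if (min(dmat) < 0.8)
    stop("impossible placement: atoms closer than 0.8 A")
  st <- new_fes_structure(all_atoms, id = spec$id,
                          resolution = spec$resolution)
  gt <- do.call(rbind, gt_rows)
  rownames(gt) <- NULL
  list(structure = st, ground_truth = gt)
}

#' Substitute residues of a toy structure at fixed coordinates
#'
#' Realizes a synthetic mutant: the residue three-letter codes at the given
#' positions are replaced, coordinates untouched (no repacking — descriptors
#' depend on identity and geometry only). Glycine targets drop the CB atom.
#'
#' @param structure an `fes_structure` from [make_toy_structure()].
#' @param resno residue numbers to substitute.
#' @param new_codes replacement three-letter codes, recycled to `length(resno)`.
#' @param id identifier of the mutant structure.
#' @return the mutated `fes_structure`.
#' @export
mutate_structure <- function(structure, resno, new_codes, id = NULL) {
  new_codes <- rep(new_codes, length.out = length(resno))
  stopifnot(all(new_codes %in% .aa_codes))
  a <- structure$atoms
  drop <- logical(nrow(a))
  for (i in seq_along(resno)) {
    sel <- !a$het & a$resno == resno[i]
    if (!any(sel)) stop("no residue with resno ", resno[i])
    a$resid[sel] <- new_codes[i]
    if (new_codes[i] == "GLY") drop <- drop | (sel & a$elety == "CB")
  }
  a <- a[!drop, , drop = FALSE]
  new_fes_structure(a, id = if (is.null(id)) paste0(structure$id, "_mut")
                    else id,
                    resolution = structure$resolution)
}

#' Specification of a synthetic reduction-potential data set
#'
#' Defines the generative model `RP = b0 + sum(w * feature) + Normal(0, sigma)`
#' over strategy-A schema features, together with the population of toy
#' proteins and mutants the entries are drawn from.
#'
#' @param n_proteins number of wild-type toy proteins.
#' @param mutants_per_protein synthetic mutants per protein (1-2 residue
#'   substitutions at fixed coordinates).
#' @param ph_per_entry measurements per structure, each at its own pH.
#' @param support character vector of schema feature names carrying signal.
#' @param weights numeric weights (mV per feature unit), same length.
#' @param sigma measurement noise standard deviation, mV.
#' @param ph_range range the per-entry pH is drawn from.
#' @param r1,r2 radii (Angstrom) at which the generative features are computed.
#' @param seed integer seed.
#' @return object of class `synthetic_rp_spec`.
#' @export
synthetic_rp_spec <- function(n_proteins = 50, mutants_per_protein = 2,
                              ph_per_entry = 2,
                              support = c("Global.pH",
                                          "Protein.n.aromatic",
                                          "Global.Inv.FAD.whole",
                                          "Global.Inv.HEM.whole",
                                          "AroundFe.sum.steric.flex"),
                              weights = c(-30, 25, 60, -55, -35),
                              sigma = 20, ph_range = c(4, 9),
                              r1 = 11, r2 = 4, seed = 1) {
  stopifnot(length(support) == length(weights), sigma >= 0,
            n_proteins >= 1, mutants_per_protein >= 0)
  structure(list(n_proteins = n_proteins,
                 mutants_per_protein = mutants_per_protein,
                 ph_per_entry = ph_per_entry, support = support,
                 weights = weights, sigma = sigma, ph_range = ph_range,
                 r1 = r1, r2 = r2, seed = seed),
            class = "synthetic_rp_spec")
}

.one_letter <- function(code) .aa_property_table[code, "one.letter"]

#' Generate a synthetic reduction-potential data set
#'
#' Builds `n_proteins` toy wild-type structures (a mix of \[2Fe-2S\] and
#' mononuclear sites) plus their mutants, featurizes every structure at the
#' spec's radii, and draws reduction potentials from the linear generative
#' model `RP = b0 + X[, support] %*% weights + Normal(0, sigma)`. Entries
#' carry parent-protein group ids for leakage-aware splits, protein classes,
#' nominal resolutions and technique labels, in the same table dialect
#' [load_dataset()] reads.
#'
#' @param spec a [synthetic_rp_spec()].
#' @return list with `entries` (data.frame), `structures` (named list of
#'   `fes_structure`), `X` (entry-aligned strategy-A design matrix), `schema`,
#'   `true` (list: `support`, `weights`, `intercept`, `sigma`), and
#'   `true_fun(X)` returning the noise-free RP of feature rows.
#' @export
make_synthetic_dataset <- function(spec = synthetic_rp_spec()) {
  stopifnot(inherits(spec, "synthetic_rp_spec"))
  schema <- feature_schema("A", r1 = spec$r1, r2 = spec$r2)
  missing <- setdiff(spec$support, schema$name)
  if (length(missing))
    stop("support features absent from schema: ",
         paste(missing, collapse = ", "))
  structures <- list()
  meta <- list()
  for (p in seq_len(spec$n_proteins)) {
    kind <- if (p %% 4 == 0) "mono_fe" else "fe2s2"
    # larger proteins carry other cofactors: 0-2 flavins and 0-2 hemes in the
    # periphery, shared between a wild type and its mutants
    set.seed(spec$seed * 1000L + p + 900L)
    n_fad <- sample(0:2, 1)
    n_hem <- sample(0:2, 1)
    extras <- if (n_fad + n_hem > 0) data.frame(
      code = c(rep("FAD", n_fad), rep("HEM", n_hem)),
      distance = round(stats::runif(n_fad + n_hem, 15, 25), 2),
      stringsAsFactors = FALSE) else NULL
    wt_spec <- toy_structure_spec(site_kind = kind,
                                  seed = spec$seed * 1000L + p,
                                  extra_cofactors = extras,
                                  id = sprintf("prot%02d", p))
    wt <- make_toy_structure(wt_spec)$structure
    structures[[wt$id]] <- wt
    meta[[length(meta) + 1L]] <- data.frame(
      structure = wt$id, protein_id = sprintf("prot%02d", p),
      class = if (kind == "mono_fe") "rubredoxin" else "ferredoxin",
      mutation = "WT", stringsAsFactors = FALSE)
    set.seed(spec$seed * 1000L + p + 500L)
    res <- structure_residues(wt)
    gt <- res[res$is_standard, , drop = FALSE]
    lig_resno <- detect_cluster_sites(wt)[[1]]$coord_residues$resno
    free <- setdiff(gt$resno, lig_resno)
    for (m in seq_len(spec$mutants_per_protein)) {
      k <- sample(1:2, 1)
      pos <- sample(free, k)
      old <- gt$resid[match(pos, gt$resno)]
      new <- vapply(old, function(o) sample(setdiff(.aa_codes, o), 1), "")
      mut_id <- sprintf("prot%02d_m%d", p, m)
      structures[[mut_id]] <- mutate_structure(wt, pos, new, id = mut_id)
      lab <- paste0(.one_letter(old), pos, .one_letter(new), collapse = "+")
      meta[[length(meta) + 1L]] <- data.frame(
        structure = mut_id, protein_id = sprintf("prot%02d", p),
        class = if (kind == "mono_fe") "rubredoxin" else "ferredoxin",
        mutation = lab, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  # structural feature rows, one per structure (pH filled per entry below)
  feat <- lapply(structures, function(s) {
    site <- detect_cluster_sites(s)[[1]]
    featurize(s, site, r1 = spec$r1, r2 = spec$r2, ph = 7, schema = schema)
  })
  set.seed(spec$seed)
  entries <- list()
  X <- matrix(NA_real_, nrow = nrow(meta) * spec$ph_per_entry,
              ncol = nrow(schema), dimnames = list(NULL, schema$name))
  row <- 0L
  for (i in seq_len(nrow(meta))) {
    resolution <- round(stats::runif(1, 1.2, 2.8), 2)
    for (j in seq_len(spec$ph_per_entry)) {
      row <- row + 1L
      ph <- round(stats::runif(1, spec$ph_range[1], spec$ph_range[2]), 2)
      v <- feat[[meta$structure[i]]]
      v["Global.pH"] <- ph
      X[row, ] <- v
      entries[[row]] <- data.frame(
        entry_id = sprintf("%s_ph%d", meta$structure[i], j),
        structure = meta$structure[i],
        site_chain = "A", site_resno = NA_integer_,
        rp_mv = NA_real_, ph = ph, class = meta$class[i],
        technique = sample(c("voltammetry", "potentiometry", "optical"), 1),
        resolution = resolution, mutation = meta$mutation[i],
        protein_id = meta$protein_id[i], stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, entries)
  signal <- drop(X[, spec$support, drop = FALSE] %*% spec$weights)
  intercept <- -60 - mean(signal)
  y <- intercept + signal +
    if (spec$sigma > 0) stats::rnorm(length(signal), 0, spec$sigma) else 0
  entries$rp_mv <- y
  true <- list(support = spec$support, weights = spec$weights,
               intercept = intercept, sigma = spec$sigma)
  true_fun <- function(Xnew)
    intercept + drop(Xnew[, spec$support, drop = FALSE] %*% spec$weights)
  list(entries = entries, structures = structures, X = X, schema = schema,
       true = true, true_fun = true_fun)
}

#' Write a synthetic data set to disk in the curated-table dialect
#'
#' Writes the entry table as CSV and each structure as a PDB file in
#' `dir/structures/`, with the `structure` column pointing at the files, so
#' the on-disk set round-trips through [load_dataset()] and
#' [build_design_matrix()].
#'
#' @param dataset result of [make_synthetic_dataset()].
#' @param dir output directory (created if needed).
#' @return path of the entry table, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  sdir <- file.path(dir, "structures")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  entries <- dataset$entries
  for (id in names(dataset$structures))
    write_structure_pdb(dataset$structures[[id]],
                        file.path(sdir, paste0(id, ".pdb")))
  entries$structure <- file.path("structures",
                                 paste0(entries$structure, ".pdb"))
  path <- file.path(dir, "entries.csv")
  utils::write.csv(entries, path, row.names = FALSE)
  invisible(path)
}
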